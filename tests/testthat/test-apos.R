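test_that("attribute ranking is coverage-descending with lexicographic ties", {
  ctx <- rbind(o1 = c(a = 1, b = 1, c = 1),
               o2 = c(a = 1, b = 0, c = 1),
               o3 = c(a = 1, b = 0, c = 1))
  expect_identical(attribute_ranking(ctx), c("a", "c", "b"))

  eq <- rbind(o1 = c(b = 1, a = 1, c = 1))
  expect_identical(attribute_ranking(eq), c("a", "b", "c"))

  z <- rbind(o1 = c(a = 1, b = 0), o2 = c(a = 1, b = 0))
  expect_identical(attribute_ranking(z), "a")
})

test_that("branches are coverage-ordered intents; universal attributes root every branch", {
  ctx <- rbind(o1 = c(a = 1, b = 1, c = 0),
               o2 = c(a = 1, b = 0, c = 1),
               o3 = c(a = 1, b = 1, c = 1))
  g <- build_apos(ctx)
  # 'a' covers all objects: it is the single level-1 node on every branch
  lvl1 <- g$nodes$id[g$nodes$level == 1]
  expect_length(lvl1, 1)
  expect_identical(g$nodes$attribute[lvl1], "a")
  for (o in c("o1", "o2", "o3"))
    expect_identical(query_branch(g, o)$attributes[1], "a")

  single <- build_apos(rbind(o1 = c(b = 1, a = 1)))
  expect_identical(query_branch(single, "o1")$attributes, c("a", "b"))
})

test_that("branch structure matches brute-force intent enumeration (contexts up to 6 x 6)", {
  set.seed(17)
  for (rep in 1:120) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    ctx <- random_context(n, m, p = runif(1, 0.2, 0.8))
    intents <- apply(ctx, 1, function(r) paste(colnames(ctx)[r == 1], collapse = ","))
    nonempty <- intents[intents != ""]
    g <- suppressWarnings(build_apos(ctx))
    expect_length(g$leaves, length(unique(nonempty)))
    expect_length(g$root_objects, sum(intents == ""))
    # branch contents reconstruct each object's context row exactly
    for (o in rownames(ctx)) {
      br <- query_branch(g, o)
      expect_setequal(br$attributes, colnames(ctx)[ctx[o, ] == 1])
    }
    # objects with identical intents share a branch
    for (leaf in g$leaves)
      expect_length(unique(intents[leaf]), 1)
  }
})

test_that("coverage is non-increasing along every root-to-leaf path", {
  set.seed(23)
  for (rep in 1:20) {
    ctx <- random_context(sample(2:10, 1), sample(2:12, 1))
    g <- suppressWarnings(build_apos(ctx))
    nd <- g$nodes
    for (i in nd$id[nd$parent != 0])
      expect_lte(nd$coverage[i], nd$coverage[nd$parent[i]])
  }
})

test_that("the auxiliary order is extent containment", {
  set.seed(29)
  ctx <- random_context(8, 6, 0.5)
  g <- suppressWarnings(build_apos(ctx))
  for (a in rownames(g$order)) for (b in colnames(g$order)) {
    ea <- which(ctx[, a] == 1); eb <- which(ctx[, b] == 1)
    expect_identical(unname(g$order[a, b]), all(ea %in% eb),
                     info = paste(a, b))
  }
})

test_that("unknown objects are rejected; duplicate rows share branches", {
  ctx <- rbind(o1 = c(a = 1, b = 1), o2 = c(a = 1, b = 1))
  g <- build_apos(ctx)
  expect_identical(query_branch(g, "o1")$objects, c("o1", "o2"))
  expect_error(query_branch(g, "nope"), class = "lookup_error")
})

test_that("level report lists attributes by depth; universal coverage pins level 1", {
  ctx <- rbind(o1 = c(`ROI11-H` = 1, `ROI3-L` = 1),
               o2 = c(`ROI11-H` = 1, `ROI3-L` = 0))
  g <- build_apos(ctx)
  lv <- level_report(g)
  expect_identical(lv[["1"]], "ROI11-H")
  expect_false("ROI11-H" %in% unlist(lv[-1]))

  # face-H common, chest-H rare => face attributes sit at shallower depths
  set.seed(31)
  n <- 40
  ctx2 <- cbind(`ROI9-H` = rbinom(n, 1, 0.9), `ROI10-H` = rbinom(n, 1, 0.85),
                `ROI13-H` = rbinom(n, 1, 0.15), `ROI14-H` = rbinom(n, 1, 0.1),
                `ROI2-L` = rbinom(n, 1, 0.5), `ROI6-L` = rbinom(n, 1, 0.5))
  rownames(ctx2) <- paste0("s", 1:n)
  g2 <- suppressWarnings(build_apos(ctx2))
  face_d <- thermoapos:::mean_attribute_depth(g2, c("ROI9-H", "ROI10-H"))
  chest_d <- thermoapos:::mean_attribute_depth(g2, c("ROI13-H", "ROI14-H"))
  expect_lt(face_d, chest_d)
})

test_that("graph exports are lossless (JSON) and well-formed (DOT, GraphML)", {
  ph <- generate_phantom(small_spec(), seed = 13)
  rs <- segment(filter_background(ph$field), ph$anchors)
  gr <- granulate_roiset(rs)
  noise <- function(g, s) { set.seed(s); flip <- sample(36, 6); g2 <- g
    g2[flip > 18, "high"] <- 1L - g2[flip > 18, "high"]; g2 }
  ctx <- build_formal_context(list(a = gr, b = noise(gr, 1), c = noise(gr, 2)))
  g <- build_apos(ctx)

  jp <- withr::local_tempfile(fileext = ".json")
  export_graph(g, jp, "json")
  back <- read_apos_json(jp)
  expect_identical(back$nodes$attribute, g$nodes$attribute)
  expect_identical(back$nodes$level, g$nodes$level)
  expect_identical(back$edges$from, g$nodes$parent)
  expect_identical(back$edges$to, g$nodes$id)

  dp <- withr::local_tempfile(fileext = ".dot")
  export_graph(g, dp, "dot")
  dot <- readLines(dp)
  expect_identical(dot[1], "digraph apos {")
  expect_identical(dot[length(dot)], "}")
  expect_equal(sum(grepl("->", dot, fixed = TRUE)), nrow(g$nodes))

  gp <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, gp, "graphml")
  if (requireNamespace("xml2", quietly = TRUE)) {
    doc <- xml2::read_xml(gp)
    ns <- xml2::xml_ns(doc)
    expect_equal(length(xml2::xml_find_all(doc, ".//d1:node", ns)),
                 nrow(g$nodes) + 1)  # + root
    expect_equal(length(xml2::xml_find_all(doc, ".//d1:edge", ns)),
                 nrow(g$nodes))
  }
  expect_error(export_graph(g, jp, "svg"))

  # single-branch graph is a linear chain in every format
  lin <- build_apos(rbind(o1 = c(a = 1, b = 1, c = 1)))
  lp <- withr::local_tempfile(fileext = ".json")
  export_graph(lin, lp, "json")
  lb <- read_apos_json(lp)
  expect_identical(lb$edges$from, 0:2)
  expect_identical(lb$edges$to, 1:3)
})
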