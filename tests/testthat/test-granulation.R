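test_that("K selection and deterministic centers follow the background rule", {
  expect_equal(select_k(c(0, 30.1, 33.2)), 4L)
  expect_equal(select_k(c(29.5, 31.0, 33.0)), 3L)
  expect_equal(select_k(c(0, 0, 0)), 4L)

  expect_equal(init_centers(c(0, 28, 30, 34), 4L), c(0, 28, 92 / 3, 34))
  expect_equal(init_centers(c(28, 30, 34), 3L), c(28, 92 / 3, 34))
  expect_error(init_centers(c(0, 0, 0), 4L), class = "degenerate_roi_error")
})

test_that("Lloyd iterations converge to the contiguous-partition optimum", {
  # fixed point: values equal to the initial centers
  v <- rep(c(28, 30, 34), each = 3)
  out <- kmeans_1d(v, c(28, 30, 34))
  expect_equal(out$centers, c(28, 30, 34))
  expect_equal(out$sizes, c(3L, 3L, 3L))

  # the worked small instance
  v2 <- c(0, 0, 27.9, 28.1, 30.0, 33.9, 34.1)
  out2 <- kmeans_1d(v2, init_centers(v2, select_k(v2)))
  expect_equal(sort(out2$means[out2$sizes > 0]), c(0, 28, 30, 34))
  expect_equal(sort(out2$means[out2$sizes > 0]),
               contiguous_kmeans_oracle(v2, 4L))

  # mixture instances up to 200 values against the DP oracle
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(30:200, 1)
    K <- if (rep %% 2 == 0) 3L else 4L
    mus <- sort(runif(3, 27, 35))
    while (min(diff(mus)) < 1.8) mus <- sort(runif(3, 27, 35))
    vals <- rnorm(n, sample(mus, n, replace = TRUE), 0.25)
    if (K == 4L) vals <- c(rep(0, sample(5:40, 1)), vals)
    res <- kmeans_1d(vals, init_centers(vals, K))
    expect_equal(sort(res$means[res$sizes > 0]),
                 contiguous_kmeans_oracle(vals, K), tolerance = 1e-8)
  }
  expect_error(kmeans_1d(c(1, NA), c(1)), class = "input_error")
})

test_that("clustering is bitwise deterministic", {
  set.seed(12)
  v <- c(rep(0, 20), rnorm(150, 31, 2))
  a <- kmeans_1d(v, init_centers(v, 4L))
  b <- kmeans_1d(v, init_centers(v, 4L))
  expect_identical(a, b)
})

test_that("whole-body thresholds average the extreme nonzero cluster means", {
  mk <- function(means) structure(list(means = means, sizes = rep(1L, length(means)),
                                       centers = means, assignment = seq_along(means)),
                                  class = "cluster_outcome")
  same <- setNames(replicate(18, mk(c(28, 30, 34)), simplify = FALSE),
                   paste0("ROI", 1:18))
  thr <- global_thresholds(same)
  expect_equal(thr$tbar_min, 28)
  expect_equal(thr$tbar_max, 34)

  odd <- same
  odd$ROI7 <- mk(c(26, 29, 37))
  thr2 <- global_thresholds(odd)
  expect_equal(thr2$tbar_min, (17 * 28 + 26) / 18)
  expect_equal(thr2$tbar_max, (17 * 34 + 37) / 18)

  # tbar_min <= tbar_max on random outcomes
  set.seed(6)
  for (i in 1:25) {
    rnd <- setNames(replicate(18, mk(sort(runif(3, 25, 38))), simplify = FALSE),
                    paste0("ROI", 1:18))
    t3 <- global_thresholds(rnd)
    expect_lte(t3$tbar_min, t3$tbar_max)
  }

  bad <- same
  bad$ROI4 <- mk(c(0))
  expect_error(global_thresholds(bad), class = "degenerate_roi_error")
  expect_error(global_thresholds(bad), "ROI4")
})

test_that("attribute rule uses inclusive boundaries on the nonzero cluster means", {
  mk <- function(means) structure(list(means = means, sizes = rep(1L, length(means)),
                                       centers = means, assignment = seq_along(means)),
                                  class = "cluster_outcome")
  thr <- structure(list(tbar_min = 28.0, tbar_max = 33.0),
                   class = "global_thresholds")
  expect_identical(granulate_roi(mk(c(28.0, 30)), thr), c(low = 1L, high = 0L))
  expect_identical(granulate_roi(mk(c(29, 33.0)), thr), c(low = 0L, high = 1L))
  thr2 <- structure(list(tbar_min = 28.5, tbar_max = 33.0),
                    class = "global_thresholds")
  expect_identical(granulate_roi(mk(c(29, 31)), thr2), c(low = 0L, high = 0L))
})

test_that("identical ROIs everywhere fire both attributes everywhere", {
  # every ROI equal => every ROI matches the global means on both sides
  vals <- c(rep(0, 10), rep(c(28, 30, 34), each = 20))
  outcomes <- setNames(lapply(1:18, function(i)
    kmeans_1d(vals, init_centers(vals, 4L))), paste0("ROI", 1:18))
  thr <- global_thresholds(outcomes)
  pairs <- t(vapply(outcomes, granulate_roi, integer(2), thresholds = thr))
  expect_true(all(pairs == 1L))
})

test_that("formal context assembles as N x 36 with stable ordering", {
  ph <- generate_phantom(small_spec(), seed = 3)
  rs <- segment(filter_background(ph$field), ph$anchors)
  gr <- granulate_roiset(rs)
  expect_identical(dim(gr), c(18L, 2L))

  ctx <- build_formal_context(list(s1 = gr, s2 = gr, s3 = gr))
  expect_identical(dim(unclass(ctx)), c(3L, 36L))
  expect_identical(rownames(ctx), c("s1", "s2", "s3"))
  expect_identical(colnames(ctx)[1:4], c("ROI1-H", "ROI1-L", "ROI2-H", "ROI2-L"))
  expect_identical(colnames(ctx)[35:36], c("ROI18-H", "ROI18-L"))
  expect_true(all(ctx %in% 0:1))
  expect_identical(ctx["s1", "ROI5-H"], unname(gr["ROI5", "high"]))

  one <- build_formal_context(list(gr))
  expect_identical(dim(unclass(one)), c(1L, 36L))

  incomplete <- gr[1:17, ]
  expect_error(build_formal_context(list(s1 = incomplete)), class = "validation_error")
})

test_that("context round-trips through CSV and exports Burmeister", {
  ph <- generate_phantom(small_spec(), seed = 3)
  rs <- segment(filter_background(ph$field), ph$anchors)
  gr <- granulate_roiset(rs)
  ctx <- build_formal_context(list(a = gr, b = gr))
  p <- withr::local_tempfile(fileext = ".csv")
  write_context_csv(ctx, p)
  back <- read_context_csv(p)
  expect_identical(unclass(back)[, ], unclass(ctx)[, ])

  bp <- withr::local_tempfile(fileext = ".cxt")
  write_context_burmeister(ctx, bp)
  lines <- readLines(bp)
  expect_identical(lines[1], "B")
  expect_identical(lines[3:4], c("2", "36"))
  expect_match(lines[length(lines)], "^[X.]{36}$")
})
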