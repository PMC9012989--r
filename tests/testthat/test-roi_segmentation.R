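filtered_phantom <- function(seed = 42, spec = small_spec()) {
  ph <- generate_phantom(spec, seed = seed)
  list(ph = ph, filt = filter_background(ph$field))
}

test_that("anchor validation enforces presence, bounds, distinctness, ordering", {
  fx <- filtered_phantom()
  expect_silent(validate_anchors(fx$ph$anchors, fx$filt))

  a <- unclass(fx$ph$anchors)
  bad <- a; bad["Pur_9", ] <- a["Pur_10", ] + c(5, 0)  # forehead below chin
  expect_error(validate_anchors(anchor_set(bad), fx$filt), class = "validation_error")

  oob <- a; oob["Pur_1", ] <- c(-1, 5)
  expect_error(validate_anchors(anchor_set(oob), fx$filt), class = "validation_error")

  dup <- a; dup["Pur_1", ] <- dup["Pur_2", ]
  expect_error(validate_anchors(anchor_set(dup), fx$filt), class = "validation_error")

  expect_error(anchor_set(a[1:11, ]), class = "validation_error")

  onbg <- a; onbg["Pur_1", ] <- c(2, 2)  # background corner, but rows still ordered
  expect_warning(validate_anchors(anchor_set(onbg), fx$filt),
                 class = "thermoapos_warning")
})

test_that("body boundary equals a linear scan of nonzero positions", {
  m <- matrix(0, 5, 5)
  m[3, 3:4] <- c(31, 32)
  f <- temperature_field(m)
  expect_equal(body_boundary(f, "row", 3), list(first = 3, last = 4))
  expect_null(body_boundary(f, "row", 1))

  fx <- filtered_phantom()
  for (r in seq(1, fx$filt$rows, by = 17)) {
    nz <- which(fx$filt$values[r, ] != 0)
    bb <- body_boundary(fx$filt, "row", r)
    if (length(nz)) expect_equal(bb, list(first = min(nz), last = max(nz)))
    else expect_null(bb)
  }
  for (cl in seq(1, fx$filt$cols, by = 23)) {
    nz <- which(fx$filt$values[, cl] != 0)
    bb <- body_boundary(fx$filt, "col", cl)
    if (length(nz)) expect_equal(bb, list(first = min(nz), last = max(nz)))
    else expect_null(bb)
  }
})

test_that("segmentation yields exactly 18 labelled ROIs with the mapped anchors", {
  fx <- filtered_phantom()
  rs <- segment(fx$filt, fx$ph$anchors)
  expect_length(rs, 18)
  expect_identical(names(rs), paste0("ROI", 1:18))
  expect_true(all(vapply(rs, function(q) length(q$temps) > 0, logical(1))))
  governance <- list(
    ROI1 = "Pur_1", ROI2 = c("Pur_1", "Pur_2"), ROI3 = "Pur_2",
    ROI4 = c("Pur_2", "Pur_3", "Pur_4"), ROI5 = "Pur_5",
    ROI6 = c("Pur_5", "Pur_6"), ROI7 = "Pur_6",
    ROI8 = c("Pur_6", "Pur_7", "Pur_8"),
    ROI9 = c("Pur_9", "Pur_10"), ROI10 = c("Pur_9", "Pur_10"),
    ROI11 = c("Pur_4", "Pur_8", "Pur_10"), ROI12 = c("Pur_4", "Pur_8", "Pur_10"),
    ROI13 = c("Pur_3", "Pur_4", "Pur_7", "Pur_8", "Pur_11"),
    ROI14 = c("Pur_3", "Pur_4", "Pur_7", "Pur_8", "Pur_11"),
    ROI15 = c("Pur_4", "Pur_8", "Pur_11"), ROI16 = c("Pur_4", "Pur_8", "Pur_11"),
    ROI17 = c("Pur_11", "Pur_12"), ROI18 = c("Pur_11", "Pur_12"))
  for (lab in names(governance))
    expect_identical(rs[[lab]]$anchors, governance[[lab]])
})

test_that("default geometry reproduces hand-computed vertices on a block body", {
  m <- matrix(0, 40, 40)
  m[5:35, 10:30] <- 33
  f <- temperature_field(m)
  a <- anchor_set(rbind(
    Pur_1 = c(24, 11), Pur_2 = c(18, 11), Pur_3 = c(14, 11), Pur_4 = c(12, 12),
    Pur_5 = c(24, 29), Pur_6 = c(18, 29), Pur_7 = c(14, 29), Pur_8 = c(12, 28),
    Pur_9 = c(6, 20), Pur_10 = c(10, 20), Pur_11 = c(25, 20), Pur_12 = c(32, 20)))
  # expected (r1, r2, c1, c2) bands, derived once by executing the documented
  # rules by hand on this layout
  expected <- list(
    ROI1 = c(24, 35, 10, 30), ROI2 = c(18, 24, 10, 30), ROI3 = c(16, 20, 9, 13),
    ROI4 = c(12, 18, 10, 30), ROI5 = c(24, 35, 10, 30), ROI6 = c(18, 24, 10, 30),
    ROI7 = c(16, 20, 27, 31), ROI8 = c(12, 18, 10, 30),
    ROI9 = c(6, 10, 10, 20), ROI10 = c(6, 10, 20, 30),
    ROI11 = c(10, 12, 12, 20), ROI12 = c(10, 12, 20, 28),
    ROI13 = c(12, 19, 11, 20), ROI14 = c(12, 19, 20, 29),
    ROI15 = c(19, 25, 12, 20), ROI16 = c(19, 25, 20, 28),
    ROI17 = c(25, 32, 10, 20), ROI18 = c(25, 32, 20, 30))
  quads <- compute_roi_quads(a, f)
  for (lab in names(expected)) {
    e <- expected[[lab]]
    v <- quads[[lab]]$vertices
    expect_equal(range(v[, "row"]), e[1:2], info = lab)
    expect_equal(range(v[, "col"]), e[3:4], info = lab)
  }
})

test_that("ROI rasterization agrees with a per-pixel even-odd oracle", {
  fx <- filtered_phantom()
  rs <- segment(fx$filt, fx$ph$anchors)
  for (lab in c("ROI3", "ROI9", "ROI13")) {
    q <- rs[[lab]]
    n_oracle <- 0L
    v <- q$vertices
    for (r in floor(min(v[, 1])):ceiling(max(v[, 1])))
      for (cl in floor(min(v[, 2])):ceiling(max(v[, 2])))
        if (pip_oracle(r, cl, v)) n_oracle <- n_oracle + 1L
    expect_equal(length(q$temps), n_oracle, info = lab)
  }
  # a genuinely non-rectangular quad against the same oracle
  poly <- structure(list(label = "Q", body_part = "q", anchors = "Pur_1",
                         vertices = cbind(row = c(10, 14, 30, 22),
                                          col = c(20, 38, 30, 12))),
                    class = "roi_quad")
  got <- length(extract_roi(fx$filt, poly))
  n_oracle <- sum(vapply(1:40, function(r)
    sum(vapply(1:40, function(cl) pip_oracle(r, cl, poly$vertices), logical(1))),
    numeric(1)))
  expect_equal(got, n_oracle)
})

test_that("extract_roi keeps zeros, errors only on empty enclosure", {
  m <- matrix(0, 6, 6); m[3, 3] <- 33
  f <- temperature_field(m)
  unit <- structure(list(label = "U", body_part = "u", anchors = "Pur_1",
                         vertices = cbind(row = c(2.6, 2.6, 3.4, 3.4),
                                          col = c(2.6, 3.4, 3.4, 2.6))),
                    class = "roi_quad")
  expect_equal(extract_roi(f, unit), 33)
  bgq <- structure(list(label = "B", body_part = "b", anchors = "Pur_1",
                        vertices = cbind(row = c(1, 1, 2, 2), col = c(1, 2, 2, 1))),
                   class = "roi_quad")
  expect_identical(extract_roi(f, bgq), rep(0, 4))
  tiny <- structure(list(label = "T", body_part = "t", anchors = "Pur_1",
                         vertices = cbind(row = c(2.1, 2.1, 2.4, 2.4),
                                          col = c(2.1, 2.4, 2.4, 2.1))),
                    class = "roi_quad")
  expect_error(extract_roi(f, tiny), class = "empty_roi_error")
})

test_that("mirrored input swaps left/right ROI contents exactly", {
  fx <- filtered_phantom(seed = 77)
  rs <- segment(fx$filt, fx$ph$anchors)
  mir <- mirror_phantom(list(field = fx$filt, anchors = fx$ph$anchors,
                             spec = fx$ph$spec))
  rs_m <- segment(mir$field, mir$anchors)
  for (i in seq_len(nrow(roi_mirror_pairs()))) {
    pr <- roi_mirror_pairs()[i, ]
    expect_identical(sort(rs_m[[pr[1]]]$temps), sort(rs[[pr[2]]]$temps),
                     info = paste(pr, collapse = "<->"))
    expect_identical(sort(rs_m[[pr[2]]]$temps), sort(rs[[pr[1]]]$temps),
                     info = paste(pr, collapse = "<->"))
  }
})

test_that("cropped-out limbs raise a labelled segmentation error", {
  fx <- filtered_phantom()
  vals <- fx$filt$values
  vals[, 1:56] <- 0  # erase the participant-right arm columns
  cropped <- temperature_field(vals)
  expect_error(suppressWarnings(segment(cropped, fx$ph$anchors)),
               class = "segmentation_error")
  expect_error(suppressWarnings(segment(cropped, fx$ph$anchors)), "ROI1")
})
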