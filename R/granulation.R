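#' Choose the number of clusters for an ROI
#'
#' ROIs whose quadrilateral overlaps the background contain exact zeros and
#' get an extra cluster to absorb them: `K = 4` iff any value equals 0,
#' otherwise `K = 3` (high / medium / low temperature).
#'
#' @param values numeric temperature multiset of one ROI (degC).
#' @return 3L or 4L.
#' @export
select_k <- function(values) {
  if (!length(values)) ta_error("empty ROI", "degenerate_roi_error")
  if (any(values == 0)) 4L else 3L
}

#' Deterministic initial cluster centers
#'
#' `K = 4`: centers at 0, the nonzero minimum, nonzero mean and nonzero
#' maximum. `K = 3`: minimum, mean, maximum. Fixing the initialization to
#' the data's own distribution features removes the run-to-run variability
#' of randomly seeded K-means.
#'
#' @inheritParams select_k
#' @param K result of [select_k()].
#' @return Numeric vector of K centers (degC), in the order above.
#' @export
init_centers <- function(values, K) {
  if (K == 4L) {
    nz <- values[values != 0]
    if (!length(nz))
      ta_error("ROI contains no nonzero values: granulation undefined",
               "degenerate_roi_error")
    c(0, min(nz), mean(nz), max(nz))
  } else if (K == 3L) {
    c(min(values), mean(values), max(values))
  } else ta_error("K must be 3 or 4", "parameter_error")
}

#' One-dimensional K-means with fixed initialization
#'
#' Lloyd iterations from the given centers: assign each value to the
#' nearest center (ties to the lower-index center), recompute centers as
#' cluster means (an empty cluster keeps its previous center), stop when the
#' largest center shift is below `tol` or after `max_iter` iterations.
#' Identical inputs always give bitwise-identical outcomes.
#'
#' @param values finite numeric vector.
#' @param centers initial centers, e.g. from [init_centers()].
#' @param max_iter iteration cap (default 300).
#' @param tol convergence tolerance on center movement in degC (default 1e-6).
#' @return An object of class `cluster_outcome`: `centers` (final), `means`
#'   (exact per-cluster means, `NA` for empty clusters), `sizes`,
#'   `assignment` and `iterations`.
#' @export
kmeans_1d <- function(values, centers, max_iter = 300L, tol = 1e-6) {
  if (!length(values) || !all(is.finite(values)))
    ta_error("values must be a nonempty finite vector", "input_error")
  if (!length(centers) || !all(is.finite(centers)))
    ta_error("centers must be finite", "input_error")
  K <- length(centers)
  assign_pts <- function(ctr) max.col(-abs(outer(values, ctr, "-")),
                                      ties.method = "first")
  it <- 0L
  repeat {
    it <- it + 1L
    a <- assign_pts(centers)
    new_centers <- vapply(seq_len(K), function(k)
      if (any(a == k)) mean(values[a == k]) else centers[k], numeric(1))
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol || it >= max_iter) break
  }
  a <- assign_pts(centers)
  sizes <- tabulate(a, K)
  means <- vapply(seq_len(K), function(k)
    if (sizes[k] > 0L) mean(values[a == k]) else NA_real_, numeric(1))
  structure(list(centers = centers, means = means, sizes = sizes,
                 assignment = a, iterations = it),
            class = "cluster_outcome")
}

#' @export
print.cluster_outcome <- function(x, ...) {
  cat("<cluster_outcome>\n")
  print(data.frame(center = x$centers, mean = x$means, size = x$sizes))
  invisible(x)
}

# mean temperatures of the nonempty, nonzero clusters, ascending
nonzero_cluster_means <- function(outcome) {
  m <- outcome$means[outcome$sizes > 0L & !is.na(outcome$means) & outcome$means > 0]
  sort(unique(m))
}

# full clustering of one ROI's raw multiset
cluster_roi <- function(values, max_iter = 300L, tol = 1e-6) {
  K <- select_k(values)
  kmeans_1d(values, init_centers(values, K), max_iter = max_iter, tol = tol)
}

#' Whole-body granulation thresholds
#'
#' `tbar_min` is the mean over the 18 ROIs of each ROI's smallest nonzero
#' cluster mean; `tbar_max` the mean of each ROI's largest nonzero cluster
#' mean. These whole-body references decide which ROIs carry the dominant
#' low/high temperature attributes.
#'
#' @param outcomes named list of 18 [kmeans_1d()] outcomes (one per ROI).
#' @return An object of class `global_thresholds` with `tbar_min <= tbar_max`.
#' @export
global_thresholds <- function(outcomes) {
  troi <- lapply(outcomes, nonzero_cluster_means)
  bad <- vapply(troi, length, 0L) == 0L
  if (any(bad))
    ta_error(sprintf("degenerate ROI(s) with no nonzero cluster: %s",
                     paste(names(outcomes)[bad], collapse = ", ")),
             "degenerate_roi_error")
  structure(list(tbar_min = mean(vapply(troi, min, numeric(1))),
                 tbar_max = mean(vapply(troi, max, numeric(1)))),
            class = "global_thresholds")
}

#' Binary high/low attributes of one ROI
#'
#' The low-temperature attribute fires when the ROI's smallest nonzero
#' cluster mean is at or below the whole-body `tbar_min`; the
#' high-temperature attribute when its largest nonzero cluster mean is at
#' or above `tbar_max`. Boundary equality yields 1 (inclusive comparisons).
#'
#' @param outcome a [kmeans_1d()] outcome for the ROI.
#' @param thresholds a [global_thresholds()] result.
#' @return Named integer vector `c(low = 0/1, high = 0/1)`.
#' @export
granulate_roi <- function(outcome, thresholds) {
  stopifnot(inherits(thresholds, "global_thresholds"))
  troi <- nonzero_cluster_means(outcome)
  if (!length(troi))
    ta_error("ROI has no nonzero cluster", "degenerate_roi_error")
  c(low = as.integer(min(troi) <= thresholds$tbar_min),
    high = as.integer(max(troi) >= thresholds$tbar_max))
}

#' Granulate a segmented ROI set
#'
#' Runs the deterministic clustering on each of the 18 ROIs, derives the
#' whole-body thresholds, and returns the 18 attribute pairs.
#'
#' @param roiset an [segment()] result.
#' @param max_iter,tol clustering controls, see [kmeans_1d()].
#' @return An 18 x 2 integer matrix (columns `low`, `high`; rownames the ROI
#'   labels) with attributes `thresholds` and `outcomes`.
#' @export
granulate_roiset <- function(roiset, max_iter = 300L, tol = 1e-6) {
  stopifnot(inherits(roiset, "roi_set"))
  outcomes <- lapply(roiset, function(q) cluster_roi(q$temps, max_iter, tol))
  thr <- global_thresholds(outcomes)
  pairs <- t(vapply(outcomes, granulate_roi, integer(2), thresholds = thr))
  attr(pairs, "thresholds") <- thr
  attr(pairs, "outcomes") <- outcomes
  pairs
}

#' Assemble the formal context
#'
#' Binds the per-participant attribute pairs into an N x 36 binary incidence
#' table with columns `ROI1-H, ROI1-L, ..., ROI18-H, ROI18-L` and row order
#' equal to input order.
#'
#' @param granulations list (one element per participant) of 18 x 2 matrices
#'   from [granulate_roiset()], with ROI labels as rownames.
#' @param ids character vector of object (participant) identifiers; defaults
#'   to the list names or `obj1 ... objN`.
#' @return An object of class `formal_context`: binary integer matrix with
#'   object ids as rownames.
#' @export
build_formal_context <- function(granulations, ids = NULL) {
  n <- length(granulations)
  if (!n) ta_error("no participants", "validation_error")
  if (is.null(ids))
    ids <- if (!is.null(names(granulations))) names(granulations)
           else paste0("obj", seq_len(n))
  labels <- paste0("ROI", 1:18)
  cols <- as.vector(rbind(paste0(labels, "-H"), paste0(labels, "-L")))
  m <- matrix(0L, n, 36L, dimnames = list(ids, cols))
  for (i in seq_len(n)) {
    g <- granulations[[i]]
    if (is.null(rownames(g)) || !all(labels %in% rownames(g)))
      ta_error(sprintf("participant %s is missing ROI attribute pairs", ids[i]),
               "validation_error")
    m[i, paste0(labels, "-H")] <- as.integer(g[labels, "high"])
    m[i, paste0(labels, "-L")] <- as.integer(g[labels, "low"])
  }
  structure(m, class = c("formal_context", class(m)))
}

#' @export
print.formal_context <- function(x, ...) {
  cat(sprintf("<formal_context> %d objects x %d attributes, density %.2f\n",
              nrow(x), ncol(x), mean(x)))
  invisible(x)
}

#' Write a formal context as CSV or Burmeister FCA format
#'
#' The CSV has the attribute names as header and the object id as first
#' column. The Burmeister format is the plain-text `B` context dialect used
#' by formal-concept-analysis tools.
#'
#' @param context a [build_formal_context()] result.
#' @param path output path.
#' @export
write_context_csv <- function(context, path) {
  df <- data.frame(object = rownames(context), unclass(context),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_context_csv
#' @export
read_context_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  structure(m, class = c("formal_context", class(m)))
}

#' @rdname write_context_csv
#' @export
write_context_burmeister <- function(context, path) {
  lines <- c("B", "", nrow(context), ncol(context), "",
             rownames(context), colnames(context),
             apply(context, 1, function(r) paste(ifelse(r == 1, "X", "."),
                                                 collapse = "")))
  writeLines(as.character(lines), path)
  invisible(path)
}
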