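#' Pipeline configuration
#'
#' All tunable numeric choices of the pipeline in one place, so every
#' default is visible and overridable.
#'
#' @param bin_width histogram bin width, degC (default 0.1).
#' @param smooth_size Gaussian operator size (odd, default 5).
#' @param min_prominence_frac peak prominence floor (default 0.05).
#' @param threshold_mode `"midpoint"` or `"segment-median"`.
#' @param geometry ROI geometry table (default [roi_geometry()]).
#' @param max_iter,tol K-means controls.
#' @param pool_features pool face/chest pixels across sides (default TRUE).
#' @param dialect [raw_grid_dialect()] for file-based manifests.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(bin_width = 0.1, smooth_size = 5L,
                            min_prominence_frac = 0.05,
                            threshold_mode = "midpoint",
                            geometry = roi_geometry(),
                            max_iter = 300L, tol = 1e-6,
                            pool_features = TRUE,
                            dialect = raw_grid_dialect()) {
  structure(list(bin_width = bin_width, smooth_size = smooth_size,
                 min_prominence_frac = min_prominence_frac,
                 threshold_mode = threshold_mode, geometry = geometry,
                 max_iter = max_iter, tol = tol,
                 pool_features = pool_features, dialect = dialect),
            class = "pipeline_config")
}

#' Process one participant
#'
#' filter -> validate anchors -> segment -> granulate -> difference
#' features, for a single field/anchor pair.
#'
#' @param field a raw [temperature_field()].
#' @param anchors an [anchor_set()].
#' @param config a [pipeline_config()].
#' @return List with `pairs` (18 x 2 attribute matrix), `deltas`
#'   (face-chest features) and `threshold`.
#' @export
process_subject <- function(field, anchors, config = pipeline_config()) {
  filt <- filter_background(field, bin_width = config$bin_width,
                            smooth_size = config$smooth_size,
                            min_prominence_frac = config$min_prominence_frac,
                            threshold_mode = config$threshold_mode)
  roiset <- segment(filt, anchors, geometry = config$geometry)
  pairs <- granulate_roiset(roiset, max_iter = config$max_iter, tol = config$tol)
  list(pairs = pairs,
       deltas = face_chest_delta(roiset, pool = config$pool_features),
       threshold = attr(filt, "threshold"))
}

# resolve a cohort manifest entry (in-memory phantom or file paths)
subject_input <- function(cohort, i, config) {
  if (!is.null(cohort$phantoms) && length(cohort$phantoms)) {
    ph <- cohort$phantoms[[cohort$manifest$id[i]]]
    list(field = ph$field, anchors = ph$anchors)
  } else {
    list(field = read_temperature_grid(cohort$manifest$path[i], config$dialect),
         anchors = read_anchors(cohort$manifest$anchor_path[i]))
  }
}

run_group <- function(cohort, config, group_name) {
  n <- nrow(cohort$manifest)
  if (!n) ta_error(sprintf("%s: empty manifest", group_name), "validation_error")
  pairs <- vector("list", n)
  deltas <- matrix(NA_real_, n, 3, dimnames = list(cohort$manifest$id,
                                                   c("d_avg", "d_max", "d_min")))
  for (i in seq_len(n)) {
    id <- cohort$manifest$id[i]
    res <- withCallingHandlers(
      tryCatch({
        inp <- subject_input(cohort, i, config)
        process_subject(inp$field, inp$anchors, config)
      }, thermoapos_error = function(e)
        ta_error(sprintf("[%s / %s] %s", group_name, id, conditionMessage(e)),
                 class(e)[1])),
      thermoapos_warning = function(w) invokeRestart("muffleWarning"))
    pairs[[i]] <- res$pairs
    deltas[i, ] <- res$deltas
  }
  names(pairs) <- cohort$manifest$id
  list(context = build_formal_context(pairs), deltas = as.data.frame(deltas))
}

#' Run the full knowledge-mining pipeline on two cohorts
#'
#' Filters, segments and granulates every participant of both cohorts,
#' assembles one formal context and one APOS graph per group, and computes
#' the face-chest verification statistics (group A minus group B).
#'
#' @param cohort_a,cohort_b `phantom_cohort` objects from
#'   [generate_cohort()], or lists with a `manifest` data.frame pointing at
#'   `.tgrid`/anchor files.
#' @param config a [pipeline_config()].
#' @return An object of class `thermoapos_report`: `context_a`, `context_b`,
#'   `apos_a`, `apos_b`, `levels_a`, `levels_b`, `features_a`, `features_b`,
#'   `stats` (see [verification_stats()]) and the resolved `config`.
#' @export
run_pipeline <- function(cohort_a, cohort_b, config = pipeline_config()) {
  a <- run_group(cohort_a, config, "group A")
  b <- run_group(cohort_b, config, "group B")
  apos_a <- build_apos(a$context)
  apos_b <- build_apos(b$context)
  structure(list(context_a = a$context, context_b = b$context,
                 apos_a = apos_a, apos_b = apos_b,
                 levels_a = level_report(apos_a), levels_b = level_report(apos_b),
                 features_a = a$deltas, features_b = b$deltas,
                 stats = verification_stats(a$deltas, b$deltas),
                 config = config),
            class = "thermoapos_report")
}

#' @export
print.thermoapos_report <- function(x, ...) {
  cat("<thermoapos_report>\n")
  cat(sprintf("  contexts: %d x %d (A), %d x %d (B)\n",
              nrow(x$context_a), ncol(x$context_a),
              nrow(x$context_b), ncol(x$context_b)))
  cat(sprintf("  APOS branches: %d (A), %d (B)\n",
              length(x$apos_a$leaves), length(x$apos_b$leaves)))
  for (f in names(x$stats)) {
    w <- x$stats[[f]]$welch
    cat(sprintf("  %s: diff %.2f degC, Welch t = %.3f (df %.1f), p = %.3g, CI [%.2f, %.2f], power %.3f\n",
                f, w$mean_diff, w$t, w$df, w$p, w$ci[1], w$ci[2],
                x$stats[[f]]$power$power))
  }
  invisible(x)
}

#' Serialize the verification statistics as JSON
#'
#' @param report a [run_pipeline()] result.
#' @param path output path.
#' @export
write_stats_json <- function(report, path) {
  out <- lapply(report$stats, function(s) list(
    welch = s$welch[c("t", "df", "p", "mean_diff", "se", "ci")],
    pooled = s$pooled[c("t", "df", "p", "mean_diff", "se", "ci")],
    selected = s$selected, levene_p = s$levene_p,
    power = s$power$power))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
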