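#' Phantom specification
#'
#' Parameters of the synthetic human-silhouette thermal phantom. The
#' silhouette is a parametric polygon/ellipse template (head, neck, torso,
#' two hanging arms) expressed in fractions of the image size, so the same
#' anatomy renders at any resolution. Defaults emulate the acquisition
#' setting the pipeline assumes: a 256 x 336 grid, ~25 degC ambient
#' background, ~32.5 degC skin baseline, and regional offsets spanning a
#' few degC (warm clavicle fossae and face, cool extremities), which makes
#' the global temperature histogram bimodal.
#'
#' @param rows,cols grid size (default 256 x 336).
#' @param ambient background temperature in degC (default 25.0); must be at
#'   least 4 degC below `body_base` to guarantee bimodality.
#' @param body_base skin baseline temperature in degC (default 32.5).
#' @param region_offsets named length-18 vector of per-ROI offsets (degC)
#'   added to `body_base`.
#' @param noise_sd per-pixel Gaussian noise SD on the body (degC, default 0.3).
#' @param background_sd per-pixel noise SD on the background (default
#'   `noise_sd`).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(rows = 256L, cols = 336L, ambient = 25.0,
                         body_base = 32.5,
                         region_offsets = default_region_offsets(),
                         noise_sd = 0.3, background_sd = noise_sd) {
  if (rows < 64L || cols < 64L)
    ta_error("phantom grid must be at least 64 x 64", "validation_error")
  if (!(ambient < body_base - 4))
    ta_error("ambient must be at least 4 degC below body_base (bimodality)",
             "validation_error")
  if (noise_sd < 0 || background_sd < 0)
    ta_error("noise SDs must be >= 0", "validation_error")
  region_offsets <- region_offsets[paste0("ROI", 1:18)]
  if (any(is.na(region_offsets)))
    ta_error("region_offsets must name all of ROI1 ... ROI18", "validation_error")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 ambient = ambient, body_base = body_base,
                 region_offsets = region_offsets,
                 noise_sd = noise_sd, background_sd = background_sd),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_region_offsets <- function() {
  c(ROI1 = -1.2, ROI2 = -0.6, ROI3 = 0.8, ROI4 = -0.3,     # right arm chain
    ROI5 = -1.2, ROI6 = -0.6, ROI7 = 0.8, ROI8 = -0.3,     # left arm chain
    ROI9 = 1.3, ROI10 = 1.3,                               # face halves
    ROI11 = 2.0, ROI12 = 2.0,                              # clavicle fossae
    ROI13 = 0.4, ROI14 = 0.4,                              # chest
    ROI15 = 0.0, ROI16 = 0.0,                              # upper abdomen
    ROI17 = -0.2, ROI18 = -0.2)                            # lower abdomen
}

# fractional silhouette template; "right" = participant's right, drawn on
# the image-left side
phantom_layout <- function() {
  list(mid = 0.5,
       head = list(cr = 0.16, cc = 0.5, ar = 0.11, ac = 0.06),
       forehead = 0.08, chin = 0.25,
       neck = c(r1 = 0.25, r2 = 0.32, c1 = 0.465, c2 = 0.535),
       torso = c(r1 = 0.31, r2 = 0.82, c1 = 0.36, c2 = 0.64),
       arm_right = c(c1 = 0.28, c2 = 0.335),
       arm_left = c(c1 = 0.665, c2 = 0.72),
       arm_rows = c(r1 = 0.33, r2 = 0.78),
       shoulder_row = 0.32, armpit_row = 0.39,
       elbow_row = 0.55, wrist_row = 0.70,
       belly_row = 0.66, crotch_row = 0.81,
       chest_rows = c(0.34, 0.525), upper_abd_rows = c(0.525, 0.66))
}

#' Generate one thermal phantom
#'
#' Renders the silhouette at `body_base` plus regional offsets plus
#' Gaussian pixel noise over an `ambient` background, places the 12 anchor
#' points at the template's landmark positions, and returns ground-truth
#' masks. Generation is a pure function of `(spec, seed, shifts)`.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed; the caller's RNG state is untouched.
#' @param face_shift extra offset (degC) added to the face regions (used by
#'   [generate_cohort()] to implant a group effect).
#' @param body_shift subject-level baseline shift (degC) added to the whole
#'   body.
#' @return An object of class `thermal_phantom`: `field`
#'   ([temperature_field()]), `anchors` ([anchor_set()]), `truth` (logical
#'   `body` mask and integer `regions` matrix, 0 = unassigned body or
#'   background), and the `spec`, `seed`, `face_shift`, `body_shift` used.
#' @examples
#' ph <- generate_phantom(seed = 42)
#' ph$field
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = 1L,
                             face_shift = 0, body_shift = 0) {
  stopifnot(inherits(spec, "phantom_spec"))
  lay <- phantom_layout()
  R <- spec$rows; C <- spec$cols
  rr <- matrix(seq_len(R), R, C)
  cc <- matrix(seq_len(C), R, C, byrow = TRUE)
  fr <- function(x) round(x * R)   # fractional row -> pixel
  fc <- function(x) round(x * C)

  head <- ((rr - fr(lay$head$cr)) / (lay$head$ar * R))^2 +
    ((cc - fc(lay$head$cc)) / (lay$head$ac * C))^2 <= 1
  neck <- rr >= fr(lay$neck["r1"]) & rr <= fr(lay$neck["r2"]) &
    cc >= fc(lay$neck["c1"]) & cc <= fc(lay$neck["c2"])
  torso <- rr >= fr(lay$torso["r1"]) & rr <= fr(lay$torso["r2"]) &
    cc >= fc(lay$torso["c1"]) & cc <= fc(lay$torso["c2"])
  armr <- rr >= fr(lay$arm_rows["r1"]) & rr <= fr(lay$arm_rows["r2"]) &
    cc >= fc(lay$arm_right["c1"]) & cc <= fc(lay$arm_right["c2"])
  arml <- rr >= fr(lay$arm_rows["r1"]) & rr <= fr(lay$arm_rows["r2"]) &
    cc >= fc(lay$arm_left["c1"]) & cc <= fc(lay$arm_left["c2"])
  body <- head | neck | torso | armr | arml

  midc <- fc(lay$mid)
  regions <- matrix(0L, R, C)
  assign_region <- function(mask, id) regions[mask] <<- id
  # torso bands
  assign_region(torso & rr > fr(lay$chest_rows[1]) & rr <= fr(lay$chest_rows[2]) &
                  cc <= midc, 13L)
  assign_region(torso & rr > fr(lay$chest_rows[1]) & rr <= fr(lay$chest_rows[2]) &
                  cc > midc, 14L)
  assign_region(torso & rr > fr(lay$upper_abd_rows[1]) & rr <= fr(lay$upper_abd_rows[2]) &
                  cc <= midc, 15L)
  assign_region(torso & rr > fr(lay$upper_abd_rows[1]) & rr <= fr(lay$upper_abd_rows[2]) &
                  cc > midc, 16L)
  assign_region(torso & rr > fr(lay$belly_row) & cc <= midc, 17L)
  assign_region(torso & rr > fr(lay$belly_row) & cc > midc, 18L)
  # arm chains (elbow band last so it overrides forearm/upper-arm overlap)
  assign_region(armr & rr <= fr(lay$elbow_row), 4L)
  assign_region(arml & rr <= fr(lay$elbow_row), 8L)
  assign_region(armr & rr > fr(lay$elbow_row) & rr <= fr(lay$wrist_row), 2L)
  assign_region(arml & rr > fr(lay$elbow_row) & rr <= fr(lay$wrist_row), 6L)
  assign_region(armr & rr > fr(lay$wrist_row), 1L)
  assign_region(arml & rr > fr(lay$wrist_row), 5L)
  elbow_half <- fr(0.04)
  assign_region(armr & abs(rr - fr(lay$elbow_row)) <= elbow_half, 3L)
  assign_region(arml & abs(rr - fr(lay$elbow_row)) <= elbow_half, 7L)
  # head and fossae
  assign_region(head & cc <= midc, 9L)
  assign_region(head & cc > midc, 10L)
  assign_region(neck & !head & cc <= midc, 11L)
  assign_region(neck & !head & cc > midc, 12L)

  offsets <- c(0, unname(spec$region_offsets))  # index by region id + 1
  face_ids <- regions == 9L | regions == 10L
  temps <- with_seed(seed, {
    t0 <- matrix(stats::rnorm(R * C, spec$ambient, spec$background_sd), R, C)
    t0[body] <- spec$body_base + body_shift + offsets[regions[body] + 1L] +
      stats::rnorm(sum(body), 0, spec$noise_sd)
    t0[face_ids] <- t0[face_ids] + face_shift
    round(t0, 2)   # detector precision 0.01 degC; matches the file dialect
  })

  a <- lay
  arm_r_mid <- fc((a$arm_right["c1"] + a$arm_right["c2"]) / 2)
  arm_l_mid <- fc((a$arm_left["c1"] + a$arm_left["c2"]) / 2)
  anchors <- anchor_set(rbind(
    Pur_1 = c(fr(a$wrist_row), arm_r_mid),
    Pur_2 = c(fr(a$elbow_row), arm_r_mid),
    Pur_3 = c(fr(a$armpit_row), fc(a$torso["c1"]) + 2L),
    Pur_4 = c(fr(a$shoulder_row), fc(a$torso["c1"]) + 4L),
    Pur_5 = c(fr(a$wrist_row), arm_l_mid),
    Pur_6 = c(fr(a$elbow_row), arm_l_mid),
    Pur_7 = c(fr(a$armpit_row), fc(a$torso["c2"]) - 2L),
    Pur_8 = c(fr(a$shoulder_row), fc(a$torso["c2"]) - 4L),
    Pur_9 = c(fr(a$forehead), midc),
    Pur_10 = c(fr(a$chin), midc),
    Pur_11 = c(fr(a$belly_row), midc),
    Pur_12 = c(fr(a$crotch_row), midc)))

  structure(list(field = temperature_field(temps), anchors = anchors,
                 truth = list(body = body, regions = regions),
                 spec = spec, seed = seed, face_shift = face_shift,
                 body_shift = body_shift),
            class = "thermal_phantom")
}

#' @export
print.thermal_phantom <- function(x, ...) {
  cat(sprintf("<thermal_phantom> %d x %d, %d body px, seed %d\n",
              x$spec$rows, x$spec$cols, sum(x$truth$body), x$seed))
  invisible(x)
}

#' Cohort specification
#'
#' Two-group study design for the synthetic phantoms: per-group size 43 (as
#' in the study the pipeline is designed for), a case-group shift of the
#' face-minus-chest mean difference of 2.74 degC, and a between-subject SD
#' of that difference of 1.53 degC (recovered from a reported SE of 0.33
#' degC at n = 43 per group: SD = SE * sqrt(n / 2)). The case group's shift
#' is implanted in the face regions; a whole-body baseline SD adds
#' subject-level variation that cancels in the difference features.
#'
#' @param n_per_group participants per group (default 43, >= 2).
#' @param effect face-shift of the case group in degC (default 2.74).
#' @param subject_sd between-subject SD of the face shift in degC
#'   (default 1.53).
#' @param baseline_sd between-subject whole-body baseline SD in degC
#'   (default 0.5).
#' @param phantom a [phantom_spec()] shared by all subjects.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 43L, effect = 2.74, subject_sd = 1.53,
                        baseline_sd = 0.5, phantom = phantom_spec()) {
  if (n_per_group < 2L) ta_error("n_per_group must be >= 2", "validation_error")
  if (subject_sd < 0 || baseline_sd < 0)
    ta_error("SDs must be >= 0", "validation_error")
  structure(list(n_per_group = as.integer(n_per_group), effect = effect,
                 subject_sd = subject_sd, baseline_sd = baseline_sd,
                 phantom = phantom),
            class = "cohort_spec")
}

#' Generate a two-group phantom cohort
#'
#' Case subjects receive a face shift drawn from N(effect, subject_sd);
#' controls from N(0, subject_sd); all subjects get a whole-body baseline
#' shift from N(0, baseline_sd). Fully reproducible in `(spec, seed)`.
#'
#' @param spec a [cohort_spec()].
#' @param seed master integer seed.
#' @param dir optional directory: when given, each phantom is written as a
#'   `.tgrid` file with a JSON anchor file, and the manifest gains `path` /
#'   `anchor_path` columns.
#' @return An object of class `phantom_cohort`: `manifest` (data.frame with
#'   `id`, `group` in `"case"`/`"control"`) and `phantoms` (named list of
#'   [generate_phantom()] results, `NULL`ed out when written to `dir`).
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_per_group
  params <- with_seed(seed, {
    list(face = c(stats::rnorm(n, spec$effect, spec$subject_sd),
                  stats::rnorm(n, 0, spec$subject_sd)),
         base = stats::rnorm(2L * n, 0, spec$baseline_sd),
         seeds = sample.int(.Machine$integer.max, 2L * n))
  })
  group <- rep(c("case", "control"), each = n)
  ids <- sprintf("%s_%02d", group, c(seq_len(n), seq_len(n)))
  phantoms <- lapply(seq_len(2L * n), function(i)
    generate_phantom(spec$phantom, seed = params$seeds[i],
                     face_shift = params$face[i], body_shift = params$base[i]))
  names(phantoms) <- ids
  manifest <- data.frame(id = ids, group = group)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    manifest$path <- file.path(dir, paste0(ids, ".tgrid"))
    manifest$anchor_path <- file.path(dir, paste0(ids, "_anchors.json"))
    for (i in seq_along(phantoms)) {
      write_temperature_grid(phantoms[[i]]$field, manifest$path[i])
      write_anchors(phantoms[[i]]$anchors, manifest$anchor_path[i])
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  structure(list(manifest = manifest, phantoms = phantoms, spec = spec,
                 seed = seed),
            class = "phantom_cohort")
}

#' Simulate face-chest difference features directly
#'
#' Feature-level counterpart of [generate_cohort()] for Monte-Carlo studies
#' of the verification statistics: draws each subject's face-minus-chest
#' mean-temperature difference from the between-subject model
#' N(baseline (+ effect for cases), sd) without rendering images.
#'
#' @param n_per_group subjects per group.
#' @param effect case-group shift in degC (default 2.74).
#' @param sd between-subject SD in degC (default 1.53).
#' @param baseline control-group mean difference in degC (default 0.9, the
#'   face-minus-chest offset gap of the default phantom).
#' @param seed integer seed.
#' @return List with numeric vectors `case` and `control`.
#' @export
simulate_delta_features <- function(n_per_group, effect = 2.74, sd = 1.53,
                                    baseline = 0.9, seed = 1L) {
  with_seed(seed, list(
    case = stats::rnorm(n_per_group, baseline + effect, sd),
    control = stats::rnorm(n_per_group, baseline, sd)))
}

#' Split a two-group cohort into per-group cohorts
#'
#' Convenience for feeding [run_pipeline()], whose contract takes one
#' cohort per group.
#'
#' @param cohort a [generate_cohort()] result.
#' @return List with elements `case` and `control`, each pipeline-ready.
#' @export
split_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  one <- function(g) {
    keep <- cohort$manifest$group == g
    list(manifest = cohort$manifest[keep, , drop = FALSE],
         phantoms = cohort$phantoms[cohort$manifest$id[keep]])
  }
  list(case = one("case"), control = one("control"))
}
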