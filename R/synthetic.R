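# Synthetic-data generation: a template pelvis with known ground truth,
# phantom views for the accuracy protocol, and patient cohorts whose
# marginals and generating models follow the published cohort tables.

# Canonical template design values (degrees)
TEMPLATE_SACRAL_SLOPE <- 38.5
TEMPLATE_PELVIC_TILT <- 15
TEMPLATE_PELVIC_INCIDENCE <- TEMPLATE_SACRAL_SLOPE + TEMPLATE_PELVIC_TILT
TEMPLATE_LLA <- 48.4
TEMPLATE_L1_TANGENT <- TEMPLATE_LLA - TEMPLATE_SACRAL_SLOPE  # +9.9 deg
TEMPLATE_L5_TANGENT <- -14.5
TEMPLATE_LLA_FUSED <- TEMPLATE_L1_TANGENT - TEMPLATE_L5_TANGENT

template_coords <- function() {
  ss <- TEMPLATE_SACRAL_SLOPE * DEG
  # S1 endplate tangent points anterior and inferior (sacral slope 38.5 deg)
  d_s1 <- c(0, cos(ss), -sin(ss))
  C <- c(0, -3.5, 41)  # S1 endplate centre
  # hip-centre midpoint 110 mm from the S1 centre, 15 deg anterior of vertical
  pt <- TEMPLATE_PELVIC_TILT * DEG
  hjc_mid <- C + 110 * c(0, sin(pt), -cos(pt))
  th1 <- TEMPLATE_L1_TANGENT * DEG
  d_l1 <- c(0, cos(th1), sin(th1))
  c_l1 <- c(0, -25, 150)
  th5 <- TEMPLATE_L5_TANGENT * DEG
  d_l5 <- c(0, cos(th5), sin(th5))
  c_l5 <- c(0, -15, 65)
  rbind(
    ASIS_L = c(115, 70, 0),
    ASIS_R = c(-115, 70, 0),
    PSIS_L = c(45, -95, 15),
    PSIS_R = c(-45, -95, 15),
    pubic_symphysis = c(0, 70, -70),
    pubic_tubercle_L = c(28, 72, -64),
    pubic_tubercle_R = c(-28, 72, -64),
    sacral_promontory = C + 16 * d_s1,
    S1_endplate_anterior = C + 14 * d_s1,
    S1_endplate_posterior = C - 14 * d_s1,
    S1_endplate_center = C,
    hip_center_L = c(85, hjc_mid[2], hjc_mid[3]),
    hip_center_R = c(-85, hjc_mid[2], hjc_mid[3]),
    ischial_tuberosity_L = c(55, -20, -135),
    ischial_tuberosity_R = c(-55, -20, -135),
    iliac_crest_L = c(130, -25, 60),
    iliac_crest_R = c(-130, -25, 60),
    L1sup_a = c_l1 + 17 * d_l1,
    L1sup_p = c_l1 - 17 * d_l1,
    L5sup_a = c_l5 + 16 * d_l5,
    L5sup_p = c_l5 - 16 * d_l5)
}

#' Template pelvis landmark set
#'
#' An anatomically plausible, bilaterally symmetric landmarked pelvis in the
#' canonical standing pose (anterior pelvic plane vertical in the world
#' frame). Designed ground truth is attached as attributes: sacral slope
#' 38.5 deg, pelvic incidence 53.5 deg, lumbar lordosis angle 48.4 deg
#' (L1-S1) and 24.4 deg (L1-L5).
#'
#' @param seed RNG seed used when `jitter_sd > 0`.
#' @param scale global scale factor (unitless); distances scale, angles do
#'   not.
#' @param jitter_sd total per-landmark jitter SD (mm) emulating inter-subject
#'   shape variation. Landmarks on the same bony structure (the S1 endplate
#'   with the promontory, and each lumbar endplate pair) move coherently:
#'   most of the jitter variance (95%) is a shared displacement of the
#'   structure and the remainder is independent per-landmark noise, so
#'   short-baseline angles stay anatomically plausible.
#' @return A [landmark_set()] with attribute `ground_truth`.
#' @export
template_pelvis <- function(seed = NULL, scale = 1, jitter_sd = 0) {
  stopifnot(scale > 0, jitter_sd >= 0)
  coords <- template_coords() * scale
  if (jitter_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    groups <- list(
      c("sacral_promontory", "S1_endplate_anterior", "S1_endplate_posterior",
        "S1_endplate_center"),
      c("L1sup_a", "L1sup_p"), c("L5sup_a", "L5sup_p"))
    grouped <- unlist(groups)
    solo <- setdiff(rownames(coords), grouped)
    coords[solo, ] <- coords[solo, ] +
      matrix(rnorm(3 * length(solo), 0, jitter_sd), length(solo), 3)
    for (g in groups) {
      shared <- rnorm(3, 0, jitter_sd * sqrt(0.95))
      coords[g, ] <- coords[g, ] + rep(shared, each = length(g)) +
        matrix(rnorm(3 * length(g), 0, jitter_sd * sqrt(0.05)), length(g), 3)
    }
  }
  lm <- landmark_set(coords)
  attr(lm, "ground_truth") <- list(
    sacral_slope = TEMPLATE_SACRAL_SLOPE,
    pelvic_incidence = TEMPLATE_PELVIC_INCIDENCE,
    lla = TEMPLATE_LLA,
    lla_fused = TEMPLATE_LLA_FUSED)
  lm
}

# quadratic Bezier arc
bezier3 <- function(p0, p1, p2, n) {
  t <- seq(0, 1, length.out = n)
  (1 - t)^2 %o% p0 + 2 * t * (1 - t) %o% p1 + t^2 %o% p2
}

#' Silhouette sample cloud of a landmarked pelvis
#'
#' Deterministic point cloud derived from the landmarks (pelvic brim ellipse,
#' iliac crest arcs, pubis-to-ischium struts), used as the model silhouette
#' for contour-based refinement and as an ICP test cloud. Because every point
#' is a fixed function of the landmarks, the cloud transforms rigidly with
#' the pelvis.
#'
#' @param lm a [landmark_set()].
#' @param n_per points per curve segment.
#' @return An m x 3 matrix (mm).
#' @export
pelvic_contour_points <- function(lm, n_per = 40) {
  need_landmarks(lm, REQUIRED_LANDMARKS)
  sym <- lm_pt(lm, "pubic_symphysis")
  prom <- lm_pt(lm, "sacral_promontory")
  ctr <- (sym + prom) / 2
  a1 <- (sym - prom) / 2
  a2 <- 0.55 * (lm_pt(lm, "ASIS_L") - lm_pt(lm, "ASIS_R")) / 2
  th <- seq(0, 2 * pi, length.out = n_per + 1)[-1]
  brim <- t(ctr + outer(a1, cos(th)) + outer(a2, sin(th)))
  crest_L <- bezier3(lm_pt(lm, "ASIS_L"), 1.25 * lm_pt(lm, "iliac_crest_L"),
                     lm_pt(lm, "PSIS_L"), n_per)
  crest_R <- bezier3(lm_pt(lm, "ASIS_R"), 1.25 * lm_pt(lm, "iliac_crest_R"),
                     lm_pt(lm, "PSIS_R"), n_per)
  t2 <- seq(0, 1, length.out = ceiling(n_per / 2))
  strut_L <- t2 %o% lm_pt(lm, "ischial_tuberosity_L") + (1 - t2) %o% sym
  strut_R <- t2 %o% lm_pt(lm, "ischial_tuberosity_R") + (1 - t2) %o% sym
  out <- rbind(brim, crest_L, crest_R, strut_L, strut_R)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Phantom pose grid
#'
#' The 19 controlled phantom orientations of the accuracy protocol: sagittal
#' offsets of 0 and +/-15 deg crossed with transverse offsets
#' {-30,-15,0,15,30}, two frontal offsets (+/-15 at 15 deg sagittal), and
#' pure sagittal offsets of +/-30 deg.
#'
#' @return Data frame with columns `d_sop`, `d_fop`, `d_top` (degrees).
#' @export
phantom_pose_grid <- function() {
  g <- expand.grid(d_sop = c(0, 15, -15), d_top = c(-30, -15, 0, 15, 30))
  out <- rbind(
    data.frame(d_sop = g$d_sop, d_fop = 0, d_top = g$d_top),
    data.frame(d_sop = c(15, 15), d_fop = c(15, -15), d_top = 0),
    data.frame(d_sop = c(30, -30), d_fop = 0, d_top = 0))
  rownames(out) <- NULL
  out
}

#' Generate biplanar phantom views
#'
#' Rotates the model by the controlled offsets (transverse, then sagittal,
#' then frontal, i.e. [recompose_orientation()] of the offset triple),
#' projects the picked landmarks orthographically into the AP and lateral
#' views, and adds seeded isotropic Gaussian pick noise emulating manual
#' landmark selection.
#'
#' @param lm a [landmark_set()].
#' @param d_sop,d_fop,d_top controlled orientation offsets (degrees).
#' @param pick_noise_sd pick noise SD (mm) per 2D coordinate.
#' @param seed RNG seed (optional).
#' @param picks landmark names picked in both views.
#' @param contours logical; also project the silhouette cloud.
#' @return A [biplanar_views()] with attribute `true_pose`.
#' @export
generate_phantom_views <- function(lm, d_sop = 0, d_fop = 0, d_top = 0,
                                   pick_noise_sd = 0.5, seed = NULL,
                                   picks = DEFAULT_PICKS, contours = FALSE) {
  need_landmarks(lm, picks)
  if (!is.null(seed)) set.seed(seed)
  p <- pose(recompose_orientation(c(d_sop, d_fop, d_top)))
  pts <- unclass(lm)[picks, , drop = FALSE]
  pr <- project_points(pts, p)
  noise <- function(m) m + matrix(rnorm(length(m), 0, pick_noise_sd),
                                  nrow(m), ncol(m))
  ap <- pr$ap; lat <- pr$lat
  if (pick_noise_sd > 0) { ap <- noise(ap); lat <- noise(lat) }
  rownames(ap) <- rownames(lat) <- picks
  ap_contour <- lat_contour <- NULL
  if (contours) {
    cc <- project_points(pelvic_contour_points(lm), p)
    ap_contour <- cc$ap; lat_contour <- cc$lat
  }
  v <- biplanar_views(ap, lat, ap_contour, lat_contour)
  attr(v, "true_pose") <- p
  v
}

# ---- cohort generator ----------------------------------------------------

#' Cohort generator configuration
#'
#' Fixes the study conditions of the synthetic cohort: predictor marginals
#' matching the published biometric and functional tables, and the linear
#' generating model of the postoperative standing SOP. Scenario A (supine CT
#' only) uses `postop = 7.53 - 0.19 age + 1.01 supine_sop + e`,
#' `e ~ N(0, 4.8^2)`; scenario B (supine CT + standing imaging) uses
#' `postop = -4.59 + 0.09 lla + 0.31 supine_sop + 0.61 standing_sop + e`,
#' `e ~ N(0, 3.6^2)`. The residual SDs equal the reported one-standard-error
#' model LOOCV RMSEs of the two scenarios.
#'
#' @param n number of subjects (>= 10).
#' @param scenario `"A"` or `"B"`.
#' @param seed RNG seed.
#' @param noise_sd residual SD in degrees (default 4.8 for A, 3.6 for B).
#' @param coefficients named list with `intercept` and named slopes;
#'   defaults to the scenario's generating model.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(n, scenario = c("A", "B"), seed = 1,
                             noise_sd = NULL, coefficients = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(n >= 10)
  if (is.null(noise_sd)) noise_sd <- if (scenario == "A") 4.8 else 3.6
  stopifnot(noise_sd > 0)
  if (is.null(coefficients)) {
    coefficients <- if (scenario == "A") {
      list(intercept = 7.53, age = -0.19, supine_sop = 1.01)
    } else {
      list(intercept = -4.59, lla = 0.09, supine_sop = 0.31,
           standing_sop = 0.61)
    }
  }
  structure(list(n = as.integer(n), scenario = scenario, seed = seed,
                 noise_sd = noise_sd, coefficients = coefficients),
            class = "generator_config")
}

# normal draw with a wide rejection guard (physical plausibility only; the
# published min/max are order statistics, not hard bounds)
rnorm_guard <- function(n, mean, sd, width = 4.5) {
  x <- rnorm(n, mean, sd)
  bad <- abs(x - mean) > width * sd
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- abs(x - mean) > width * sd
  }
  x
}

#' Names of the range-of-motion predictors
#' @return Character vector of the six hip range-of-motion predictor names.
#' @export
rom_names <- function() {
  c("rom_flexion", "rom_extension", "rom_abduction", "rom_adduction",
    "rom_internal_rotation", "rom_external_rotation")
}

#' Generate a synthetic THA cohort
#'
#' Draws per-subject predictors with the published marginals (age
#' `N(62.7, 10.7^2)`; height and weight per sex, sex ratio 29:168 male to
#' female; BMI derived from height and weight; preoperative supine SOP
#' `N(38.5, 8.3^2)`; standing SOP = supine + `N(-0.8, 5.2^2)`; standing LLA
#' `N(48.4, 10^2)`; L5-S1 fusion prevalence 8%) and the postoperative
#' standing SOP from the scenario's linear generating model (see
#' [generator_config()]). Morphological and range-of-motion predictors are
#' nuisance variables, independent of the response. The morphological
#' columns are centred at the template pelvis values with 5% (distances) or
#' 4% (angles) coefficient of variation.
#'
#' @param config a [generator_config()].
#' @return A data frame with one row per subject, attribute `scenario`;
#'   response column `postop_standing_sop`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n
  set.seed(config$seed)
  sex <- rbinom(n, 1, 29 / 197)  # 1 = male
  age <- rnorm_guard(n, 62.7, 10.7)
  height <- ifelse(sex == 1, rnorm_guard(n, 166.2, 7.6),
                   rnorm_guard(n, 154.4, 6.4))
  weight <- ifelse(sex == 1, rnorm_guard(n, 69.3, 12.0),
                   rnorm_guard(n, 55.0, 7.9))
  bmi <- weight / (height / 100)^2
  morpho0 <- morphological_parameters(template_pelvis())
  morpho <- vapply(names(morpho0), function(nm) {
    cv <- if (nm %in% names(default_morpho_registry()$distances)) 0.05 else 0.04
    rnorm_guard(n, morpho0[[nm]], cv * abs(morpho0[[nm]]))
  }, numeric(n))
  if (n == 1) morpho <- matrix(morpho, 1, dimnames = list(NULL, names(morpho0)))
  supine_sop <- rnorm_guard(n, 38.5, 8.3)
  standing_sop <- supine_sop + rnorm_guard(n, -0.8, 5.2)
  lla <- rnorm_guard(n, 48.4, 10)
  l5s1_fused <- rbinom(n, 1, 0.08)
  rom_mean <- c(90, 5, 20, 15, 10, 20)
  rom_sd <- c(20, 5, 10, 8, 8, 10)
  rom <- mapply(function(m, s) pmax(0, rnorm_guard(n, m, s)), rom_mean, rom_sd)
  if (n == 1) rom <- matrix(rom, 1)
  colnames(rom) <- rom_names()
  cf <- config$coefficients
  eta <- rep(cf$intercept, n)
  base <- data.frame(sex, age, height, weight, bmi, supine_sop, standing_sop,
                     lla, l5s1_fused)
  for (nm in setdiff(names(cf), "intercept")) {
    if (!nm %in% names(base)) stop("unknown generating-model predictor: ", nm)
    eta <- eta + cf[[nm]] * base[[nm]]
  }
  postop_standing_sop <- eta + rnorm(n, 0, config$noise_sd)
  out <- cbind(base[c("sex", "age", "height", "weight", "bmi")],
               as.data.frame(morpho),
               base[c("supine_sop", "standing_sop", "lla", "l5s1_fused")],
               as.data.frame(rom),
               postop_standing_sop = postop_standing_sop)
  attr(out, "scenario") <- config$scenario
  attr(out, "config") <- config
  out
}

#' Implied lumbar lordosis mean of the scenario-B generating model
#'
#' Solves the scenario-B generating model for the LLA mean that makes the
#' implied postoperative standing SOP mean equal the published value (34.7
#' deg) given the supine (38.5) and standing (37.7) SOP means: a brute-force
#' consistency check of the calibrated constant 48.4.
#'
#' @param postop_mean,supine_mean,standing_mean cohort means (degrees).
#' @param coefficients scenario-B generating coefficients.
#' @return The implied LLA mean in degrees.
#' @export
implied_lla_mean <- function(postop_mean = 34.7, supine_mean = 38.5,
                             standing_mean = 37.7,
                             coefficients = generator_config(100, "B")$coefficients) {
  cf <- coefficients
  (postop_mean - cf$intercept - cf$supine_sop * supine_mean -
      cf$standing_sop * standing_mean) / cf$lla
}

#' Read / write cohort tables as CSV
#'
#' Comma-separated, UTF-8, header row, `.` decimal separator.
#'
#' @param cohort data frame from [generate_cohort()].
#' @param path file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @param scenario scenario label to attach (`"A"` or `"B"`).
#' @export
read_cohort_csv <- function(path, scenario = c("A", "B")) {
  scenario <- match.arg(scenario)
  out <- read.csv(path, fileEncoding = "UTF-8")
  attr(out, "scenario") <- scenario
  out
}
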