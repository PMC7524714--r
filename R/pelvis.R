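# Pelvic landmark parametrisation: reference planes, morphological
# parameters and the lumbar lordosis angle.

REQUIRED_LANDMARKS <- c(
  "ASIS_L", "ASIS_R", "PSIS_L", "PSIS_R", "pubic_symphysis",
  "pubic_tubercle_L", "pubic_tubercle_R", "sacral_promontory",
  "S1_endplate_anterior", "S1_endplate_posterior", "S1_endplate_center",
  "hip_center_L", "hip_center_R", "ischial_tuberosity_L",
  "ischial_tuberosity_R", "iliac_crest_L", "iliac_crest_R")

LUMBAR_LANDMARKS <- c("L1sup_a", "L1sup_p", "L5sup_a", "L5sup_p")

#' Create a named pelvic landmark set
#'
#' @param coords numeric matrix with 3 columns (x, y, z in mm) and row names,
#'   or a named list of length-3 vectors. Coordinates are in the world frame:
#'   X medio-lateral (left positive), Y anterior, Z cranial.
#' @return A matrix of class `"landmark_set"` (rows = landmarks).
#' @export
landmark_set <- function(coords) {
  if (is.list(coords)) {
    coords <- do.call(rbind, coords)
  }
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, !is.null(rownames(coords)),
            all(is.finite(coords)))
  colnames(coords) <- c("x", "y", "z")
  structure(coords, class = c("landmark_set", "matrix", "array"))
}

need_landmarks <- function(lm, names) {
  missing <- setdiff(names, rownames(lm))
  if (length(missing))
    stop("missing landmark(s): ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

lm_pt <- function(lm, name) {
  if (!name %in% rownames(lm)) stop("missing landmark(s): ", name)
  as.numeric(lm[name, ])
}

lm_mid <- function(lm, a, b) (lm_pt(lm, a) + lm_pt(lm, b)) / 2

#' Read / write landmark sets as JSON
#'
#' The JSON file maps landmark names to `[x, y, z]` coordinates in mm.
#'
#' @param path file path.
#' @return [read_landmarks()] returns a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(raw) || is.null(names(raw)))
    stop("landmark JSON must map names to [x, y, z] mm coordinates")
  bad <- names(raw)[vapply(raw, function(v) length(v) != 3 ||
                             !is.numeric(v), logical(1))]
  if (length(bad))
    stop("landmark(s) without 3 numeric coordinates: ",
         paste(bad, collapse = ", "))
  landmark_set(lapply(raw, as.numeric))
}

#' @rdname read_landmarks
#' @param lm a [landmark_set()].
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  out <- lapply(seq_len(nrow(lm)), function(i) as.numeric(lm[i, ]))
  names(out) <- rownames(lm)
  jsonlite::write_json(out, path, digits = NA)
  invisible(path)
}

PLANE_IDS <- c("SSP", "PTP", "APP", "X1", "X2")

# Orientation helpers that depend only on landmarks, so the constructed plane
# is rigidly equivariant: plane(R lm) has frame R %*% plane(lm)$frame.
anterior_proxy <- function(lm) {
  lm_mid(lm, "ASIS_L", "ASIS_R") - lm_mid(lm, "PSIS_L", "PSIS_R")
}
cranial_proxy <- function(lm) {
  lm_mid(lm, "iliac_crest_L", "iliac_crest_R") -
    lm_mid(lm, "ischial_tuberosity_L", "ischial_tuberosity_R")
}
orient_towards <- function(v, ref) if (sum(v * ref) < 0) -v else v

plane_from_3pts <- function(p1, p2, p3) {
  n <- cross3(p2 - p1, p3 - p1)
  if (sqrt(sum(n^2)) < 1e-9) stop("degenerate plane: defining points are collinear")
  unit3(n)
}

# near-vertical plane frame: columns [normal x up, normal, up]; the plane
# normal (anterior) plays the role of the Y axis.
vertical_frame <- function(n, up_raw) {
  u <- up_raw - sum(up_raw * n) * n
  u <- unit3(u)
  cbind(cross3(n, u), n, u)
}

#' Construct one of the five pelvic reference planes
#'
#' Five registered planes measure the sagittal orientation of the pelvis:
#' \describe{
#'   \item{SSP}{sacral slope plane: the S1 superior endplate. Its sagittal
#'     angle is the sacral slope.}
#'   \item{APP}{anterior pelvic plane through both ASIS and the pubic
#'     symphysis; sagittal angle zero when the plane is vertical.}
#'   \item{PTP}{pelvic tilt plane containing the inter-ASIS axis and the
#'     pubic symphysis, through the ASIS midpoint.}
#'   \item{X1}{plane through both PSIS and the pubic symphysis.}
#'   \item{X2}{plane through both iliac crest points and the midpoint of the
#'     ischial tuberosities.}
#' }
#' All plane frames are derived from landmarks only, so they transform
#' rigidly with the pelvis.
#'
#' @param lm a [landmark_set()].
#' @param id one of `"SSP"`, `"PTP"`, `"APP"`, `"X1"`, `"X2"`.
#' @return A [plane()].
#' @export
construct_reference_plane <- function(lm, id = PLANE_IDS) {
  id <- match.arg(id)
  stopifnot(inherits(lm, "landmark_set"))
  ant <- function() anterior_proxy(lm)
  cran <- function() cranial_proxy(lm)
  switch(id,
    SSP = {
      need_landmarks(lm, c("S1_endplate_anterior", "S1_endplate_posterior",
                           "S1_endplate_center", "ASIS_L", "ASIS_R"))
      a_raw <- lm_pt(lm, "S1_endplate_anterior") -
        lm_pt(lm, "S1_endplate_posterior")
      if (sqrt(sum(a_raw^2)) < 1e-9)
        stop("degenerate plane: endplate points coincide")
      ml <- lm_pt(lm, "ASIS_L") - lm_pt(lm, "ASIS_R")
      n <- unit3(cross3(ml, a_raw))
      n <- orient_towards(n, cran())
      plane(lm_pt(lm, "S1_endplate_center"), n, a_raw)
    },
    APP = {
      need_landmarks(lm, c("ASIS_L", "ASIS_R", "pubic_symphysis",
                           "PSIS_L", "PSIS_R"))
      n <- plane_from_3pts(lm_pt(lm, "ASIS_L"), lm_pt(lm, "ASIS_R"),
                           lm_pt(lm, "pubic_symphysis"))
      n <- orient_towards(n, ant())
      up <- lm_mid(lm, "ASIS_L", "ASIS_R") - lm_pt(lm, "pubic_symphysis")
      fr <- vertical_frame(n, up)
      plane(lm_pt(lm, "pubic_symphysis"), n, fr[, 3], frame = fr)
    },
    PTP = {
      need_landmarks(lm, c("ASIS_L", "ASIS_R", "pubic_symphysis",
                           "PSIS_L", "PSIS_R"))
      ml <- lm_pt(lm, "ASIS_L") - lm_pt(lm, "ASIS_R")
      v <- lm_pt(lm, "pubic_symphysis") - lm_mid(lm, "ASIS_L", "ASIS_R")
      n <- cross3(ml, v)
      if (sqrt(sum(n^2)) < 1e-9)
        stop("degenerate plane: symphysis lies on the inter-ASIS axis")
      n <- orient_towards(unit3(n), ant())
      up <- -v
      fr <- vertical_frame(n, up)
      plane(lm_mid(lm, "ASIS_L", "ASIS_R"), n, fr[, 3], frame = fr)
    },
    X1 = {
      need_landmarks(lm, c("PSIS_L", "PSIS_R", "pubic_symphysis",
                           "ASIS_L", "ASIS_R"))
      n <- plane_from_3pts(lm_pt(lm, "PSIS_L"), lm_pt(lm, "PSIS_R"),
                           lm_pt(lm, "pubic_symphysis"))
      # near-horizontal plane: the normal points cranially, the in-plane
      # anterior axis runs from the PSIS midpoint towards the symphysis
      n <- orient_towards(n, cran())
      a_raw <- lm_pt(lm, "pubic_symphysis") - lm_mid(lm, "PSIS_L", "PSIS_R")
      plane(lm_mid(lm, "PSIS_L", "PSIS_R"), n, a_raw)
    },
    X2 = {
      need_landmarks(lm, c("iliac_crest_L", "iliac_crest_R",
                           "ischial_tuberosity_L", "ischial_tuberosity_R"))
      im <- lm_mid(lm, "ischial_tuberosity_L", "ischial_tuberosity_R")
      n <- plane_from_3pts(lm_pt(lm, "iliac_crest_L"),
                           lm_pt(lm, "iliac_crest_R"), im)
      n <- orient_towards(n, ant())
      up <- lm_mid(lm, "iliac_crest_L", "iliac_crest_R") - im
      fr <- vertical_frame(n, up)
      plane(im, n, fr[, 3], frame = fr)
    })
}

# ---- morphological parameters ------------------------------------------

# Derived points available to the registry
derived_points <- function(lm) {
  list(
    pubic_symphysis = lm_pt(lm, "pubic_symphysis"),
    sacral_promontory = lm_pt(lm, "sacral_promontory"),
    S1_endplate_center = lm_pt(lm, "S1_endplate_center"),
    hjc_mid = lm_mid(lm, "hip_center_L", "hip_center_R"),
    asis_mid = lm_mid(lm, "ASIS_L", "ASIS_R"),
    psis_mid = lm_mid(lm, "PSIS_L", "PSIS_R"),
    ASIS_L = lm_pt(lm, "ASIS_L"), ASIS_R = lm_pt(lm, "ASIS_R"),
    hip_center_L = lm_pt(lm, "hip_center_L"),
    hip_center_R = lm_pt(lm, "hip_center_R"))
}

angle_at <- function(vertex, a, b) angle_between(a - vertex, b - vertex)

#' Pelvic incidence
#'
#' Angle between the perpendicular to the S1 superior endplate at its centre
#' (the perpendicular pointing towards the hip centres) and the line from the
#' endplate centre to the midpoint of the hip joint centres. Pose-invariant.
#'
#' @param lm a [landmark_set()].
#' @return Angle in degrees.
#' @export
pelvic_incidence <- function(lm) {
  need_landmarks(lm, c("S1_endplate_anterior", "S1_endplate_posterior",
                       "S1_endplate_center", "hip_center_L", "hip_center_R",
                       "ASIS_L", "ASIS_R"))
  tangent <- lm_pt(lm, "S1_endplate_anterior") -
    lm_pt(lm, "S1_endplate_posterior")
  ml <- lm_pt(lm, "ASIS_L") - lm_pt(lm, "ASIS_R")
  n <- unit3(cross3(ml, tangent))
  v <- lm_mid(lm, "hip_center_L", "hip_center_R") -
    lm_pt(lm, "S1_endplate_center")
  n <- orient_towards(n, v)  # perpendicular on the hip side of the endplate
  angle_between(n, v)
}

# angle at the S1 endplate centre between the endplate perpendicular (on the
# pelvic side) and the line to the pubic symphysis; complements the pelvic
# incidence with the symphysis in place of the hip-centre midpoint
sacral_pubic_angle <- function(lm) {
  need_landmarks(lm, c("pubic_symphysis", "S1_endplate_anterior",
                       "S1_endplate_posterior", "S1_endplate_center",
                       "ASIS_L", "ASIS_R"))
  tangent <- lm_pt(lm, "S1_endplate_anterior") -
    lm_pt(lm, "S1_endplate_posterior")
  ml <- lm_pt(lm, "ASIS_L") - lm_pt(lm, "ASIS_R")
  n <- unit3(cross3(ml, tangent))
  v <- lm_pt(lm, "pubic_symphysis") - lm_pt(lm, "S1_endplate_center")
  n <- orient_towards(n, v)
  angle_between(n, v)
}

s1_endplate_app_angle <- function(lm) {
  tangent <- lm_pt(lm, "S1_endplate_anterior") -
    lm_pt(lm, "S1_endplate_posterior")
  app <- construct_reference_plane(lm, "APP")
  90 - angle_between(tangent, app$normal)
}

#' Default morphological parameter registry
#'
#' The registry fixes 13 landmark distances and 5 landmark angles (18
#' parameters in total); the counts are enforced by
#' [morphological_parameters()], the identities are configurable. Distances
#' are pairs of (possibly derived) points; angles are functions of the
#' landmark set. All entries are rigid-invariant.
#'
#' @return A list with elements `distances` (named list of character pairs)
#'   and `angles` (named list of functions).
#' @export
default_morpho_registry <- function() {
  list(
    distances = list(
      pubic_symphysis_to_hjc_midpoint = c("pubic_symphysis", "hjc_mid"),
      sacral_center_to_hjc_midpoint = c("S1_endplate_center", "hjc_mid"),
      symphysis_to_promontory = c("pubic_symphysis", "sacral_promontory"),
      symphysis_to_sacral_center = c("pubic_symphysis", "S1_endplate_center"),
      symphysis_to_asis_midpoint = c("pubic_symphysis", "asis_mid"),
      symphysis_to_psis_midpoint = c("pubic_symphysis", "psis_mid"),
      promontory_to_hjc_midpoint = c("sacral_promontory", "hjc_mid"),
      promontory_to_asis_midpoint = c("sacral_promontory", "asis_mid"),
      promontory_to_psis_midpoint = c("sacral_promontory", "psis_mid"),
      asis_midpoint_to_psis_midpoint = c("asis_mid", "psis_mid"),
      sacral_center_to_asis_midpoint = c("S1_endplate_center", "asis_mid"),
      inter_asis_width = c("ASIS_L", "ASIS_R"),
      inter_hip_center_width = c("hip_center_L", "hip_center_R")),
    angles = list(
      pelvic_incidence = pelvic_incidence,
      sacral_pubic_angle = sacral_pubic_angle,
      asis_symphysis_promontory_angle = function(lm) {
        p <- derived_points(lm)
        angle_at(p$pubic_symphysis, p$asis_mid, p$sacral_promontory)
      },
      promontory_hjc_symphysis_angle = function(lm) {
        p <- derived_points(lm)
        angle_at(p$hjc_mid, p$sacral_promontory, p$pubic_symphysis)
      },
      s1_endplate_app_angle = s1_endplate_app_angle))
}

#' Morphological pelvic parameters
#'
#' Computes the 18 morphological parameters (13 landmark distances in mm and
#' 5 landmark angles in degrees). Morphological parameters depend only on the
#' shape of the pelvis and are invariant to any rigid transform of the
#' landmark set.
#'
#' @param lm a [landmark_set()].
#' @param registry a registry as returned by [default_morpho_registry()];
#'   must contain exactly 13 distances and 5 angles.
#' @return Named numeric vector of length 18.
#' @export
morphological_parameters <- function(lm, registry = default_morpho_registry()) {
  stopifnot(inherits(lm, "landmark_set"))
  if (length(registry$distances) != 13L)
    stop("registry must define exactly 13 distances (got ",
         length(registry$distances), ")")
  if (length(registry$angles) != 5L)
    stop("registry must define exactly 5 angles (got ",
         length(registry$angles), ")")
  need_landmarks(lm, REQUIRED_LANDMARKS)
  pts <- derived_points(lm)
  d <- vapply(registry$distances, function(pair) {
    sqrt(sum((pts[[pair[1]]] - pts[[pair[2]]])^2))
  }, numeric(1))
  a <- vapply(registry$angles, function(f) f(lm), numeric(1))
  c(d, a)
}

#' Lumbar lordosis angle
#'
#' Angle between the superior-endplate tangent lines of L1 and S1, measured
#' in the sagittal (Y-Z) projection, as on a lateral standing radiograph. In
#' the case of an L5-S1 fusion or ankylosis the angle is measured between L1
#' and L5 and the S1 endplate points are ignored.
#'
#' @param lm a [landmark_set()] containing `L1sup_a`/`L1sup_p` and, depending
#'   on `l5s1_fused`, `S1_endplate_anterior`/`S1_endplate_posterior` or
#'   `L5sup_a`/`L5sup_p`.
#' @param l5s1_fused logical; measure against L5 instead of S1.
#' @return Angle in degrees, in `[0, 180)`.
#' @export
lumbar_lordosis_angle <- function(lm, l5s1_fused = FALSE) {
  stopifnot(inherits(lm, "landmark_set"))
  need_landmarks(lm, c("L1sup_a", "L1sup_p"))
  lower <- if (l5s1_fused) c("L5sup_a", "L5sup_p") else
    c("S1_endplate_anterior", "S1_endplate_posterior")
  need_landmarks(lm, lower)
  sag <- function(a, b) {  # tangent angle in the sagittal projection
    d <- lm_pt(lm, a) - lm_pt(lm, b)
    atan2(d[3], d[2]) / DEG
  }
  th1 <- sag("L1sup_a", "L1sup_p")
  th0 <- sag(lower[1], lower[2])
  d <- abs(th1 - th0) %% 360
  if (d > 180) d <- 360 - d
  d
}
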