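# Range-of-motion based cup safe zone and its shrinkage under uncertainty of
# the sagittal pelvic orientation change.
#
# Generic cone-impingement model: the prosthetic neck, driven through the
# required hip motion arcs, must stay inside the free cone of half-angle
# OA/2 about the cup axis, where OA is the oscillation angle set by the
# head/neck diameter ratio. Cup orientations use the radiographic (Murray)
# inclination/anteversion convention in the anterior-pelvic-plane frame;
# a left hip is modelled (lateral = +X).

#' Prosthesis specification
#'
#' @param head_diameter femoral head diameter (mm).
#' @param neck_diameter neck diameter (mm), strictly smaller than the head.
#' @param ccd_angle caput-collum-diaphyseal (neck-shaft) angle (degrees).
#' @param stem_anteversion femoral stem anteversion (degrees).
#' @return A list of class `"prosthesis_spec"`. Defaults follow a common
#'   configuration: 32 mm head, 11.5 mm neck, CCD 130 deg, 15 deg stem
#'   anteversion.
#' @export
prosthesis_spec <- function(head_diameter = 32, neck_diameter = 11.5,
                            ccd_angle = 130, stem_anteversion = 15) {
  stopifnot(neck_diameter > 0, head_diameter > 0)
  if (neck_diameter >= head_diameter)
    stop("neck diameter must be smaller than head diameter")
  structure(list(head_diameter = head_diameter,
                 neck_diameter = neck_diameter, ccd_angle = ccd_angle,
                 stem_anteversion = stem_anteversion),
            class = "prosthesis_spec")
}

#' Oscillation angle of a head/neck combination
#'
#' Total cone angle of neck motion permitted by the cup before neck-liner
#' impingement: `OA = 180 - 2 asin(neck / head)` degrees. Strictly
#' decreasing in the neck diameter.
#'
#' @param spec a [prosthesis_spec()].
#' @return Oscillation angle in degrees.
#' @export
oscillation_angle <- function(spec) {
  r <- spec$neck_diameter / spec$head_diameter
  if (r >= 1) stop("neck/head ratio must be < 1")
  180 - 2 * asin(r) / DEG
}

#' Default required range of motion
#'
#' Target motion amplitudes (degrees) the cup orientation must allow free of
#' prosthetic impingement: flexion 130, extension 40, internal rotation at
#' 90 degrees flexion 40, external rotation 40.
#'
#' @return Named numeric vector.
#' @export
default_required_rom <- function() {
  c(flexion = 130, extension = 40, internal_rotation_90flex = 40,
    external_rotation = 40)
}

# cup axis (unit, pointing out of the cup mouth) for radiographic
# inclination/anteversion, left hip, APP frame
cup_axis <- function(incl_deg, antev_deg) {
  ri <- incl_deg * DEG; ra <- antev_deg * DEG
  cbind(sin(ri) * cos(ra), sin(ra), -cos(ri) * cos(ra))
}

# neck axis (head centre -> shaft) at neutral stance, left femur
neck_axis_neutral <- function(spec) {
  delta <- (spec$ccd_angle - 90) * DEG  # neck drop below horizontal
  n0 <- c(cos(delta), 0, -sin(delta))
  # stem anteversion tips the head anteriorly, hence the shaft end of the
  # neck posteriorly: rotate about the shaft (vertical) axis
  as.numeric(rot_top(-spec$stem_anteversion) %*% n0)
}

rot_axis_angle <- function(axis, deg) {
  a <- unit3(axis); th <- deg * DEG
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# femur rotation for one named motion at amplitude theta (degrees)
motion_rotation <- function(motion, theta, spec) {
  switch(motion,
    flexion = rot_sop(-theta),             # distal femur swings anteriorly
    extension = rot_sop(theta),
    external_rotation = rot_axis_angle(c(0, 0, 1), -theta),
    internal_rotation_90flex = {
      F90 <- rot_sop(-90)
      shaft <- as.numeric(F90 %*% c(0, 0, -1))  # anterior after 90 flexion
      rot_axis_angle(shaft, -theta) %*% F90
    },
    stop("unknown motion: ", motion))
}

# unit neck directions sampled along all required motion arcs (rows)
motion_neck_samples <- function(spec, required_rom, arc_step = 2.5) {
  n0 <- neck_axis_neutral(spec)
  out <- list(rbind(n0))
  for (m in names(required_rom)) {
    amp <- required_rom[[m]]
    if (amp <= 0) next
    thetas <- seq(arc_step, amp, by = arc_step)
    if (thetas[length(thetas)] < amp) thetas <- c(thetas, amp)
    out[[m]] <- t(vapply(thetas, function(th)
      as.numeric(motion_rotation(m, th, spec) %*% n0), numeric(3)))
  }
  do.call(rbind, out)
}

#' Range-of-motion cup safe zone
#'
#' Evaluates, on a radiographic inclination x anteversion grid, whether every
#' required motion keeps the prosthetic neck inside the free cone of
#' half-angle `OA/2` about the cup axis (`OA` = [oscillation_angle()]). Cup
#' axes are expressed in the anterior-pelvic-plane frame; motions are
#' functional arcs in the same frame at zero pelvic tilt.
#'
#' @param spec a [prosthesis_spec()].
#' @param required_rom named amplitudes in degrees (>= 0), see
#'   [default_required_rom()].
#' @param grid_step grid resolution in degrees.
#' @param inclination,anteversion grid axis limits `c(min, max)` in degrees.
#' @param arc_step motion-arc sampling step in degrees.
#' @return A list of class `"safe_zone_grid"`: `inclination`, `anteversion`
#'   (axes), `mask` (logical matrix, inclination x anteversion), `grid_step`,
#'   `area` (deg^2).
#' @export
rom_safe_zone <- function(spec = prosthesis_spec(),
                          required_rom = default_required_rom(),
                          grid_step = 1,
                          inclination = c(0, 90), anteversion = c(0, 90),
                          arc_step = 2.5) {
  stopifnot(all(required_rom >= 0), grid_step > 0)
  if (inclination[2] < inclination[1] || anteversion[2] < anteversion[1])
    stop("empty grid: axis limits must be increasing")
  incl <- seq(inclination[1], inclination[2], by = grid_step)
  antev <- seq(anteversion[1], anteversion[2], by = grid_step)
  if (!length(incl) || !length(antev)) stop("empty grid")
  g <- expand.grid(incl = incl, antev = antev)
  U <- cup_axis(g$incl, g$antev)              # ncell x 3
  N <- motion_neck_samples(spec, required_rom, arc_step)  # nsamp x 3
  cosmin <- cos(oscillation_angle(spec) / 2 * DEG)
  dots <- U %*% t(N)                          # ncell x nsamp
  safe <- rowSums(dots < cosmin - 1e-12) == 0
  mask <- matrix(safe, length(incl), length(antev),
                 dimnames = list(incl, antev))
  structure(list(inclination = incl, anteversion = antev, mask = mask,
                 grid_step = grid_step, area = sum(mask) * grid_step^2,
                 spec = spec, required_rom = required_rom,
                 arc_step = arc_step),
            class = "safe_zone_grid")
}

#' Safe-zone area
#' @param zone a `"safe_zone_grid"`.
#' @return Area in deg^2 on the zone's grid.
#' @export
zone_area <- function(zone) zone$area

#' Shrink a safe zone for pelvic-tilt uncertainty
#'
#' Recomputes the zone with the pelvis tilted sagittally by each offset (the
#' cup, fixed to the pelvis, tilts with it while the functional motion arcs
#' stay put) and intersects the resulting zones: a cup orientation survives
#' only if it is safe at every plausible postoperative tilt. The reduction is
#' `100 (1 - area(intersection) / area(zone))`.
#'
#' @param zone baseline zone from [rom_safe_zone()].
#' @param tilt_offsets sagittal tilt offsets in degrees; must include 0.
#' @return List with the intersected `zone` and `reduction_percent`.
#' @export
shrink_for_uncertainty <- function(zone, tilt_offsets) {
  stopifnot(inherits(zone, "safe_zone_grid"))
  if (!any(abs(tilt_offsets) < 1e-12))
    stop("tilt_offsets must include 0 (the nominal orientation)")
  U <- cup_axis(expand.grid(zone$inclination, zone$anteversion)[, 1],
                expand.grid(zone$inclination, zone$anteversion)[, 2])
  N <- motion_neck_samples(zone$spec, zone$required_rom, zone$arc_step)
  cosmin <- cos(oscillation_angle(zone$spec) / 2 * DEG)
  mask <- matrix(TRUE, nrow(zone$mask), ncol(zone$mask))
  for (tau in tilt_offsets) {
    # dot(rot_sop(tau) u, n) = dot(u, rot_sop(-tau) n)
    Nt <- N %*% t(rot_sop(-tau))
    dots <- U %*% t(Nt)
    safe <- rowSums(dots < cosmin - 1e-12) == 0
    mask <- mask & matrix(safe, nrow(mask), ncol(mask))
  }
  dimnames(mask) <- dimnames(zone$mask)
  shrunk <- zone
  shrunk$mask <- mask
  shrunk$area <- sum(mask) * zone$grid_step^2
  reduction <- if (zone$area > 0) 100 * (1 - shrunk$area / zone$area) else 0
  list(zone = shrunk, reduction_percent = reduction)
}

#' @export
print.safe_zone_grid <- function(x, ...) {
  cat(sprintf("safe zone: %.0f deg^2 (%.1f%% of the %g-deg grid)\n",
              x$area, 100 * mean(x$mask), x$grid_step))
  cat(sprintf("  oscillation angle %.1f deg; required ROM: %s\n",
              oscillation_angle(x$spec),
              paste(names(x$required_rom), x$required_rom, sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Plot a safe zone mask
#'
#' @param x a `"safe_zone_grid"`.
#' @param ... passed to [image()].
#' @export
plot.safe_zone_grid <- function(x, ...) {
  image(x$inclination, x$anteversion, x$mask * 1,
        xlab = "radiographic inclination (deg)",
        ylab = "radiographic anteversion (deg)",
        col = c("grey90", "steelblue"), ...)
  invisible(x)
}

#' Write a safe-zone mask as CSV
#'
#' @param zone a `"safe_zone_grid"`.
#' @param path output path (rows = inclination, columns = anteversion).
#' @export
write_zone_csv <- function(zone, path) {
  write.csv(zone$mask * 1, path, row.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
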