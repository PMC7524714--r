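# Rigid-body primitives and the sagittal/frontal/transverse decomposition of
# a pelvic pose.
#
# World frame (right-handed): X medio-lateral (left positive), Y
# antero-posterior (anterior positive), Z vertical (cranial positive).
# All angles are handled in degrees at the interface.

DEG <- pi / 180

#' Elementary anatomical rotations
#'
#' `rot_sop()` is an anterior pelvic tilt: a positive angle tips the cranial
#' axis anteriorly and an anterior-pointing vector inferiorly, so an anterior
#' tilt has a positive sagittal angle. `rot_fop()` and `rot_top()` are
#' right-handed rotations about the antero-posterior (Y) and vertical (Z)
#' axes.
#'
#' @param deg rotation angle in degrees.
#' @return A 3x3 rotation matrix.
#' @keywords internal
rot_sop <- function(deg) {
  a <- deg * DEG
  matrix(c(1, 0, 0,
           0, cos(a), sin(a),
           0, -sin(a), cos(a)), 3, 3, byrow = TRUE)
}

#' @rdname rot_sop
#' @keywords internal
rot_fop <- function(deg) {
  b <- deg * DEG
  matrix(c(cos(b), 0, sin(b),
           0, 1, 0,
           -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
}

#' @rdname rot_sop
#' @keywords internal
rot_top <- function(deg) {
  g <- deg * DEG
  matrix(c(cos(g), -sin(g), 0,
           sin(g), cos(g), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a (near-)zero vector")
  v / n
}

#' Angle between two vectors
#'
#' @param a,b numeric 3-vectors.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
angle_between <- function(a, b) {
  ua <- unit3(a); ub <- unit3(b)
  # atan2 form is numerically stable near 0 and 180 degrees
  atan2(sqrt(sum(cross3(ua, ub)^2)), sum(ua * ub)) / DEG
}

#' Rigid pose
#'
#' A pose maps model coordinates to world coordinates, `x_world = R x + t`.
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation length-3 numeric vector in mm.
#' @return An object of class `"pose"`.
#' @export
pose <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3,
            all(is.finite(rotation)), all(is.finite(translation)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-7)
    stop("rotation is not orthogonal")
  if (abs(det(rotation) - 1) > 1e-7)
    stop("rotation is not proper (det != 1)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "pose")
}

apply_pose <- function(p, pts) {
  pts <- rbind(pts)  # n x 3
  sweep(pts %*% t(p$rotation), 2, p$translation, `+`)
}

compose_pose <- function(a, b) {
  # apply b first, then a
  pose(a$rotation %*% b$rotation,
       as.numeric(a$rotation %*% b$translation) + a$translation)
}

invert_pose <- function(p) {
  pose(t(p$rotation), as.numeric(-t(p$rotation) %*% p$translation))
}

#' Decompose a rotation into pelvic orientation angles
#'
#' Decomposes a rotation into the sagittal (SOP), frontal (FOP) and
#' transverse (TOP) orientation of the pelvis using the fixed sequence
#' `rot_top(top) %*% rot_sop(sop) %*% rot_fop(fop)`: the transverse rotation
#' is applied last (outermost), which makes the sagittal angle invariant to
#' axial rotation applied first, i.e. the SOP is adjusted for the transverse
#' and frontal orientation. Positive SOP is anterior tilt.
#'
#' The middle (sagittal) angle lies in `[-90, 90]`; at `|sop| = 90` the
#' sequence is gimbal-degenerate and the result carries the attribute
#' `degenerate = TRUE` (transverse and frontal angles are then confounded and
#' the transverse angle is set by convention).
#'
#' @param p a [pose()] or a 3x3 rotation matrix.
#' @return Named numeric vector `c(sop, fop, top)` in degrees.
#' @seealso [recompose_orientation()]
#' @export
decompose_orientation <- function(p) {
  R <- if (inherits(p, "pose")) p$rotation else as.matrix(p)
  s <- -R[3, 2]                     # sin(sop)
  s <- max(-1, min(1, s))
  sop <- asin(s) / DEG
  degenerate <- abs(abs(s) - 1) < 1e-9
  if (degenerate) {
    fop <- 0
    top <- atan2(R[2, 1], R[1, 1]) / DEG
  } else {
    fop <- atan2(-R[3, 1], R[3, 3]) / DEG
    top <- atan2(-R[1, 2], R[2, 2]) / DEG
  }
  out <- c(sop = sop, fop = fop, top = top)
  attr(out, "degenerate") <- degenerate
  out
}

#' Recompose a rotation from pelvic orientation angles
#'
#' Inverse of [decompose_orientation()]: builds
#' `rot_top(top) %*% rot_sop(sop) %*% rot_fop(fop)`.
#'
#' @param triple named or positional numeric vector `(sop, fop, top)` in
#'   degrees, or three separate arguments.
#' @param fop,top frontal and transverse angles when `triple` is scalar.
#' @return A 3x3 rotation matrix.
#' @export
recompose_orientation <- function(triple, fop = NULL, top = NULL) {
  if (!is.null(fop) || !is.null(top)) {
    triple <- c(triple, fop %||% 0, top %||% 0)
  }
  if (!is.null(names(triple)) && all(c("sop", "fop", "top") %in% names(triple)))
    triple <- triple[c("sop", "fop", "top")]
  stopifnot(length(triple) == 3, all(is.finite(triple)))
  rot_top(triple[3]) %*% rot_sop(triple[1]) %*% rot_fop(triple[2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reference plane with an oriented frame
#'
#' A plane carries an origin, a unit normal, a unit in-plane `anterior_axis`
#' orthogonal to the normal, and a full right-handed orientation frame used
#' to read off its orientation angles. When constructed directly the frame is
#' `[anterior_axis x normal, anterior_axis, normal]`, i.e. the normal plays
#' the role of the cranial axis (appropriate for near-horizontal planes such
#' as the sacral endplate); [construct_reference_plane()] chooses the frame
#' per plane type.
#'
#' @param origin point on the plane (mm).
#' @param normal plane normal.
#' @param anterior_axis in-plane axis; its component along the normal is
#'   removed before normalisation.
#' @param frame optional explicit 3x3 orientation frame (columns = plane
#'   axes in world coordinates); overrides the default construction.
#' @return An object of class `"pelvic_plane"`.
#' @export
plane <- function(origin, normal, anterior_axis, frame = NULL) {
  n <- unit3(normal)
  a <- anterior_axis - sum(anterior_axis * n) * n
  a <- unit3(a)
  if (is.null(frame)) frame <- cbind(cross3(a, n), a, n)
  stopifnot(abs(det(frame) - 1) < 1e-7)
  structure(list(origin = as.numeric(origin), normal = n, anterior_axis = a,
                 frame = frame),
            class = "pelvic_plane")
}

wrap180 <- function(a) {
  w <- ((a + 180) %% 360) - 180
  ifelse(w == -180, 180, w)
}

#' Orientation angles of a posed reference plane
#'
#' Returns the sagittal, frontal and transverse orientation of a reference
#' plane under a rigid pose: the decomposition of the pose rotation offset by
#' the plane's intrinsic (canonical) orientation angles,
#' `decompose(R) + decompose(frame)` componentwise. For a pure sagittal pose
#' this equals the direct decomposition of the posed frame; in general it is
#' the plane's sagittal angle adjusted for the frontal and transverse
#' orientation of the pelvis, so every reference plane reports the same
#' orientation *change* for the same pelvic rotation and the measurement
#' does not depend on the plane chosen.
#'
#' The sagittal angle of the sacral-endplate plane is the sacral slope; for
#' the anterior pelvic plane it is the (APP) pelvic tilt, zero when the plane
#' is vertical.
#'
#' @param pl a [plane()].
#' @param p a [pose()] (default: identity).
#' @return Named vector `c(sop, fop, top)` in degrees, each in
#'   `(-180, 180]`.
#' @export
plane_orientation <- function(pl, p = pose()) {
  stopifnot(inherits(pl, "pelvic_plane"))
  R <- if (inherits(p, "pose")) p$rotation else as.matrix(p)
  pose_tr <- decompose_orientation(R)
  plane_tr <- decompose_orientation(pl$frame)
  out <- wrap180(pose_tr + plane_tr)
  names(out) <- c("sop", "fop", "top")
  attr(out, "degenerate") <- isTRUE(attr(pose_tr, "degenerate")) ||
    isTRUE(attr(plane_tr, "degenerate"))
  out
}
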