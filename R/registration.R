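# 3D/2.5D rigid registration of a landmarked pelvis model to two orthogonal
# projections (biplanar, AP + lateral), plus rigid ICP for point clouds.
#
# Projection model: orthographic in both views. The AP view is a projection
# along Y and returns (x, z); the lateral view projects along X and returns
# (y, z). The two views share the vertical (Z) axis.

DEFAULT_PICKS <- c("hip_center_L", "hip_center_R", "pubic_symphysis",
                   "sacral_promontory")

#' Biplanar orthogonal views with picked 2D landmarks
#'
#' @param ap_picks named matrix (n x 2) of AP-view picks, columns `(x, z)` mm.
#' @param lat_picks named matrix (n x 2) of lateral-view picks, columns
#'   `(y, z)` mm. Row names must match `ap_picks`.
#' @param ap_contour,lat_contour optional 2-column matrices of projected
#'   silhouette samples.
#' @return An object of class `"biplanar_views"`.
#' @export
biplanar_views <- function(ap_picks, lat_picks, ap_contour = NULL,
                           lat_contour = NULL) {
  ap_picks <- as.matrix(ap_picks); lat_picks <- as.matrix(lat_picks)
  stopifnot(ncol(ap_picks) == 2, ncol(lat_picks) == 2,
            !is.null(rownames(ap_picks)),
            identical(sort(rownames(ap_picks)), sort(rownames(lat_picks))))
  structure(list(ap_picks = ap_picks,
                 lat_picks = lat_picks[rownames(ap_picks), , drop = FALSE],
                 ap_contour = ap_contour, lat_contour = lat_contour),
            class = "biplanar_views")
}

#' Orthographic biplanar projection
#'
#' @param pts n x 3 matrix of model points (mm).
#' @param p a [pose()] applied before projecting.
#' @return List with elements `ap` (n x 2: x, z) and `lat` (n x 2: y, z).
#' @export
project_points <- function(pts, p = pose()) {
  w <- apply_pose(p, pts)
  list(ap = w[, c(1, 3), drop = FALSE], lat = w[, c(2, 3), drop = FALSE])
}

# least-squares rigid transform mapping A onto B (Kabsch/Horn)
kabsch <- function(A, B) {
  stopifnot(nrow(A) == nrow(B), nrow(A) >= 3)
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  pose(R, cb - as.numeric(R %*% ca))
}

pose_to_par <- function(p) {
  tr <- decompose_orientation(p)
  c(tr, p$translation)
}

par_to_pose <- function(par) {
  pose(recompose_orientation(par[1:3]), par[4:6])
}

pick_residuals <- function(par, model_pts, views) {
  pr <- project_points(model_pts, par_to_pose(par))
  c(pr$ap - views$ap_picks, pr$lat - views$lat_picks)
}

#' Pre-registration from picked landmarks
#'
#' Finds the rigid pose minimising the sum of squared 2D residuals of the
#' projected picked landmarks over both views (each 3D pick contributes up to
#' four scalar constraints). A closed-form rigid fit to the pseudo-3D points
#' reconstructed from the two views initialises a local 6-DOF least-squares
#' refinement of the true projective objective.
#'
#' @param lm a [landmark_set()] (the model).
#' @param views a [biplanar_views()]; pick names must exist in `lm`.
#' @return A [pose()] with attributes `rms_residual` (mm) and `converged`.
#' @export
preregister <- function(lm, views) {
  stopifnot(inherits(lm, "landmark_set"), inherits(views, "biplanar_views"))
  nm <- rownames(views$ap_picks)
  if (length(nm) < 3)
    stop("under-constrained: at least 3 picked landmarks are required")
  need_landmarks(lm, nm)
  model_pts <- unclass(lm)[nm, , drop = FALSE]
  # pseudo-3D reconstruction: x from AP, y from lateral, z averaged
  recon <- cbind(views$ap_picks[, 1], views$lat_picks[, 1],
                 (views$ap_picks[, 2] + views$lat_picks[, 2]) / 2)
  p0 <- kabsch(model_pts, recon)
  obj <- function(par) sum(pick_residuals(par, model_pts, views)^2)
  fit <- optim(pose_to_par(p0), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  p <- par_to_pose(fit$par)
  res <- pick_residuals(fit$par, model_pts, views)
  attr(p, "rms_residual") <- sqrt(mean(res^2))
  attr(p, "converged") <- fit$convergence == 0
  p
}

# mean squared distance from each projected model point to the nearest
# target contour point, per view
contour_msd <- function(proj, target) {
  d2 <- outer(proj[, 1], target[, 1], `-`)^2 +
    outer(proj[, 2], target[, 2], `-`)^2
  mean(apply(d2, 1, min))
}

#' Contour-based refinement of a registration
#'
#' Local derivative-free refinement of a pose: minimises the mean squared
#' distance from the projected model silhouette samples to the nearest target
#' contour point, summed over both views (a stand-in for the interactive
#' fine-alignment an examiner would perform on the radiographs). The returned
#' pose never has a larger objective than the starting pose.
#'
#' @param pose0 starting [pose()] (typically from [preregister()]).
#' @param model_contour3d n x 3 matrix of model silhouette samples.
#' @param views a [biplanar_views()] carrying `ap_contour` and `lat_contour`.
#' @param maxit maximum optimiser iterations.
#' @param tol relative convergence tolerance on the objective.
#' @return A list of class `"registration_result"`: `pose`, `rms_residual`
#'   (mm), `n_iterations`, `converged`, `objective_trace`.
#' @export
refine_registration <- function(pose0, model_contour3d, views,
                                maxit = 500, tol = 1e-8) {
  if (is.null(views$ap_contour) || is.null(views$lat_contour) ||
      nrow(views$ap_contour) == 0 || nrow(views$lat_contour) == 0)
    stop("empty contours: refinement requires contour samples in both views")
  model_contour3d <- as.matrix(model_contour3d)
  trace_env <- new.env()
  trace_env$best <- Inf
  trace_env$trace <- numeric(0)
  obj <- function(par) {
    pr <- project_points(model_contour3d, par_to_pose(par))
    v <- contour_msd(pr$ap, views$ap_contour) +
      contour_msd(pr$lat, views$lat_contour)
    if (v < trace_env$best) {
      trace_env$best <- v
      trace_env$trace <- c(trace_env$trace, v)
    }
    v
  }
  par0 <- pose_to_par(pose0)
  f0 <- obj(par0)
  fit <- optim(par0, obj, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = tol))
  if (fit$value <= f0) {
    p <- par_to_pose(fit$par); val <- fit$value
  } else {
    p <- pose0; val <- f0  # never worse than the start
  }
  structure(list(pose = p, rms_residual = sqrt(val / 2),
                 n_iterations = fit$counts[["function"]],
                 converged = fit$convergence == 0,
                 objective_trace = trace_env$trace),
            class = "registration_result")
}

#' Measure the sagittal orientation of the pelvis from biplanar views
#'
#' Runs the full measurement chain: landmark pre-registration, optional
#' contour refinement, and decomposition of the requested reference plane's
#' orientation at the solved pose.
#'
#' @param lm a [landmark_set()] (the 3D model).
#' @param views a [biplanar_views()].
#' @param plane_id reference plane identifier (see
#'   [construct_reference_plane()]).
#' @param model_contour3d optional n x 3 silhouette samples; refinement runs
#'   only when both these and the view contours are present.
#' @return Named vector `c(sop, fop, top)` in degrees with attribute `pose`.
#' @export
measure_sop <- function(lm, views, plane_id = "SSP", model_contour3d = NULL) {
  p <- preregister(lm, views)
  if (!is.null(model_contour3d) && !is.null(views$ap_contour) &&
      !is.null(views$lat_contour)) {
    p <- refine_registration(p, model_contour3d, views)$pose
  }
  pl <- construct_reference_plane(lm, plane_id)
  out <- plane_orientation(pl, p)
  attr(out, "pose") <- p
  out
}

#' Rigid iterative closest point registration
#'
#' Alternates nearest-neighbour correspondence and closed-form least-squares
#' rigid fitting until the RMS distance change falls below `tol` or `maxit`
#' iterations. The RMS is non-increasing across iterations.
#'
#' @param source,target n x 3 point matrices (at least 3 non-collinear points
#'   each).
#' @param init initial [pose()] applied to `source`.
#' @param maxit,tol iteration cap and RMS-change tolerance (mm).
#' @return A list of class `"registration_result"`: `pose`, `rms_residual`,
#'   `n_iterations`, `converged`.
#' @export
icp_rigid <- function(source, target, init = pose(), maxit = 200,
                      tol = 1e-6) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (nrow(source) < 3 || nrow(target) < 3)
    stop("degenerate geometry: at least 3 points required in each cloud")
  if (qr(sweep(source, 2, colMeans(source)))$rank < 2)
    stop("degenerate geometry: source points are collinear")
  p <- init
  rms_prev <- Inf
  rms <- Inf
  it <- 0
  for (it in seq_len(maxit)) {
    moved <- apply_pose(p, source)
    d2 <- outer(moved[, 1], target[, 1], `-`)^2 +
      outer(moved[, 2], target[, 2], `-`)^2 +
      outer(moved[, 3], target[, 3], `-`)^2
    nn <- max.col(-d2, ties.method = "first")
    rms <- sqrt(mean(d2[cbind(seq_len(nrow(moved)), nn)]))
    if (abs(rms_prev - rms) < tol) break
    rms_prev <- rms
    p <- kabsch(source, target[nn, , drop = FALSE])
  }
  structure(list(pose = p, rms_residual = rms, n_iterations = it,
                 converged = abs(rms_prev - rms) < tol),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("rigid registration result\n")
  cat(sprintf("  rms residual : %.4g mm\n", x$rms_residual))
  cat(sprintf("  iterations   : %d\n", x$n_iterations))
  cat(sprintf("  converged    : %s\n", x$converged))
  tr <- decompose_orientation(x$pose)
  cat(sprintf("  orientation  : sop %.2f, fop %.2f, top %.2f deg\n",
              tr[1], tr[2], tr[3]))
  invisible(x)
}
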