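test_that("orthographic projection drops the view axis", {
  pr <- project_points(c(1, 2, 3))
  expect_equal(pr$ap[1, ], c(1, 3))
  expect_equal(pr$lat[1, ], c(2, 3))
  pr2 <- project_points(c(1, 2, 3), pose(diag(3), c(0, 5, 0)))
  expect_equal(pr2$ap[1, ], c(1, 3))        # AP unchanged by Y translation
  expect_equal(pr2$lat[1, ], c(7, 3))
  # against a hand-built matrix product
  R <- oracle_rz(90)
  w <- as.numeric(R %*% c(1, 0, 0))
  pr3 <- project_points(c(1, 0, 0), pose(rot_top(90)))
  expect_equal(pr3$ap[1, ], w[c(1, 3)], tolerance = 1e-12)
  expect_equal(pr3$lat[1, ], w[c(2, 3)], tolerance = 1e-12)
})

test_that("preregistration recovers an exact pose from noise-free picks", {
  tp <- template_pelvis()
  true_pose <- pose(recompose_orientation(c(12, -8, 25)), c(4, -6, 10))
  pts <- unclass(tp)[c("hip_center_L", "hip_center_R", "pubic_symphysis",
                       "sacral_promontory"), ]
  pr <- project_points(pts, true_pose)
  rownames(pr$ap) <- rownames(pr$lat) <- rownames(pts)
  v <- biplanar_views(pr$ap, pr$lat)
  p <- preregister(tp, v)
  expect_lt(rotation_angle_between(p$rotation, true_pose$rotation), 1e-5)
  expect_lt(max(abs(p$translation - true_pose$translation)), 1e-4)
  expect_lt(attr(p, "rms_residual"), 1e-5)
})

test_that("fewer than three picks is under-constrained", {
  tp <- template_pelvis()
  pts <- unclass(tp)[c("hip_center_L", "hip_center_R"), ]
  pr <- project_points(pts)
  rownames(pr$ap) <- rownames(pr$lat) <- rownames(pts)
  expect_error(preregister(tp, biplanar_views(pr$ap, pr$lat)),
               "under-constrained")
})

test_that("pick noise of 0.5 mm keeps the orientation error within 1.5 deg", {
  tp <- template_pelvis()
  set.seed(314)
  n_ok <- 0
  n_trials <- 200
  for (k in seq_len(n_trials)) {
    v <- generate_phantom_views(tp, 5, 0, 10, pick_noise_sd = 0.5)
    p <- preregister(tp, v)
    err <- rotation_angle_between(p$rotation, attr(v, "true_pose")$rotation)
    if (err <= 1.5) n_ok <- n_ok + 1
  }
  expect_gte(n_ok / n_trials, 0.95)
})

test_that("contour refinement recovers a sagittally perturbed pose", {
  tp <- template_pelvis()
  truth <- pose(recompose_orientation(c(10, 0, 0)))
  contour3d <- pelvic_contour_points(tp)
  target <- project_points(contour3d, truth)
  picks <- unclass(tp)[c("hip_center_L", "hip_center_R", "pubic_symphysis",
                         "sacral_promontory"), ]
  pp <- project_points(picks, truth)
  rownames(pp$ap) <- rownames(pp$lat) <- rownames(picks)
  v <- biplanar_views(pp$ap, pp$lat, target$ap, target$lat)
  start <- pose(recompose_orientation(c(15, 0, 0)))  # 5 deg sagittal offset
  res <- refine_registration(start, contour3d, v)
  sop_err <- decompose_orientation(res$pose)[1] - 10
  expect_lt(abs(sop_err), 0.3)
  # objective trace is non-increasing and the result never degrades the start
  expect_true(all(diff(res$objective_trace) <= 0))
  res0 <- refine_registration(truth, contour3d, v)
  expect_lt(rotation_angle_between(res0$pose$rotation, truth$rotation), 0.2)
  expect_error(refine_registration(start, contour3d,
                                   biplanar_views(pp$ap, pp$lat)),
               "empty contours")
})

test_that("measure_sop returns the generating plane orientation", {
  tp <- template_pelvis()
  # canonical pose: SOP of the sacral slope plane is 38.5 deg
  v <- generate_phantom_views(tp, 0, 0, 0, pick_noise_sd = 0)
  m <- measure_sop(tp, v, "SSP")
  expect_lt(abs(m[1] - 38.5), 0.1)
  # two different planes: values differ, measured - truth agrees
  v2 <- generate_phantom_views(tp, 7, 3, -12, pick_noise_sd = 0.3)
  truth_pose <- attr(v2, "true_pose")
  for (ids in list(c("SSP", "APP"), c("PTP", "X2"))) {
    errs <- vapply(ids, function(id) {
      truth <- plane_orientation(construct_reference_plane(tp, id), truth_pose)[1]
      measure_sop(tp, v2, id)[1] - truth
    }, numeric(1))
    expect_lt(abs(diff(errs)), 0.1)
  }
  bad <- biplanar_views(
    rbind(hip_center_L = c(0, 0), hip_center_R = c(1, 1), unknown = c(2, 2)),
    rbind(hip_center_L = c(0, 0), hip_center_R = c(1, 1), unknown = c(2, 2)))
  expect_error(measure_sop(tp, bad), "missing landmark")
})

test_that("measurement is unbiased on noise-free views across a pose sweep", {
  tp <- template_pelvis()
  set.seed(99)
  planes <- c("SSP", "PTP", "APP", "X1", "X2")
  ref <- lapply(planes, construct_reference_plane, lm = tp)
  names(ref) <- planes
  for (k in 1:50) {
    tr <- c(runif(1, -25, 25), runif(1, -12, 12), runif(1, -25, 25))
    v <- generate_phantom_views(tp, tr[1], tr[2], tr[3], pick_noise_sd = 0)
    p <- preregister(tp, v)
    for (id in planes) {
      truth <- plane_orientation(ref[[id]], attr(v, "true_pose"))[1]
      expect_lt(abs(plane_orientation(ref[[id]], p)[1] - truth), 0.05)
    }
  }
})

test_that("a shared sagittal rotation shifts the measured SOP one-to-one", {
  tp <- template_pelvis()
  set.seed(17)
  v1 <- generate_phantom_views(tp, 5, 0, 0, pick_noise_sd = 0)
  v2 <- generate_phantom_views(tp, 5 + 9, 0, 0, pick_noise_sd = 0)
  m1 <- measure_sop(tp, v1, "SSP")
  m2 <- measure_sop(tp, v2, "SSP")
  expect_lt(abs(m2[1] - m1[1] - 9), 0.05)
})

test_that("rigid ICP recovers exact and perturbed alignments", {
  tp <- template_pelvis()
  cloud <- pelvic_contour_points(tp, n_per = 30)
  # target = source -> identity
  res <- icp_rigid(cloud, cloud)
  expect_lt(rotation_angle_between(res$pose$rotation, diag(3)), 1e-6)
  expect_lt(max(abs(res$pose$translation)), 1e-6)
  # known transform, good initialisation
  R <- recompose_orientation(c(4, -3, 6)); t <- c(3, -2, 5)
  target <- sweep(cloud %*% t(R), 2, t, `+`)
  res2 <- icp_rigid(cloud, target, init = pose(recompose_orientation(c(3, -2, 5)), t))
  expect_lt(rotation_angle_between(res2$pose$rotation, R), 1e-4)
  expect_lt(max(abs(res2$pose$translation - t)), 1e-3)
  # 5 deg + 5 mm perturbed start converges to the truth
  res3 <- icp_rigid(cloud, target,
                    init = pose(recompose_orientation(c(9, -3, 6)), t + c(5, 0, 0)))
  expect_lt(rotation_angle_between(res3$pose$rotation, R), 0.1)
  expect_lt(max(abs(res3$pose$translation - t)), 0.1)
  expect_error(icp_rigid(cbind(1:5, 1:5, 1:5), cloud), "collinear")
})
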