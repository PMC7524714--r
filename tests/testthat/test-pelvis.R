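test_that("APP through symmetric ASIS and symphysis is vertical", {
  lm <- landmark_set(rbind(
    ASIS_L = c(120, 0, 0), ASIS_R = c(-120, 0, 0),
    pubic_symphysis = c(0, 0, -90),
    PSIS_L = c(45, -95, 15), PSIS_R = c(-45, -95, 15)))
  app <- construct_reference_plane(lm, "APP")
  expect_equal(abs(app$normal), c(0, 1, 0), tolerance = 1e-12)
  expect_equal(unname(plane_orientation(app)[1]), 0, tolerance = 1e-9)
})

test_that("reference planes ignore unrelated landmarks and validate inputs", {
  tp <- template_pelvis()
  ssp1 <- construct_reference_plane(tp, "SSP")
  shuffled <- tp
  shuffled["iliac_crest_L", ] <- tp["iliac_crest_L", ] + c(5, -3, 2)
  ssp2 <- construct_reference_plane(landmark_set(unclass(shuffled)), "SSP")
  expect_equal(ssp1$frame, ssp2$frame, tolerance = 1e-12)
  expect_error(construct_reference_plane(
    landmark_set(rbind(ASIS_L = c(1, 0, 0))), "APP"), "missing landmark")
  degen <- unclass(tp)
  degen["pubic_symphysis", ] <-
    (degen["ASIS_L", ] + degen["ASIS_R", ]) / 2  # on the inter-ASIS axis
  expect_error(construct_reference_plane(landmark_set(degen), "PTP"),
               "degenerate")
})

test_that("template SSP matches the designed sacral slope ground truth", {
  tp <- template_pelvis()
  gt <- attr(tp, "ground_truth")
  expect_equal(unname(plane_orientation(construct_reference_plane(tp, "SSP"))[1]),
               gt$sacral_slope, tolerance = 1e-9)
})

test_that("morphological parameters are rigid-invariant, 13 distances + 5 angles", {
  tp <- template_pelvis()
  mp <- morphological_parameters(tp)
  expect_length(mp, 18)
  reg <- default_morpho_registry()
  expect_length(reg$distances, 13)
  expect_length(reg$angles, 5)
  set.seed(5)
  for (k in 1:10) {
    R <- random_rotation()
    t <- rnorm(3, 0, 50)
    mp2 <- morphological_parameters(transform_landmarks(tp, R, t))
    expect_equal(mp2, mp, tolerance = 1e-9)
  }
})

test_that("scaling doubles distances and leaves angles unchanged", {
  tp <- template_pelvis()
  mp1 <- morphological_parameters(tp)
  mp2 <- morphological_parameters(template_pelvis(scale = 2))
  reg <- default_morpho_registry()
  dn <- names(reg$distances); an <- names(reg$angles)
  expect_equal(unname(mp2[dn] / mp1[dn]), rep(2, 13), tolerance = 1e-12)
  expect_equal(mp2[an], mp1[an], tolerance = 1e-9)
})

test_that("pelvic incidence matches an independent dot-product oracle", {
  tp <- template_pelvis()
  # oracle in the sagittal plane: all defining points are on the midline
  yz <- function(nm) tp[nm, c("y", "z")]
  tangent <- yz("S1_endplate_anterior") - yz("S1_endplate_posterior")
  perp <- c(tangent[2], -tangent[1])  # rotate -90 deg: points infero-posterior
  v <- (yz("hip_center_L") + yz("hip_center_R")) / 2 - yz("S1_endplate_center")
  if (sum(perp * v) < 0) perp <- -perp
  oracle <- acos(sum(perp * v) / sqrt(sum(perp^2) * sum(v^2))) / deg2rad
  expect_equal(pelvic_incidence(tp), unname(oracle), tolerance = 1e-9)
  expect_equal(pelvic_incidence(tp),
               attr(tp, "ground_truth")$pelvic_incidence, tolerance = 1e-9)
})

test_that("pelvic incidence is zero when the endplate perpendicular hits the hip midpoint", {
  coords <- unclass(template_pelvis())
  # horizontal endplate centred above the hip-centre midpoint
  hjc <- (coords["hip_center_L", ] + coords["hip_center_R", ]) / 2
  coords["S1_endplate_center", ] <- hjc + c(0, 0, 110)
  coords["S1_endplate_anterior", ] <- hjc + c(0, 14, 110)
  coords["S1_endplate_posterior", ] <- hjc + c(0, -14, 110)
  expect_equal(pelvic_incidence(landmark_set(coords)), 0, tolerance = 1e-9)
})

test_that("registry counts are enforced but identities are configurable", {
  tp <- template_pelvis()
  reg <- default_morpho_registry()
  reg$distances$pubic_symphysis_to_hjc_midpoint <- NULL
  expect_error(morphological_parameters(tp, reg), "13 distances")
  reg <- default_morpho_registry()
  reg$angles$extra <- function(lm) 0
  expect_error(morphological_parameters(tp, reg), "5 angles")
  reg <- default_morpho_registry()
  reg$distances$inter_hip_center_width <- c("ASIS_L", "hip_center_L")
  mp <- morphological_parameters(tp, reg)
  expect_length(mp, 18)
})

test_that("lumbar lordosis angle follows the endplate tangents", {
  base <- unclass(template_pelvis())
  # parallel endplates -> 0
  lm <- base
  lm["L1sup_a", ] <- lm["S1_endplate_anterior", ] + c(0, 0, 100)
  lm["L1sup_p", ] <- lm["S1_endplate_posterior", ] + c(0, 0, 100)
  expect_equal(lumbar_lordosis_angle(landmark_set(lm)), 0, tolerance = 1e-9)
  # L1 at +30 deg, S1 at -18 deg -> 48
  lm <- base
  lm["L1sup_a", ] <- c(0, 20 * cos(30 * deg2rad), 150 + 20 * sin(30 * deg2rad))
  lm["L1sup_p", ] <- c(0, -20 * cos(30 * deg2rad), 150 - 20 * sin(30 * deg2rad))
  lm["S1_endplate_anterior", ] <- c(0, 14 * cos(18 * deg2rad), 41 - 14 * sin(18 * deg2rad))
  lm["S1_endplate_posterior", ] <- c(0, -14 * cos(18 * deg2rad), 41 + 14 * sin(18 * deg2rad))
  expect_equal(lumbar_lordosis_angle(landmark_set(lm)), 48, tolerance = 1e-9)
  # the fused measurement ignores the S1 points entirely
  tp <- template_pelvis()
  fused1 <- lumbar_lordosis_angle(tp, l5s1_fused = TRUE)
  moved <- unclass(tp)
  moved["S1_endplate_anterior", ] <- moved["S1_endplate_anterior", ] + 30
  fused2 <- lumbar_lordosis_angle(landmark_set(moved), l5s1_fused = TRUE)
  expect_equal(fused1, fused2)
  expect_equal(fused1, attr(tp, "ground_truth")$lla_fused, tolerance = 1e-9)
  expect_equal(lumbar_lordosis_angle(tp), attr(tp, "ground_truth")$lla,
               tolerance = 1e-9)
  expect_error(
    lumbar_lordosis_angle(landmark_set(rbind(L1sup_a = c(0, 1, 2)))),
    "missing landmark")
})

test_that("landmark JSON round-trips and the loader validates", {
  tp <- template_pelvis()
  path <- tempfile(fileext = ".json")
  write_landmarks(tp, path)
  back <- read_landmarks(path)
  expect_equal(unclass(back), unclass(tp), tolerance = 1e-12,
               ignore_attr = TRUE)
  bad <- tempfile(fileext = ".json")
  writeLines('{"ASIS_L": [1, 2]}', bad)
  expect_error(read_landmarks(bad), "3 numeric coordinates")
})

test_that("shipped template fixture matches the in-code template", {
  path <- system.file("extdata", "template_pelvis.json", package = "pelvisop")
  expect_true(nzchar(path))
  fixture <- read_landmarks(path)
  tp <- template_pelvis()
  expect_equal(unclass(fixture)[rownames(tp), ], unclass(tp),
               tolerance = 1e-12, ignore_attr = TRUE)
})
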