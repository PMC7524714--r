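# Shared fixtures and independent oracles used across test files.

deg2rad <- pi / 180

# independent elementary rotation matrices (hand-written trig, not the
# package's constructors)
oracle_rx_anterior <- function(deg) {
  a <- deg * deg2rad
  matrix(c(1, 0, 0,
           0, cos(a), sin(a),
           0, -sin(a), cos(a)), 3, 3, byrow = TRUE)
}
oracle_ry <- function(deg) {
  b <- deg * deg2rad
  matrix(c(cos(b), 0, sin(b),
           0, 1, 0,
           -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
}
oracle_rz <- function(deg) {
  g <- deg * deg2rad
  matrix(c(cos(g), -sin(g), 0,
           sin(g), cos(g), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

# random proper rotation via QR
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# angle (deg) of the relative rotation between two rotation matrices;
# atan2 form stays accurate near the identity
rotation_angle_between <- function(R1, R2) {
  D <- t(R1) %*% R2
  s <- sqrt(sum(c(D[3, 2] - D[2, 3], D[1, 3] - D[3, 1],
                  D[2, 1] - D[1, 2])^2)) / 2
  co <- (sum(diag(D)) - 1) / 2
  atan2(s, co) / deg2rad
}

# rigidly transform a landmark set
transform_landmarks <- function(lm, R, t = c(0, 0, 0)) {
  gt <- attr(lm, "ground_truth")
  out <- landmark_set(sweep(unclass(lm) %*% t(R), 2, t, `+`))
  attr(out, "ground_truth") <- gt
  out
}

# small OLS problem used by several selection tests
make_toy_regression <- function(n = 60, p = 5, seed = 42, sd = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("v", seq_len(p))
  beta <- rep_len(c(2, -1, 0, 0, 0.5), p)
  y <- 1.5 + X %*% beta + rnorm(n, 0, sd)
  list(X = X, y = as.numeric(y), beta = beta)
}
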