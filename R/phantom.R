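# Phantom accuracy protocol: measure the SOP at controlled orientations and
# summarise the corrected errors, mirroring the published evaluation table.

#' Run the phantom accuracy protocol
#'
#' For each controlled phantom orientation and repeat, generates biplanar
#' views with seeded pick noise, measures the SOP for the requested reference
#' planes by landmark registration, and corrects each measurement by
#' subtracting the mean measurement at the neutral orientation and the
#' applied sagittal offset: `SOP - mean(SOP(0,0,0)) - d_sop`. At the exact
#' registration limit (zero noise) every corrected value is zero.
#'
#' Pick noise is the only error source modelled; registration runs on the
#' picked landmarks alone so that the declared noise model drives the error.
#'
#' @param lm a [landmark_set()] standing in for the physical phantom.
#' @param poses data frame of controlled offsets (columns `d_sop`, `d_fop`,
#'   `d_top`); must contain the neutral pose. Default: [phantom_pose_grid()].
#' @param repeats measurements per pose.
#' @param pick_noise_sd pick noise SD in mm.
#' @param seed RNG seed for the whole protocol.
#' @param planes reference planes to evaluate.
#' @return A data frame of class `"phantom_report"`: per pose and plane the
#'   mean, SD, min and max of the corrected values, plus pooled rows
#'   `"all values"` and `"all absolute values"`. Raw corrected values are in
#'   `attr(, "corrected")`.
#' @export
run_phantom_protocol <- function(lm, poses = phantom_pose_grid(),
                                 repeats = 5, pick_noise_sd = 0.5, seed = 1,
                                 planes = c("SSP", "PTP", "APP")) {
  stopifnot(repeats >= 1)
  neutral <- which(poses$d_sop == 0 & poses$d_fop == 0 & poses$d_top == 0)
  if (length(neutral) == 0)
    stop("poses must include the neutral orientation (0, 0, 0): ",
         "the reference value is undefined without it")
  set.seed(seed)
  n_pose <- nrow(poses)
  raw <- array(NA_real_, c(n_pose, repeats, length(planes)),
               dimnames = list(NULL, NULL, planes))
  ref_planes <- lapply(planes, function(id) construct_reference_plane(lm, id))
  names(ref_planes) <- planes
  for (i in seq_len(n_pose)) {
    for (r in seq_len(repeats)) {
      v <- generate_phantom_views(lm, poses$d_sop[i], poses$d_fop[i],
                                  poses$d_top[i],
                                  pick_noise_sd = pick_noise_sd)
      p <- preregister(lm, v)
      for (pl in planes) raw[i, r, pl] <- plane_orientation(ref_planes[[pl]], p)[1]
    }
  }
  corrected <- raw
  for (pl in planes) {
    neutral_mean <- mean(raw[neutral, , pl])
    corrected[, , pl] <- raw[, , pl] - neutral_mean - poses$d_sop
  }
  summarise <- function(x) c(mean = mean(x), sd = sd(x), min = min(x),
                             max = max(x))
  rows <- list()
  for (i in seq_len(n_pose)) {
    row <- data.frame(d_sop = poses$d_sop[i], d_fop = poses$d_fop[i],
                      d_top = poses$d_top[i])
    for (pl in planes) {
      s <- summarise(corrected[i, , pl])
      names(s) <- paste0(pl, "_", names(s))
      row <- cbind(row, as.data.frame(as.list(s)))
    }
    rows[[i]] <- row
  }
  pooled <- function(f, label) {
    row <- data.frame(d_sop = NA, d_fop = NA, d_top = NA)
    for (pl in planes) {
      s <- summarise(f(as.vector(corrected[, , pl])))
      names(s) <- paste0(pl, "_", names(s))
      row <- cbind(row, as.data.frame(as.list(s)))
    }
    rownames(row) <- label
    row
  }
  out <- do.call(rbind, rows)
  out <- rbind(out, pooled(identity, "all values"),
               pooled(abs, "all absolute values"))
  attr(out, "corrected") <- corrected
  attr(out, "planes") <- planes
  class(out) <- c("phantom_report", "data.frame")
  out
}

#' Pooled mean absolute corrected SOP error
#'
#' @param report a phantom report from [run_phantom_protocol()].
#' @param plane reference plane.
#' @return Pooled mean of the absolute corrected values, in degrees.
#' @export
pooled_abs_error <- function(report, plane = "SSP") {
  corrected <- attr(report, "corrected")
  stopifnot(plane %in% dimnames(corrected)[[3]])
  mean(abs(as.vector(corrected[, , plane])))
}

#' @export
print.phantom_report <- function(x, digits = 2, ...) {
  cat("phantom accuracy protocol:",
      sum(!is.na(x$d_sop)), "poses,",
      dim(attr(x, "corrected"))[2], "repeats\n")
  cat("corrected SOP error, mean (SD, min to max) per plane:\n")
  df <- as.data.frame(x)
  print(round(df[, -(1:3)], digits))
  invisible(x)
}

#' Write a phantom report as CSV
#'
#' @param report a phantom report.
#' @param path output path.
#' @export
write_phantom_report <- function(report, path) {
  write.csv(as.data.frame(report), path, row.names = TRUE,
            fileEncoding = "UTF-8")
  invisible(path)
}
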