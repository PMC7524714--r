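# Descriptive statistics, hypothesis-test wrappers, predictor assembly and
# study configuration.

#' Descriptive statistics in "mean (SD, min to max)" form
#'
#' @param x numeric vector with at least 2 values.
#' @return Named vector `c(mean, sd, min, max, n)` of class
#'   `"descriptive_stats"`; printed as `"mean (SD, min to max)"` with sample
#'   SD (n - 1 denominator).
#' @export
descriptive_stats <- function(x) {
  x <- x[!is.na(x)]
  stopifnot(length(x) >= 2)
  structure(c(mean = mean(x), sd = sd(x), min = min(x), max = max(x),
              n = length(x)),
            class = "descriptive_stats")
}

#' @rdname descriptive_stats
#' @param digits decimals in the formatted string.
#' @export
format_descriptive <- function(x, digits = 1) {
  if (!inherits(x, "descriptive_stats")) x <- descriptive_stats(x)
  sprintf("%.*f (%.*f, %.*f to %.*f)", digits, x[["mean"]], digits,
          x[["sd"]], digits, x[["min"]], digits, x[["max"]])
}

#' @export
print.descriptive_stats <- function(x, digits = 1, ...) {
  cat(format_descriptive(x, digits), "\n")
  invisible(x)
}

#' Two-sided hypothesis-test wrappers
#'
#' Thin wrappers returning `(statistic, p)` for a paired t-test, a two-sample
#' (Welch) t-test and a one-way ANOVA, all two-sided.
#'
#' @param x,y numeric samples (paired vectors for `paired_t`).
#' @return Named vector `c(statistic, p)`.
#' @export
paired_t <- function(x, y) {
  d <- x - y
  if (all(d == 0)) return(c(statistic = 0, p = 1))  # identical samples
  ht <- t.test(x, y, paired = TRUE)
  c(statistic = unname(ht$statistic), p = ht$p.value)
}

#' @rdname paired_t
#' @export
two_sample_t <- function(x, y) {
  ht <- t.test(x, y)
  c(statistic = unname(ht$statistic), p = ht$p.value)
}

#' @rdname paired_t
#' @param values numeric vector of observations.
#' @param groups factor (or coercible) of group labels, sizes >= 2.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(all(table(groups) >= 2))
  sm <- summary(aov(values ~ groups))[[1]]
  c(statistic = sm[["F value"]][1], p = sm[["Pr(>F)"]][1])
}

#' Predictor registry
#'
#' Names of the predictors by group: 5 biometric, 18 morphological (from
#' [default_morpho_registry()]) and 10 functional (supine and standing SOP,
#' standing LLA, L5-S1 fusion check, six range-of-motion measures). Scenario
#' A (supine CT only) excludes the standing SOP and the LLA, leaving 31
#' predictors; scenario B uses all 33.
#'
#' @param scenario `"A"`, `"B"` or `"all"`.
#' @return Named list of character vectors (`biometric`, `morphological`,
#'   `functional`).
#' @export
predictor_registry <- function(scenario = c("all", "A", "B")) {
  scenario <- match.arg(scenario)
  reg <- default_morpho_registry()
  functional <- c("supine_sop", "standing_sop", "lla", "l5s1_fused",
                  rom_names())
  if (scenario == "A")
    functional <- setdiff(functional, c("standing_sop", "lla"))
  list(biometric = c("sex", "age", "height", "weight", "bmi"),
       morphological = c(names(reg$distances), names(reg$angles)),
       functional = functional)
}

#' Assemble the predictor matrix of a cohort
#'
#' Selects and orders the scenario's predictor columns (31 for scenario A, 33
#' for scenario B) as a numeric matrix; `sex` and `l5s1_fused` are coded 0/1.
#'
#' @param cohort data frame (see [generate_cohort()]).
#' @param scenario `"A"` or `"B"`.
#' @return Numeric matrix with one column per predictor.
#' @export
assemble_predictors <- function(cohort, scenario = c("A", "B")) {
  scenario <- match.arg(scenario)
  reg <- predictor_registry(scenario)
  cols <- unlist(reg, use.names = FALSE)
  missing <- setdiff(cols, names(cohort))
  if (length(missing))
    stop("cohort is missing predictor column(s): ",
         paste(missing, collapse = ", "))
  X <- as.matrix(cohort[, cols])
  storage.mode(X) <- "double"
  X
}

#' Study configuration
#'
#' Bundles the analysis constants: significance level (two-sided, 0.001),
#' the coefficient exclusion floor (1e-3), cohort size, scenario, seed and
#' noise parameters.
#'
#' @param seed RNG seed.
#' @param scenario `"A"` or `"B"`.
#' @param n cohort size.
#' @param alpha two-sided significance level, in `(0, 0.05]`.
#' @param coef_floor LASSO coefficient exclusion threshold.
#' @param pick_noise_sd phantom pick noise SD (mm).
#' @param exclude_multilevel_fusion drop subjects flagged with fusion of more
#'   than two lumbar vertebrae (always absent in default synthetic cohorts).
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(seed = 1, scenario = "B", n = 196, alpha = 0.001,
                         coef_floor = 1e-3, pick_noise_sd = 0.5,
                         exclude_multilevel_fusion = TRUE) {
  stopifnot(alpha > 0, alpha <= 0.05, coef_floor >= 0, n >= 10)
  structure(list(seed = seed, scenario = match.arg(scenario, c("A", "B")),
                 n = as.integer(n), alpha = alpha, coef_floor = coef_floor,
                 pick_noise_sd = pick_noise_sd,
                 exclude_multilevel_fusion = exclude_multilevel_fusion),
            class = "study_config")
}
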