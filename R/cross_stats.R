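#' Read an F2 phenotype table
#'
#' @param path TSV with columns `individual` (unique ids) and `fsi`
#'   (fruit shape index, longitudinal / transverse diameter, > 0).
#' @return Data frame `individual`, `fsi`.
#' @export
read_phenotype_table <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(ph)[1:2] <- c("individual", "fsi")
  if (anyDuplicated(ph$individual)) stop("duplicate individual ids")
  if (any(!is.finite(ph$fsi)) || any(ph$fsi <= 0))
    stop("fsi values must be finite and positive")
  ph
}

#' Descriptive statistics of a fruit-shape-index distribution
#'
#' Mean, sample sd (divisor n-1), range, moment skewness
#' `g1 = m3 / m2^(3/2)`, excess kurtosis `g2 = m4 / m2^2 - 3` (central
#' moments with divisor n), and the coefficient of variation
#' `100 * sd / mean`. Bias-corrected skewness/kurtosis (G1, G2) are available
#' behind `bias_correct`.
#'
#' @param fsi Numeric vector (or a data frame with an `fsi` column); n >= 2.
#' @param bias_correct Use small-sample corrected G1/G2 (default `FALSE`).
#' @return An object of class `fsi_describe` with fields `n`, `mean`, `sd`,
#'   `min`, `max`, `skew`, `kurtosis`, `cv_percent`.
#' @export
describe_fsi <- function(fsi, bias_correct = FALSE) {
  if (is.data.frame(fsi)) fsi <- fsi$fsi
  fsi <- fsi[!is.na(fsi)]
  n <- length(fsi)
  if (n < 2L) stop("need at least 2 observations")
  m <- mean(fsi)
  s <- stats::sd(fsi)
  m2 <- mean((fsi - m)^2)
  m3 <- mean((fsi - m)^3)
  m4 <- mean((fsi - m)^4)
  if (m2 == 0) {
    skew <- kurt <- NA_real_
  } else {
    skew <- m3 / m2^1.5
    kurt <- m4 / m2^2 - 3
    if (bias_correct) {
      if (n < 4L) stop("bias-corrected moments need n >= 4")
      skew <- skew * sqrt(n * (n - 1)) / (n - 2)
      kurt <- ((n + 1) * kurt + 6) * (n - 1) / ((n - 2) * (n - 3))
    }
  }
  structure(list(n = n, mean = m, sd = s, min = min(fsi), max = max(fsi),
                 skew = skew, kurtosis = kurt,
                 cv_percent = 100 * s / m),
            class = "fsi_describe")
}

#' @export
print.fsi_describe <- function(x, digits = 3, ...) {
  cat("FSI descriptives (n =", x$n, ")\n")
  v <- unlist(x[c("mean", "sd", "min", "max", "skew", "kurtosis",
                  "cv_percent")])
  print(round(v, digits))
  invisible(x)
}

#' Classify fruit shape from the shape index
#'
#' @param fsi Numeric vector of fruit shape indices (> 0).
#' @param threshold Class boundary (default 1.0): oval iff `fsi > threshold`,
#'   round iff `fsi <= threshold`.
#' @return Character vector in `{"oval", "round"}`.
#' @export
classify_shape <- function(fsi, threshold = 1.0) {
  ifelse(fsi > threshold, "oval", "round")
}

#' Chi-square goodness-of-fit test for a Mendelian segregation ratio
#'
#' Tests observed dominant:recessive counts against an expected ratio
#' (3:1 by default) with the uncorrected Pearson statistic (no Yates
#' continuity correction), 1 degree of freedom, critical value 3.841 at the
#' 5% level.
#'
#' @param n_dominant,n_recessive Observed class counts.
#' @param ratio Expected dominant:recessive ratio as a length-2 vector
#'   (default `c(3, 1)`).
#' @param critical Critical value (default 3.841).
#' @return An object of class `segregation_test`: counts, `expected`, `chi2`,
#'   `df`, `p_value`, `critical`, `conforms`.
#' @export
chi_square_3to1 <- function(n_dominant, n_recessive, ratio = c(3, 1),
                            critical = 3.841) {
  n <- n_dominant + n_recessive
  if (n < 1L) stop("zero total count")
  p <- ratio / sum(ratio)
  expected <- n * p
  obs <- c(n_dominant, n_recessive)
  chi2 <- sum((obs - expected)^2 / expected)
  structure(list(n_dominant = n_dominant, n_recessive = n_recessive,
                 expected = expected, chi2 = chi2, df = 1L,
                 p_value = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
                 critical = critical, conforms = chi2 < critical),
            class = "segregation_test")
}

#' @export
print.segregation_test <- function(x, ...) {
  cat(sprintf("segregation %d:%d vs expected %.2f:%.2f\n",
              x$n_dominant, x$n_recessive, x$expected[1], x$expected[2]))
  cat(sprintf("chi2 = %.4f (df = 1, critical = %.3f, p = %.4g): %s\n",
              x$chi2, x$critical, x$p_value,
              if (x$conforms) "conforms" else "does not conform"))
  invisible(x)
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target,test - Ct_ref,test) - (Ct_target,calib - Ct_ref,calib)`;
#' fold change `= 2^-ddCt`.
#'
#' @param ct_target_test,ct_ref_test Ct of target and reference gene in the
#'   test sample.
#' @param ct_target_calib,ct_ref_calib Same in the calibrator sample.
#' @return Fold change (vectorised).
#' @export
ddct_fold_change <- function(ct_target_test, ct_ref_test,
                             ct_target_calib, ct_ref_calib) {
  stopifnot(is.finite(ct_target_test), is.finite(ct_ref_test),
            is.finite(ct_target_calib), is.finite(ct_ref_calib))
  ddct <- (ct_target_test - ct_ref_test) -
    (ct_target_calib - ct_ref_calib)
  2^(-ddct)
}

#' Percentage of a cohort
#'
#' Report helper: the share of `count` in `total` as a percentage rounded to
#' `digits` decimals (e.g. a 147-genotype subgroup of 577 accessions is
#' 25.48%).
#'
#' @param count,total Non-negative counts, `total > 0`.
#' @param digits Decimals to round to (default 2).
#' @return Percentage value.
#' @export
percent_share <- function(count, total, digits = 2) {
  if (any(total <= 0)) stop("total must be positive")
  round(100 * count / total, digits)
}
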