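# Population-differentiation metrics.
#
# For a locus observed in s subpopulations with allele frequencies p_1..p_s
# and sample sizes n_1..n_s (allele copies), the unbiased F_ST estimate is
#
#   F_ST = (MSP - MSG) / (MSP + (n_c - 1) * MSG)
#
# with the within-population mean square
#   MSG = sum_i n_i p_i (1 - p_i) / (sum_i n_i - 1)          ["printed" form]
#       = sum_i n_i p_i (1 - p_i) / (sum_i n_i - s)          ["classical" form]
# the between-population mean square
#   MSP = sum_i n_i (p_i - p_w)^2 / (s - 1),  p_w = sum n_i p_i / sum n_i
# and the variance-corrected average sample size
#   n_c = (sum n_i - sum n_i^2 / sum n_i) / (s - 1).
#
# The dispersion score is DS = sqrt( sum_i (p_i - p_u)^2 / n_tot ) with the
# unweighted mean p_u = sum p_i / s and n_tot the total sample size.

#' Unbiased F_ST estimate per locus
#'
#' Computes the mean-square components and the unbiased F_ST estimate for
#' every locus of a frequency table. At a monomorphic locus (all frequencies
#' jointly 0 or jointly 1) both mean squares vanish and the estimate is
#' undefined (`defined = FALSE`, `fst = NA`). The estimator can be negative
#' at low differentiation; raw values are reported unless
#' `clampNonnegative = TRUE`, which maps negatives to 0 (the convention used
#' when F_ST enters the feature matrix).
#'
#' @param t a [PopulationFrequencyTable-class] with `s >= 2` populations.
#' @param msgDenominator `"printed"` uses `sum(n_i) - 1` in MSG (the default);
#'   `"classical"` uses `sum(n_i) - s`, the standard literature form.
#' @param clampNonnegative clamp negative estimates to 0.
#' @return data.frame with one row per locus: `msg`, `msp`, `n_c`, `fst`,
#'   `p_w` (weighted mean frequency), `p_u` (unweighted mean), `defined`.
#' @export
fstUnbiased <- function(t, msgDenominator = c("printed", "classical"),
                        clampNonnegative = FALSE) {
  msgDenominator <- match.arg(msgDenominator)
  p <- t@p; n <- as.numeric(t@n); s <- length(n)
  if (s < 2L) stop("F_ST requires at least two populations")
  ntot <- sum(n)
  if (ntot <= 1) stop("total sample size must exceed 1")
  denom <- if (msgDenominator == "printed") ntot - 1 else ntot - s
  msg <- as.numeric((p * (1 - p)) %*% n) / denom
  p_w <- as.numeric(p %*% n) / ntot
  msp <- as.numeric((p - p_w)^2 %*% n) / (s - 1)
  n_c <- (ntot - sum(n^2) / ntot) / (s - 1)
  den <- msp + (n_c - 1) * msg
  defined <- den != 0
  fst <- ifelse(defined, (msp - msg) / den, NA_real_)
  if (clampNonnegative) fst <- pmax(fst, 0)
  data.frame(msg = msg, msp = msp, n_c = n_c, fst = fst,
             p_w = p_w, p_u = rowMeans(p), defined = defined)
}

#' Dispersion score per locus
#'
#' Square root of the summed squared deviations of the subpopulation
#' frequencies from their unweighted mean, divided by the *total sample size*
#' (not the number of populations): the score is defined operationally, not
#' as a textbook variance. It is 0 exactly when all frequencies are equal.
#'
#' @param t a [PopulationFrequencyTable-class].
#' @return numeric vector of nonnegative scores, one per locus.
#' @export
dispersionScore <- function(t) {
  if (length(t@n) < 2L) stop("dispersion score requires at least two populations")
  sqrt(rowSums((t@p - rowMeans(t@p))^2) / sum(as.numeric(t@n)))
}

#' Genetic differentiation category
#'
#' `fst <= 0.05` is "little", `0.05 < fst <= 0.25` "moderate", `fst > 0.25`
#' "large" differentiation (boundaries closed on the left category).
#'
#' @param fst numeric F_ST estimates; must be defined (no `NA` from
#'   monomorphic loci).
#' @return character vector in `{"little", "moderate", "large"}`.
#' @export
fstCategory <- function(fst) {
  if (any(is.na(fst)))
    stop("undefined F_ST (monomorphic locus); handle undefined loci before categorizing")
  ifelse(fst <= 0.05, "little", ifelse(fst <= 0.25, "moderate", "large"))
}

#' Population-preference calls
#'
#' A population is flagged `"higher"` at a locus when its allele frequency
#' exceeds every other population's by at least `margin`, `"lower"` when it is
#' below every other by at least `margin`, else `"none"`. At most one
#' population can be higher and at most one lower per locus.
#'
#' @param t a [PopulationFrequencyTable-class].
#' @param margin required frequency gap, in (0, 1); default 0.10.
#' @return character matrix, loci x populations, with values
#'   `"higher"`, `"lower"` or `"none"`.
#' @export
populationPreference <- function(t, margin = 0.10) {
  if (margin <= 0 || margin >= 1) stop("margin must lie in (0, 1)")
  p <- t@p; s <- ncol(p)
  if (s < 2L) stop("population preference requires at least two populations")
  out <- matrix("none", nrow(p), s, dimnames = list(NULL, t@populations))
  for (i in seq_len(s)) {
    others <- p[, -i, drop = FALSE]
    hi <- p[, i] >= apply(others, 1L, max) + margin
    lo <- p[, i] <= apply(others, 1L, min) - margin
    out[hi, i] <- "higher"
    out[lo, i] <- "lower"
  }
  out
}
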