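#' Delete-one-group jackknife standard error (JK1)
#'
#' `SE = sqrt(((R - 1) / R) * sum((theta_r - theta_hat)^2))`, the JK1
#' convention for a full set of delete-one-group replicate weights.
#'
#' @param theta_hat full-sample point estimate.
#' @param theta_r vector of replicate estimates (length R >= 2, finite).
#' @return the standard error.
#' @export
jackknife_se <- function(theta_hat, theta_r) {
  r <- length(theta_r)
  if (r < 2) stop("need at least 2 replicate estimates", call. = FALSE)
  if (any(!is.finite(theta_r)))
    stop("replicate estimates must be finite", call. = FALSE)
  sqrt((r - 1) / r * sum((theta_r - theta_hat)^2))
}

#' Compare current and modeled scenario estimates
#'
#' Two-sided t-test of the difference between two estimates computed on the
#' same replicate-weight set.  By default the comparison is paired on
#' replicates: the jackknife SE is taken on the per-replicate differences,
#' exploiting the correlation between scenarios run on the same sample.  The
#' `independent` option combines the two scenario SEs instead.
#'
#' @param current,modeled lists with `estimate` and `replicates` (equal
#'   replicate counts), e.g. built from [usual_intake_exceedance()] output.
#' @param paired pair on replicates (default `TRUE`).
#' @return list with `difference`, `se`, `t`, `p` (two-sided, `R - 1` df) and
#'   `df`.
#' @export
compare_scenarios <- function(current, modeled, paired = TRUE) {
  if (length(current$replicates) != length(modeled$replicates))
    stop("replicate counts differ between scenarios", call. = FALSE)
  r <- length(current$replicates)
  diff <- modeled$estimate - current$estimate
  if (paired) {
    se <- jackknife_se(diff, modeled$replicates - current$replicates)
  } else {
    se <- sqrt(jackknife_se(current$estimate, current$replicates)^2 +
                 jackknife_se(modeled$estimate, modeled$replicates)^2)
  }
  tstat <- if (se == 0) {
    if (diff == 0) 0 else sign(diff) * Inf
  } else diff / se
  p <- 2 * stats::pt(-abs(tstat), df = r - 1)
  list(difference = diff, se = se, t = tstat, p = p, df = r - 1)
}

#' Survey-weighted proportion with jackknife inference
#'
#' `100 * sum(w * flag) / sum(w)`, with a JK1 standard error from replicate
#' weights when supplied and a 95% confidence interval clipped to [0, 100].
#'
#' @param flags logical vector.
#' @param weights positive analytic weights.
#' @param replicate_weights optional replicate-weight matrix aligned with
#'   `flags`.
#' @return list with `percent`, `se`, `ci95` and `n_unweighted`.
#' @export
weighted_proportion <- function(flags, weights, replicate_weights = NULL) {
  if (any(weights < 0)) stop("weights must be >= 0", call. = FALSE)
  if (sum(weights) == 0) stop("total weight is zero", call. = FALSE)
  est <- 100 * sum(weights * flags) / sum(weights)
  se <- NA_real_
  ci <- c(NA_real_, NA_real_)
  if (!is.null(replicate_weights)) {
    reps <- vapply(seq_len(ncol(replicate_weights)), function(r) {
      w <- replicate_weights[, r]
      # a replicate that deletes the whole domain carries no information
      # about its variability; the convention is a zero contribution
      if (sum(w) == 0) est else 100 * sum(w * flags) / sum(w)
    }, numeric(1))
    se <- jackknife_se(est, reps)
    ci <- pmin(100, pmax(0, est + c(-1.96, 1.96) * se))
  }
  list(percent = est, se = se, ci95 = ci, n_unweighted = sum(flags))
}
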