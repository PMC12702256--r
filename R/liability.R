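#' Robertson observed-to-liability transformation
#'
#' Rescales a heritability estimated on the observed 0/1 scale of a binary
#' trait to the latent liability scale: `h2_liab = h2_obs * K(1 - K) / z^2`,
#' where `K` is the trait prevalence, `t = qnorm(1 - K)` the liability
#' threshold and `z = dnorm(t)` the standard-normal density at the threshold.
#' The multiplier equals `pi/2` at `K = 0.5` and grows symmetrically as the
#' prevalence departs from one half. The transformation is linear, so a
#' standard error supplied alongside is propagated exactly by the same
#' multiplier.
#'
#' No ascertainment correction is applied: the transformation assumes the
#' estimation sample is population-sampled, so sample prevalence equals
#' population prevalence.
#'
#' @param h2Observed observed-scale heritability in `[0, 1]`.
#' @param K prevalence in the open interval (0, 1).
#' @param se optional standard error of `h2Observed`.
#' @return List with `h2Liability`, `multiplier`, `threshold`, `z`, and
#'   `seLiability` when `se` was given.
#' @examples
#' robertsonLiability(0.1, 0.5)$h2Liability   # 0.1 * pi/2
#' @export
robertsonLiability <- function(h2Observed, K, se = NULL) {
  if (any(K <= 0 | K >= 1)) stop("prevalence K must lie strictly in (0, 1)")
  if (any(h2Observed < 0 | h2Observed > 1))
    stop("h2Observed must lie in [0, 1]")
  t <- stats::qnorm(1 - K)
  z <- stats::dnorm(t)
  mult <- K * (1 - K) / z^2
  out <- list(h2Liability = h2Observed * mult, multiplier = mult,
              threshold = t, z = z)
  if (!is.null(se)) out$seLiability <- se * mult
  out
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up FDR-adjusted q-values via [stats::p.adjust()]. Output is bounded
#' below by the input p-values and above by 1.
#'
#' @param p numeric p-values in `[0, 1]` (empty input gives empty output).
#' @return q-values, same length as `p`.
#' @examples
#' fdrBH(c(0.01, 0.02, 0.03, 0.04))   # all 0.04
#' @export
fdrBH <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
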