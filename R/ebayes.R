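# Empirical-Bayes variance moderation for protein-wise one-sample tests.
#
# The per-protein sample variances s_i^2 (d_i residual df each) are modeled
# as s_i^2 | sigma_i^2 ~ sigma_i^2 chisq(d_i)/d_i with a scaled inverse
# chi-square prior sigma_i^2 ~ s0^2 d0 / chisq(d0). The prior (d0, s0^2) is
# estimated by moment-matching the log-variances: marginally
#   E[log s_i^2] = log s0^2 + psi(d_i/2) - log(d_i/2) - psi(d0/2) + log(d0/2)
#   Var[log s_i^2] = psi'(d_i/2) + psi'(d0/2),
# so d0 solves var{e_i} - mean psi'(d_i/2) = psi'(d0/2) with
# e_i = log s_i^2 - psi(d_i/2) + log(d_i/2), inverted by Newton iteration on
# the trigamma function. When the spread of log-variances does not exceed
# what sampling alone explains, d0 is infinite and the prior collapses to
# the (geometric-mean-based) pooled variance.

#' Invert the trigamma function
#'
#' Solves `trigamma(y) = x` for `y > 0` by Newton iteration on `1/trigamma`
#' (which is nearly linear), the standard approach for moment-based
#' estimation of inverse-chi-square priors.
#'
#' @param x positive values.
#' @return `y` with `trigamma(y) = x`; `Inf` maps to 0-like behaviour is not
#'   needed here (`x <= 0` returns `Inf`).
#' @export
trigamma_inverse <- function(x) {
  out <- x
  large <- is.finite(x) & x > 1e7
  out[large] <- 1 / sqrt(x[large])
  small <- is.finite(x) & x < 1e-6
  out[small] <- 1 / x[small]
  mid <- is.finite(x) & !large & !small
  if (any(mid)) {
    xm <- x[mid]
    y <- 0.5 + 1 / xm
    for (iter in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xm) / psigamma(y, deriv = 2L)
      y <- y + dif
      if (max(abs(dif / y)) < 1e-8) break
    }
    out[mid] <- y
  }
  out[!is.finite(x) & x == Inf] <- 0
  out[x <= 0] <- Inf
  out
}

#' Fit the empirical-Bayes variance prior
#'
#' @param s2 per-protein sample variances (> 0; nonpositive or missing
#'   entries are dropped with a warning).
#' @param df per-protein residual degrees of freedom (>= 1), recycled.
#' @return list of class `ebayes_prior` with elements `d0` (prior df,
#'   possibly `Inf`), `s0_sq` (prior variance), and `n_used`.
#' @export
fit_ebayes_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & is.finite(df) & df >= 1
  if (sum(!ok) > 0 && sum(ok) > 0)
    warning(sum(!ok), " variance(s) dropped (nonpositive, missing, or df < 1)")
  s2 <- s2[ok]; df <- df[ok]
  if (length(s2) < 10L)
    stop("need at least 10 proteins with positive variance and df >= 1 to fit the prior (got ",
         length(s2), ")")
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  structure(list(d0 = d0, s0_sq = s0_sq, n_used = length(s2)),
            class = "ebayes_prior")
}

#' @export
print.ebayes_prior <- function(x, ...) {
  cat("empirical-Bayes variance prior: d0 =",
      if (is.finite(x$d0)) signif(x$d0, 4) else "Inf",
      ", s0^2 =", signif(x$s0_sq, 4),
      " (fit on", x$n_used, "proteins)\n")
  invisible(x)
}

#' Moderated one-sample t-test
#'
#' Shrinks each protein's variance toward the prior,
#' `s2_post = (d0 s0^2 + d_i s_i^2) / (d0 + d_i)` (equal to `s0^2` when
#' `d0` is infinite and to `s_i^2` when `d0 = 0`), and tests the mean log2
#' fold change against zero with `t = mean / sqrt(s2_post / n)` on
#' `d0 + d_i` degrees of freedom, two-sided.
#'
#' @param mean_fc per-protein mean log2 fold change over `n` replicates.
#' @param s2 per-protein sample variance of the replicate log2 ratios.
#' @param df per-protein residual df (`n - 1`), recycled.
#' @param n number of replicates, recycled.
#' @param prior an `ebayes_prior` (or a list with `d0`, `s0_sq`).
#' @return `data.frame` with columns `t`, `p_value`, `s2_post`, `df_total`,
#'   and logical `zero_variance` flagging degenerate rows whose p-value is
#'   reported as the smallest representable value.
#' @export
moderated_test <- function(mean_fc, s2, df, n, prior) {
  k <- length(mean_fc)
  s2 <- rep_len(s2, k); df <- rep_len(df, k); n <- rep_len(n, k)
  if (any(n < 2)) stop("need n >= 2 replicates for a one-sample test")
  d0 <- prior$d0; s0 <- prior$s0_sq
  s2_post <- if (is.finite(d0)) {
    if (d0 == 0) s2 else (d0 * s0 + df * s2) / (d0 + df)
  } else rep_len(s0, k)
  df_total <- d0 + df
  zero_var <- s2_post <= 0
  tstat <- ifelse(zero_var,
                  sign(mean_fc) * Inf,
                  mean_fc / sqrt(s2_post / n))
  tstat[zero_var & mean_fc == 0] <- 0
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  p[zero_var & mean_fc != 0] <- .Machine$double.xmin
  p[zero_var & mean_fc == 0] <- 1
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  data.frame(t = tstat, p_value = p, s2_post = s2_post,
             df_total = df_total, zero_variance = zero_var)
}
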