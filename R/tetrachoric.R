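# Maximum-likelihood tetrachoric correlation under the liability
# threshold model.
#
# A same-sex double-entered twin table has three unordered cells
# (both affected / discordant / neither), giving a just-identified model
# in (rho, threshold); opposite-sex tables keep the ordered discordant
# split and two sex-specific thresholds.  Optimization is on the Fisher-z
# transform of rho so the search is unconstrained.

#' Liability thresholds from the marginal prevalences
#'
#' Threshold = \eqn{\Phi^{-1}(1 - prevalence)} per margin.  For same-sex
#' double-entered tables the two margins are identical by construction;
#' for opposite-sex tables (ordered discordant split available) the
#' female and male margins differ.
#'
#' @param counts A `pair_counts` object.
#' @return Named vector of two thresholds (`h1`, `h2`).
#' @export
thresholds_from_margins <- function(counts) {
  n <- counts$n_pairs
  if (n == 0) stop("no pairs")
  if (!is.null(counts$n_d_f)) {
    prev1 <- (counts$n_cc + counts$n_d_f) / n
    prev2 <- (counts$n_cc + counts$n_d_m) / n
  } else {
    prev1 <- prev2 <- (2 * counts$n_cc + counts$n_d) / (2 * n)
  }
  for (p in c(prev1, prev2))
    if (p <= 0 || p >= 1)
      stop("degenerate margin (prevalence ", signif(p, 3),
           "); thresholds undefined")
  c(h1 = stats::qnorm(1 - prev1), h2 = stats::qnorm(1 - prev2))
}

# Multinomial log-likelihood of a pair-count table given thresholds and
# rho.  Same-sex tables use the unordered 3-cell form; tables with an
# ordered discordant split use all 4 cells.
.tetra_loglik <- function(counts, h1, h2, rho) {
  p <- bvn_cell_probs(h1, h2, rho)
  eps <- 1e-300
  if (!is.null(counts$n_d_f)) {
    counts$n_cc * log(max(p[["p11"]], eps)) +
      counts$n_d_f * log(max(p[["p10"]], eps)) +
      counts$n_d_m * log(max(p[["p01"]], eps)) +
      counts$n_uu * log(max(p[["p00"]], eps))
  } else {
    counts$n_cc * log(max(p[["p11"]], eps)) +
      counts$n_d * log(max(p[["p10"]] + p[["p01"]], eps)) +
      counts$n_uu * log(max(p[["p00"]], eps))
  }
}

# Central-difference Hessian of f at x.
.num_hessian <- function(f, x, eps = 1e-4) {
  k <- length(x)
  H <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) for (j in i:k) {
    ei <- ej <- numeric(k); ei[i] <- eps; ej[j] <- eps
    H[i, j] <- H[j, i] <-
      (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
      (4 * eps^2)
  }
  H
}

#' Maximum-likelihood tetrachoric correlation for a twin pair table
#'
#' Fits the bivariate-normal threshold model to a pair-count table.
#' `method = "two_stage"` fixes the thresholds at the marginal-prevalence
#' estimates and maximizes the likelihood over rho alone;
#' `method = "full_ml"` (default) maximizes over rho and threshold(s)
#' jointly.  For same-sex (3-cell) and opposite-sex (4-cell) tables the
#' model is just-identified, so the two methods agree to optimizer
#' tolerance.
#'
#' @param counts A `pair_counts` object.  When it carries the ordered
#'   discordant split (`n_d_f`/`n_d_m`) and `equal_thresholds = FALSE`,
#'   two sex-specific thresholds are fitted.
#' @param method `"full_ml"` or `"two_stage"`.
#' @param equal_thresholds Force a single common threshold.
#' @return A list of class `tetrachoric_fit`: `rho`, `thresholds`,
#'   `log_likelihood`, `se_rho`, `converged`, `boundary`, `method`.
#' @export
fit_tetrachoric <- function(counts, method = c("full_ml", "two_stage"),
                            equal_thresholds = TRUE) {
  method <- match.arg(method)
  if (counts$n_cc + counts$n_d == 0)
    warning("no affected pairs; rho is weakly identified")
  use_split <- !equal_thresholds && !is.null(counts$n_d_f)
  cnt <- counts
  if (!use_split) cnt$n_d_f <- cnt$n_d_m <- NULL
  h0 <- thresholds_from_margins(cnt)

  nll_rho <- function(z, h1, h2) -.tetra_loglik(cnt, h1, h2, tanh(z))

  # stage 1: thresholds fixed from margins, 1-D search over Fisher-z(rho)
  opt1 <- stats::optimize(nll_rho, interval = atanh(c(-0.9999, 0.9999)),
                          h1 = h0[["h1"]], h2 = h0[["h2"]], tol = 1e-10)
  z_hat <- opt1$minimum
  h_hat <- h0
  ll <- -opt1$objective
  converged <- TRUE

  if (method == "full_ml") {
    if (use_split) {
      par0 <- c(z_hat, h0[["h1"]], h0[["h2"]])
      nll <- function(p) -.tetra_loglik(cnt, p[2], p[3], tanh(p[1]))
    } else {
      par0 <- c(z_hat, h0[["h1"]])
      nll <- function(p) -.tetra_loglik(cnt, p[2], p[2], tanh(p[1]))
    }
    opt2 <- stats::optim(par0, nll, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-12))
    converged <- opt2$convergence == 0
    z_hat <- opt2$par[1]
    h_hat <- if (use_split) c(h1 = opt2$par[2], h2 = opt2$par[3])
             else c(h1 = opt2$par[2], h2 = opt2$par[2])
    ll <- -opt2$value
  }

  rho <- tanh(z_hat)
  boundary <- abs(rho) > 0.999

  # observed information on the z scale -> delta method for se(rho)
  se_rho <- NA_real_
  H <- try(.num_hessian(function(z) nll_rho(z, h_hat[["h1"]], h_hat[["h2"]]),
                        z_hat), silent = TRUE)
  if (!inherits(H, "try-error") && is.finite(H[1, 1]) && H[1, 1] > 0)
    se_rho <- (1 - rho^2) / sqrt(H[1, 1])

  structure(list(rho = rho, thresholds = h_hat, log_likelihood = ll,
                 se_rho = se_rho, converged = converged,
                 boundary = boundary, method = method,
                 counts = counts),
            class = "tetrachoric_fit")
}

#' @export
print.tetrachoric_fit <- function(x, ...) {
  cat(sprintf("Tetrachoric fit (%s): rho = %.4f (se %.4f), thresholds = %.4f / %.4f\n",
              x$method, x$rho, x$se_rho, x$thresholds[["h1"]],
              x$thresholds[["h2"]]))
  cat(sprintf("  logLik = %.4f; converged: %s%s\n", x$log_likelihood,
              x$converged, if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Likelihood-ratio test of rho = 0 for a pair table
#'
#' Alternative to the Pearson screen in [independence_test()]: twice the
#' log-likelihood gain of the fitted tetrachoric correlation over
#' rho = 0, referred to chi-square with 1 df.
#'
#' @param counts A `pair_counts` object.
#' @return List with `statistic`, `df`, `p_value`, `rho`.
#' @export
independence_test_lr <- function(counts) {
  fit <- fit_tetrachoric(counts, method = "two_stage")
  h <- thresholds_from_margins(counts)
  ll0 <- .tetra_loglik(counts, h[["h1"]], h[["h2"]], 0)
  stat <- max(0, 2 * (fit$log_likelihood - ll0))
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, 1, lower.tail = FALSE), rho = fit$rho)
}
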