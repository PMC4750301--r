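# Shared fixtures and independent oracles.

# Published same-sex zygosity-by-sex pair-count tables (concordant
# affected / discordant / concordant unaffected) with their printed
# tetrachoric correlations.  The printed digit strings are ambiguous and
# are resolved against the marginal case counts of the cohort table
# (e.g. "12945090.45" parses as 1 / 29 / 4509 / rho 0.45: 2*1+29 = 31
# affected fits the 39 affected MZ males, while 12/9/... does not).
reference_tables <- list(
  mz_males   = list(counts = c(1, 29, 4509),   rho = 0.45),
  dz_males   = list(counts = c(4, 72, 8176),   rho = 0.51),
  mz_females = list(counts = c(10, 52, 4701),  rho = 0.73),
  dz_females = list(counts = c(6, 122, 7575),  rho = 0.42)
)

ref_counts <- function(name) {
  ct <- reference_tables[[name]]$counts
  pair_counts(n_cc = ct[1], n_d = ct[2], n_uu = ct[3], label = name)
}

# Independent quadrature oracle for the upper orthant probability.
orthant_oracle <- function(h, k, rho) {
  stats::integrate(function(x)
    stats::dnorm(x) * stats::pnorm((k - rho * x) / sqrt(1 - rho^2),
                                   lower.tail = FALSE),
    h, Inf, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# Grid-search oracle for the tetrachoric MLE: thresholds fixed at the
# margins, rho maximizing the same multinomial likelihood over a step
# 1e-3 grid.
tetrachoric_grid_oracle <- function(counts) {
  h <- thresholds_from_margins(counts)
  grid <- seq(-0.999, 0.999, by = 1e-3)
  ll <- vapply(grid, function(r) {
    p11 <- bvn_orthant(h[["h1"]], h[["h2"]], r)
    m <- stats::pnorm(-h[["h1"]])
    pd <- max(2 * (m - p11), 1e-300)
    p00 <- max(1 - 2 * m + p11, 1e-300)
    counts$n_cc * log(max(p11, 1e-300)) + counts$n_d * log(pd) +
      counts$n_uu * log(p00)
  }, numeric(1))
  grid[which.max(ll)]
}

# A tiny hand-buildable cohort: n complete pairs, all entering at
# `entry`, with per-member exit/status supplied as vectors of length 2n.
make_cohort <- function(exit, status, zygosity = "MZ", sex = NULL,
                        entry = 0, birth_year = 1950) {
  n <- length(exit) / 2
  pid <- rep(sprintf("P%03d", seq_len(n)), each = 2)
  zyg <- rep_len(zygosity, n)[rep(seq_len(n), each = 2)]
  if (is.null(sex))
    sex <- ifelse(zyg == "DZ_OS", rep(c("F", "M"), n), "F")
  twin_cohort(
    twin_id = sprintf("%s_%d", pid, rep(1:2, n)),
    pair_id = pid, zygosity = zyg, sex = sex,
    birth_year = birth_year, entry_age = entry,
    exit_age = exit, status = status)
}

# Simulated pair table with complete lifetime observation (no death, no
# censoring window effects), cached per test file run.
complete_pairs <- function(n_mz = 4000, n_dz = 4000, seed = 42,
                           a2 = 0.18, d2 = 0, c2 = 0.61, e2 = 0.21,
                           risk = 0.2) {
  p <- simulation_params(n_mz = n_mz, n_dz_ss = n_dz, n_dz_os = 0,
                         a2 = a2, d2 = d2, c2 = c2, e2 = e2,
                         lifetime_risk_F = risk, lifetime_risk_M = risk,
                         gompertz_a = 0, window_length = Inf,
                         birth_year_range = c(1997, 1997), seed = seed)
  assemble_pairs(simulate_cohort(p))$pairs
}
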