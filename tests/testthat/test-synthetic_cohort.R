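test_that("parameter validation rejects impossible worlds", {
  expect_error(simulation_params(a2 = 0.5, c2 = 0.6, e2 = 0.2, d2 = 0),
               "equal 1")
  expect_error(simulation_params(a2 = -0.1, c2 = 0.9, e2 = 0.2), "nonnegative")
  expect_error(simulation_params(n_mz = -5), ">= 0")
  expect_error(simulation_params(lifetime_risk_F = 0), "risks")
})

test_that("a fixed seed reproduces the cohort exactly", {
  p <- simulation_params(n_mz = 500, n_dz_ss = 500, n_dz_os = 500, seed = 99)
  expect_identical(simulate_cohort(p), simulate_cohort(p))
})

test_that("no familial variance gives uncorrelated pair liabilities", {
  p <- simulation_params(n_mz = 20000, n_dz_ss = 20000, n_dz_os = 0,
                         a2 = 0, c2 = 0, e2 = 1, d2 = 0,
                         lifetime_risk_F = 0.2, lifetime_risk_M = 0.2,
                         gompertz_a = 0, window_length = Inf,
                         birth_year_range = c(1997, 1997), seed = 12)
  pr <- assemble_pairs(simulate_cohort(p))$pairs
  for (z in c("MZ", "DZ_SS")) {
    fit <- fit_tetrachoric(pair_counts(select_stratum(pr, zygosity = z)),
                           method = "two_stage")
    expect_lt(abs(fit$rho), 3 * fit$se_rho + 0.01)
  }
})

test_that("latent pair correlations match the zygosity-implied values", {
  p <- simulation_params(n_mz = 20000, n_dz_ss = 20000, n_dz_os = 20000,
                         a2 = 0.18, c2 = 0.61, e2 = 0.21,
                         gompertz_a = 0, window_length = Inf,
                         birth_year_range = c(1997, 1997), seed = 4)
  co <- simulate_cohort(p, return_liabilities = TRUE)
  rho <- implied_correlations(p)
  for (z in c("MZ", "DZ_SS", "DZ_OS")) {
    d <- co[co$zygosity == z, ]
    d <- d[order(d$pair_id, d$twin_id), ]
    i <- seq(1, nrow(d), by = 2)
    r_hat <- cor(d$liability[i], d$liability[i + 1])
    r_true <- if (z == "MZ") rho[["MZ"]] else rho[["DZ"]]
    se <- (1 - r_true^2) / sqrt(length(i))    # Fisher large-sample SE
    expect_lt(abs(r_hat - r_true), 3 * se)
  }
  # marginal liabilities standard normal
  expect_lt(abs(mean(co$liability)), 0.02)
  expect_lt(abs(sd(co$liability) - 1), 0.02)
})

test_that("event fraction is monotone in lifetime risk and window length", {
  frac <- function(risk, wl) {
    p <- simulation_params(n_mz = 4000, n_dz_ss = 4000, n_dz_os = 0,
                           lifetime_risk_F = risk, lifetime_risk_M = risk,
                           window_length = wl, seed = 21)
    co <- simulate_cohort(p)
    mean(co$status == "EVENT")
  }
  expect_lte(frac(0.02, 13), frac(0.10, 13))
  expect_lte(frac(0.05, 6), frac(0.05, 25))
})

test_that("with no mortality and an unbounded window the event fraction approaches the lifetime risk", {
  risk <- 0.1
  p <- simulation_params(n_mz = 15000, n_dz_ss = 0, n_dz_os = 0,
                         lifetime_risk_F = risk, lifetime_risk_M = risk,
                         gompertz_a = 0, window_length = Inf,
                         birth_year_range = c(1997, 1997), seed = 31)
  co <- simulate_cohort(p)
  se <- sqrt(risk * (1 - risk) / nrow(co))
  expect_lt(abs(mean(co$status == "EVENT") - risk), 3 * se + 1e-3)
})

test_that("prevalent-case handling follows the include_prevalent flag", {
  base <- simulation_params(n_mz = 5000, n_dz_ss = 0, n_dz_os = 0,
                            lifetime_risk_F = 0.3, lifetime_risk_M = 0.3,
                            birth_year_range = c(1910, 1930), seed = 77)
  co_excl <- simulate_cohort(base)
  base$include_prevalent <- TRUE
  co_incl <- simulate_cohort(base)
  # old entry ages: many onsets precede the window; including them adds
  # events recorded right at entry
  expect_gt(nrow(co_incl), nrow(co_excl))
  extra <- co_incl[co_incl$exit_age - co_incl$entry_age <= 0.0011, ]
  expect_true(all(extra$status == "EVENT"))
  expect_gt(nrow(extra), 0)
})

test_that("the default scenario has registry-like scale and composition", {
  p <- default_scenario(seed = 2)
  expect_equal(p$n_mz + p$n_dz_ss + p$n_dz_os, 46374L)
  co <- simulate_cohort(p)
  frac <- mean(co$status == "EVENT")
  expect_gt(frac, 0.004); expect_lt(frac, 0.008)   # ~0.6% window cases
  evF <- sum(co$status == "EVENT" & co$sex == "F")
  evM <- sum(co$status == "EVENT" & co$sex == "M")
  expect_gt(evF, evM)                              # female case excess
})
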