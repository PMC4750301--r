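test_that("pair likelihood reduces to the rectangle probabilities", {
  h <- c(F = 0, M = 0)
  expect_equal(pair_likelihood(FALSE, FALSE, "F", "F", h, 0), log(0.25))
  expect_equal(pair_likelihood(TRUE, TRUE, "F", "F", h, 0), log(0.25))
  # weights multiply the contribution
  expect_equal(pair_likelihood(TRUE, FALSE, "F", "M", h, 0.3, w1 = 2, w2 = 3),
               6 * pair_likelihood(TRUE, FALSE, "F", "M", h, 0.3))
  # the four cells always sum to one
  set.seed(2)
  for (i in 1:10) {
    p <- bvn_cell_probs(runif(1, -2, 2), runif(1, -2, 2), runif(1, -0.95, 0.95))
    expect_equal(sum(p), 1, tolerance = 1e-10)
  }
})

test_that("unweighted fit equals the weights-equal-one fit", {
  pr <- complete_pairs(n_mz = 1500, n_dz = 1500, seed = 51, risk = 0.2)
  rec <- pairs_to_records(pr)
  w1 <- data.frame(twin_id = rec$twin_id, weight = 1,
                   eval_age = rec$exit_age)
  f0 <- fit_model(model_spec("ACE"), pr)
  f1 <- fit_model(model_spec("ACE"), pr, weights = w1)
  expect_equal(f0$logLik, f1$logLik, tolerance = 1e-6)
  expect_equal(f0$components, f1$components, tolerance = 1e-5)
})

test_that("weighted fit reduces to the tetrachoric trinomial likelihood", {
  # single-zygosity saturated fit must reproduce the tetrachoric MLE
  pr <- complete_pairs(n_mz = 3000, n_dz = 0, seed = 52, risk = 0.25)
  mz <- select_stratum(pr, zygosity = "MZ", sex = "F")
  f <- fit_model(model_spec("sat", "stratified_F"), mz)
  tf <- fit_tetrachoric(pair_counts(mz))
  expect_equal(f$rho_MZ, tf$rho, tolerance = 1e-3)
})

test_that("Falconer heritability and the ACE identities match hand arithmetic", {
  expect_equal(falconer_H(0.79, 0.70), 0.18, tolerance = 1e-12)
  expect_equal(falconer_H(0.77, 0.74), 0.06, tolerance = 1e-12)
  expect_equal(falconer_H(0.66, 0.71), 0)          # clipped at 0
  expect_equal(falconer_H(0.4, 0.4), 0)
  expect_equal(falconer_H(0.9, 0.1), 1)            # clipped at 1

  d <- ace_from_correlations(0.79, 0.70)
  expect_equal(c(d$A, d$C, d$E), c(0.18, 0.61, 0.21), tolerance = 1e-12)
  expect_false(d$boundary)
  d2 <- ace_from_correlations(0.69, 0.69)
  expect_equal(c(d2$A, d2$C, d2$E), c(0, 0.69, 0.31), tolerance = 1e-12)
  d3 <- ace_from_correlations(0.66, 0.71)
  expect_true(d3$boundary)   # negative A reported raw
  expect_lt(d3$A, 0)
})

test_that("ACE identities invert the forward correlation map exactly", {
  set.seed(7)
  for (i in 1:25) {
    x <- runif(3); x <- x / sum(x)
    rmz <- x[1] + x[2]; rdz <- 0.5 * x[1] + x[2]
    d <- ace_from_correlations(rmz, rdz)
    expect_equal(c(d$A, d$C, d$E), x, tolerance = 1e-12)
  }
})

test_that("structural constraints of the model family hold", {
  pr <- complete_pairs(n_mz = 1500, n_dz = 1500, seed = 53, risk = 0.2)
  # CE forces equal implied correlations whatever the data say
  ce <- fit_model(model_spec("CE"), pr)
  expect_equal(ce$rho_MZ, ce$rho_DZ, tolerance = 1e-10)
  expect_equal(ce$H, 0)
  # components are a simplex
  for (m in c("ACE", "ADE", "AE", "DE", "E")) {
    f <- fit_model(model_spec(m), pr)
    expect_true(all(f$components >= 0))
    expect_equal(sum(f$components), 1, tolerance = 1e-8)
    expect_gte(f$rho_MZ, f$rho_DZ - 1e-10)
    # saturated likelihood dominates every nested model
  }
  sat <- fit_model(model_spec("sat"), pr)
  for (m in c("ACE", "AE", "CE", "E"))
    expect_gte(sat$logLik + 1e-6, fit_model(model_spec(m), pr)$logLik)
})

test_that("a perfectly heritable trait drives the AE fit to A = 1", {
  p <- simulation_params(n_mz = 4000, n_dz_ss = 4000, n_dz_os = 0,
                         a2 = 1, d2 = 0, c2 = 0, e2 = 0,
                         lifetime_risk_F = 0.3, lifetime_risk_M = 0.3,
                         gompertz_a = 0, window_length = Inf,
                         birth_year_range = c(1997, 1997), seed = 54)
  expect_error(simulation_params(a2 = 1, e2 = 0.1, c2 = 0, d2 = 0), "equal 1")
  pr <- assemble_pairs(simulate_cohort(p))$pairs
  f <- fit_model(model_spec("AE"), pr)
  expect_gt(f$components[["A"]], 0.95)
})

test_that("model comparison applies the LR and AIC formulas", {
  pr <- complete_pairs(n_mz = 1500, n_dz = 1500, seed = 55, risk = 0.2)
  fits <- list(sat = fit_model(model_spec("sat"), pr),
               ACE = fit_model(model_spec("ACE"), pr),
               CE = fit_model(model_spec("CE"), pr),
               E = fit_model(model_spec("E"), pr))
  cmp <- compare_models(fits)
  # AIC by formula
  for (f in fits) expect_equal(f$AIC, 2 * f$n_parameters - 2 * f$logLik)
  # equal-likelihood nested fits -> LR 0, p 1; AIC(-100, k=3) = 206
  fake <- list(sat = list(logLik = -100, n_parameters = 4, AIC = 208),
               ACE = list(logLik = -100, n_parameters = 3, AIC = 206))
  cmp2 <- compare_models(fake)
  expect_equal(cmp2$tests$lr, 0)
  expect_equal(cmp2$tests$p_value, 1)
  expect_equal(fake$ACE$AIC, 2 * 3 - 2 * fake$ACE$logLik)
  row <- cmp$tests[cmp$tests$model == "CE" & cmp$tests$against == "ACE", ]
  expect_equal(row$lr, 2 * (fits$ACE$logLik - fits$CE$logLik), tolerance = 1e-8)
  expect_equal(row$p_value, pchisq(row$lr, row$df, lower.tail = FALSE))
  expect_true(all(cmp$tests$lr >= 0))
  # AIC ranking is sorted ascending
  expect_true(!is.unsorted(cmp$aic$AIC))
})

test_that("AE is rejected against ACE when C is truly large", {
  pr <- complete_pairs(n_mz = 12000, n_dz = 12000, seed = 56, risk = 0.2)
  fits <- list(ACE = fit_model(model_spec("ACE"), pr),
               AE = fit_model(model_spec("AE"), pr))
  cmp <- compare_models(fits)
  row <- cmp$tests[cmp$tests$model == "AE", ]
  expect_lt(row$p_value, 1e-4)
  expect_lt(fits$ACE$AIC, fits$AE$AIC)
})

test_that("age-resolved components are flat when the truth is age-constant", {
  pr <- complete_pairs(n_mz = 10000, n_dz = 10000, seed = 57, risk = 0.15)
  curves <- heritability_by_age(pr, model_spec("ACE"),
                                ages = c(65, 75, 85, 101))
  done <- curves[!is.na(curves$A), ]
  expect_gt(nrow(done), 1)
  # flat within sampling noise (early windows carry few cases)
  expect_lt(max(done$A) - min(done$A), 0.35)
  expect_lt(max(done$C) - min(done$C), 0.35)
  # a window before any onset is reported missing, not an error
  early <- heritability_by_age(pr, model_spec("ACE"), ages = 20)
  expect_true(is.na(early$A))
  expect_equal(early$n_affected, 0)
})
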