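test_that("the four-record worked example is reproduced exactly", {
  co <- twin_cohort(
    twin_id = paste0("t", 1:4), pair_id = paste0("p", c(1, 1, 2, 2)),
    zygosity = "MZ", sex = "F", birth_year = 1950, entry_age = 0,
    exit_age = c(1, 2, 3, 4),
    status = c("EVENT", "DEATH", "CENSORED", "EVENT"))
  ev <- aalen_johansen(co, "EVENT")
  de <- aalen_johansen(co, "DEATH")
  expect_equal(step_at(ev, 1), 0.25)
  expect_equal(step_at(ev, 4), 0.75)
  expect_equal(step_at(de, 2), 0.25)
  expect_equal(step_at(de, 10), 0.25)
  expect_equal(step_at(ev, 0.5), 0)          # zero before the first event
  # event-age grid spans both causes; no EVENT jump at the death age
  expect_equal(ev$ages, c(1, 2, 4))
  expect_equal(ev$estimate, c(0.25, 0.25, 0.75))
  expect_equal(ev$at_risk, c(4L, 3L, 1L))
  expect_true(all(ev$variance >= 0))
})

test_that("with a single cause the CIF is exactly 1 - Kaplan-Meier", {
  set.seed(5)
  n <- 300
  exit <- pmin(rweibull(n, 3, 60) + 1, 119)
  status <- ifelse(runif(n) < 0.6, "EVENT", "CENSORED")
  co <- make_cohort(exit = exit, status = status, zygosity = "MZ", entry = 0)
  cif <- aalen_johansen(co, "EVENT")
  skip_if_not_installed("survival")
  km <- survival::survfit(
    survival::Surv(co$exit_age, co$status == "EVENT") ~ 1)
  km_at <- summary(km, times = cif$ages)$surv
  expect_equal(cif$estimate, 1 - km_at, tolerance = 1e-12)
})

test_that("cause-specific CIFs and survival conserve probability", {
  set.seed(9)
  n <- 400
  co <- make_cohort(exit = runif(n, 40, 100),
                    status = sample(c("EVENT", "DEATH"), n, replace = TRUE),
                    zygosity = "MZ", entry = 30)
  ev <- aalen_johansen(co, "EVENT")
  de <- aalen_johansen(co, "DEATH")
  # no censoring: CIF_E + CIF_D + S = 1 at every event age
  ages <- ev$ages
  total <- step_at(ev, ages) + step_at(de, ages) + ev$surv
  expect_equal(total, rep(1, length(ages)), tolerance = 1e-12)
  # monotone nondecreasing estimates
  expect_true(all(diff(ev$estimate) >= 0))
  expect_true(all(diff(de$estimate) >= 0))
})

test_that("delayed entry matches the survival package on competing risks", {
  skip_if_not_installed("survival")
  p <- simulation_params(n_mz = 2000, n_dz_ss = 0, n_dz_os = 0,
                         lifetime_risk_F = 0.3, lifetime_risk_M = 0.3,
                         seed = 17)
  co <- simulate_cohort(p)
  cif <- aalen_johansen(co, "EVENT")
  st <- factor(ifelse(co$status == "CENSORED", "cens", co$status),
               levels = c("cens", "EVENT", "DEATH"))
  fit <- survival::survfit(
    survival::Surv(co$entry_age, co$exit_age, st) ~ 1)
  sm <- summary(fit, times = cif$ages)
  oracle <- sm$pstate[, match("EVENT", colnames(sm$pstate))]
  expect_equal(cif$estimate, oracle, tolerance = 1e-8)
})

test_that("estimators ignore record order and honor entry ages", {
  p <- simulation_params(n_mz = 800, n_dz_ss = 0, n_dz_os = 0,
                         lifetime_risk_F = 0.3, lifetime_risk_M = 0.3,
                         seed = 23)
  co <- simulate_cohort(p)
  cif1 <- aalen_johansen(co, "EVENT")
  cif2 <- aalen_johansen(co[sample(nrow(co)), ], "EVENT")
  expect_equal(cif1, cif2)
  # nobody contributes to a risk set before entry
  expect_true(all(cif1$at_risk <=
                    sapply(cif1$ages, function(t) sum(co$entry_age < t))))
})

test_that("censoring survival is the role-swapped Kaplan-Meier", {
  # hand-computed: entries 0, exits 2(E) 3(C) 5(C) 7(D) 9(C)
  co <- make_cohort(exit = c(2, 3, 5, 7, 9, 11),
                    status = c("EVENT", "CENSORED", "CENSORED", "DEATH",
                               "CENSORED", "EVENT"),
                    zygosity = c("MZ", "DZ_SS", "MZ"), entry = 0)
  G <- censoring_survival(co)
  # at 3: 5 at risk -> 4/5; at 5: 4 at risk -> 4/5*3/4; at 9: 2 -> *1/2
  expect_equal(G$ages, c(3, 5, 9))
  expect_equal(G$surv, c(4 / 5, 4 / 5 * 3 / 4, 4 / 5 * 3 / 4 * 1 / 2))
  # no censored records -> G identically 1
  co2 <- make_cohort(exit = c(2, 3), status = c("EVENT", "DEATH"),
                     zygosity = "MZ")
  G2 <- censoring_survival(co2)
  expect_equal(step_at(G2, c(1, 5)), c(1, 1))
  # all censored at the same age -> G drops to 0 there
  co3 <- make_cohort(exit = c(4, 4), status = c("CENSORED", "CENSORED"),
                     zygosity = "MZ")
  expect_equal(step_at(censoring_survival(co3), 4), 0)
})

test_that("IPC weights are reciprocals of the censoring survival", {
  co <- make_cohort(exit = c(2, 3, 5, 7, 9, 11),
                    status = c("EVENT", "CENSORED", "CENSORED", "DEATH",
                               "CENSORED", "EVENT"),
                    zygosity = c("MZ", "DZ_SS", "MZ"), entry = 0)
  w <- ipc_weights(co)
  G <- attr(w, "G")
  # the event at 11 occurs after censorings at 3, 5, 9: weight 1/G(11-)
  expect_equal(w$weight[co$exit_age == 11],
               1 / (4 / 5 * 3 / 4 * 1 / 2))
  # the event at 2 precedes all censoring: weight 1
  expect_equal(w$weight[co$exit_age == 2], 1)
  # no censoring anywhere -> all weights 1
  co2 <- make_cohort(exit = c(2, 3), status = c("EVENT", "DEATH"),
                     zygosity = "MZ")
  expect_equal(ipc_weights(co2)$weight, c(1, 1))
  # positivity violation: everyone under observation is censored at 4,
  # so G hits 0 there, and a later-entering event needs G beyond 4
  co3 <- make_cohort(exit = c(4, 4, 6, 7),
                     status = c("CENSORED", "CENSORED", "EVENT", "EVENT"),
                     zygosity = c("MZ", "DZ_SS"), entry = c(0, 0, 5, 5))
  expect_error(ipc_weights(co3), "positivity")
})

test_that("weighting corrects the censored non-case fraction", {
  # simulation oracle: weighted case fraction under the window vs the
  # uncensored within-window case fraction of the same population
  p <- simulation_params(n_mz = 30000, n_dz_ss = 0, n_dz_os = 0,
                         lifetime_risk_F = 0.15, lifetime_risk_M = 0.15,
                         gompertz_a = 0, birth_year_range = c(1930, 1950),
                         window_length = 13, seed = 3)
  co <- simulate_cohort(p)
  w <- ipc_weights(co, cap = 50)
  # canonical IPCW margin: (1/N) sum of I(case) / G(T-)
  cases_w <- sum(w$weight[co$status == "EVENT"]) / nrow(co)
  # oracle: same population, window long enough that no one is censored
  # before the oldest attained age observed above
  p2 <- p; p2$window_length <- 40
  co2 <- simulate_cohort(p2)
  horizon <- max(co$exit_age)
  cases_u <- mean(co2$status == "EVENT" & co2$exit_age <= horizon)
  expect_lt(abs(cases_w - cases_u), 0.01)
})

test_that("concordance function matches brute-force counting on complete data", {
  pr <- complete_pairs(n_mz = 3000, n_dz = 0, seed = 19, risk = 0.3)
  ages <- c(55, 65, 75, 85, 100)
  cc <- concordance_function(pr, ages, n_boot = 0)
  for (i in seq_along(ages)) {
    t <- ages[i]
    b1 <- pr$status_1 == "EVENT" & pr$exit_age_1 <= t
    b2 <- pr$status_2 == "EVENT" & pr$exit_age_2 <= t
    C <- sum(b1 & b2); D <- sum(xor(b1, b2))
    if (2 * C + D == 0) {
      expect_true(is.na(cc$concordance[i]))
    } else {
      expect_equal(cc$concordance[i], 2 * C / (2 * C + D))
    }
  }
  # before any event the value is undefined, not 0
  early <- concordance_function(pr, 20, n_boot = 0)
  expect_true(is.na(early$concordance))
})

test_that("MZ concordance exceeds the marginal curve under familial correlation", {
  pr <- complete_pairs(n_mz = 6000, n_dz = 0, seed = 25, risk = 0.2)
  set.seed(1)
  cc <- concordance_function(select_stratum(pr, zygosity = "MZ"),
                             c(75, 85, 100), n_boot = 30)
  ok <- is.finite(cc$concordance)
  expect_true(all(cc$concordance[ok] > cc$marginal[ok]))
  expect_true(all(cc$lower[ok] <= cc$concordance[ok] &
                    cc$concordance[ok] <= cc$upper[ok]))
})
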