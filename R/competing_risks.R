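# Nonparametric time-to-event machinery on the attained-age scale:
# Aalen-Johansen cause-specific cumulative incidence with delayed entry,
# Kaplan-Meier for the censoring distribution, inverse-probability-of-
# censoring weights, and the age-indexed proband-wise concordance
# function.
#
# Tie convention throughout: at a tied age, EVENT and DEATH are processed
# before CENSORED (a twin censored at age t is still in the risk set at
# t); between the two causes the increments share the same S(t-).

# Risk-set size at each age in `at` (sorted): #{i : entry < t <= exit},
# computed in O((n + T) log n) via sorted counting.
.n_at_risk <- function(entry, exit, at) {
  findInterval(at, sort(entry), left.open = TRUE) -
    findInterval(at, sort(exit), left.open = TRUE)
}

#' Aalen-Johansen cause-specific cumulative incidence
#'
#' Estimates the cumulative incidence function of one cause (the
#' surgical endpoint or death) in the illness-death model with states
#' healthy / diseased / dead, honouring delayed entry: an individual is
#' in the risk set at age `t` iff `entry_age < t <= exit_age`.  The
#' overall survival is Kaplan-Meier over both causes and
#' `CIF(t) = sum over event ages t_j <= t of S(t_j-) d_cause_j / n_j`.
#'
#' @param records Cohort records (a `twin_cohort` or compatible
#'   data.frame).
#' @param cause `"EVENT"` or `"DEATH"`.
#' @return Object of class `cif_curve`: data.frame `ages`, `estimate`,
#'   `variance`, `at_risk`, `surv` plus attributes `cause` and
#'   `identifiable_to` (the age beyond which an empty interior risk set
#'   makes the curve non-identifiable, `Inf` if none).
#' @export
aalen_johansen <- function(records, cause = c("EVENT", "DEATH")) {
  cause <- match.arg(cause)
  entry <- records$entry_age
  exit <- records$exit_age
  is_ev <- records$status %in% c("EVENT", "DEATH")
  times <- sort(unique(exit[is_ev]))
  if (!length(times)) {
    out <- data.frame(ages = numeric(0), estimate = numeric(0),
                      variance = numeric(0), at_risk = integer(0),
                      surv = numeric(0))
    class(out) <- c("cif_curve", class(out))
    attr(out, "cause") <- cause
    attr(out, "identifiable_to") <- Inf
    return(out)
  }
  n_j <- .n_at_risk(entry, exit, times)
  d_all <- tabulate(match(exit[is_ev], times), length(times))
  d_c <- tabulate(match(exit[records$status == cause], times),
                  length(times))
  identifiable_to <- Inf
  bad <- which(n_j == 0)
  if (length(bad)) {
    identifiable_to <- times[bad[1]]
    warning("empty risk set at age ", signif(identifiable_to, 6),
            "; curve non-identifiable beyond it")
    keep <- seq_len(bad[1] - 1)
    times <- times[keep]; n_j <- n_j[keep]
    d_all <- d_all[keep]; d_c <- d_c[keep]
  }
  S <- cumprod(1 - d_all / n_j)
  S_minus <- c(1, utils::head(S, -1))
  inc <- S_minus * d_c / n_j
  cif <- cumsum(inc)

  # Aalen (1978)-type variance, expanded into cumulative sums so the
  # whole curve is O(J)
  denom <- n_j * (n_j - d_all)
  a_j <- ifelse(denom > 0, d_all / denom, 0)
  b_j <- S_minus^2 * ((n_j - d_c) / n_j) * d_c / n_j^2
  c_j <- S_minus * d_c / n_j^2
  A1 <- cumsum(a_j); A2 <- cumsum(cif * a_j); A3 <- cumsum(cif^2 * a_j)
  B <- cumsum(b_j); C1 <- cumsum(c_j); C2 <- cumsum(cif * c_j)
  var_cif <- pmax(0, cif^2 * A1 - 2 * cif * A2 + A3 + B -
                    2 * (cif * C1 - C2))

  out <- data.frame(ages = times, estimate = cif, variance = var_cif,
                    at_risk = as.integer(n_j), surv = S)
  class(out) <- c("cif_curve", class(out))
  attr(out, "cause") <- cause
  attr(out, "identifiable_to") <- identifiable_to
  out
}

#' Evaluate a step curve at given ages
#'
#' Right-continuous step-function evaluation for [aalen_johansen()] and
#' [censoring_survival()] output.
#'
#' @param curve A `cif_curve` or `censoring_km` object.
#' @param at Ages at which to evaluate.
#' @param minus If `TRUE`, return the left limit (value just before each
#'   age).
#' @return Numeric vector.
#' @export
step_at <- function(curve, at, minus = FALSE) {
  ages <- curve$ages
  vals <- if (!is.null(curve$estimate)) curve$estimate else curve$surv
  start <- if (!is.null(curve$estimate)) 0 else 1
  vapply(at, function(t) {
    i <- if (minus) sum(ages < t) else sum(ages <= t)
    if (i == 0) start else vals[i]
  }, numeric(1))
}

#' Kaplan-Meier estimate of the censoring distribution
#'
#' Role-swapped Kaplan-Meier with delayed entry: CENSORED is the event,
#' EVENT and DEATH act as censorings.  Used to build the inverse
#' probability of censoring weights.
#'
#' @param records Cohort records.
#' @return Object of class `censoring_km`: data.frame `ages`, `surv`,
#'   `at_risk`, `d` (censorings at each age); `surv` starts at 1.
#' @export
censoring_survival <- function(records) {
  entry <- records$entry_age
  exit <- records$exit_age
  is_c <- records$status == "CENSORED"
  times <- sort(unique(exit[is_c]))
  if (!length(times)) {
    out <- data.frame(ages = numeric(0), surv = numeric(0),
                      at_risk = integer(0), d = integer(0))
  } else {
    # censorings happen after events at ties, so at a censoring age the
    # risk set excludes twins whose EVENT/DEATH occurred at that age
    n_base <- .n_at_risk(entry, exit, times)
    d_tied_ev <- tabulate(match(exit[!is_c], times), length(times))
    n_j <- n_base - d_tied_ev
    d_j <- tabulate(match(exit[is_c], times), length(times))
    ok <- n_j > 0
    surv <- cumprod(ifelse(ok, 1 - d_j / n_j, 1))
    out <- data.frame(ages = times, surv = surv,
                      at_risk = as.integer(n_j), d = as.integer(d_j))
  }
  class(out) <- c("censoring_km", class(out))
  out
}

#' Inverse probability of censoring weights
#'
#' A twin with a complete observation (EVENT or DEATH at age `T`) gets
#' weight `1 / G(T-)`; a twin censored administratively contributes as a
#' non-case with weight `1 / G(admin_end-)`, where `G` is the
#' Kaplan-Meier censoring survival from [censoring_survival()].  Death
#' is a complete observation for the liability outcome (a twin dying
#' without the endpoint is a known non-case), so the weights correct
#' administrative censoring only.
#'
#' @param records Cohort records.
#' @param admin_end Administrative window end per record; defaults to
#'   `exit_age` (correct when CENSORED records are censored exactly at
#'   window close).
#' @param cap Upper bound on weights (positivity protection); the number
#'   of capped weights is reported in attribute `"n_capped"`.
#' @param G Optional pre-computed `censoring_km` (e.g. from a larger
#'   sample).
#' @return Data.frame `twin_id`, `weight`, `eval_age`; attributes
#'   `n_capped` and `G`.
#' @export
ipc_weights <- function(records, admin_end = records$exit_age, cap = 20,
                        G = NULL) {
  if (is.null(G)) G <- censoring_survival(records)
  eval_age <- ifelse(records$status == "CENSORED", admin_end,
                     records$exit_age)
  g <- step_at(G, eval_age, minus = TRUE)
  if (any(g <= 0)) {
    bad <- eval_age[which(g <= 0)[1]]
    stop("censoring survival is 0 at age ", signif(bad, 6),
         " (positivity violation)")
  }
  w <- 1 / g
  n_capped <- sum(w > cap)
  w <- pmin(w, cap)
  out <- data.frame(twin_id = records$twin_id, weight = w,
                    eval_age = eval_age, stringsAsFactors = FALSE)
  attr(out, "n_capped") <- n_capped
  attr(out, "G") <- G
  out
}

# Look up per-member weights for a pair table; missing ids get weight 1.
.pair_weights <- function(pairs, weights) {
  if (is.null(weights))
    return(list(w1 = rep(1, nrow(pairs)), w2 = rep(1, nrow(pairs))))
  idx <- stats::setNames(weights$weight, weights$twin_id)
  w1 <- unname(idx[pairs$twin_id_1]); w1[is.na(w1)] <- 1
  w2 <- unname(idx[pairs$twin_id_2]); w2[is.na(w2)] <- 1
  list(w1 = w1, w2 = w2)
}

#' Age-indexed proband-wise concordance function
#'
#' For each grid age `t`, estimates
#' `concordance(t) = P(both members affected by t) / P(a named member
#' affected by t)` with the IPC-weighted pair estimator in the numerator
#' (`mean of I1 I2 w1 w2` over pairs) and the IPC-weighted individual
#' estimator in the denominator.  The marginal curve is the individual
#' estimator itself: the risk faced by a twin of an affected proband if
#' the pair were genetically unrelated.  Percentile bootstrap bands
#' resample pairs (not individuals), preserving within-pair dependence.
#'
#' @param pairs Pair table (one zygosity/sex stratum).
#' @param ages Evaluation grid.
#' @param weights Optional [ipc_weights()] output.
#' @param n_boot Bootstrap replicates for the band (0 disables).
#' @param conf_level Band level.
#' @return Data.frame `age`, `concordance`, `marginal`, `lower`,
#'   `upper`; ages where no proband is yet affected are `NA`.
#' @export
concordance_function <- function(pairs, ages, weights = NULL,
                                 n_boot = 200, conf_level = 0.95) {
  w <- .pair_weights(pairs, weights)
  e1 <- pairs$status_1 == "EVENT"; t1 <- pairs$exit_age_1
  e2 <- pairs$status_2 == "EVENT"; t2 <- pairs$exit_age_2
  est <- function(idx, t) {
    i1 <- e1[idx] & t1[idx] <= t
    i2 <- e2[idx] & t2[idx] <= t
    num <- mean(i1 * i2 * w$w1[idx] * w$w2[idx])
    den <- mean(c(i1 * w$w1[idx], i2 * w$w2[idx]))
    c(conc = if (den > 0) num / den else NA_real_, marg = den)
  }
  all_idx <- seq_len(nrow(pairs))
  point <- t(vapply(ages, function(t) est(all_idx, t), numeric(2)))
  lower <- upper <- rep(NA_real_, length(ages))
  if (n_boot > 0 && nrow(pairs) > 0) {
    reps <- matrix(NA_real_, n_boot, length(ages))
    for (b in seq_len(n_boot)) {
      idx <- sample(all_idx, replace = TRUE)
      reps[b, ] <- vapply(ages, function(t) est(idx, t)[["conc"]],
                          numeric(1))
    }
    a <- (1 - conf_level) / 2
    qs <- apply(reps, 2, function(col) {
      col <- col[is.finite(col)]
      if (length(col) < 2) c(NA_real_, NA_real_)
      else stats::quantile(col, c(a, 1 - a), names = FALSE)
    })
    lower <- qs[1, ]; upper <- qs[2, ]
  }
  data.frame(age = ages, concordance = point[, "conc"],
             marginal = point[, "marg"], lower = lower, upper = upper)
}
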