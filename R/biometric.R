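# Liability-threshold biometric models for twin pair data.
#
# Each twin pair contributes a weighted bivariate-probit cell
# probability: both liabilities standard normal with correlation implied
# by zygosity and the free variance components (MZ: A+D+C, DZ:
# A/2+D/4+C), thresholds set by prevalence (optionally sex-specific).
# Components are parameterized through a softmax over the free set with
# E as reference, which enforces nonnegativity and the unit total
# liability variance without boundary failures.

.known_models <- c("sat", "ACE", "ADE", "AE", "CE", "DE", "E")

#' Specification of one biometric model
#'
#' @param model One of `"sat"` (saturated: one free correlation per
#'   zygosity class), `"ACE"`, `"ADE"`, `"AE"`, `"CE"`, `"DE"`, `"E"`.
#'   `A` and `D` are never free together with `C` (classical twin-design
#'   identifiability); `E` is always free.
#' @param sex_mode `"adjusted"` (all pairs, sex-specific thresholds,
#'   opposite-sex pairs pooled with same-sex DZ), `"stratified_F"` or
#'   `"stratified_M"` (same-sex pairs of one sex, one threshold).
#' @return List of class `model_spec`.
#' @export
model_spec <- function(model = c("sat", "ACE", "ADE", "AE", "CE", "DE", "E"),
                       sex_mode = c("adjusted", "stratified_F",
                                    "stratified_M")) {
  model <- match.arg(model)
  sex_mode <- match.arg(sex_mode)
  free <- switch(model,
    sat = character(0),
    ACE = c("A", "C"), ADE = c("A", "D"),
    AE = "A", CE = "C", DE = "D", E = character(0))
  structure(list(model = model, free = free, sex_mode = sex_mode),
            class = "model_spec")
}

# Correlations implied by a component vector c(A, D, C, E).
.rho_from_components <- function(v) {
  c(MZ = unname(v[["A"]] + v[["D"]] + v[["C"]]),
    DZ = unname(0.5 * v[["A"]] + 0.25 * v[["D"]] + v[["C"]]))
}

# Softmax over free components with E as reference.
.components_from_theta <- function(theta, free) {
  e <- exp(c(theta, 0))
  v <- e / sum(e)
  out <- c(A = 0, D = 0, C = 0, E = unname(v[length(v)]))
  out[free] <- v[seq_along(free)]
  out
}

# Aggregate a pair table into weighted outcome-cell groups.  Outcome
# y = EVENT with exit_age <= eval_age.  Opposite-sex pairs are oriented
# female-first so their discordant cells keep the sex identity; same-sex
# pairs are collapsed to the unordered cell.
.aggregate_pairs <- function(pairs, weights = NULL, eval_age = Inf) {
  w <- .pair_weights(pairs, weights)
  y1 <- (pairs$status_1 == "EVENT") & (pairs$exit_age_1 <= eval_age)
  y2 <- (pairs$status_2 == "EVENT") & (pairs$exit_age_2 <= eval_age)
  os <- pairs$sex_1 != pairs$sex_2
  yA <- ifelse(os, ifelse(pairs$sex_1 == "F", y1, y2), pmax(y1, y2))
  yB <- ifelse(os, ifelse(pairs$sex_1 == "F", y2, y1), pmin(y1, y2))
  sexA <- ifelse(os, "F", pairs$sex_1)
  sexB <- ifelse(os, "M", pairs$sex_1)
  zclass <- ifelse(pairs$zygosity == "MZ", "MZ", "DZ")
  df <- data.frame(zclass = zclass, sexA = sexA, sexB = sexB,
                   os = os, yA = yA, yB = yB,
                   wprod = w$w1 * w$w2, w1 = w$w1, w2 = w$w2,
                   stringsAsFactors = FALSE)
  groups <- stats::aggregate(wprod ~ zclass + sexA + sexB + os + yA + yB,
                             data = df, FUN = sum)
  n <- stats::aggregate(cbind(count = wprod) ~ zclass + sexA + sexB +
                          os + yA + yB, data = df, FUN = length)
  groups$count <- n$count
  groups
}

# Weighted log-likelihood of grouped cells given thresholds (named
# vector c(F=,M=)) and correlations (named vector c(MZ=,DZ=)).
.grouped_loglik <- function(groups, h, rho) {
  eps <- 1e-300
  ll <- 0
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    p <- bvn_cell_probs(h[[g$sexA]], h[[g$sexB]], rho[[g$zclass]])
    pr <- if (g$yA && g$yB) p[["p11"]]
          else if (!g$yA && !g$yB) p[["p00"]]
          else if (g$os) { if (g$yA) p[["p10"]] else p[["p01"]] }
          else p[["p10"]] + p[["p01"]]
    ll <- ll + g$wprod * log(max(pr, eps))
  }
  ll
}

#' Log-likelihood contribution of one twin pair
#'
#' The weighted bivariate-probit contribution
#' `w1 w2 log P(cell)`, with the rectangle probability of the observed
#' affection cell under thresholds `h` (named `F`/`M`) and zygosity
#' correlation `rho`.
#'
#' @param y1,y2 Logical affection indicators of the two members.
#' @param sex1,sex2 Member sexes (`"F"`/`"M"`).
#' @param h Named threshold vector `c(F =, M =)`.
#' @param rho Latent correlation for the pair's zygosity.
#' @param w1,w2 Member weights.
#' @return Scalar log-likelihood contribution.
#' @export
pair_likelihood <- function(y1, y2, sex1, sex2, h, rho, w1 = 1, w2 = 1) {
  p <- bvn_cell_probs(h[[sex1]], h[[sex2]], rho)
  pr <- if (y1 && y2) p[["p11"]]
        else if (y1) p[["p10"]]
        else if (y2) p[["p01"]]
        else p[["p00"]]
  w1 * w2 * log(max(pr, 1e-300))
}

# Parameter packing: [structure params..., threshold params...]
.fit_engine <- function(spec, groups) {
  sexes <- if (spec$sex_mode == "adjusted") c("F", "M")
           else substr(spec$sex_mode, 12, 12)
  n_thr <- length(sexes)
  sat <- spec$model == "sat"
  n_struct <- if (sat) 2L else length(spec$free)

  unpack <- function(par) {
    thr <- unname(par[n_struct + seq_len(n_thr)])
    h <- if (n_thr == 2) c(F = thr[1], M = thr[2])
         else stats::setNames(rep(thr, 2), c("F", "M"))
    if (sat) {
      rho <- c(MZ = tanh(par[1]), DZ = tanh(par[2]))
      comps <- NULL
    } else {
      comps <- .components_from_theta(par[seq_len(n_struct)], spec$free)
      rho <- .rho_from_components(comps)
    }
    list(h = h, rho = rho, comps = comps)
  }
  nll <- function(par) {
    u <- unpack(par)
    -.grouped_loglik(groups, u$h, u$rho)
  }

  # starting thresholds from the observed (weighted) margins
  aff_w <- sapply(c("F", "M"), function(s) {
    wa <- sum(groups$wprod[groups$sexA == s & groups$yA]) +
          sum(groups$wprod[groups$sexB == s & groups$yB])
    wt <- sum(groups$wprod[groups$sexA == s]) +
          sum(groups$wprod[groups$sexB == s])
    if (wt > 0) max(min(wa / wt, 0.99), 1e-5) else 0.01
  })
  h_start <- stats::qnorm(1 - aff_w)
  thr0 <- if (n_thr == 2) h_start else mean(h_start[paste(sexes)])

  starts <- list()
  if (sat) {
    starts[[1]] <- c(atanh(0.5), atanh(0.4), thr0)
    starts[[2]] <- c(atanh(0.8), atanh(0.7), thr0)
  } else if (n_struct > 0) {
    starts[[1]] <- c(rep(0, n_struct), thr0)
    starts[[2]] <- c(rep(1, n_struct), thr0)
  } else {
    starts[[1]] <- thr0
  }

  best <- NULL
  for (s in starts) {
    o <- if (length(s) == 1)
      stats::optim(s, nll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12))
    else
      stats::optim(s, nll, method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(opt = best, unpack = unpack, n_par = n_struct + n_thr)
}

#' Fit a biometric liability-threshold model to twin pairs
#'
#' Maximizes the (optionally IPC-weighted) bivariate-probit likelihood
#' of the pair affection table over the model's free parameters:
#' thresholds plus either per-zygosity correlations (saturated) or
#' variance components.  Affection is `status == EVENT` with
#' `exit_age <= eval_age`.
#'
#' @param spec A [model_spec()].
#' @param pairs Pair table from [assemble_pairs()].
#' @param weights Optional [ipc_weights()] output.
#' @param eval_age Attained-age cutoff defining affection (default
#'   `Inf`: any recorded event).
#' @param n_boot Pair-bootstrap replicates for component confidence
#'   intervals (0 = none).
#' @param conf_level CI level.
#' @param boot_seed Seed for the bootstrap resampling.
#' @return List of class `biometric_fit`: `components`, `rho_MZ`,
#'   `rho_DZ`, `thresholds`, `prevalence`, `casewise` (per zygosity,
#'   from the fitted model), `H` (broad-sense heritability), `logLik`,
#'   `n_parameters`, `AIC`, `n_pairs`, `converged`, `boundary`, `ci`.
#' @export
fit_model <- function(spec, pairs, weights = NULL, eval_age = Inf,
                      n_boot = 0, conf_level = 0.95, boot_seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$sex_mode == "stratified_F")
    pairs <- select_stratum(pairs, sex = "F")
  if (spec$sex_mode == "stratified_M")
    pairs <- select_stratum(pairs, sex = "M")
  if (!nrow(pairs)) stop("no pairs in stratum")
  if (length(intersect(spec$free, c("A", "D"))) &&
      length(unique(ifelse(pairs$zygosity == "MZ", "MZ", "DZ"))) < 2)
    warning("genetic components are not identified without both MZ and DZ pairs")

  groups <- .aggregate_pairs(pairs, weights, eval_age)
  eng <- .fit_engine(spec, groups)
  u <- eng$unpack(eng$opt$par)

  point <- .fit_summary(spec, u, eng, pairs)
  point$logLik <- -eng$opt$value
  point$AIC <- 2 * eng$n_par - 2 * point$logLik
  point$n_parameters <- eng$n_par
  point$n_pairs <- nrow(pairs)
  point$converged <- eng$opt$convergence == 0
  point$spec <- spec

  if (n_boot > 0) {
    set.seed(boot_seed)
    stats_mat <- matrix(NA_real_, n_boot, 5,
                        dimnames = list(NULL, c("A", "D", "C", "E", "H")))
    for (b in seq_len(n_boot)) {
      idx <- sample(nrow(pairs), replace = TRUE)
      gb <- .aggregate_pairs(pairs[idx, , drop = FALSE], weights, eval_age)
      eb <- try(.fit_engine(spec, gb), silent = TRUE)
      if (inherits(eb, "try-error")) next
      ub <- eb$unpack(eb$opt$par)
      sb <- .fit_summary(spec, ub, eb, pairs[idx, , drop = FALSE])
      stats_mat[b, ] <- c(sb$components, sb$H)
    }
    a <- (1 - conf_level) / 2
    point$ci <- apply(stats_mat, 2, function(col) {
      col <- col[is.finite(col)]
      if (length(col) < 2) c(NA_real_, NA_real_)
      else stats::quantile(col, c(a, 1 - a), names = FALSE)
    })
    rownames(point$ci) <- c("lower", "upper")
  }
  class(point) <- "biometric_fit"
  point
}

# Shared derived-quantity block for point fits and bootstrap replicates.
.fit_summary <- function(spec, u, eng, pairs) {
  comps <- if (is.null(u$comps))
    c(A = NA_real_, D = NA_real_, C = NA_real_, E = NA_real_) else u$comps
  H <- if (spec$model == "sat")
    falconer_H(u$rho[["MZ"]], u$rho[["DZ"]])
  else unname(comps[["A"]] + comps[["D"]])
  prev <- stats::pnorm(-u$h)
  # pooled threshold for the model-implied case-wise concordance
  sex_n <- c(F = sum(pairs$sex_1 == "F") + sum(pairs$sex_2 == "F"),
             M = sum(pairs$sex_1 == "M") + sum(pairs$sex_2 == "M"))
  pool_prev <- sum(prev[c("F", "M")] * sex_n) / sum(sex_n)
  h_bar <- stats::qnorm(1 - pool_prev)
  cwc <- vapply(c("MZ", "DZ"), function(z)
    bvn_orthant(h_bar, h_bar, u$rho[[z]]) / pool_prev, numeric(1))
  list(components = comps,
       rho_MZ = unname(u$rho[["MZ"]]), rho_DZ = unname(u$rho[["DZ"]]),
       thresholds = u$h, prevalence = prev,
       casewise = cwc, H = H, boundary = any(comps < 1e-4, na.rm = TRUE))
}

#' @export
print.biometric_fit <- function(x, ...) {
  cat(sprintf("Biometric %s model (%s): logLik %.2f, AIC %.2f, %d pairs\n",
              x$spec$model, x$spec$sex_mode, x$logLik, x$AIC, x$n_pairs))
  if (!all(is.na(x$components)))
    cat(sprintf("  A=%.3f D=%.3f C=%.3f E=%.3f  H=%.3f\n",
                x$components[["A"]], x$components[["D"]],
                x$components[["C"]], x$components[["E"]], x$H))
  cat(sprintf("  rho_MZ=%.3f rho_DZ=%.3f  cwc_MZ=%.3f cwc_DZ=%.3f  prev F=%.4f M=%.4f\n",
              x$rho_MZ, x$rho_DZ, x$casewise[["MZ"]], x$casewise[["DZ"]],
              x$prevalence[["F"]], x$prevalence[["M"]]))
  invisible(x)
}

#' Broad-sense heritability from twin correlations
#'
#' The descriptive estimator `2 (rho_MZ - rho_DZ)`, clipped to `[0, 1]`:
#' the liability variance fraction attributable to all genetic effects
#' (additive plus non-additive).
#'
#' @param rho_MZ,rho_DZ Tetrachoric correlations in `(-1, 1)`.
#' @return Heritability in `[0, 1]`.
#' @export
falconer_H <- function(rho_MZ, rho_DZ) {
  stopifnot(abs(rho_MZ) < 1, abs(rho_DZ) < 1)
  min(1, max(0, 2 * (rho_MZ - rho_DZ)))
}

#' Closed-form ACE decomposition from twin correlations
#'
#' The classical identities `A = 2 (rho_MZ - rho_DZ)`,
#' `C = 2 rho_DZ - rho_MZ`, `E = 1 - rho_MZ`.  Negative components are
#' returned raw with a `boundary` flag so the caller can decide to
#' re-fit a constrained model.
#'
#' @param rho_MZ,rho_DZ Correlations in `(-1, 1)`.
#' @return List with `A`, `C`, `E` and `boundary`.
#' @export
ace_from_correlations <- function(rho_MZ, rho_DZ) {
  stopifnot(abs(rho_MZ) < 1, abs(rho_DZ) < 1)
  A <- 2 * (rho_MZ - rho_DZ)
  C <- 2 * rho_DZ - rho_MZ
  E <- 1 - rho_MZ
  list(A = A, C = C, E = E, boundary = (A < 0 || C < 0))
}

# Declared nesting relations among the model grid.
.nesting <- list(
  sat = c("ACE", "ADE", "AE", "CE", "DE", "E"),
  ACE = c("AE", "CE", "E"),
  ADE = c("AE", "DE", "E"),
  AE = "E", CE = "E", DE = "E")

#' Likelihood-ratio and AIC comparison of fitted biometric models
#'
#' For every declared nested pair among the supplied fits, computes the
#' LR statistic `2 (logLik_big - logLik_small)` with df the difference
#' in free parameters; tests of a variance component on its boundary use
#' the naive chi-square reference and are conservative.  Also returns
#' the AIC ranking (ties broken by fewer parameters).
#'
#' @param fits Named list of `biometric_fit` objects (names from
#'   `.known_models`, e.g. `list(sat = ..., ACE = ...)`), all fitted on
#'   identical data and weights.
#' @return List with `tests` (data.frame) and `aic` (data.frame sorted
#'   ascending).
#' @export
compare_models <- function(fits) {
  nm <- names(fits)
  rows <- list()
  for (big in nm) for (small in intersect(.nesting[[big]], nm)) {
    lr <- 2 * (fits[[big]]$logLik - fits[[small]]$logLik)
    df <- fits[[big]]$n_parameters - fits[[small]]$n_parameters
    if (df <= 0) next
    lr <- max(lr, 0)
    rows[[length(rows) + 1]] <- data.frame(
      model = small, against = big, lr = lr, df = df,
      p_value = stats::pchisq(lr, df, lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  aic <- data.frame(model = nm,
                    n_parameters = vapply(fits, `[[`, numeric(1),
                                          "n_parameters"),
                    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
                    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
                    stringsAsFactors = FALSE)
  aic <- aic[order(aic$AIC, aic$n_parameters), ]
  rownames(aic) <- NULL
  list(tests = if (length(rows)) do.call(rbind, rows) else NULL, aic = aic)
}

#' Age-resolved variance components
#'
#' Refits one model specification with affection defined as "event by
#' attained age t", sliding t over a grid, yielding cumulative-case
#' component curves A(t), D(t), C(t), E(t) and H(t).  Grid ages with
#' fewer affected members than `min_affected` are reported missing.
#'
#' @param pairs Pair table.
#' @param spec A [model_spec()].
#' @param ages Grid of attained-age cutoffs.
#' @param weights Optional [ipc_weights()] output.
#' @param min_affected Minimum affected members required to attempt a
#'   fit (default 10).
#' @return Data.frame `age`, `A`, `D`, `C`, `E`, `H`, `n_affected`.
#' @export
heritability_by_age <- function(pairs, spec, ages, weights = NULL,
                                min_affected = 10) {
  rows <- lapply(ages, function(t) {
    n_aff <- sum(pairs$status_1 == "EVENT" & pairs$exit_age_1 <= t) +
             sum(pairs$status_2 == "EVENT" & pairs$exit_age_2 <= t)
    if (n_aff < min_affected)
      return(data.frame(age = t, A = NA_real_, D = NA_real_, C = NA_real_,
                        E = NA_real_, H = NA_real_, n_affected = n_aff))
    fit <- try(fit_model(spec, pairs, weights, eval_age = t),
               silent = TRUE)
    if (inherits(fit, "try-error"))
      return(data.frame(age = t, A = NA_real_, D = NA_real_, C = NA_real_,
                        E = NA_real_, H = NA_real_, n_affected = n_aff))
    data.frame(age = t, A = fit$components[["A"]], D = fit$components[["D"]],
               C = fit$components[["C"]], E = fit$components[["E"]],
               H = fit$H, n_affected = n_aff)
  })
  do.call(rbind, rows)
}
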