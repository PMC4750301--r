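# Pair-level 2x2 summaries, case-wise concordance, within-pair
# independence screen.

#' Pair-level affection counts
#'
#' Classifies each pair in a stratum by the number of members whose
#' status is EVENT, returning the unordered triple (concordant affected,
#' discordant, concordant unaffected).
#'
#' @param pairs Pair table from [assemble_pairs()] (one stratum), or
#'   `NULL` when the counts are given directly.
#' @param n_cc,n_d,n_uu Direct counts (used when `pairs` is `NULL`).
#' @param label Stratum description carried into reports.
#' @param n_d_f,n_d_m Optional split of the discordant count for
#'   opposite-sex strata (female member affected / male member
#'   affected); filled automatically when `pairs` is given.  Needed for
#'   tetrachoric fits with sex-specific thresholds.
#' @return A list of class `pair_counts` with fields `n_cc`, `n_d`,
#'   `n_uu`, `n_pairs`, `label` and, when available, `n_d_f`/`n_d_m`.
#' @export
pair_counts <- function(pairs = NULL, n_cc = NULL, n_d = NULL, n_uu = NULL,
                        label = "", n_d_f = NULL, n_d_m = NULL) {
  if (!is.null(pairs)) {
    a1 <- pairs$status_1 == "EVENT"
    a2 <- pairs$status_2 == "EVENT"
    aff <- a1 + a2
    n_cc <- sum(aff == 2); n_d <- sum(aff == 1); n_uu <- sum(aff == 0)
    os <- pairs$sex_1 != pairs$sex_2
    if (any(os)) {
      f_aff <- ifelse(pairs$sex_1 == "F", a1, a2)
      m_aff <- ifelse(pairs$sex_1 == "M", a1, a2)
      n_d_f <- sum(os & f_aff & !m_aff)
      n_d_m <- sum(os & m_aff & !f_aff)
    }
  }
  stopifnot(n_cc >= 0, n_d >= 0, n_uu >= 0)
  out <- list(n_cc = as.integer(n_cc), n_d = as.integer(n_d),
              n_uu = as.integer(n_uu),
              n_pairs = as.integer(n_cc + n_d + n_uu), label = label)
  if (!is.null(n_d_f)) {
    out$n_d_f <- as.integer(n_d_f)
    out$n_d_m <- as.integer(n_d_m)
  }
  structure(out, class = "pair_counts")
}

#' @export
print.pair_counts <- function(x, ...) {
  cat(sprintf("Pair counts%s: %d concordant affected, %d discordant, %d concordant unaffected (%d pairs)\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$n_cc, x$n_d, x$n_uu, x$n_pairs))
  invisible(x)
}

# Double-entered 2x2 table (each pair entered in both orders): rows/cols
# are the affection status of the "first"/"second" member.
double_entry_table <- function(counts) {
  matrix(c(2 * counts$n_cc, counts$n_d,
           counts$n_d, 2 * counts$n_uu),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("aff", "unaff"), c("aff", "unaff")))
}

#' Case-wise concordance rate
#'
#' The probability that a twin is affected given that the co-twin is
#' affected: `2 n_cc / (2 n_cc + n_d)`.  Under complete double
#' ascertainment (every concordant pair counted from both probands, as
#' with a national register) this equals the proband-wise concordance
#' rate.
#'
#' @param counts A `pair_counts` object.
#' @return Probability in `[0, 1]`, or `NA_real_` (with a warning) when
#'   no member of any pair is affected.
#' @export
casewise_concordance <- function(counts) {
  denom <- 2 * counts$n_cc + counts$n_d
  if (denom == 0) {
    warning("no affected twins in stratum; concordance undefined")
    return(NA_real_)
  }
  2 * counts$n_cc / denom
}

#' Within-pair independence test
#'
#' Pearson chi-square screen on the double-entered 2x2 table, with
#' expected cells from the marginal prevalence (1 df).  Because each pair
#' is entered twice the twins are treated as exchangeable rather than
#' independent; this is a descriptive screen, not an exact test.
#'
#' @param counts A `pair_counts` object.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
independence_test <- function(counts) {
  if (counts$n_pairs == 0) stop("no pairs in stratum")
  tab <- double_entry_table(counts)
  n <- sum(tab)
  p_aff <- sum(tab[1, ]) / n
  if (p_aff == 0 || p_aff == 1) {
    warning("degenerate margin (prevalence 0 or 1); test undefined")
    return(list(statistic = NA_real_, df = 1L, p_value = NA_real_))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / n
  stat <- sum((tab - expected)^2 / expected)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Concordance and tetrachoric summary across strata
#'
#' Builds the standard zygosity-by-sex report (same-sex strata by
#' zygosity and sex, plus the pooled opposite-sex stratum) on pairs where
#' both members were alive at entry: pair counts, case-wise concordance,
#' ML tetrachoric correlation and the within-pair independence screen.
#'
#' @param pairs Pair table from [assemble_pairs()].
#' @return A data.frame, one row per stratum.
#' @export
concordance_table <- function(pairs) {
  pairs <- select_stratum(pairs, both_alive_at_entry = TRUE)
  strata <- list(
    `MZ males` = list(zyg = "MZ", sex = "M"),
    `DZ males` = list(zyg = "DZ_SS", sex = "M"),
    `MZ females` = list(zyg = "MZ", sex = "F"),
    `DZ females` = list(zyg = "DZ_SS", sex = "F"),
    `OS-DZ` = list(zyg = "DZ_OS", sex = "both")
  )
  rows <- lapply(names(strata), function(nm) {
    st <- strata[[nm]]
    sub <- select_stratum(pairs, zygosity = st$zyg, sex = st$sex)
    cnt <- pair_counts(sub, label = nm)
    if (cnt$n_pairs == 0 || (cnt$n_cc + cnt$n_d) == 0) {
      return(data.frame(stratum = nm, n_cc = cnt$n_cc, n_d = cnt$n_d,
                        n_uu = cnt$n_uu, casewise = NA_real_,
                        rho = NA_real_, se_rho = NA_real_,
                        chisq = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    }
    fit <- fit_tetrachoric(cnt,
                           equal_thresholds = !identical(st$sex, "both"))
    it <- independence_test(cnt)
    data.frame(stratum = nm, n_cc = cnt$n_cc, n_d = cnt$n_d,
               n_uu = cnt$n_uu, casewise = casewise_concordance(cnt),
               rho = fit$rho, se_rho = fit$se_rho,
               chisq = it$statistic, p_value = it$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
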