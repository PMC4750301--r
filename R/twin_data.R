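# Core data model: twin records, pairs, strata, cohort file I/O.
#
# A cohort is a plain data.frame with one row per twin (class "twin_cohort"
# for printing convenience); pairs are built on demand.  All ages are
# attained age in years: entry_age encodes delayed entry (left truncation
# at the start of the administrative observation window) and exit_age
# carries the terminal status EVENT / DEATH / CENSORED.

.zygosity_levels <- c("MZ", "DZ_SS", "DZ_OS")
.sex_levels <- c("F", "M")
.status_levels <- c("EVENT", "DEATH", "CENSORED")
.cohort_columns <- c("twin_id", "pair_id", "zygosity", "sex",
                     "birth_year", "entry_age", "exit_age", "status")

#' Construct and validate a twin cohort table
#'
#' Builds a cohort data.frame from per-twin vectors, enforcing the record
#' invariants: `exit_age > entry_age`, ages within `[0, 120]`, and
#' categorical fields restricted to their allowed levels.
#'
#' @param twin_id,pair_id Character identifiers (opaque).
#' @param zygosity `"MZ"`, `"DZ_SS"` or `"DZ_OS"`.
#' @param sex `"F"` or `"M"`.
#' @param birth_year Integer birth year (bookkeeping only).
#' @param entry_age,exit_age Ages in years; entry is delayed entry.
#' @param status `"EVENT"` (endpoint surgery), `"DEATH"` or `"CENSORED"`.
#' @return A `data.frame` of class `twin_cohort`.
#' @export
twin_cohort <- function(twin_id, pair_id, zygosity, sex, birth_year,
                        entry_age, exit_age, status) {
  df <- data.frame(
    twin_id = as.character(twin_id),
    pair_id = as.character(pair_id),
    zygosity = as.character(zygosity),
    sex = as.character(sex),
    birth_year = as.integer(birth_year),
    entry_age = as.numeric(entry_age),
    exit_age = as.numeric(exit_age),
    status = as.character(status),
    stringsAsFactors = FALSE
  )
  validate_cohort(df)
}

#' Validate a cohort table against the record invariants
#'
#' @param df A data.frame with the eight cohort columns.
#' @return The validated data.frame, classed `twin_cohort`.
#' @export
validate_cohort <- function(df) {
  missing_cols <- setdiff(.cohort_columns, names(df))
  if (length(missing_cols))
    stop("cohort is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  bad_row <- function(cond, what) {
    i <- which(cond)
    if (length(i))
      stop(sprintf("row %d: %s (twin_id=%s)", i[1], what, df$twin_id[i[1]]))
  }
  bad_row(!df$zygosity %in% .zygosity_levels, "invalid zygosity")
  bad_row(!df$sex %in% .sex_levels, "invalid sex")
  bad_row(!df$status %in% .status_levels, "invalid status")
  bad_row(!is.finite(df$entry_age) | df$entry_age < 0 | df$entry_age > 120,
          "entry_age outside [0, 120]")
  bad_row(!is.finite(df$exit_age) | df$exit_age < 0 | df$exit_age > 120,
          "exit_age outside [0, 120]")
  bad_row(df$exit_age <= df$entry_age, "exit_age <= entry_age")
  bad_row(duplicated(df$twin_id), "duplicated twin_id")
  class(df) <- unique(c("twin_cohort", class(df)))
  df
}

#' Read a twin cohort from a delimited text file
#'
#' Expects a header naming the eight mandatory columns
#' (`twin_id, pair_id, zygosity, sex, birth_year, entry_age, exit_age,
#' status`); unknown columns are ignored.  Lines starting with `#` are
#' treated as comments (the simulator writes its seed there).
#'
#' @param path File path.
#' @param sep Field delimiter, default comma.
#' @return A validated `twin_cohort` data.frame.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  missing_cols <- setdiff(.cohort_columns, names(df))
  if (length(missing_cols))
    stop("file ", path, " is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[.cohort_columns]
  for (col in c("entry_age", "exit_age")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("row %d: cannot parse %s value '%s'",
                   bad[1], col, df[[col]][bad[1]]))
    df[[col]] <- v
  }
  v <- suppressWarnings(as.integer(df$birth_year))
  bad <- which(is.na(v) & !is.na(df$birth_year))
  if (length(bad))
    stop(sprintf("row %d: cannot parse birth_year value '%s'",
                 bad[1], df$birth_year[bad[1]]))
  df$birth_year <- v
  validate_cohort(df)
}

#' Write a twin cohort to a delimited text file
#'
#' Emits the same schema [read_cohort()] reads; an optional comment line
#' (e.g. the simulation seed) is written first, prefixed with `#`.
#'
#' @param cohort A `twin_cohort` data.frame.
#' @param path Output path.
#' @param sep Field delimiter.
#' @param comment Optional character comment line(s).
#' @export
write_cohort <- function(cohort, path, sep = ",", comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  utils::write.table(cohort[.cohort_columns], con, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble twin pairs from a cohort
#'
#' Every `pair_id` with exactly two records becomes a pair; pair ids with
#' one or more than two records are orphaned (excluded from pair-level
#' analyses, with a warning for the >2 case).  Sex/zygosity consistency
#' is enforced: same-sex zygosities (MZ, DZ_SS) must have concordant sex,
#' and DZ_OS must have discordant sex.
#'
#' @param cohort A `twin_cohort` data.frame.
#' @return A list with `pairs` (a data.frame, one row per pair, with
#'   member columns suffixed `_1`/`_2`) and `orphans` (record-level
#'   data.frame of twins without a complete pair).
#' @export
assemble_pairs <- function(cohort) {
  cohort <- validate_cohort(as.data.frame(cohort))
  tab <- table(cohort$pair_id)
  full <- names(tab)[tab == 2]
  over <- names(tab)[tab > 2]
  if (length(over))
    warning(length(over), " pair_id(s) with >2 records orphaned: ",
            paste(utils::head(over, 5), collapse = ", "))
  orphans <- cohort[!cohort$pair_id %in% full, , drop = FALSE]
  members <- cohort[cohort$pair_id %in% full, , drop = FALSE]
  members <- members[order(members$pair_id, members$twin_id), , drop = FALSE]
  i1 <- seq(1, nrow(members), by = 2)
  i2 <- i1 + 1L
  m1 <- members[i1, , drop = FALSE]
  m2 <- members[i2, , drop = FALSE]
  if (any(m1$zygosity != m2$zygosity))
    stop("pair ", m1$pair_id[which(m1$zygosity != m2$zygosity)[1]],
         ": members disagree on zygosity")
  same_sex <- m1$sex == m2$sex
  bad_mz <- which(m1$zygosity %in% c("MZ", "DZ_SS") & !same_sex)
  if (length(bad_mz))
    stop("pair ", m1$pair_id[bad_mz[1]],
         ": same-sex zygosity with discordant sex (impossible pair)")
  bad_os <- which(m1$zygosity == "DZ_OS" & same_sex)
  if (length(bad_os))
    stop("pair ", m1$pair_id[bad_os[1]],
         ": DZ_OS zygosity with concordant sex (impossible pair)")
  pairs <- data.frame(
    pair_id = m1$pair_id,
    zygosity = m1$zygosity,
    twin_id_1 = m1$twin_id, sex_1 = m1$sex,
    entry_age_1 = m1$entry_age, exit_age_1 = m1$exit_age, status_1 = m1$status,
    twin_id_2 = m2$twin_id, sex_2 = m2$sex,
    entry_age_2 = m2$entry_age, exit_age_2 = m2$exit_age, status_2 = m2$status,
    stringsAsFactors = FALSE
  )
  rownames(pairs) <- NULL
  rownames(orphans) <- NULL
  list(pairs = pairs, orphans = orphans)
}

#' Select a stratum of twin pairs
#'
#' Composable filters on a pair table: zygosity, sex, and the
#' "both alive at entry" condition used for the pairwise concordance and
#' tetrachoric analyses.  The sex filter keeps same-sex pairs of the
#' requested sex; opposite-sex pairs are kept only when `sex = "both"`.
#'
#' @param pairs Pair table from [assemble_pairs()].
#' @param zygosity One of `"MZ"`, `"DZ_SS"`, `"DZ_OS"` or `"any"`.
#' @param sex `"F"`, `"M"` or `"both"`.
#' @param both_alive_at_entry If `TRUE`, drop pairs in which a member was
#'   dead at or before the start of observation (operationally: a member
#'   with status DEATH and `exit_age <= entry_age` — excluded already at
#'   validation — never occurs, so the filter drops nothing on valid
#'   records; it is retained for cohorts assembled from external data
#'   where a dead-at-entry member is encoded by `exit_age == entry_age`).
#' @return Filtered pair table (possibly empty).
#' @export
select_stratum <- function(pairs, zygosity = "any", sex = "both",
                           both_alive_at_entry = FALSE) {
  keep <- rep(TRUE, nrow(pairs))
  if (!identical(zygosity, "any")) {
    if (!all(zygosity %in% .zygosity_levels)) stop("unknown zygosity filter")
    keep <- keep & pairs$zygosity %in% zygosity
  }
  if (!identical(sex, "both")) {
    if (!sex %in% .sex_levels) stop("unknown sex filter")
    keep <- keep & pairs$sex_1 == sex & pairs$sex_2 == sex
  }
  if (both_alive_at_entry) {
    alive1 <- pairs$status_1 != "DEATH" | pairs$exit_age_1 > pairs$entry_age_1
    alive2 <- pairs$status_2 != "DEATH" | pairs$exit_age_2 > pairs$entry_age_2
    keep <- keep & alive1 & alive2
  }
  pairs[keep, , drop = FALSE]
}

#' Flatten a pair table back to per-twin records
#'
#' @param pairs Pair table from [assemble_pairs()].
#' @return A data.frame with one row per twin member.
#' @export
pairs_to_records <- function(pairs) {
  pick <- function(suffix) {
    data.frame(
      twin_id = pairs[[paste0("twin_id_", suffix)]],
      pair_id = pairs$pair_id,
      zygosity = pairs$zygosity,
      sex = pairs[[paste0("sex_", suffix)]],
      entry_age = pairs[[paste0("entry_age_", suffix)]],
      exit_age = pairs[[paste0("exit_age_", suffix)]],
      status = pairs[[paste0("status_", suffix)]],
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(pick(1), pick(2))
  rownames(out) <- NULL
  out
}

#' @export
print.twin_cohort <- function(x, ...) {
  cat(sprintf("Twin cohort: %d records, %d pair ids\n",
              nrow(x), length(unique(x$pair_id))))
  cat(sprintf("  zygosity: %s\n",
              paste(sprintf("%s=%d", names(table(x$zygosity)),
                            as.integer(table(x$zygosity))), collapse = " ")))
  cat(sprintf("  status:   %s\n",
              paste(sprintf("%s=%d", names(table(x$status)),
                            as.integer(table(x$status))), collapse = " ")))
  invisible(x)
}
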