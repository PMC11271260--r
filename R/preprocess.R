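#' Drop features with too much missing data
#'
#' Retains exactly the features whose per-column missing fraction is at
#' most `max_missing_frac`; features with *over* that fraction missing
#' are excluded.  Column order of the survivors is preserved.
#'
#' @param table a [modality_table()].
#' @param max_missing_frac maximum tolerated missing fraction (default
#'   0.10, i.e. features with over 10 percent missing data are dropped).
#' @return the filtered `modality_table`, with attribute `"dropped"`
#'   listing the removed feature names.
#' @export
filter_missing_features <- function(table, max_missing_frac = 0.10) {
  stopifnot(inherits(table, "modality_table"))
  if (max_missing_frac < 0 || max_missing_frac > 1)
    config_stop("max_missing_frac must be in [0, 1]")
  if (nrow(table$features) == 0L || ncol(table$features) == 0L)
    data_stop(sprintf("modality '%s' is empty", table$modality_name))
  frac <- colMeans(is.na(table$features))
  keep <- frac <= max_missing_frac
  out <- mt_cols(table, which(keep))
  attr(out, "dropped") <- colnames(table$features)[!keep]
  out
}

#' Drop subjects with any missing feature value
#'
#' Removes every row containing at least one missing entry; the result
#' has no missing values.
#'
#' @param table a [modality_table()].
#' @return the filtered `modality_table`, with attribute
#'   `"dropped_rows"` giving the number of removed rows.
#' @export
drop_incomplete_records <- function(table) {
  stopifnot(inherits(table, "modality_table"))
  complete <- rowSums(is.na(table$features)) == 0L
  if (!any(complete))
    data_stop(sprintf(
      "modality '%s': every record has missing entries",
      table$modality_name))
  out <- mt_rows(table, which(complete))
  attr(out, "dropped_rows") <- sum(!complete)
  out
}

#' Keep each subject's earliest (baseline) visit
#'
#' For subjects with multiple dated visits, retains the row with the
#' earliest `visit_date`; ties on date are resolved by the first
#' occurrence in the table.
#'
#' @param table a [modality_table()] with `visit_date` set.
#' @return a `modality_table` with one row per subject.
#' @export
select_baseline_visit <- function(table) {
  stopifnot(inherits(table, "modality_table"))
  multi <- duplicated(table$subject_id) |
    duplicated(table$subject_id, fromLast = TRUE)
  if (is.null(table$visit_date)) {
    if (any(multi))
      data_stop(sprintf(
        "modality '%s': multi-visit subjects but no visit dates",
        table$modality_name))
    return(table)
  }
  if (anyNA(table$visit_date[multi]))
    data_stop(sprintf(
      "modality '%s': missing visit date for a multi-visit subject",
      table$modality_name))
  ord <- order(match(table$subject_id, unique(table$subject_id)),
               table$visit_date)
  first <- !duplicated(table$subject_id[ord])
  keep <- sort(ord[first])
  mt_rows(table, keep)
}

#' Pair two modalities within a date window
#'
#' Keeps subjects present in both tables whose visit dates differ by at
#' most `window_days` days.  When a subject has several eligible
#' visit/scan pairs, the pair with the smallest absolute date gap is
#' kept; remaining ties are broken by the earlier date in `a`.  Both
#' returned tables are row-aligned on the shared subjects.
#'
#' @param a,b [modality_table()] objects with `visit_date` set.  `a` may
#'   contain several rows per subject (e.g. repeat visits), as may `b`.
#' @param window_days maximum allowed gap in days (default 548, i.e. 18
#'   months at 365.25 days per year).
#' @return a named list with row-aligned modality tables `a` and `b`.
#' @export
merge_within_window <- function(a, b, window_days = 548) {
  stopifnot(inherits(a, "modality_table"), inherits(b, "modality_table"))
  if (is.null(a$visit_date) || is.null(b$visit_date))
    data_stop("both modalities need visit dates for window merging")
  keep_a <- integer(0)
  keep_b <- integer(0)
  for (sid in intersect(unique(a$subject_id), unique(b$subject_id))) {
    ia <- which(a$subject_id == sid)
    ib <- which(b$subject_id == sid)
    gaps <- abs(outer(as.numeric(a$visit_date[ia]),
                      as.numeric(b$visit_date[ib]), "-"))
    eligible <- which(gaps <= window_days, arr.ind = TRUE)
    if (nrow(eligible) == 0L) next
    gap_vals <- gaps[eligible]
    best <- eligible[order(gap_vals, as.numeric(a$visit_date[ia])[
      eligible[, 1L]])[1L], , drop = TRUE]
    keep_a <- c(keep_a, ia[best[1L]])
    keep_b <- c(keep_b, ib[best[2L]])
  }
  if (!length(keep_a))
    data_stop(sprintf(
      "no subjects shared by '%s' and '%s' within %d days",
      a$modality_name, b$modality_name, window_days))
  list(a = mt_rows(a, keep_a), b = mt_rows(b, keep_b))
}

#' Keep subjects strictly older than a minimum age
#'
#' @param table a [modality_table()] with `age` set.
#' @param min_age_years strict lower bound in years (default 65: only
#'   subjects *over* 65 are kept).
#' @return the filtered `modality_table`.
#' @export
filter_age <- function(table, min_age_years = 65) {
  stopifnot(inherits(table, "modality_table"))
  if (is.null(table$age))
    data_stop(sprintf("modality '%s' has no age column",
                      table$modality_name))
  mt_rows(table, which(table$age > min_age_years))
}

#' Run the standard two-modality preprocessing pipeline
#'
#' Applies the canonical filter order to a pair of raw visit-level
#' tables: baseline-visit selection, feature-missingness filter, record
#' drop, age filter (when ages are present), then the scan-window
#' merge.  Emits a per-stage count report.
#'
#' @param a,b raw [modality_table()] objects.
#' @param labels named character vector mapping subject id to diagnosis
#'   (`HC`/`MCI`/`AD`).
#' @param max_missing_frac forwarded to [filter_missing_features()].
#' @param window_days forwarded to [merge_within_window()].
#' @param min_age_years forwarded to [filter_age()]; `NULL` skips the
#'   age filter.
#' @return a list with `cohort` (a [labeled_cohort()]) and `report`
#'   (a data frame of per-stage row/column counts).
#' @export
preprocess_pair <- function(a, b, labels, max_missing_frac = 0.10,
                            window_days = 548, min_age_years = 65) {
  report <- list()
  note <- function(stage, tab) {
    report[[length(report) + 1L]] <<- data.frame(
      stage = stage, modality = tab$modality_name,
      rows = nrow(tab$features), features = ncol(tab$features))
  }
  stage1 <- function(tab) {
    note("input", tab)
    tab <- select_baseline_visit(tab); note("baseline", tab)
    tab <- filter_missing_features(tab, max_missing_frac)
    note("feature_filter", tab)
    tab <- drop_incomplete_records(tab); note("complete_records", tab)
    if (!is.null(min_age_years) && !is.null(tab$age)) {
      tab <- filter_age(tab, min_age_years); note("age_filter", tab)
    }
    tab
  }
  a <- stage1(a)
  b <- stage1(b)
  merged <- merge_within_window(a, b, window_days)
  note("merged", merged$a); note("merged", merged$b)
  ids <- merged$a$subject_id
  if (!all(ids %in% names(labels)))
    data_stop("labels missing for some merged subjects")
  cohort <- labeled_cohort(
    stats::setNames(list(merged$a, merged$b),
                    c(merged$a$modality_name, merged$b$modality_name)),
    labels[ids])
  list(cohort = cohort, report = do.call(rbind, report))
}

#' Read a modality table from CSV
#'
#' Expects a header row, a subject-id column, optional ISO-8601 date and
#' age columns, and numeric feature columns (everything else).
#'
#' @param path CSV file path.
#' @param modality_name name for the modality.
#' @param id_col subject-id column name (default `"subject_id"`).
#' @param date_col optional date column name.
#' @param age_col optional age column name.
#' @return a [modality_table()].
#' @export
read_modality_csv <- function(path, modality_name,
                              id_col = "subject_id",
                              date_col = NULL, age_col = NULL) {
  df <- read.csv(path, check.names = FALSE)
  if (!id_col %in% names(df))
    data_stop(sprintf("'%s' has no column '%s'", path, id_col))
  aux <- c(id_col, date_col, age_col)
  feats <- as.matrix(df[setdiff(names(df), aux)])
  storage.mode(feats) <- "double"
  modality_table(
    subject_id = df[[id_col]],
    features = feats,
    modality_name = modality_name,
    visit_date = if (!is.null(date_col)) as.Date(df[[date_col]]),
    age = if (!is.null(age_col)) df[[age_col]])
}
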