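#' Construct a modality table
#'
#' A modality table holds one modality's subject-by-feature numeric
#' matrix together with subject identifiers, optional visit dates, and
#' optional auxiliary columns (e.g. age) used by preprocessing filters.
#'
#' @param subject_id character or integer vector of subject identifiers.
#'   Identifiers may repeat before baseline-visit selection (one row per
#'   visit) but must be unique in a preprocessed table.
#' @param features numeric matrix (rows = subjects/visits, columns =
#'   features) with unique column names.  `NA` entries encode missing
#'   values; they must be removed by preprocessing before modelling.
#' @param modality_name single string naming the modality (e.g. "UDS").
#' @param visit_date optional `Date` vector (one per row).
#' @param age optional numeric vector of ages in years (one per row).
#' @return an object of class `modality_table`.
#' @seealso [filter_missing_features()], [drop_incomplete_records()],
#'   [select_baseline_visit()], [merge_within_window()], [filter_age()]
#' @export
modality_table <- function(subject_id, features, modality_name,
                           visit_date = NULL, age = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features)
  if (length(subject_id) != n)
    data_stop(sprintf(
      "modality '%s': %d subject ids for %d feature rows",
      modality_name, length(subject_id), n))
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  if (anyDuplicated(colnames(features)))
    data_stop(sprintf("modality '%s': duplicate feature names",
                      modality_name))
  if (!is.null(visit_date)) {
    visit_date <- as.Date(visit_date)
    if (length(visit_date) != n)
      data_stop("visit_date length does not match row count")
  }
  if (!is.null(age)) {
    age <- as.numeric(age)
    if (length(age) != n)
      data_stop("age length does not match row count")
  }
  structure(
    list(subject_id = as.character(subject_id),
         features = features,
         modality_name = as.character(modality_name),
         visit_date = visit_date,
         age = age),
    class = "modality_table")
}

#' @export
print.modality_table <- function(x, ...) {
  cat(sprintf("<modality_table '%s'> %d rows x %d features",
              x$modality_name, nrow(x$features), ncol(x$features)))
  if (!is.null(x$visit_date)) cat(", dated")
  miss <- sum(is.na(x$features))
  if (miss > 0) cat(sprintf(", %d missing entries", miss))
  cat("\n")
  invisible(x)
}

#' @export
dim.modality_table <- function(x) dim(x$features)

# subset rows of a modality table, keeping all parallel vectors aligned
mt_rows <- function(table, idx) {
  modality_table(
    subject_id = table$subject_id[idx],
    features = table$features[idx, , drop = FALSE],
    modality_name = table$modality_name,
    visit_date = if (!is.null(table$visit_date)) table$visit_date[idx],
    age = if (!is.null(table$age)) table$age[idx])
}

# subset feature columns
mt_cols <- function(table, cols) {
  modality_table(
    subject_id = table$subject_id,
    features = table$features[, cols, drop = FALSE],
    modality_name = table$modality_name,
    visit_date = table$visit_date,
    age = table$age)
}

#' Diagnosis label levels
#'
#' Canonical ordering of the three-class diagnosis factor: healthy
#' control, mild cognitive impairment, dementia.
#' @export
DIAGNOSIS_LEVELS <- c("HC", "MCI", "AD")

#' Assemble a labeled multimodal cohort
#'
#' Aligns one or more preprocessed modality tables with a per-subject
#' diagnosis label.  Every modality must carry the same subjects in the
#' same order, with no missing feature entries.
#'
#' @param modalities named list of [modality_table()] objects.
#' @param labels factor or character vector of diagnoses in
#'   `c("HC", "MCI", "AD")`, one per subject, ordered as the modality
#'   rows.
#' @return an object of class `labeled_cohort`.
#' @export
labeled_cohort <- function(modalities, labels) {
  if (!length(modalities)) data_stop("cohort needs at least one modality")
  if (is.null(names(modalities)) || any(!nzchar(names(modalities))))
    names(modalities) <- vapply(modalities, `[[`, "", "modality_name")
  ids <- modalities[[1L]]$subject_id
  for (m in modalities) {
    if (!inherits(m, "modality_table"))
      data_stop("all modalities must be modality_table objects")
    if (!identical(m$subject_id, ids))
      data_stop(sprintf(
        "modality '%s' subject ordering differs from '%s'",
        m$modality_name, modalities[[1L]]$modality_name))
    if (anyNA(m$features))
      data_stop(sprintf(
        "modality '%s' still contains missing entries; preprocess first",
        m$modality_name))
    if (anyDuplicated(m$subject_id))
      data_stop(sprintf("modality '%s' has duplicated subjects",
                        m$modality_name))
  }
  labels <- as.character(labels)
  if (length(labels) != length(ids))
    data_stop("labels must cover every subject")
  bad <- setdiff(unique(labels), DIAGNOSIS_LEVELS)
  if (length(bad))
    data_stop(paste0("unknown diagnosis label(s): ",
                     paste(bad, collapse = ", ")))
  structure(
    list(modalities = modalities,
         labels = factor(labels, levels = DIAGNOSIS_LEVELS)),
    class = "labeled_cohort")
}

#' @export
print.labeled_cohort <- function(x, ...) {
  cat(sprintf("<labeled_cohort> %d subjects, %d modalities\n",
              length(x$labels), length(x$modalities)))
  for (m in x$modalities)
    cat(sprintf("  %s: %d features\n", m$modality_name,
                ncol(m$features)))
  print(table(x$labels))
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort a [labeled_cohort()].
#' @return integer subject count.
#' @export
n_subjects <- function(cohort) length(cohort$labels)

# row-subset an entire cohort (used by split evaluation)
cohort_rows <- function(cohort, idx) {
  labeled_cohort(lapply(cohort$modalities, mt_rows, idx = idx),
                 as.character(cohort$labels[idx]))
}

#' Collapse three-class diagnoses to the binary task
#'
#' The binary task separates healthy controls from any level of
#' impairment: HC maps to 0, MCI and AD both map to 1.
#'
#' @param labels factor or character vector with values in
#'   `c("HC", "MCI", "AD")`.
#' @return integer vector of 0 (HC) / 1 (impaired).
#' @export
collapse_binary <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), DIAGNOSIS_LEVELS)
  if (length(bad))
    data_stop(paste0("unknown diagnosis label(s): ",
                     paste(bad, collapse = ", ")))
  as.integer(labels != "HC")
}

# task-specific label coding: binary -> factor 0/1, multiclass -> 3-level
task_labels <- function(labels, task) {
  if (task == "binary") factor(collapse_binary(labels), levels = c(0L, 1L))
  else factor(as.character(labels), levels = DIAGNOSIS_LEVELS)
}
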