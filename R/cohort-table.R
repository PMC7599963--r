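# Subject/cohort tables (TSV)

GROUP_LEVELS <- c("HC", "EM", "CM")

# fields required per group (besides id, group, sex, age)
MIGRAINE_FIELDS <- c("duration", "headache_freq", "migraine_freq",
                     "aura", "overuse")
CM_FIELDS <- "cm_onset_months"

#' Construct and validate a cohort table
#'
#' Subjects belong to one of three groups: healthy controls (HC),
#' episodic migraine (EM) or chronic migraine (CM). Clinical fields
#' (migraine duration in years, headache/migraine frequency in
#' days/month, aura, medication overuse) must be present exactly for the
#' migraine groups, and time from onset of chronification
#' (`cm_onset_months`) only for CM.
#'
#' @param df data.frame with columns id, group, sex, age and the clinical
#'   fields above.
#' @return validated data.frame of class `cohort_table`.
#' @export
cohort_table <- function(df) {
  need <- c("id", "group", "sex", "age")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_format("cohort table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$id))
    stop_validation("duplicate subject id(s): ",
                    paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  grp <- toupper(trimws(as.character(df$group)))
  bad <- setdiff(unique(grp), GROUP_LEVELS)
  if (length(bad))
    stop_validation("unknown group label(s): ", paste(bad, collapse = ", "))
  df$group <- factor(grp, levels = GROUP_LEVELS)
  sx <- tolower(trimws(as.character(df$sex)))
  if (!all(sx %in% c("male", "female")))
    stop_validation("sex must be male or female")
  df$sex <- factor(sx, levels = c("male", "female"))
  if (any(!is.finite(df$age) | df$age < 0))
    stop_validation("ages must be non-negative")
  mig <- df$group %in% c("EM", "CM")
  for (f in MIGRAINE_FIELDS) {
    if (!f %in% names(df)) {
      if (any(mig)) stop_format("cohort table lacks column(s): ", f)
      next
    }
    if (any(mig & is.na(df[[f]])))
      stop_validation("missing ", f, " for migraine subject(s)")
  }
  if (any(df$group == "CM")) {
    if (!"cm_onset_months" %in% names(df))
      stop_format("cohort table lacks column(s): cm_onset_months")
    if (any(df$group == "CM" & is.na(df$cm_onset_months)))
      stop_validation("missing cm_onset_months for CM subject(s)")
  }
  if ("duration" %in% names(df) && any(mig & df$duration < 0))
    stop_validation("negative duration")
  for (f in c("headache_freq", "migraine_freq"))
    if (f %in% names(df) &&
        any(mig & (df[[f]] < 0 | df[[f]] > 31)))
      stop_validation(f, " must lie in [0, 31] days/month")
  for (f in c("aura", "overuse"))
    if (f %in% names(df)) df[[f]] <- as.logical(df[[f]])
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Read a cohort table from TSV
#' @param path TSV file with a header row.
#' @return a validated [cohort_table()].
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  cohort_table(df)
}

#' Write a cohort table to TSV
#' @param tab a [cohort_table()].
#' @param path output path.
#' @export
write_cohort_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-group subject counts
#' @param tab a [cohort_table()].
#' @return named integer vector over HC, EM, CM.
#' @export
group_counts <- function(tab) table(tab$group)
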