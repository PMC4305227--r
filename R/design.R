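#' Study groups and comparison pairs
#'
#' The design has five groups: healthy controls (\code{CON}), stable COPD
#' (\code{STABLE}) and acute exacerbation of COPD sampled on hospital days
#' 1, 3 and 10 (\code{AE1}, \code{AE3}, \code{AE10}). All differential
#' analysis is carried out over the ten ordered comparison pairs these
#' groups admit: each disease group against control, each exacerbation day
#' against stable disease, and the three between-day contrasts.
#'
#' @return `study_groups()` returns the five group labels in design order.
#' @export
study_groups <- function() {
  c("CON", "STABLE", "AE1", "AE3", "AE10")
}

#' @rdname study_groups
#' @return `comparison_pairs()` returns a data frame with columns
#'   \code{pair}, \code{numerator} and \code{denominator} enumerating the
#'   ten comparisons. The numerator is the group whose mean goes on top of
#'   the fold-change ratio.
#' @export
comparison_pairs <- function() {
  num <- c("STABLE", "AE1", "AE3", "AE10",
           "AE1", "AE3", "AE10",
           "AE3", "AE10", "AE10")
  den <- c("CON", "CON", "CON", "CON",
           "STABLE", "STABLE", "STABLE",
           "AE1", "AE1", "AE3")
  data.frame(pair = paste0(num, "_vs_", den),
             numerator = num, denominator = den,
             stringsAsFactors = FALSE)
}

#' Construct and validate a study design
#'
#' A study design maps each sample to a subject and one of the five study
#' groups. Exacerbation samples are longitudinal: the three AE groups share
#' subject identifiers, one sample per subject per day.
#'
#' @param sample_id,subject_id character vectors, one entry per sample.
#' @param group character vector of group labels drawn from
#'   [study_groups()].
#' @param day optional numeric day of sampling (1, 3 or 10 for AE samples,
#'   \code{NA} otherwise); derived from the group when omitted.
#' @return A data frame of class \code{study_design} with columns
#'   \code{sample_id}, \code{subject_id}, \code{group}, \code{day}.
#' @export
study_design <- function(sample_id, subject_id, group, day = NULL) {
  group <- as.character(group)
  bad <- setdiff(unique(group), study_groups())
  if (length(bad) > 0) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(study_groups(), collapse = ", "), ")")
  }
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id(s): ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  if (is.null(day)) {
    day <- c(CON = NA, STABLE = NA, AE1 = 1, AE3 = 3, AE10 = 10)[group]
  }
  design <- data.frame(sample_id = as.character(sample_id),
                       subject_id = as.character(subject_id),
                       group = group, day = as.numeric(day),
                       stringsAsFactors = FALSE)
  ae <- design[design$group %in% c("AE1", "AE3", "AE10"), ]
  if (nrow(ae) > 0) {
    days_per_subject <- tapply(ae$group, ae$subject_id,
                               function(g) length(unique(g)))
    gaps <- names(days_per_subject)[days_per_subject < 3]
    if (length(gaps) > 0) {
      warning("AE subject(s) missing one or more sampling days: ",
              paste(gaps, collapse = ", "))
    }
  }
  class(design) <- c("study_design", "data.frame")
  design
}

group_samples <- function(design, group) {
  design$sample_id[design$group == group]
}
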