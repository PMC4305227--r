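#' The Digital Evaluation Score System (DESS)
#'
#' DESS is a composite clinical severity score for COPD: 64 clinical
#' components (symptoms and signs, biochemistry, imaging and other
#' findings) are each graded 0, 1, 2 or 4 — 0 within the normal
#' physiological range, higher values more severe — and summed, so a
#' patient record totals between 0 and 256 points. Component grading
#' rubrics (how a raw measurement maps to 0/1/2/4) are supplied by the
#' user; this module validates records, totals them and summarises groups.
#'
#' @name dess
NULL

DESS_N_COMPONENTS <- 64L
DESS_LEVELS <- c(0L, 1L, 2L, 4L)

#' Build a DESS record
#'
#' @param sample_id sample identifier.
#' @param levels integer vector of 64 component levels, each 0, 1, 2 or 4.
#' @param component_id identifiers for the components; defaults to
#'   \code{C01..C64}.
#' @param category optional component categories (e.g. symptom_sign,
#'   biochemistry, imaging, other).
#' @return Data frame with columns \code{sample_id}, \code{component_id},
#'   \code{category}, \code{level} — the long record format used
#'   throughout.
#' @export
dess_record <- function(sample_id, levels,
                        component_id = sprintf("C%02d", seq_along(levels)),
                        category = "other") {
  data.frame(sample_id = sample_id, component_id = component_id,
             category = category, level = as.integer(levels),
             stringsAsFactors = FALSE)
}

validate_dess_record <- function(record) {
  sid <- record$sample_id[1]
  bad <- !(record$level %in% DESS_LEVELS)
  if (any(bad)) {
    stop("invalid DESS level for sample '", sid, "', component(s) ",
         paste(record$component_id[bad], collapse = ", "),
         ": levels must be 0, 1, 2 or 4")
  }
  if (nrow(record) != DESS_N_COMPONENTS) {
    stop("DESS record for sample '", sid, "' has ", nrow(record),
         " components; exactly ", DESS_N_COMPONENTS, " are required")
  }
  if (anyDuplicated(record$component_id)) {
    stop("DESS record for sample '", sid, "' has duplicate component ids")
  }
  invisible(record)
}

#' Score DESS records
#'
#' Totals the component levels of each sample's record after validation
#' (exactly 64 components, unique ids, levels in \{0, 1, 2, 4\}).
#'
#' @param records long data frame of DESS components (\code{sample_id},
#'   \code{component_id}, \code{level}; a \code{category} column is
#'   carried but not required).
#' @return Data frame with columns \code{sample_id} and \code{total}
#'   (integer in [0, 256]).
#' @export
score_dess <- function(records) {
  split_records <- split(records, records$sample_id)
  totals <- vapply(split_records, function(rec) {
    validate_dess_record(rec)
    sum(rec$level)
  }, integer(1))
  data.frame(sample_id = names(totals), total = unname(totals),
             stringsAsFactors = FALSE)
}

#' Round half away from zero
#'
#' Display rounding used for the published-style summary tables (R's
#' \code{round} rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 1) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Summarise DESS totals per group
#'
#' @param scores data frame with \code{sample_id} and \code{total} (from
#'   [score_dess()]), or any numeric column named \code{total}.
#' @param groups character vector assigning each score row to a group.
#' @return Data frame with columns \code{group}, \code{n}, \code{mean},
#'   \code{se} (standard error, sample SD over sqrt(n); \code{NA} for
#'   n = 1) at full precision, plus display columns \code{mean_1dp} and
#'   \code{se_1dp} rounded half-up to one decimal.
#' @export
summarize_dess <- function(scores, groups) {
  if (nrow(scores) == 0) stop("no scores to summarise")
  stopifnot(length(groups) == nrow(scores))
  glev <- unique(groups)
  out <- do.call(rbind, lapply(glev, function(g) {
    x <- scores$total[groups == g]
    se <- if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
    data.frame(group = g, n = length(x), mean = mean(x), se = se,
               stringsAsFactors = FALSE)
  }))
  out$mean_1dp <- round_half_up(out$mean, 1)
  out$se_1dp <- round_half_up(out$se, 1)
  out
}

#' Severity trajectory over the exacerbation days
#'
#' Reduces the ordered DESS group means at days 1, 3, 10 to a two-step
#' sign pattern. Severity is expected to decline as the patient recovers,
#' i.e. \code{down-down}.
#'
#' @param means numeric length-3 vector of group mean DESS at days 1, 3, 10.
#' @return One of \code{"down-down"}, \code{"down-up"}, \code{"up-down"},
#'   \code{"up-up"}, \code{"flat-containing"}.
#' @export
severity_trajectory <- function(means) {
  stopifnot(length(means) == 3)
  s <- sign(diff(means))
  if (any(s == 0)) return("flat-containing")
  paste0(ifelse(s > 0, "up", "down"), collapse = "-")
}
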