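#' Classify two-step expression trajectories across the exacerbation
#'
#' Each gene's course over hospital days 1 -> 3 -> 10 of an exacerbation is
#' summarised by two steps (day 3 vs day 1, day 10 vs day 3), each an
#' up/down direction with a fold ratio. The pattern is the Cartesian
#' product of the two step directions — \code{down-down}, \code{down-up},
#' \code{up-down}, \code{up-up} — and the qualifying fold is the smaller of
#' the two step ratios. A flat step (ratio exactly 1) leaves the gene
#' \code{unclassified}: the four patterns cover strict movements only.
#'
#' @param step1,step2 data frames with columns \code{gene_id}, \code{ratio},
#'   \code{direction}, typically the [fold_change()] output for
#'   \code{AE3_vs_AE1} and \code{AE10_vs_AE3}. Genes are matched by id.
#' @return Data frame with columns \code{gene_id}, \code{step1_ratio},
#'   \code{step1_direction}, \code{step2_ratio}, \code{step2_direction},
#'   \code{pattern}, \code{qualifying_fold}.
#' @export
classify_trajectory <- function(step1, step2) {
  idx <- match(step1$gene_id, step2$gene_id)
  if (anyNA(idx)) {
    stop("gene(s) present in step1 but not step2: ",
         paste(utils::head(step1$gene_id[is.na(idx)], 5), collapse = ", "))
  }
  s2 <- step2[idx, ]
  flat <- step1$direction == "flat" | s2$direction == "flat"
  pattern <- ifelse(flat, "unclassified",
                    paste0(step1$direction, "-", s2$direction))
  data.frame(gene_id = step1$gene_id,
             step1_ratio = step1$ratio, step1_direction = step1$direction,
             step2_ratio = s2$ratio, step2_direction = s2$direction,
             pattern = pattern,
             qualifying_fold = pmin(step1$ratio, s2$ratio),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Trajectory pattern labels
#' @return The four strict two-step patterns.
#' @export
trajectory_patterns <- function() {
  c("down-down", "down-up", "up-down", "up-up")
}

#' Count trajectory patterns above a qualifying-fold threshold
#'
#' @param calls output of [classify_trajectory()].
#' @param threshold inclusive fold threshold (>= 1) applied to the
#'   qualifying fold (the smaller step ratio).
#' @return Named integer vector over the four patterns.
#' @export
pattern_census <- function(calls, threshold = 2) {
  if (threshold < 1) stop("fold threshold must be >= 1, got ", threshold)
  pats <- trajectory_patterns()
  qualified <- calls[calls$pattern %in% pats &
                       calls$qualifying_fold >= threshold, ]
  table(factor(qualified$pattern, levels = pats)) |> c()
}

#' Concordance of a gene trajectory with clinical severity
#'
#' Compares a gene's signed stable-relative expression at exacerbation days
#' 1, 3 and 10 with the DESS severity means of the same days. The signed
#' values follow the convention of exacerbation-vs-stable displays: the
#' fold versus the stable-COPD group, negative when below stable. The
#' primary output is whether the gene's two-step sign pattern equals the
#' severity pattern; a Pearson correlation over the two 3-vectors is also
#' reported but is descriptive only (one degree of freedom).
#'
#' @param gene_values numeric length-3 vector of signed stable-relative
#'   values at days 1, 3, 10.
#' @param dess_means numeric length-3 vector of DESS group means at days
#'   1, 3, 10.
#' @param log_signed if \code{TRUE}, correlate sign x log2(|fold|) instead
#'   of the raw signed folds; the correlation scale is a presentation
#'   choice, the pattern match is unaffected.
#' @return List with \code{pattern} (gene), \code{dess_pattern},
#'   \code{pattern_match} (logical, \code{NA} when either trajectory is
#'   unclassifiable), and \code{r} (Pearson correlation, \code{NA} with a
#'   warning when a vector has zero variance).
#' @export
dess_concordance <- function(gene_values, dess_means, log_signed = FALSE) {
  stopifnot(length(gene_values) == 3, length(dess_means) == 3)
  step_pattern <- function(v) {
    s <- sign(diff(v))
    if (any(s == 0)) return("unclassified")
    paste0(ifelse(s > 0, "up", "down"), collapse = "-")
  }
  gp <- step_pattern(gene_values)
  dp <- step_pattern(dess_means)
  match_ok <- if (gp == "unclassified" || dp == "unclassified") NA else gp == dp
  gv <- gene_values
  if (log_signed) gv <- sign(gv) * log2(abs(gv))
  if (stats::sd(gv) == 0 || stats::sd(dess_means) == 0) {
    warning("zero-variance trajectory; correlation undefined")
    r <- NA_real_
  } else {
    r <- stats::cor(gv, dess_means)
  }
  list(pattern = gp, dess_pattern = dp, pattern_match = match_ok, r = r)
}
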