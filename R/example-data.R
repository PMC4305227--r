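#' Bundled worked-example datasets
#'
#' Small plain-text tables shipped with the package, recording the
#' published summary of a PBMC microarray screen of COPD and its acute
#' exacerbation (five groups, six subjects per arm). They let the panel
#' selectors, trajectory classifier and DESS summaries be exercised and
#' checked against printed reference results without any raw-array input.
#'
#' \describe{
#'   \item{\code{example_copd_panel_folds()}}{per-sequence fold ratios over
#'     the four vs-control comparisons for the COPD-specific candidate
#'     rows (14 upregulated, 23 downregulated at fivefold).}
#'   \item{\code{example_aecopd_panel_folds()}}{fold ratios over the six
#'     exacerbation comparisons for the AECOPD-specific candidate rows
#'     (8 up at tenfold, 8 down at threefold).}
#'   \item{\code{example_trajectory_steps()}}{two-step fold pairs
#'     (day 3 vs day 1, day 10 vs day 3) for the highlighted dynamic
#'     genes, with their published pattern.}
#'   \item{\code{example_stable_relative()}}{signed stable-relative
#'     expression of the same genes at days 1, 3, 10 (negative = below the
#'     stable-COPD group).}
#'   \item{\code{example_dess_totals()}}{per-patient DESS totals for the
#'     five groups (patients x groups).}
#'   \item{\code{example_clinical()}}{clinical phenotypes (age, smoking,
#'     lung function, emphysema score) of the three arms.}
#' }
#'
#' @return A data frame; see the item descriptions.
#' @name example_data
NULL

read_example <- function(file) {
  path <- system.file("extdata", file, package = "pbmcopd", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname example_data
#' @export
example_copd_panel_folds <- function() read_example("example_copd_panel_folds.tsv")

#' @rdname example_data
#' @export
example_aecopd_panel_folds <- function() read_example("example_aecopd_panel_folds.tsv")

#' @rdname example_data
#' @export
example_trajectory_steps <- function() read_example("example_trajectory_steps.tsv")

#' @rdname example_data
#' @export
example_stable_relative <- function() read_example("example_stable_relative.tsv")

#' @rdname example_data
#' @export
example_dess_totals <- function() read_example("example_dess_totals.tsv")

#' @rdname example_data
#' @export
example_clinical <- function() read_example("example_clinical.tsv")

#' Convert a wide per-gene fold table to long fold-change records
#'
#' The panel and census operations consume long records (one row per gene
#' per comparison); reference tables are usually printed wide (one ratio
#' column per comparison with a single direction column). This reshapes
#' the latter into the former.
#'
#' @param wide data frame with an id column, a \code{direction} column and
#'   one numeric ratio column per comparison pair.
#' @param comparisons names of the ratio columns (comparison pair labels).
#' @param id name of the id column.
#' @return Long data frame with columns \code{gene_id}, \code{pair},
#'   \code{ratio}, \code{direction}.
#' @export
as_fold_records <- function(wide, comparisons, id = "seq_id") {
  stopifnot(id %in% names(wide), all(comparisons %in% names(wide)))
  do.call(rbind, lapply(comparisons, function(p) {
    data.frame(gene_id = wide[[id]], pair = p, ratio = wide[[p]],
               direction = wide$direction, stringsAsFactors = FALSE)
  }))
}
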