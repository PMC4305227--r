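#' Per-gene fold change for one comparison pair
#'
#' The fold change between two groups is computed on the log2 scale as
#' \eqn{2^{|m_A - m_B|}} where \eqn{m_A} and \eqn{m_B} are the group mean
#' log2 expressions, so the reported ratio is always >= 1 and carries a
#' direction: \code{up} when the numerator group is higher, \code{down}
#' when lower, and \code{flat} when the means are exactly equal.
#'
#' @param gene_matrix numeric matrix of log2 expression, genes x samples.
#' @param design a [study_design()].
#' @param pair a pair label from [comparison_pairs()] (e.g.
#'   \code{"AE1_vs_CON"}).
#' @return Data frame with columns \code{gene_id}, \code{pair},
#'   \code{ratio}, \code{direction}.
#' @export
fold_change <- function(gene_matrix, design, pair) {
  pairs <- comparison_pairs()
  idx <- match(pair, pairs$pair)
  if (is.na(idx)) {
    stop("unknown comparison pair '", pair, "'; see comparison_pairs()")
  }
  num_samples <- group_samples(design, pairs$numerator[idx])
  den_samples <- group_samples(design, pairs$denominator[idx])
  if (length(num_samples) == 0) stop("empty group: ", pairs$numerator[idx])
  if (length(den_samples) == 0) stop("empty group: ", pairs$denominator[idx])
  m_a <- rowMeans(gene_matrix[, num_samples, drop = FALSE])
  m_b <- rowMeans(gene_matrix[, den_samples, drop = FALSE])
  d <- m_a - m_b
  data.frame(gene_id = rownames(gene_matrix), pair = pair,
             ratio = 2^abs(d),
             direction = ifelse(d > 0, "up", ifelse(d < 0, "down", "flat")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fold changes for all ten comparison pairs
#'
#' @inheritParams fold_change
#' @param pairs character vector of pair labels; defaults to all ten.
#' @return Row-bound data frame of [fold_change()] results.
#' @export
fold_change_all <- function(gene_matrix, design, pairs = comparison_pairs()$pair) {
  do.call(rbind, lapply(pairs, function(p) fold_change(gene_matrix, design, p)))
}

#' Filter genes by fold-change threshold
#'
#' Selects the genes of one comparison whose change is in the requested
#' direction with ratio at or above the threshold. Thresholds are
#' inclusive (a gene at exactly 2.0 passes threshold 2). Flat genes
#' (ratio exactly 1) belong to neither direction.
#'
#' @param records fold-change data frame as returned by [fold_change()].
#' @param pair comparison pair label.
#' @param direction \code{"up"} or \code{"down"}.
#' @param threshold fold threshold, >= 1.
#' @return Character vector of gene ids.
#' @export
filter_genes <- function(records, pair, direction, threshold) {
  if (threshold < 1) stop("fold threshold must be >= 1, got ", threshold)
  direction <- match.arg(direction, c("up", "down"))
  keep <- records$pair == pair & records$direction == direction &
    records$ratio >= threshold
  records$gene_id[keep]
}

#' Census of differential genes across fold thresholds
#'
#' Counts, for every comparison pair present in \code{records}, the genes
#' changed in the given direction at or above each threshold — the summary
#' table conventionally printed for array screens (counts at >2, >5, >8,
#' ... fold). Counts are non-increasing along increasing thresholds.
#'
#' @inheritParams filter_genes
#' @param thresholds ascending numeric vector of fold thresholds.
#' @return Integer matrix, pairs x thresholds, with dimnames.
#' @export
threshold_census <- function(records, direction, thresholds = c(2, 5, 8, 10, 15, 20, 30, 50, 100)) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly ascending")
  }
  if (any(thresholds < 1)) stop("fold thresholds must be >= 1")
  pairs <- intersect(comparison_pairs()$pair, unique(records$pair))
  out <- matrix(0L, nrow = length(pairs), ncol = length(thresholds),
                dimnames = list(pairs, paste0(">=", thresholds)))
  for (p in pairs) {
    for (j in seq_along(thresholds)) {
      out[p, j] <- length(filter_genes(records, p, direction, thresholds[j]))
    }
  }
  out
}
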