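#' Quantile-normalize a probe intensity matrix
#'
#' Forces every sample column to share one empirical distribution: each
#' column's sorted values are replaced by the row-wise means of the sorted
#' columns, then put back in the column's original rank order. Tied values
#' within a column receive the mean of the reference quantiles they span.
#' The transformation is idempotent and equalises all column means.
#'
#' @param m numeric matrix, probes x samples, strictly positive linear
#'   intensities with probe ids as rownames.
#' @return Matrix of the same shape and dimnames, normalized.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("quantile normalization needs at least 2 samples")
  if (anyNA(m)) stop("matrix contains missing values; normalization rejects NA")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Log2-transform a positive intensity matrix
#'
#' @param m numeric matrix of strictly positive linear intensities.
#' @return The elementwise log2 of \code{m}.
#' @export
log2_transform <- function(m) {
  m <- as.matrix(m)
  bad <- which(!(m > 0), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-positive intensity at row ", bad[1, 1], ", column ", bad[1, 2],
         " (", nrow(bad), " offending cell(s) in total)")
  }
  log2(m)
}

#' Summarize probe-level log2 values to gene level by median polish
#'
#' For each gene, fits the additive model probe effect + sample effect +
#' residual to its log2 probes-by-samples block by median polish (rows
#' first, at most 10 iterations or convergence below 1e-6) and reports the
#' sample effects, re-centred so the gene's grand mean is preserved. The
#' median polish makes the summary robust to a discrepant probe, unlike a
#' plain column mean. Genes with a single probe pass through unchanged.
#'
#' @param m numeric matrix of normalized log2 intensities, probes x samples,
#'   with probe ids as rownames.
#' @param probe_to_gene data frame with columns \code{probe_id} and
#'   \code{gene_id} mapping every probe to exactly one gene. Probes of
#'   \code{m} absent from the map are dropped with a message.
#' @return Numeric matrix, genes x samples, log2 scale; gene ids as
#'   rownames, rows in first-appearance order of the map.
#' @export
summarize_probes <- function(m, probe_to_gene) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) stop("probe matrix must have probe ids as rownames")
  map <- probe_to_gene[, c("probe_id", "gene_id")]
  if (anyDuplicated(map$probe_id)) {
    stop("probe(s) mapped to more than one gene: ",
         paste(unique(map$probe_id[duplicated(map$probe_id)]), collapse = ", "))
  }
  unmapped <- setdiff(rownames(m), map$probe_id)
  if (length(unmapped) > 0) {
    message("summarize_probes: dropping ", length(unmapped),
            " probe(s) with no gene annotation")
    m <- m[setdiff(rownames(m), unmapped), , drop = FALSE]
  }
  gene_of <- map$gene_id[match(rownames(m), map$probe_id)]
  genes <- unique(map$gene_id[map$probe_id %in% rownames(m)])
  out <- matrix(NA_real_, nrow = length(genes), ncol = ncol(m),
                dimnames = list(genes, colnames(m)))
  for (g in genes) {
    block <- m[gene_of == g, , drop = FALSE]
    if (nrow(block) == 1) {
      out[g, ] <- block[1, ]
    } else {
      # the iteration cap is the convention; hitting it is expected on
      # noisy blocks and is not worth a per-gene warning
      fit <- withCallingHandlers(
        stats::medpolish(block, eps = 1e-6, maxiter = 10L,
                         trace.iter = FALSE),
        warning = function(w) {
          if (grepl("did not converge", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      eff <- fit$overall + fit$col
      # re-centre: medpolish leaves a median-zero column vector, the gene's
      # grand mean must survive summarization
      out[g, ] <- eff - mean(eff) + mean(block)
    }
  }
  out
}
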