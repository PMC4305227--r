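#' Co-differential panel specifications
#'
#' A panel spec names the comparison set over which a gene must change
#' consistently, together with the fold thresholds for the up and down
#' lists. Two panels are predefined:
#' \describe{
#'   \item{\code{copd_specific}}{the four "vs control" comparisons
#'     (\code{STABLE_vs_CON}, \code{AE1_vs_CON}, \code{AE3_vs_CON},
#'     \code{AE10_vs_CON}) — genes separating all COPD states from health.}
#'   \item{\code{aecopd_specific}}{the six comparisons of each exacerbation
#'     day against both control and stable disease — genes specific to the
#'     exacerbation itself.}
#' }
#'
#' @param name \code{"copd_specific"} or \code{"aecopd_specific"}.
#' @param up_threshold,down_threshold inclusive fold thresholds (>= 1) for
#'   the up and down lists. Defaults follow the published screen: fivefold
#'   both ways for the COPD panel, fivefold up / twofold down for the
#'   AECOPD panel.
#' @return List of class \code{panel_spec} with elements \code{name},
#'   \code{comparisons}, \code{up_threshold}, \code{down_threshold}.
#' @export
panel_spec <- function(name = c("copd_specific", "aecopd_specific"),
                       up_threshold = NULL, down_threshold = NULL) {
  name <- match.arg(name)
  comparisons <- switch(name,
    copd_specific = c("STABLE_vs_CON", "AE1_vs_CON", "AE3_vs_CON",
                      "AE10_vs_CON"),
    aecopd_specific = c("AE1_vs_CON", "AE1_vs_STABLE", "AE3_vs_CON",
                        "AE3_vs_STABLE", "AE10_vs_CON", "AE10_vs_STABLE"))
  if (is.null(up_threshold)) up_threshold <- 5
  if (is.null(down_threshold)) {
    down_threshold <- if (name == "aecopd_specific") 2 else 5
  }
  if (up_threshold < 1 || down_threshold < 1) {
    stop("panel thresholds must be >= 1")
  }
  structure(list(name = name, comparisons = comparisons,
                 up_threshold = up_threshold,
                 down_threshold = down_threshold),
            class = "panel_spec")
}

#' Minimum consistent fold across a comparison set
#'
#' The qualifying fold of a candidate panel gene is the minimum of its
#' ratios over the panel's comparisons, valid only when the direction is
#' the same in every comparison; any direction conflict (or a flat
#' comparison) disqualifies the gene.
#'
#' @param ratios numeric vector of fold ratios (>= 1), one per comparison.
#' @param directions character vector of \code{"up"}/\code{"down"}/\code{"flat"}.
#' @return List with \code{fold} (the minimum ratio, or \code{NA} if
#'   disqualified) and \code{direction} (\code{"up"}, \code{"down"} or
#'   \code{"disqualified"}).
#' @export
min_fold <- function(ratios, directions) {
  if (length(ratios) != length(directions)) {
    stop("ratios and directions must have equal length")
  }
  u <- unique(directions)
  if (length(u) != 1 || u == "flat") {
    return(list(fold = NA_real_, direction = "disqualified"))
  }
  list(fold = min(ratios), direction = u)
}

#' Select a co-differential gene panel
#'
#' Applies a [panel_spec()] to a long fold-change table: a gene enters the
#' up (down) list when its direction is \code{up} (\code{down}) in every
#' comparison of the set and its minimum fold across the set is at or
#' above the list's threshold. Lists are sorted by minimum fold descending
#' with gene id as tiebreak.
#'
#' Selection runs on whatever row identity the fold table carries (probe,
#' transcript or gene symbol); when a \code{symbols} map is supplied the
#' panel additionally reports symbol-deduplicated counts, since one symbol
#' may be represented by several array sequences.
#'
#' @param records long fold-change data frame (\code{gene_id}, \code{pair},
#'   \code{ratio}, \code{direction}) covering every comparison of the spec
#'   for every gene.
#' @param spec a [panel_spec()].
#' @param symbols optional named character vector mapping gene ids to gene
#'   symbols.
#' @return Object of class \code{gene_panel}: a list with data frames
#'   \code{up} and \code{down} (columns \code{gene_id}, \code{direction},
#'   \code{min_fold}, then one ratio column per comparison), the
#'   \code{spec}, and a \code{counts} summary (rows and, if available,
#'   distinct symbols per direction).
#' @export
select_panel <- function(records, spec, symbols = NULL) {
  stopifnot(inherits(spec, "panel_spec"))
  records <- records[records$pair %in% spec$comparisons, , drop = FALSE]
  genes <- unique(records$gene_id)
  wide_ratio <- wide_dir <- matrix(NA, nrow = length(genes),
                                   ncol = length(spec$comparisons),
                                   dimnames = list(genes, spec$comparisons))
  ri <- match(records$gene_id, genes)
  ci <- match(records$pair, spec$comparisons)
  wide_ratio[cbind(ri, ci)] <- records$ratio
  wide_dir[cbind(ri, ci)] <- records$direction
  missing <- which(rowSums(is.na(wide_ratio)) > 0)
  if (length(missing) > 0) {
    stop("gene(s) missing one or more panel comparisons: ",
         paste(utils::head(genes[missing], 5), collapse = ", "))
  }
  qual <- lapply(seq_along(genes), function(i) {
    min_fold(as.numeric(wide_ratio[i, ]), as.character(wide_dir[i, ]))
  })
  folds <- vapply(qual, `[[`, numeric(1), "fold")
  dirs <- vapply(qual, `[[`, character(1), "direction")

  build <- function(direction, threshold) {
    keep <- which(dirs == direction & folds >= threshold)
    keep <- keep[order(-folds[keep], genes[keep])]
    out <- data.frame(gene_id = genes[keep],
                      direction = rep(direction, length(keep)),
                      min_fold = folds[keep], stringsAsFactors = FALSE,
                      row.names = NULL)
    cbind(out, as.data.frame(wide_ratio[keep, , drop = FALSE],
                             row.names = seq_along(keep)))
  }
  up <- build("up", spec$up_threshold)
  down <- build("down", spec$down_threshold)

  counts <- data.frame(direction = c("up", "down"),
                       rows = c(nrow(up), nrow(down)))
  if (!is.null(symbols)) {
    counts$symbols <- c(length(unique(symbols[up$gene_id])),
                        length(unique(symbols[down$gene_id])))
  }
  structure(list(up = up, down = down, spec = spec, counts = counts),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("Co-differential gene panel: %s\n", x$spec$name))
  cat(sprintf("  comparisons: %s\n", paste(x$spec$comparisons, collapse = ", ")))
  cat(sprintf("  thresholds:  up >= %g, down >= %g (inclusive)\n",
              x$spec$up_threshold, x$spec$down_threshold))
  cat(sprintf("  up:   %d row(s)%s\n", nrow(x$up),
              if ("symbols" %in% names(x$counts))
                sprintf(" (%d distinct symbol(s))", x$counts$symbols[1]) else ""))
  cat(sprintf("  down: %d row(s)%s\n", nrow(x$down),
              if ("symbols" %in% names(x$counts))
                sprintf(" (%d distinct symbol(s))", x$counts$symbols[2]) else ""))
  invisible(x)
}
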