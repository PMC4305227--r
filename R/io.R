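#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of probe/gene
#' ids. Validation failures (ragged rows, duplicate ids, non-numeric
#' cells) are reported with the offending line number.
#'
#' @param path TSV file.
#' @return Numeric matrix with row and column names.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2) stop("expression file has no data rows: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  n_col <- length(header)
  samples <- header[-1]
  rows <- cells[-1]
  widths <- lengths(rows)
  if (any(widths != n_col)) {
    bad <- which(widths != n_col)[1] + 1L
    stop("ragged row at line ", bad, " of ", path, ": expected ", n_col,
         " fields, found ", widths[bad - 1L])
  }
  ids <- vapply(rows, `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    bad <- which(duplicated(ids))[1] + 1L
    stop("duplicate row id '", ids[bad - 1L], "' at line ", bad, " of ", path)
  }
  vals <- suppressWarnings(
    vapply(rows, function(r) as.numeric(r[-1]), numeric(n_col - 1L)))
  m <- t(matrix(vals, nrow = n_col - 1L))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("non-numeric value at line ", bad[1] + 1L, ", column ",
         bad[2] + 1L, " of ", path)
  }
  dimnames(m) <- list(ids, samples)
  m
}

#' @rdname read_expression_tsv
#' @param m numeric matrix with row and column names.
#' @return `write_expression_tsv()` writes \code{m} and returns the path
#'   invisibly; a write -> read round trip is the identity.
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet into a study design
#'
#' @param path TSV with columns \code{sample_id}, \code{subject_id},
#'   \code{group} and optionally \code{day}.
#' @return A [study_design()].
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "subject_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  }
  study_design(df$sample_id, df$subject_id, df$group,
               day = if ("day" %in% names(df)) df$day else NULL)
}

#' Read and write DESS component records
#'
#' Long tab-delimited format: \code{sample_id}, \code{component_id},
#' \code{category}, \code{level}.
#'
#' @param path TSV file.
#' @return Data frame of DESS components.
#' @export
read_dess_records <- function(path) {
  if (!file.exists(path)) stop("DESS record file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "component_id", "level")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("DESS file missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!("category" %in% names(df))) df$category <- "other"
  df
}

#' @rdname read_dess_records
#' @param records long DESS component data frame.
#' @export
write_dess_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write all files of a synthetic study
#'
#' Writes the standard pipeline inputs — probe matrix, sample sheet,
#' probe annotation, planted truth — as TSVs into a directory.
#'
#' @param study result of [generate_study()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_tsv(study$probes, file.path(dir, "probe_matrix.tsv"))
  write_tsv(as.data.frame(study$design), file.path(dir, "sample_sheet.tsv"))
  write_tsv(study$annotation, file.path(dir, "annotation.tsv"))
  write_tsv(study$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
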