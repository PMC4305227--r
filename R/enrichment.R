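#' Read gene sets from a GMT file
#'
#' @param path GMT file (tab-delimited: set id, description, member ids).
#' @param domain domain tag attached to every set (\code{biological_process},
#'   \code{cellular_component}, \code{molecular_function}, \code{pathway}
#'   or \code{other}); multiple-testing correction is performed within a
#'   domain.
#' @return Named list of class \code{gene_sets}: one character vector of
#'   unique member ids per set, with a \code{domain} attribute.
#' @export
read_gmt <- function(path, domain = "other") {
  if (!file.exists(path)) stop("gene-set file not found: ", path)
  sets <- fgsea::gmtPathways(path)
  sets <- lapply(sets, unique)
  structure(sets, domain = rep(domain, length.out = length(sets)),
            class = "gene_sets")
}

# upper-tail hypergeometric probability: P(overlap >= k) for a query of
# size n drawn from a universe of N containing K set members
hyper_upper_tail <- function(k, n, K, N) {
  hi <- min(n, K)
  if (k > hi) return(0)
  sum(stats::dhyper(k:hi, K, N - K, n))
}

#' One-sided over-representation test for a single gene set
#'
#' Tests whether the query list overlaps the set more than expected by
#' chance, via the hypergeometric upper tail (the one-sided Fisher exact
#' test): with universe size N, set size K (after intersecting the set
#' with the universe), query size n and overlap k,
#' \deqn{p = \sum_{i=k}^{\min(n,K)} \frac{{K \choose i}{N-K \choose n-i}}{{N \choose n}}.}
#'
#' @param query character vector of query gene ids (must be a subset of the
#'   universe).
#' @param set character vector of set member ids (intersected with the
#'   universe before testing).
#' @param universe character vector of all testable gene ids, e.g. every
#'   gene on the normalized matrix.
#' @return One-row data frame: \code{k}, \code{n}, \code{K}, \code{N},
#'   \code{p}, \code{enrichment_score} (-log10 p).
#' @export
fisher_overrepresentation <- function(query, set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  query <- unique(query)
  offenders <- setdiff(query, universe)
  if (length(offenders) > 0) {
    stop("query gene(s) not in universe: ",
         paste(utils::head(offenders, 10), collapse = ", "))
  }
  set <- intersect(unique(set), universe)
  k <- length(intersect(query, set))
  p <- hyper_upper_tail(k, length(query), length(set), length(universe))
  data.frame(k = k, n = length(query), K = length(set),
             N = length(universe), p = p,
             enrichment_score = -log10(p))
}

#' Over-representation across a gene-set collection
#'
#' Runs [fisher_overrepresentation()] for every set with at least one
#' member in the universe, adjusts p-values by Benjamini-Hochberg within
#' each domain, and sorts ascending by p (set id as tiebreak).
#'
#' @inheritParams fisher_overrepresentation
#' @param sets a [read_gmt()] collection, or a plain named list of member
#'   vectors (domain \code{"other"}).
#' @return Data frame with columns \code{set_id}, \code{domain}, \code{k},
#'   \code{n}, \code{K}, \code{N}, \code{p}, \code{q},
#'   \code{enrichment_score}.
#' @export
enrich_all <- function(query, sets, universe) {
  domain <- attr(sets, "domain")
  if (is.null(domain)) domain <- rep("other", length(sets))
  keep <- vapply(sets, function(s) length(intersect(s, universe)) > 0,
                 logical(1))
  sets <- sets[keep]
  domain <- domain[keep]
  if (length(sets) == 0) {
    return(data.frame(set_id = character(), domain = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p = numeric(), q = numeric(),
                      enrichment_score = numeric()))
  }
  res <- do.call(rbind, lapply(seq_along(sets), function(i) {
    cbind(data.frame(set_id = names(sets)[i], domain = domain[i],
                     stringsAsFactors = FALSE),
          fisher_overrepresentation(query, sets[[i]], universe))
  }))
  res$q <- NA_real_
  for (d in unique(res$domain)) {
    sel <- res$domain == d
    res$q[sel] <- stats::p.adjust(res$p[sel], method = "BH")
  }
  res <- res[order(res$p, res$set_id), ]
  rownames(res) <- NULL
  res[, c("set_id", "domain", "k", "n", "K", "N", "p", "q",
          "enrichment_score")]
}
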