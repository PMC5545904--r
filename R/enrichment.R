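## Over-representation analysis ------------------------------------------

#' Read a GMT gene-set collection
#'
#' Thin wrapper over `fgsea::gmtPathways()` with validation: set names
#' must be unique and sets non-empty.
#'
#' @param path a GMT file (tab-separated: name, description, genes...).
#' @return named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE))
    stop("reading GMT files requires the fgsea package")
  sets <- fgsea::gmtPathways(path)
  validate_gene_sets(sets)
  sets
}

validate_gene_sets <- function(sets) {
  if (anyDuplicated(names(sets)))
    stop("gene-set names are not unique")
  empty <- lengths(sets) == 0L
  if (any(empty))
    stop("empty gene set(s): ", paste(names(sets)[empty], collapse = ", "))
  invisible(TRUE)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query list overlaps the set more
#' than expected by chance under sampling without replacement from the
#' universe: p = P(X >= k) with X hypergeometric(K, N - K, n), then
#' Benjamini-Hochberg adjustment across sets. Query genes outside the
#' universe are dropped with a warning.
#'
#' @param query_genes character vector of gene symbols.
#' @param collection named list of gene sets (see [read_gmt()]).
#' @param universe background gene symbols; defaults to the union of the
#'   collection's genes and the query.
#' @return data.frame sorted by p then set name: `set`, `overlap_k`,
#'   `set_size_K`, `query_n`, `universe_N`, `p`, `q`, plus the
#'   overlapping symbols in `overlap_genes` (comma-separated).
#' @export
ora <- function(query_genes, collection, universe = NULL) {
  validate_gene_sets(collection)
  if (is.null(universe))
    universe <- unique(c(unlist(collection, use.names = FALSE),
                         query_genes))
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(query_genes)
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    warning("dropping ", length(outside),
            " query gene(s) outside the universe", call. = FALSE)
    query <- intersect(query, universe)
  }
  n <- length(query)
  N <- length(universe)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(unique(collection[[nm]]), universe)
    K <- length(set)
    hits <- intersect(query, set)
    k <- length(hits)
    # upper tail P(X >= k)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap_k = k, set_size_K = K, query_n = n,
               universe_N = N, p = p,
               overlap_genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set), c("set", "overlap_k", "set_size_K",
                                      "query_n", "universe_N", "p", "q",
                                      "overlap_genes")]
  rownames(out) <- NULL
  out
}

#' Shared and species-unique significant gene sets
#'
#' Partitions the gene sets significant (q <= threshold) in either
#' species' ORA result into shared / unique-to-human / unique-to-mouse.
#'
#' @param result_human,result_mouse [ora()] results over the same
#'   collection.
#' @param q_threshold FDR threshold (default 0.05).
#' @return list of character vectors `shared`, `unique_to_human`,
#'   `unique_to_mouse`.
#' @export
shared_unique_sets <- function(result_human, result_mouse,
                               q_threshold = 0.05) {
  if (!setequal(result_human$set, result_mouse$set))
    stop("the two results come from different gene-set collections")
  sig_h <- result_human$set[result_human$q <= q_threshold]
  sig_m <- result_mouse$set[result_mouse$q <= q_threshold]
  list(shared = sort(intersect(sig_h, sig_m)),
       unique_to_human = sort(setdiff(sig_h, sig_m)),
       unique_to_mouse = sort(setdiff(sig_m, sig_h)))
}
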