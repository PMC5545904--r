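## Human <-> mouse symbol orthology --------------------------------------

#' Construct an orthology map
#'
#' Holds curated human--mouse gene symbol pairs plus a lookup policy.
#' Under `"table_then_casefold"` (the default), symbols absent from the
#' table fall back to the standard case conventions: human HGNC symbols
#' are all upper-case, mouse MGI symbols are capitalised (`NFKB1` <->
#' `Nfkb1`). Under `"table_only"` absent symbols simply do not map.
#' One-to-many pairs are allowed; all counterparts are returned as
#' candidates.
#'
#' @param pairs data.frame with columns `human_symbol`, `mouse_symbol`
#'   (may be empty).
#' @param policy `"table_then_casefold"` or `"table_only"`.
#' @return an object of class `orthology_map`.
#' @examples
#' om <- orthology_map(data.frame(human_symbol = "PTGS2",
#'                                mouse_symbol = "Ptgs2"))
#' map_symbol("PTGS2", om, to = "mouse")
#' map_symbol("TNF", om, to = "mouse")  # casefold fallback
#' @export
orthology_map <- function(pairs = NULL,
                          policy = c("table_then_casefold", "table_only")) {
  policy <- match.arg(policy)
  if (is.null(pairs))
    pairs <- data.frame(human_symbol = character(0),
                        mouse_symbol = character(0),
                        stringsAsFactors = FALSE)
  missing <- setdiff(c("human_symbol", "mouse_symbol"), names(pairs))
  if (length(missing) > 0L)
    stop("orthology table is missing column(s): ",
         paste(missing, collapse = ", "))
  pairs <- pairs[, c("human_symbol", "mouse_symbol")]
  if (nrow(pairs) > 0L) {
    empty <- is.na(pairs$human_symbol) | !nzchar(pairs$human_symbol) |
      is.na(pairs$mouse_symbol) | !nzchar(pairs$mouse_symbol)
    if (any(empty))
      stop("orthology table has empty cells in rows: ",
           paste(which(empty), collapse = ", "))
    pairs <- pairs[!duplicated(pairs), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  structure(list(pairs = pairs, policy = policy), class = "orthology_map")
}

#' Load an orthology map from a two-column TSV
#'
#' @param path TSV with columns `human_symbol`, `mouse_symbol`.
#' @inheritParams orthology_map
#' @return an `orthology_map`.
#' @export
load_orthology_table <- function(path,
                                 policy = c("table_then_casefold",
                                            "table_only")) {
  tab <- utils::read.delim(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  orthology_map(tab, policy = match.arg(policy))
}

casefold_symbol <- function(symbol, to) {
  if (to == "human") toupper(symbol)
  else paste0(toupper(substr(symbol, 1L, 1L)),
              tolower(substr(symbol, 2L, nchar(symbol))))
}

#' Map a gene symbol to the other species
#'
#' Returns all counterpart symbols (one-to-many orthology yields several;
#' zero-length means no mapping exists under `table_only`).
#'
#' @param symbol a single gene symbol.
#' @param map an [orthology_map()].
#' @param to target species, `"human"` or `"mouse"`.
#' @return character vector of candidate counterpart symbols.
#' @export
map_symbol <- function(symbol, map, to = c("human", "mouse")) {
  to <- match.arg(to)
  stopifnot(inherits(map, "orthology_map"))
  from_col <- if (to == "human") "mouse_symbol" else "human_symbol"
  to_col <- if (to == "human") "human_symbol" else "mouse_symbol"
  hits <- unique(map$pairs[[to_col]][map$pairs[[from_col]] == symbol])
  if (length(hits) > 0L) return(hits)
  if (map$policy == "table_then_casefold") return(casefold_symbol(symbol, to))
  character(0)
}

#' Map an entity to the other species' identifier space
#'
#' HGNC/MGI identifiers are translated through the orthology table (with
#' the case-convention fallback under the default policy) and the
#' namespace is switched accordingly; species-neutral namespaces (CHEBI,
#' GOBP, MESH, OTHER) map to themselves. Function class and modification
#' tags are never changed. Absence of a mapping is a value (`NULL`), not
#' an error.
#'
#' @param ent one-row entity data.frame (see [entity()]).
#' @param map an [orthology_map()].
#' @param target_species `"human"` or `"mouse"`.
#' @return a data.frame of candidate entities (zero rows when unmapped).
#' @export
map_entity <- function(ent, map, target_species = c("human", "mouse")) {
  target_species <- match.arg(target_species)
  if (!ent$ns %in% c("HGNC", "MGI")) return(ent)
  if (identical(unname(namespace_species(ent$ns)), target_species))
    return(ent)
  syms <- map_symbol(ent$id, map, to = target_species)
  if (length(syms) == 0L)
    return(ent[0, , drop = FALSE])
  out <- ent[rep(1L, length(syms)), , drop = FALSE]
  out$id <- syms
  out$ns <- if (target_species == "human") "HGNC" else "MGI"
  rownames(out) <- NULL
  out
}

#' @export
print.orthology_map <- function(x, ...) {
  cat(sprintf("orthology map: %d curated pair(s), policy %s\n",
              nrow(x$pairs), x$policy))
  invisible(x)
}
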