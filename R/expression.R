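## Cross-species differential-expression concordance ---------------------

#' The six cross-species expression concordance categories
#' @export
CONCORDANCE_CATEGORIES <- c("same_pattern", "human_only", "mouse_only",
                            "inconsistent_within_species",
                            "contradictory_between_species",
                            "non_significant")

#' Load a GEO2R-style differential-expression call table
#'
#' Expects tab-separated columns `Gene.symbol`, `logFC`, `P.Value` and
#' optionally `adj.P.Val` (the GEO2R export layout). Rows with an empty
#' gene symbol are dropped with a warning. Symbols are normalised to the
#' species' case convention (upper-case for human, capitalised for
#' mouse). Unicode minus signs in `logFC` are handled.
#'
#' @param path TSV path or a data.frame in that layout.
#' @param species `"human"` or `"mouse"`.
#' @param accession dataset accession carried into each call (metadata).
#' @return data.frame of calls: `gene_symbol`, `species`,
#'   `dataset_accession`, `log_fold_change`, `p_value`, `adjusted_p`.
#' @export
load_de_table <- function(path, species = c("human", "mouse"),
                          accession = NA_character_) {
  species <- match.arg(species)
  tab <- if (is.data.frame(path)) path
         else utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                                check.names = TRUE,
                                na.strings = c("NA", ""))
  missing <- setdiff(c("Gene.symbol", "logFC", "P.Value"), names(tab))
  if (length(missing) > 0L)
    stop("DE table is missing column(s): ", paste(missing, collapse = ", "))
  empty <- is.na(tab$Gene.symbol) | !nzchar(trimws(tab$Gene.symbol))
  if (any(empty)) {
    warning("dropping ", sum(empty), " row(s) with empty gene symbol",
            call. = FALSE)
    tab <- tab[!empty, , drop = FALSE]
  }
  num <- function(x) {
    if (is.numeric(x)) return(as.numeric(x))
    as.numeric(gsub("−", "-", x))  # unicode minus
  }
  lfc <- num(tab$logFC)
  p <- num(tab$P.Value)
  adj <- if ("adj.P.Val" %in% names(tab)) num(tab$adj.P.Val)
         else rep(NA_real_, nrow(tab))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values outside [0, 1]")
  data.frame(gene_symbol = casefold_symbol(trimws(tab$Gene.symbol),
                                           to = species),
             species = species,
             dataset_accession = accession,
             log_fold_change = lfc,
             p_value = p,
             adjusted_p = adj,
             stringsAsFactors = FALSE)
}

#' Direction of one expression call at a significance threshold
#'
#' `"ns"` when the chosen p-value exceeds `alpha`; otherwise `"up"` or
#' `"down"` by the sign of the log fold change. A significant call with a
#' log fold change of exactly zero is `"ns"` with a zero-effect warning.
#'
#' @param calls call data.frame (see [load_de_table()]).
#' @param alpha significance threshold in (0, 1); the conventional 0.05
#'   on the unadjusted p-value is the default.
#' @param use_adjusted use `adjusted_p` instead of `p_value`.
#' @return character vector: `"up"`, `"down"` or `"ns"` per call.
#' @export
call_direction <- function(calls, alpha = 0.05, use_adjusted = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  p <- if (use_adjusted) calls$adjusted_p else calls$p_value
  dir <- ifelse(p > alpha | is.na(p), "ns",
                ifelse(calls$log_fold_change > 0, "up",
                       ifelse(calls$log_fold_change < 0, "down", "ns")))
  zero <- !is.na(p) & p <= alpha & calls$log_fold_change == 0
  if (any(zero))
    warning(sum(zero), " significant call(s) with zero effect size ",
            "treated as ns", call. = FALSE)
  dir
}

# best (smallest-p) call per gene per dataset: the probe-collapse rule
collapse_probes <- function(calls, use_adjusted = FALSE) {
  if (nrow(calls) == 0L) return(calls)
  p <- if (use_adjusted) calls$adjusted_p else calls$p_value
  ord <- order(calls$gene_symbol, calls$dataset_accession, p)
  calls <- calls[ord, , drop = FALSE]
  keep <- !duplicated(calls[, c("gene_symbol", "dataset_accession")])
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify one gene's cross-species expression concordance
#'
#' Precedence order: (1) `inconsistent_within_species` when any single
#' species shows both up- and down-regulated significant calls; (2)
#' `non_significant` when no call in either species is significant; (3)
#' `human_only` / `mouse_only` when exactly one species has significant
#' calls; (4) `same_pattern` when both species' significant directions
#' agree; (5) `contradictory_between_species` when they disagree.
#' Multiple agreeing significant calls within a species collapse to that
#' direction. A gene with no calls at all is `"uncovered"` and excluded
#' from summary denominators.
#'
#' @param human_calls,mouse_calls call rows for this gene (the mouse
#'   symbol being the orthologue of the human one).
#' @param alpha,use_adjusted see [call_direction()].
#' @return a list: `category`, `human_direction`, `mouse_direction`
#'   (`"up"`, `"down"`, `"ns"`, or `"none"` for no calls).
#' @export
classify_gene_concordance <- function(human_calls, mouse_calls,
                                      alpha = 0.05, use_adjusted = FALSE) {
  species_state <- function(calls) {
    if (is.null(calls) || nrow(calls) == 0L) return("none")
    d <- call_direction(calls, alpha, use_adjusted)
    has_up <- any(d == "up"); has_down <- any(d == "down")
    if (has_up && has_down) return("conflict")
    if (has_up) return("up")
    if (has_down) return("down")
    "ns"
  }
  h <- species_state(human_calls)
  m <- species_state(mouse_calls)
  if (h == "none" && m == "none")
    return(list(category = "uncovered", human_direction = "none",
                mouse_direction = "none"))
  category <- if (h == "conflict" || m == "conflict")
    "inconsistent_within_species"
  else {
    h_sig <- h %in% c("up", "down")
    m_sig <- m %in% c("up", "down")
    if (!h_sig && !m_sig) "non_significant"
    else if (h_sig && !m_sig) "human_only"
    else if (!h_sig && m_sig) "mouse_only"
    else if (h == m) "same_pattern"
    else "contradictory_between_species"
  }
  list(category = category, human_direction = h, mouse_direction = m)
}

#' Classify every gene in paired human/mouse call tables
#'
#' Genes are paired across species through the orthology map (case
#' convention by default); probes are collapsed to the best (smallest-p)
#' call per gene per dataset before classification.
#'
#' @param human_calls,mouse_calls call data.frames, possibly spanning
#'   several datasets (see [load_de_table()]).
#' @param map an [orthology_map()].
#' @param alpha,use_adjusted see [call_direction()].
#' @return data.frame with one row per (human-space) gene:
#'   `gene_symbol`, `category`, `human_direction`, `mouse_direction`.
#' @export
concordance_table <- function(human_calls, mouse_calls,
                              map = orthology_map(), alpha = 0.05,
                              use_adjusted = FALSE) {
  human_calls <- collapse_probes(human_calls, use_adjusted)
  mouse_calls <- collapse_probes(mouse_calls, use_adjusted)
  # index mouse genes by their human-space counterpart(s)
  mouse_by_human <- list()
  for (msym in unique(mouse_calls$gene_symbol)) {
    for (h in map_symbol(msym, map, to = "human")) {
      mouse_by_human[[h]] <- c(mouse_by_human[[h]], msym)
    }
  }
  genes <- sort(unique(c(human_calls$gene_symbol,
                         names(mouse_by_human))))
  if (length(genes) == 0L)
    return(data.frame(gene_symbol = character(0), category = character(0),
                      human_direction = character(0),
                      mouse_direction = character(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(genes, function(g) {
    hc <- human_calls[human_calls$gene_symbol == g, , drop = FALSE]
    msyms <- mouse_by_human[[g]]
    mc <- mouse_calls[mouse_calls$gene_symbol %in% msyms, , drop = FALSE]
    cl <- classify_gene_concordance(hc, mc, alpha, use_adjusted)
    data.frame(gene_symbol = g, category = cl$category,
               human_direction = cl$human_direction,
               mouse_direction = cl$mouse_direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise gene concordance categories
#'
#' @param classifications data.frame from [concordance_table()] (or any
#'   with a `category` column). `"uncovered"` genes are excluded from the
#'   denominator and reported separately.
#' @return list: `table` (per-category count + integer percent,
#'   half-away rounding; percentages sum to 100 +/- rounding),
#'   `denominator`, `uncovered` (gene symbols). Empty input yields an
#'   empty summary with zero denominator.
#' @export
summarize_concordance <- function(classifications) {
  covered <- classifications[classifications$category != "uncovered", ,
                             drop = FALSE]
  n <- nrow(covered)
  counts <- table(factor(covered$category,
                         levels = CONCORDANCE_CATEGORIES))
  tab <- data.frame(category = CONCORDANCE_CATEGORIES,
                    count = as.integer(counts),
                    percent = if (n > 0)
                      round_half_away(100 * as.integer(counts) / n)
                    else NA_real_,
                    stringsAsFactors = FALSE)
  list(table = tab, denominator = n,
       uncovered =
         classifications$gene_symbol[classifications$category ==
                                       "uncovered"])
}
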