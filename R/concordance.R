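## Cross-species edge concordance ----------------------------------------

#' Round half away from zero
#'
#' Integer percentage rounding used throughout the summaries (2.5 -> 3),
#' as opposed to R's banker's rounding.
#'
#' @param x numeric vector.
#' @return numeric vector of integers.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Stratify an edge by interaction level
#'
#' `"molecular"` when both endpoints are proteins, genes, chemicals or
#' complexes; `"cellular"` when either endpoint is a bioprocess or a cell
#' population (microglia, astrocytes, macrophage subsets, ...).
#'
#' @param edges edge data.frame (one or more rows, model layout).
#' @return character vector, `"molecular"` or `"cellular"` per row.
#' @export
stratify_level <- function(edges) {
  mol <- edges$subject_function %in% .molecular_functions &
    edges$object_function %in% .molecular_functions
  ifelse(mol, "molecular", "cellular")
}

# matching key for one endpoint in its own species' space
endpoint_key <- function(fun, ns, id, mod, strict) {
  fam <- ifelse(fun %in% c("protein", "gene"), "genic", fun)
  base <- ifelse(ns %in% c("HGNC", "MGI"), id, paste0(ns, ":", id))
  key <- paste0(fam, "|", base)
  if (strict) {
    mod <- ifelse(is.na(mod) | mod == "", "", paste0("|", mod))
    key <- paste0(key, mod)
  }
  key
}

# candidate keys for one endpoint translated into the target species'
# space; character(0) signals an orthology gap under table_only
mapped_endpoint_keys <- function(fun, ns, id, mod, map, to_species,
                                 strict) {
  if (ns %in% c("HGNC", "MGI") &&
      !identical(unname(namespace_species(ns)), to_species)) {
    ids <- map_symbol(id, map, to = to_species)
    if (length(ids) == 0L) return(character(0))
  } else {
    ids <- if (ns %in% c("HGNC", "MGI")) id else paste0(ns, ":", id)
  }
  fam <- if (fun %in% c("protein", "gene")) "genic" else fun
  key <- paste0(fam, "|", ids)
  if (strict)
    key <- paste0(key, if (!is.na(mod) && nzchar(mod)) paste0("|", mod)
                       else "")
  key
}

# indices of target-model edges matching one source edge (endpoints
# translated, same direction; association edges also match reversed)
match_candidates <- function(edge, target_edges, map, to_species, strict) {
  s_keys <- mapped_endpoint_keys(edge$subject_function, edge$subject_ns,
                                 edge$subject_id, edge$subject_mod,
                                 map, to_species, strict)
  o_keys <- mapped_endpoint_keys(edge$object_function, edge$object_ns,
                                 edge$object_id, edge$object_mod,
                                 map, to_species, strict)
  if (length(s_keys) == 0L || length(o_keys) == 0L)
    return(list(idx = integer(0), no_orthology = TRUE))
  ts <- endpoint_key(target_edges$subject_function, target_edges$subject_ns,
                     target_edges$subject_id, target_edges$subject_mod,
                     strict)
  to <- endpoint_key(target_edges$object_function, target_edges$object_ns,
                     target_edges$object_id, target_edges$object_mod,
                     strict)
  fwd <- ts %in% s_keys & to %in% o_keys
  # symmetric matches: a target association edge stored in the other
  # orientation, or any orientation when the source edge is symmetric
  rev <- ts %in% o_keys & to %in% s_keys
  sym <- if (relation_polarity(edge$relation) == 0L &&
             edge$relation == "association") rev
         else rev & target_edges$relation == "association"
  list(idx = which(fwd | sym), no_orthology = FALSE)
}

#' Classify one human edge against the mouse model
#'
#' Endpoints are translated through the orthology map; candidate mouse
#' edges are those with matching endpoints in the same direction
#' (association edges match either orientation). If any candidate has the
#' same nonzero polarity the edge is `consistent` (flagged
#' `mixed_evidence` when an opposite-sign candidate also exists); if
#' candidates only carry the opposite nonzero polarity it is
#' `contradictory`; if only zero-polarity (correlative) candidates exist
#' it is `consistent` with `nonpolar_match = TRUE` (or
#' `unique_to_human` when `nonpolar_as_consistent = FALSE`); otherwise it
#' is `unique_to_human`. An endpoint with no orthologue under a
#' `table_only` policy yields `unique_to_human` with a `"no-orthology"`
#' note, never an error. With `strict = TRUE` modification/activity
#' decorations must also match.
#'
#' @param human_edge one-row edge data.frame from the human model.
#' @param mouse_model the mouse [cause_effect_model()].
#' @param map an [orthology_map()].
#' @param strict require matching pmod/act decorations (default FALSE).
#' @param nonpolar_as_consistent count correlative-only support as
#'   consistent (default TRUE).
#' @return one-row data.frame: `category`, `level`, `nonpolar_match`,
#'   `mixed_evidence`, `note`, `n_candidates`, `mouse_match` (canonical
#'   triple of the first matching mouse edge or `NA`).
#' @export
classify_edge <- function(human_edge, mouse_model, map, strict = FALSE,
                          nonpolar_as_consistent = TRUE) {
  res <- classify_against(human_edge, mouse_model$edges, map,
                          to_species = mouse_model$species,
                          strict = strict,
                          nonpolar_as_consistent = nonpolar_as_consistent)
  res$category[res$category == "unique"] <- "unique_to_human"
  res
}

classify_against <- function(edge, target_edges, map, to_species, strict,
                             nonpolar_as_consistent) {
  cand <- match_candidates(edge, target_edges, map, to_species, strict)
  pol <- relation_polarity(edge$relation)
  cpol <- if (length(cand$idx))
    relation_polarity(target_edges$relation[cand$idx]) else integer(0)
  nonpolar <- FALSE
  mixed <- FALSE
  note <- NA_character_
  match_triple <- NA_character_
  if (cand$no_orthology) {
    category <- "unique"
    note <- "no-orthology"
  } else if (length(cand$idx) == 0L) {
    category <- "unique"
  } else if (pol != 0L) {
    if (any(cpol == pol)) {
      category <- "consistent"
      mixed <- any(cpol == -pol)
      match_triple <- edge_triples(
        target_edges[cand$idx[cpol == pol][1L], , drop = FALSE])
    } else if (any(cpol == -pol)) {
      category <- "contradictory"
      match_triple <- edge_triples(
        target_edges[cand$idx[cpol == -pol][1L], , drop = FALSE])
    } else {
      nonpolar <- TRUE
      category <- if (nonpolar_as_consistent) "consistent" else "unique"
      match_triple <- edge_triples(
        target_edges[cand$idx[1L], , drop = FALSE])
    }
  } else {
    category <- "consistent"
    nonpolar <- !any(cpol == 0L)
    match_triple <- edge_triples(target_edges[cand$idx[1L], , drop = FALSE])
  }
  data.frame(category = category,
             level = stratify_level(edge),
             nonpolar_match = nonpolar,
             mixed_evidence = mixed,
             note = note,
             n_candidates = length(cand$idx),
             mouse_match = match_triple,
             stringsAsFactors = FALSE)
}

#' Compare two species' models edge by edge
#'
#' Classifies every (in-scope) human edge against the mouse model into
#' consistent / contradictory / unique-to-human, stratified into
#' molecular and cellular levels, and reports mouse edges with no human
#' counterpart separately as unique-to-mouse. Percentages are integers,
#' rounded half away from zero within each level's denominator.
#'
#' @param human,mouse [cause_effect_model()] objects of the two species.
#' @param map an [orthology_map()].
#' @param scope optional subset of human edges to classify: integer row
#'   indices into `human$edges`, or an edge data.frame whose canonical
#'   triples select them. Defaults to all distinct human edges.
#' @inheritParams classify_edge
#' @return a list with `records` (one row per classified human edge,
#'   including the source columns), `mouse_only` (distinct mouse edges
#'   absent from the human model), and `summary` (per level x category
#'   counts, denominators and percentages).
#' @export
compare_models <- function(human, mouse, map = orthology_map(),
                           scope = NULL, strict = FALSE,
                           nonpolar_as_consistent = TRUE) {
  stopifnot(inherits(human, "cause_effect_model"),
            inherits(mouse, "cause_effect_model"))
  h_edges <- human$edges[!duplicated(edge_triples(human$edges)), ,
                         drop = FALSE]
  if (!is.null(scope)) {
    if (is.data.frame(scope)) {
      keep <- edge_triples(h_edges) %in% edge_triples(scope)
      h_edges <- h_edges[keep, , drop = FALSE]
    } else {
      h_edges <- human$edges[scope, , drop = FALSE]
      h_edges <- h_edges[!duplicated(edge_triples(h_edges)), ,
                         drop = FALSE]
    }
  }
  records <- empty_records()
  if (nrow(h_edges) > 0L) {
    rec_list <- lapply(seq_len(nrow(h_edges)), function(i) {
      classify_against(h_edges[i, , drop = FALSE], mouse$edges, map,
                       to_species = mouse$species, strict = strict,
                       nonpolar_as_consistent = nonpolar_as_consistent)
    })
    records <- cbind(h_edges, do.call(rbind, rec_list))
    records$category[records$category == "unique"] <- "unique_to_human"
    records$human_triple <- edge_triples(h_edges)
    rownames(records) <- NULL
  }
  # mouse edges with no counterpart among ALL human edges
  m_edges <- mouse$edges[!duplicated(edge_triples(mouse$edges)), ,
                         drop = FALSE]
  mouse_only <- m_edges[0, , drop = FALSE]
  if (nrow(m_edges) > 0L) {
    rev_cat <- vapply(seq_len(nrow(m_edges)), function(i) {
      classify_against(m_edges[i, , drop = FALSE], human$edges, map,
                       to_species = human$species, strict = strict,
                       nonpolar_as_consistent = TRUE)$category
    }, character(1))
    mouse_only <- m_edges[rev_cat == "unique", , drop = FALSE]
    rownames(mouse_only) <- NULL
  }
  if (nrow(mouse_only) > 0L) {
    mouse_only$level <- stratify_level(mouse_only)
    mouse_only$category <- "unique_to_mouse"
  }
  list(records = records,
       mouse_only = mouse_only,
       summary = concordance_summary(records))
}

empty_records <- function() {
  data.frame(category = character(0), level = character(0),
             nonpolar_match = logical(0), mixed_evidence = logical(0),
             note = character(0), n_candidates = integer(0),
             mouse_match = character(0), human_triple = character(0),
             stringsAsFactors = FALSE)
}

#' Summarise concordance records into per-level percentages
#'
#' @param records the `records` component of [compare_models()].
#' @return data.frame with one row per level (plus `"all"`) and category:
#'   `count`, `denominator`, `percent` (integer, half-away rounding).
#'   Empty scope gives zero denominators and no division.
#' @export
concordance_summary <- function(records) {
  cats <- c("consistent", "contradictory", "unique_to_human")
  levels_ <- c("molecular", "cellular", "all")
  out <- expand.grid(level = levels_, category = cats,
                     stringsAsFactors = FALSE)
  out <- out[order(match(out$level, levels_), match(out$category, cats)), ]
  n <- nrow(records)
  out$count <- mapply(function(lv, ct) {
    in_lv <- if (lv == "all") rep(TRUE, n) else records$level == lv
    sum(in_lv & records$category == ct)
  }, out$level, out$category)
  out$denominator <- vapply(out$level, function(lv) {
    if (lv == "all") n else sum(records$level == lv)
  }, numeric(1))
  out$percent <- ifelse(out$denominator > 0,
                        round_half_away(100 * out$count / out$denominator),
                        NA_real_)
  rownames(out) <- NULL
  out
}
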