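## The cause-and-effect model container ----------------------------------

.edge_cols <- c("subject_function", "subject_ns", "subject_id", "subject_mod",
                "relation",
                "object_function", "object_ns", "object_id", "object_mod",
                "species", "citation", "evidence", "statement_index")

empty_edges <- function() {
  df <- as.data.frame(stats::setNames(
    replicate(length(.edge_cols), character(0), simplify = FALSE),
    .edge_cols), stringsAsFactors = FALSE)
  df$statement_index <- integer(0)
  df
}

#' Construct a species-scoped cause-and-effect model
#'
#' A model is one species' causal graph: a set of entities, a multiset of
#' causal edges (duplicate statements are kept as separate records and
#' raise the statement count, but edge identity is the canonical
#' subject--relation--object triple), and provenance counts.
#'
#' @param edges data.frame of edge records with columns
#'   `subject_function`, `subject_ns`, `subject_id`, `subject_mod`,
#'   `relation`, `object_function`, `object_ns`, `object_id`,
#'   `object_mod`, plus optional `citation`, `evidence`.
#' @param species `"human"` or `"mouse"`.
#' @param statement_count number of source statements backing the edges
#'   (defaults to `nrow(edges)`).
#' @return an object of class `cause_effect_model` with components
#'   `species`, `entities` (data.frame), `edges` (data.frame, with added
#'   `polarity` and `statement_index`), `statement_count`.
#' @examples
#' e <- data.frame(subject_function = "protein", subject_ns = "MGI",
#'                 subject_id = "Ptgs2", subject_mod = NA,
#'                 relation = "increases",
#'                 object_function = "chemical", object_ns = "CHEBI",
#'                 object_id = "amyloid-beta", object_mod = NA)
#' m <- cause_effect_model(e, species = "mouse")
#' model_stats(m)
#' @export
cause_effect_model <- function(edges, species = c("human", "mouse"),
                               statement_count = NULL) {
  species <- match.arg(species)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  for (col in setdiff(.edge_cols, names(edges))) {
    edges[[col]] <- if (col == "statement_index") seq_len(nrow(edges))
                    else NA_character_
  }
  edges <- edges[, .edge_cols, drop = FALSE]
  if (nrow(edges) > 0L) {
    validate_edges(edges, species)
    edges$polarity <- relation_polarity(edges$relation)
    edges$statement_index <- seq_len(nrow(edges))
  } else {
    edges$polarity <- integer(0)
  }
  model <- structure(
    list(species = species,
         entities = edges_to_entities(edges),
         edges = edges,
         statement_count = if (is.null(statement_count)) nrow(edges)
                           else statement_count),
    class = "cause_effect_model")
  model
}

validate_edges <- function(edges, species) {
  for (side in c("subject", "object")) {
    fun <- edges[[paste0(side, "_function")]]
    ns <- edges[[paste0(side, "_ns")]]
    id <- edges[[paste0(side, "_id")]]
    mod <- edges[[paste0(side, "_mod")]]
    bad <- !fun %in% ENTITY_FUNCTIONS
    if (any(bad))
      stop("unknown function class in rows: ",
           paste(which(bad), collapse = ", "), " (",
           paste(unique(fun[bad]), collapse = ", "), ")")
    bad <- !ns %in% NAMESPACES
    if (any(bad))
      stop("unknown namespace in rows: ",
           paste(which(bad), collapse = ", "), " (",
           paste(unique(ns[bad]), collapse = ", "), ")")
    if (any(is.na(id) | !nzchar(id)))
      stop("empty ", side, " identifier in rows: ",
           paste(which(is.na(id) | !nzchar(id)), collapse = ", "))
    bad <- !is.na(mod) & nzchar(mod) & !fun %in% c("protein", "gene")
    if (any(bad))
      stop("modification on non-protein/gene ", side, " in rows: ",
           paste(which(bad), collapse = ", "))
    implied <- namespace_species(ns)
    bad <- !is.na(implied) & implied != species
    if (any(bad))
      stop("namespace/species conflict: ", species, " model contains ",
           paste(unique(ns[bad]), collapse = ", "), " ", side,
           " entities (rows ", paste(which(bad), collapse = ", "), ")")
  }
  relation_polarity(edges$relation)  # errors on unsupported relations
  invisible(TRUE)
}

edges_to_entities <- function(edges) {
  if (nrow(edges) == 0L)
    return(data.frame(fun = character(0), ns = character(0),
                      id = character(0), mod = character(0),
                      key = character(0), stringsAsFactors = FALSE))
  ent <- rbind(
    data.frame(fun = edges$subject_function, ns = edges$subject_ns,
               id = edges$subject_id, mod = edges$subject_mod,
               stringsAsFactors = FALSE),
    data.frame(fun = edges$object_function, ns = edges$object_ns,
               id = edges$object_id, mod = edges$object_mod,
               stringsAsFactors = FALSE))
  ent$key <- entity_key(ent$fun, ent$ns, ent$id, ent$mod)
  ent <- ent[!duplicated(ent$key), , drop = FALSE]
  rownames(ent) <- NULL
  ent
}

# canonical triple strings; association edges are symmetric, so they are
# canonicalised to lexicographic endpoint order for identity and export
edge_triples <- function(edges, with_mod = TRUE) {
  if (nrow(edges) == 0L) return(character(0))
  s <- entity_key(edges$subject_function, edges$subject_ns,
                  edges$subject_id, edges$subject_mod, with_mod)
  o <- entity_key(edges$object_function, edges$object_ns,
                  edges$object_id, edges$object_mod, with_mod)
  sym <- relation_polarity(edges$relation) == 0L &
    edges$relation == "association"
  flip <- sym & s > o
  tmp <- s[flip]; s[flip] <- o[flip]; o[flip] <- tmp
  paste(s, edges$relation, o)
}

#' Summary statistics of a model
#'
#' Node count is the number of distinct entities (union of edge endpoints
#' plus any isolated declared entities); edge count counts distinct
#' canonical (subject, relation, object) triples, so duplicated
#' statements add to `statement_count` but not to the edge count.
#'
#' @param model a [cause_effect_model()].
#' @return a list with `species`, `n_nodes`, `n_edges`,
#'   `n_statements`, and `nodes_by_function` (named integer vector).
#' @export
model_stats <- function(model) {
  stopifnot(inherits(model, "cause_effect_model"))
  by_fun <- table(factor(model$entities$fun, levels = ENTITY_FUNCTIONS))
  list(species = model$species,
       n_nodes = nrow(model$entities),
       n_edges = length(unique(edge_triples(model$edges))),
       n_statements = model$statement_count,
       nodes_by_function = stats::setNames(as.integer(by_fun),
                                           names(by_fun)))
}

#' @export
print.cause_effect_model <- function(x, ...) {
  s <- model_stats(x)
  cat(sprintf("cause-and-effect model (%s): %d nodes, %d edges, %d statements\n",
              s$species, s$n_nodes, s$n_edges, s$n_statements))
  invisible(x)
}
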