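## Signed-path mode-of-action propagation --------------------------------

#' Define a drug's target actions
#'
#' @param drug drug name.
#' @param targets data.frame with columns `id` (target symbol) and
#'   `sign` (+1 activation, -1 inhibition); e.g. celecoxib inhibits both
#'   PTGS2 and PDPK1.
#' @return an object of class `drug_action`.
#' @examples
#' drug_action("celecoxib",
#'             data.frame(id = c("PTGS2", "PDPK1"), sign = c(-1, -1)))
#' @export
drug_action <- function(drug, targets) {
  stopifnot(is.data.frame(targets),
            all(c("id", "sign") %in% names(targets)),
            nrow(targets) >= 1L)
  if (any(!targets$sign %in% c(-1L, 1L)))
    stop("target action signs must be +1 or -1")
  structure(list(drug = drug,
                 targets = data.frame(id = as.character(targets$id),
                                      sign = as.integer(targets$sign),
                                      stringsAsFactors = FALSE)),
            class = "drug_action")
}

#' Load a drug action from YAML or TSV
#'
#' YAML layout: `drug: <name>` plus `targets:` as a list of
#' `{id: <symbol>, sign: <+1/-1>}`; TSV layout: columns `drug`, `id`,
#' `sign`.
#'
#' @param path file path (`.yaml`/`.yml` or `.tsv`).
#' @return a [drug_action()].
#' @export
load_drug_action <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    y <- yaml::read_yaml(path)
    targets <- do.call(rbind, lapply(y$targets, function(t)
      data.frame(id = t$id, sign = t$sign, stringsAsFactors = FALSE)))
    drug_action(y$drug, targets)
  } else {
    tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    drug_action(unique(tab$drug)[1], tab[, c("id", "sign")])
  }
}

# signed adjacency over distinct polar edges; node identity ignores
# modification decorations (an entity and its phospho-form are one node)
polar_adjacency <- function(model) {
  e <- model$edges
  e <- e[relation_polarity(e$relation) != 0L, , drop = FALSE]
  if (nrow(e) == 0L)
    return(list(nodes = character(0), edges = data.frame(
      from = character(0), to = character(0), sign = integer(0))))
  from <- entity_key(e$subject_function, e$subject_ns, e$subject_id,
                     with_mod = FALSE)
  to <- entity_key(e$object_function, e$object_ns, e$object_id,
                   with_mod = FALSE)
  ed <- unique(data.frame(from = from, to = to,
                          sign = relation_polarity(e$relation),
                          stringsAsFactors = FALSE))
  all_nodes <- unique(entity_key(
    c(model$entities$fun), c(model$entities$ns), c(model$entities$id),
    with_mod = FALSE))
  list(nodes = all_nodes, edges = ed)
}

# depth-first enumeration of simple signed paths from one start node
enumerate_signed_paths <- function(adj, start, start_sign, max_len) {
  out_by <- split(seq_len(nrow(adj$edges)), adj$edges$from)
  paths <- list()
  walk <- function(node, visited, sign, depth) {
    if (depth >= max_len) return(invisible(NULL))
    for (i in out_by[[node]]) {
      nxt <- adj$edges$to[i]
      if (nxt %in% visited) next
      s <- sign * adj$edges$sign[i]
      paths[[length(paths) + 1L]] <<- list(
        nodes = c(visited, nxt), sign = s)
      walk(nxt, c(visited, nxt), s, depth + 1L)
    }
  }
  walk(start, start, start_sign, 0L)
  paths
}

#' Propagate a drug perturbation through a model
#'
#' Enumerates simple directed paths (no repeated node, length <=
#' `max_len`) from each drug target through polar edges only
#' (association/correlative edges carry no sign and are excluded). Each
#' path's sign is the target's action sign times the product of edge
#' polarities along it. Per node, the net effect is +1 or -1 when all
#' incoming path signs agree, `conflict` when both signs reach it, and
#' `unreached` otherwise; targets themselves carry their action sign.
#' Target symbols absent from the model are matched by the species' case
#' convention before being skipped with a warning; all targets missing is
#' an error.
#'
#' @param model a [cause_effect_model()].
#' @param action a [drug_action()].
#' @param max_len maximum path length in edges (default 6; the
#'   celecoxib chains need at most 7 nodes).
#' @return an object of class `perturbation_result`: `nodes` (data.frame
#'   `node`, `id`, `status` in `"+1"`, `"-1"`, `"conflict"`,
#'   `"unreached"`, `n_pos`, `n_neg`), `paths` (data.frame with the node
#'   chain, length and sign of each supporting path), `drug`,
#'   `species`, `max_len`, `targets_used`.
#' @export
propagate <- function(model, action, max_len = 6L) {
  stopifnot(inherits(model, "cause_effect_model"),
            inherits(action, "drug_action"), max_len >= 1L)
  adj <- polar_adjacency(model)
  node_ids <- sub("^[^|]*\\|[^:]*:", "", adj$nodes)
  resolve_target <- function(id) {
    hit <- adj$nodes[node_ids == id]
    if (length(hit) == 0L)
      hit <- adj$nodes[node_ids == casefold_symbol(id, model$species)]
    hit
  }
  sign_by_node <- list()
  path_rows <- list()
  used <- character(0)
  for (t in seq_len(nrow(action$targets))) {
    id <- action$targets$id[t]
    sgn <- action$targets$sign[t]
    starts <- resolve_target(id)
    if (length(starts) == 0L) {
      warning("target ", id, " not present in the ", model$species,
              " model; skipped", call. = FALSE)
      next
    }
    used <- c(used, starts)
    for (start in starts) {
      sign_by_node[[start]] <- c(sign_by_node[[start]], sgn)
      for (p in enumerate_signed_paths(adj, start, sgn, max_len)) {
        end <- p$nodes[length(p$nodes)]
        sign_by_node[[end]] <- c(sign_by_node[[end]], p$sign)
        path_rows[[length(path_rows) + 1L]] <- data.frame(
          target = id,
          chain = paste(sub("^[^|]*\\|[^:]*:", "", p$nodes),
                        collapse = " -> "),
          length = length(p$nodes) - 1L,
          sign = p$sign, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(used) == 0L)
    stop("none of the drug targets are present in the model")
  status <- vapply(adj$nodes, function(nd) {
    s <- sign_by_node[[nd]]
    if (is.null(s)) return("unreached")
    if (all(s > 0)) return("+1")
    if (all(s < 0)) return("-1")
    "conflict"
  }, character(1))
  nodes <- data.frame(
    node = adj$nodes, id = node_ids, status = unname(status),
    n_pos = vapply(adj$nodes,
                   function(nd) sum(sign_by_node[[nd]] > 0), numeric(1)),
    n_neg = vapply(adj$nodes,
                   function(nd) sum(sign_by_node[[nd]] < 0), numeric(1)),
    stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$node), , drop = FALSE]
  rownames(nodes) <- NULL
  paths <- if (length(path_rows)) do.call(rbind, path_rows)
           else data.frame(target = character(0), chain = character(0),
                           length = integer(0), sign = integer(0))
  paths <- paths[order(paths$chain), , drop = FALSE]
  rownames(paths) <- NULL
  structure(list(nodes = nodes, paths = paths, drug = action$drug,
                 species = model$species, max_len = max_len,
                 targets_used = sort(unique(used))),
            class = "perturbation_result")
}

#' Net predicted sign for one node
#'
#' @param result a [propagate()] result.
#' @param id node identifier (symbol) as it appears in that species'
#'   model.
#' @return `"+1"`, `"-1"`, `"conflict"` or `"unreached"` (`NA` when the
#'   node is not in the model).
#' @export
node_sign <- function(result, id) {
  hit <- result$nodes$status[result$nodes$id == id]
  if (length(hit) == 0L) return(NA_character_)
  hit[1L]
}

#' Compare perturbation outcomes between species
#'
#' Nodes are paired through orthology (gene-symbol mapping for
#' genic nodes; species-neutral nodes pair by identity). Outcomes:
#' `agree` (same pure sign), `agree_on_conflict` (both conflicted),
#' `disagree` (different pure signs, or conflict in exactly one
#' species), `a_only` / `b_only` (reached in one model only). Node pairs
#' unreached in both models are omitted.
#'
#' @param result_a,result_b [propagate()] results from models of the two
#'   species (conventionally a = human, b = mouse).
#' @param map an [orthology_map()].
#' @return data.frame: `node` (a-space identifier), `status_a`,
#'   `status_b`, `outcome`.
#' @export
compare_perturbation <- function(result_a, result_b,
                                 map = orthology_map()) {
  # pairing key: function family + identifier translated into a's space
  pair_key <- function(nodes, species) {
    fam <- sub("\\|.*$", "", nodes$node)
    fam[fam %in% c("protein", "gene")] <- "genic"
    vapply(seq_len(nrow(nodes)), function(i) {
      id <- nodes$id[i]
      if (fam[i] == "genic" && species != result_a$species) {
        syms <- map_symbol(id, map, to = result_a$species)
        if (length(syms) > 0L) id <- syms[1L]
      }
      paste0(fam[i], "|", id)
    }, character(1))
  }
  a <- result_a$nodes
  b <- result_b$nodes
  a$key <- pair_key(a, result_a$species)
  b$key <- pair_key(b, result_b$species)
  keys <- union(a$key, b$key)
  rows <- lapply(keys, function(k) {
    sa <- a$status[a$key == k]
    sb <- b$status[b$key == k]
    sa <- if (length(sa)) sa[1L] else "absent"
    sb <- if (length(sb)) sb[1L] else "absent"
    reached_a <- sa %in% c("+1", "-1", "conflict")
    reached_b <- sb %in% c("+1", "-1", "conflict")
    if (!reached_a && !reached_b) return(NULL)
    outcome <- if (reached_a && !reached_b) "a_only"
      else if (!reached_a && reached_b) "b_only"
      else if (sa == "conflict" && sb == "conflict") "agree_on_conflict"
      else if (sa == "conflict" || sb == "conflict") "disagree"
      else if (sa == sb) "agree" else "disagree"
    data.frame(node = sub("^[^|]*\\|", "", k), status_a = sa,
               status_b = sb, outcome = outcome, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(node = character(0), status_a = character(0),
                         status_b = character(0), outcome = character(0))
  out <- out[order(out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.perturbation_result <- function(x, ...) {
  reach <- table(x$nodes$status)
  cat(sprintf("perturbation of %s model by %s (max path length %d):\n",
              x$species, x$drug, x$max_len))
  cat(sprintf("  %d path(s); node status: %s\n", nrow(x$paths),
              paste(names(reach), as.integer(reach), sep = "=",
                    collapse = ", ")))
  invisible(x)
}
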