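# shared fixture builders and independent oracles

# quick edge-row constructor: protein->protein unless a function class is
# tucked into the id as "bp:..."/"cell:..."/"chem:..."
edge_row <- function(s, rel, o, species = "human",
                     s_mod = NA_character_, o_mod = NA_character_) {
  ns_default <- if (species == "human") "HGNC" else "MGI"
  part <- function(x) {
    if (grepl("^bp:", x))
      list(fun = "bioprocess", ns = "GOBP", id = sub("^bp:", "", x))
    else if (grepl("^cell:", x))
      list(fun = "cell_population", ns = "MESH", id = sub("^cell:", "", x))
    else if (grepl("^chem:", x))
      list(fun = "chemical", ns = "CHEBI", id = sub("^chem:", "", x))
    else list(fun = "protein", ns = ns_default, id = x)
  }
  sp <- part(s); op <- part(o)
  data.frame(subject_function = sp$fun, subject_ns = sp$ns,
             subject_id = sp$id, subject_mod = s_mod,
             relation = rel,
             object_function = op$fun, object_ns = op$ns,
             object_id = op$id, object_mod = o_mod,
             species = species, stringsAsFactors = FALSE)
}

make_model <- function(..., species = "human") {
  cause_effect_model(do.call(rbind, list(...)), species = species)
}

# independent brute-force edge matcher: compares human-space string
# renderings of every mouse edge against one human edge, then applies
# the category rules directly
brute_classify <- function(h_edge, mouse_model) {
  fam <- function(f) if (f %in% c("protein", "gene")) "genic" else f
  up_id <- function(ns, id) if (ns == "MGI") toupper(id) else id
  end_str <- function(f, ns, id)
    paste(fam(f), if (ns %in% c("HGNC", "MGI")) up_id(ns, id)
          else paste0(ns, ":", id))
  hs <- end_str(h_edge$subject_function, h_edge$subject_ns,
                h_edge$subject_id)
  ho <- end_str(h_edge$object_function, h_edge$object_ns,
                h_edge$object_id)
  hpol <- relation_polarity(h_edge$relation)
  me <- mouse_model$edges
  pols <- integer(0)
  for (i in seq_len(nrow(me))) {
    ms <- end_str(me$subject_function[i], me$subject_ns[i],
                  me$subject_id[i])
    mo <- end_str(me$object_function[i], me$object_ns[i],
                  me$object_id[i])
    mpol <- relation_polarity(me$relation[i])
    fwd <- ms == hs && mo == ho
    bwd <- ms == ho && mo == hs
    sym_ok <- bwd && (me$relation[i] == "association" ||
                      h_edge$relation == "association")
    if (fwd || sym_ok) pols <- c(pols, mpol)
  }
  if (length(pols) == 0L) return("unique_to_human")
  if (hpol == 0L) return("consistent")
  if (any(pols == hpol)) return("consistent")
  if (any(pols == -hpol)) return("contradictory")
  "consistent"  # only zero-polarity support, default nonpolar rule
}

# independent signed-path oracle built on igraph's simple-path
# enumeration; assumes unique (subject, object) pairs and unique ids
brute_propagate_signs <- function(model, action, max_len) {
  e <- model$edges[relation_polarity(model$edges$relation) != 0L, ,
                   drop = FALSE]
  df <- unique(data.frame(from = e$subject_id, to = e$object_id,
                          sign = relation_polarity(e$relation),
                          stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(df, directed = TRUE)
  sign_of <- function(a, b)
    df$sign[df$from == a & df$to == b][1]
  signs <- list()
  for (t in seq_len(nrow(action$targets))) {
    id <- action$targets$id[t]
    if (!id %in% igraph::V(g)$name) next
    signs[[id]] <- c(signs[[id]], action$targets$sign[t])
    for (v in setdiff(igraph::V(g)$name, id)) {
      paths <- igraph::all_simple_paths(g, from = id, to = v,
                                        mode = "out", cutoff = max_len)
      for (p in paths) {
        nm <- igraph::V(g)$name[p]
        s <- action$targets$sign[t]
        for (k in seq_len(length(nm) - 1L))
          s <- s * sign_of(nm[k], nm[k + 1L])
        signs[[v]] <- c(signs[[v]], s)
      }
    }
  }
  vapply(names(signs), function(v) {
    s <- signs[[v]]
    if (all(s > 0)) "+1" else if (all(s < 0)) "-1" else "conflict"
  }, character(1))
}

# random small paired models with known mutations, for oracle cross-checks
random_pair <- function(n_edges, seed) {
  generate_model_pair(n_edges = n_edges,
                      p_consistent = 0.4, p_contradictory = 0.3,
                      p_unique = 0.3, n_mouse_only = 2L,
                      cellular_fraction = 0.3, seed = seed)
}
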