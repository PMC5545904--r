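## Parsing and writing the BEL-subset dialect ----------------------------

# term function keyword -> entity function class; a() is resolved by
# namespace (CHEBI -> chemical, MESH -> cell population)
.term_funs <- c(p = "protein", g = "gene", bp = "bioprocess",
                complex = "complex")

normalize_identifier <- function(id) {
  id <- gsub("^\"|\"$", "", id)
  # Greek-letter shorthand for amyloid-beta -> stable ASCII key
  id <- gsub("Aβ", "amyloid-beta", id, fixed = TRUE)
  id
}

# parse one BEL term like act(p(HGNC:AKT1, pmod(P, S, 473))) into an
# entity row; act()/pmod() wrappers become the entity's `mod` decoration
parse_bel_term <- function(text, line_no) {
  txt <- trimws(text)
  mod <- character(0)
  m <- regmatches(txt, regexec("^act\\((.*)\\)$", txt))[[1]]
  if (length(m) == 2L) {
    mod <- "act"
    txt <- trimws(m[2])
  }
  m <- regmatches(txt, regexec("^(p|g|a|bp|complex)\\((.*)\\)$", txt))[[1]]
  if (length(m) != 3L)
    stop("line ", line_no, ": cannot parse term '", text, "'")
  fun_kw <- m[2]
  inner <- trimws(m[3])
  pm <- regmatches(inner, regexec("^(.*?),\\s*(pmod\\([^)]*\\))$", inner))[[1]]
  if (length(pm) == 3L) {
    if (!fun_kw %in% c("p", "g"))
      stop("line ", line_no, ": pmod() only allowed inside p()/g()")
    mod <- c(mod, gsub("\\s+", "", pm[3]))
    inner <- trimws(pm[2])
  }
  nm <- regmatches(inner,
                   regexec("^([A-Za-z]+)\\s*:\\s*(\"[^\"]*\"|[^,()\"]+)$",
                           inner))[[1]]
  if (length(nm) != 3L)
    stop("line ", line_no, ": cannot parse namespace:identifier in '",
         inner, "'")
  ns <- toupper(nm[2])
  if (!ns %in% NAMESPACES)
    stop("line ", line_no, ": unknown namespace '", nm[2], "'")
  id <- normalize_identifier(trimws(nm[3]))
  if (!nzchar(id)) stop("line ", line_no, ": empty identifier")
  fun <- if (fun_kw == "a") {
    if (ns == "MESH") "cell_population" else "chemical"
  } else .term_funs[[fun_kw]]
  if (length(mod) > 0L && !fun %in% c("protein", "gene"))
    stop("line ", line_no, ": act()/pmod() only allowed on protein/gene")
  data.frame(fun = fun, ns = ns, id = id,
             mod = if (length(mod)) paste(mod, collapse = "+")
                   else NA_character_,
             stringsAsFactors = FALSE)
}

#' Parse a BEL-subset script into a cause-and-effect model
#'
#' Supports one statement per non-comment line in the form
#' `term relation term`, with term functions `p()`, `g()`, `a()`, `bp()`,
#' `complex()`, decorations `act()` and `pmod()`, and the six relations
#' in [RELATIONS]. `SET Citation`/`SET Evidence` annotations are captured
#' as edge metadata; other `SET`/`DEFINE` lines are skipped with a
#' warning. The document species is taken from a `# SPECIES: <sp>` header
#' comment, a `SET Species` annotation, or the `species` argument; if
#' none is given it is inferred from the namespaces, and a document
#' mixing HGNC and MGI without an explicit flag is a validation error.
#'
#' @param text character scalar (whole document) or vector of lines.
#' @param species optional `"human"` or `"mouse"`, overriding inference.
#' @return a [cause_effect_model()]; edge order preserves statement order
#'   in `statement_index`.
#' @examples
#' m <- parse_bel_script(c("# SPECIES: mouse",
#'   'p(MGI:Ptgs2) increases a(CHEBI:"amyloid-beta")'))
#' model_stats(m)
#' @export
parse_bel_script <- function(text, species = NULL) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
           else text
  citation <- NA_character_
  evidence <- NA_character_
  decl_species <- species
  rows <- list()
  rel_pattern <- paste0("\\s+(", paste(RELATIONS, collapse = "|"), ")\\s+")
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("^#\\s*SPECIES\\s*:\\s*(\\w+)", ln,
                                  ignore.case = TRUE))[[1]]
      if (length(m) == 2L) decl_species <- tolower(m[2])
      next
    }
    if (grepl("^UNSET\\b", ln)) {
      key <- trimws(sub("^UNSET\\s*", "", ln))
      if (tolower(key) == "citation") citation <- NA_character_
      if (tolower(key) == "evidence") evidence <- NA_character_
      next
    }
    if (grepl("^SET\\b", ln)) {
      m <- regmatches(ln, regexec("^SET\\s+(\\w+)\\s*=\\s*(.*)$", ln))[[1]]
      if (length(m) == 3L) {
        val <- normalize_identifier(trimws(gsub("^[{\"]|[}\"]$", "",
                                                trimws(m[3]))))
        key <- tolower(m[2])
        if (key == "citation") citation <- val
        else if (key == "evidence") evidence <- val
        else if (key == "species") decl_species <- tolower(val)
        else warning("line ", i, ": skipping unsupported annotation SET ",
                     m[2], call. = FALSE)
      } else {
        warning("line ", i, ": skipping unparseable SET line", call. = FALSE)
      }
      next
    }
    if (grepl("^DEFINE\\b", ln)) {
      warning("line ", i, ": skipping DEFINE line", call. = FALSE)
      next
    }
    split <- regexpr(rel_pattern, ln)
    if (split < 0) {
      # distinguish "unsupported relation" from general malformation
      m <- regmatches(ln, regexec("\\)\\s+([A-Za-z]+)\\s+[a-z]+\\(",
                                  ln))[[1]]
      if (length(m) == 2L && !m[2] %in% RELATIONS)
        stop("line ", i, ": unsupported relation '", m[2], "'")
      stop("line ", i, ": malformed statement '", ln, "'")
    }
    rel <- trimws(regmatches(ln, regexpr(rel_pattern, ln)))
    parts <- strsplit(ln, rel_pattern)[[1]]
    if (length(parts) != 2L)
      stop("line ", i, ": malformed statement '", ln, "'")
    subj <- parse_bel_term(parts[1], i)
    obj <- parse_bel_term(parts[2], i)
    rows[[length(rows) + 1L]] <- data.frame(
      subject_function = subj$fun, subject_ns = subj$ns,
      subject_id = subj$id, subject_mod = subj$mod,
      relation = rel,
      object_function = obj$fun, object_ns = obj$ns,
      object_id = obj$id, object_mod = obj$mod,
      citation = citation, evidence = evidence,
      stringsAsFactors = FALSE)
  }
  edges <- if (length(rows)) do.call(rbind, rows) else empty_edges()
  if (nrow(edges) == 0L && is.null(decl_species)) decl_species <- "human"
  species <- resolve_species(edges, decl_species)
  edges$species <- rep(species, length.out = nrow(edges))
  cause_effect_model(edges, species = species,
                     statement_count = nrow(edges))
}

resolve_species <- function(edges, declared) {
  implied <- unique(stats::na.omit(
    namespace_species(c(edges$subject_ns, edges$object_ns))))
  if (!is.null(declared)) {
    declared <- match.arg(declared, c("human", "mouse"))
    return(declared)
  }
  if (length(implied) > 1L)
    stop("document mixes HGNC and MGI namespaces; declare the species ",
         "explicitly (header '# SPECIES: ...' or species argument)")
  if (length(implied) == 1L) return(implied)
  stop("species not declared and not inferable from namespaces")
}

format_bel_term <- function(fun, ns, id, mod) {
  quoted <- ifelse(grepl("[^A-Za-z0-9_.-]", id), paste0('"', id, '"'), id)
  body <- paste0(ns, ":", quoted)
  kw <- c(protein = "p", gene = "g", chemical = "a", bioprocess = "bp",
          cell_population = "a", complex = "complex")[fun]
  has_mod <- !is.na(mod) & nzchar(ifelse(is.na(mod), "", mod))
  act <- has_mod & grepl("(^|\\+)act($|\\+)", ifelse(is.na(mod), "", mod))
  pmod <- ifelse(has_mod,
                 vapply(mod, function(m) {
                   if (is.na(m)) return("")
                   hit <- regmatches(m, regexpr("pmod\\([^)]*\\)", m))
                   if (length(hit)) hit else ""
                 }, character(1)), "")
  term <- ifelse(nzchar(pmod),
                 paste0(kw, "(", body, ", ", pmod, ")"),
                 paste0(kw, "(", body, ")"))
  ifelse(act, paste0("act(", term, ")"), term)
}

#' Write a model as a BEL-subset script
#'
#' Deterministic output: a `# SPECIES:` header followed by one statement
#' per edge record, sorted by the canonical (subject, relation, object)
#' string. The output re-parses to the same model.
#'
#' @param model a [cause_effect_model()].
#' @param path optional file path; when `NULL` the text is returned.
#' @return the script as a character vector of lines (invisibly when
#'   written to `path`).
#' @export
write_bel_script <- function(model, path = NULL) {
  stopifnot(inherits(model, "cause_effect_model"))
  e <- model$edges
  stmts <- character(0)
  if (nrow(e) > 0L) {
    subj <- format_bel_term(e$subject_function, e$subject_ns,
                            e$subject_id, e$subject_mod)
    obj <- format_bel_term(e$object_function, e$object_ns,
                           e$object_id, e$object_mod)
    stmts <- paste(subj, e$relation, obj)
    stmts <- stmts[order(edge_triples(e))]
  }
  out <- c(paste0("# SPECIES: ", model$species), stmts)
  if (!is.null(path)) {
    writeLines(out, path, useBytes = TRUE)
    return(invisible(out))
  }
  out
}

## Flat edge-table dialect ------------------------------------------------

.mandatory_table_cols <- c("subject_function", "subject_ns", "subject_id",
                           "relation",
                           "object_function", "object_ns", "object_id",
                           "species")

#' Load a model from a flat TSV edge table
#'
#' Same semantics as [parse_bel_script()]: each row is one causal
#' statement. Mandatory columns are `subject_function`, `subject_ns`,
#' `subject_id`, `relation`, `object_function`, `object_ns`, `object_id`,
#' `species`; `subject_mod`, `object_mod`, `citation`, `evidence` are
#' optional. Blank lines and `#` comments are ignored. Duplicated rows
#' are kept as separate statements of the same edge.
#'
#' @param path TSV file path, or a data.frame already in that layout.
#' @param species optional override; defaults to the (single) value of
#'   the species column.
#' @return a [cause_effect_model()].
#' @export
load_edge_table <- function(path, species = NULL) {
  tab <- if (is.data.frame(path)) path
         else utils::read.delim(path, sep = "\t", comment.char = "#",
                                blank.lines.skip = TRUE,
                                stringsAsFactors = FALSE,
                                na.strings = c("NA", ""))
  missing <- setdiff(.mandatory_table_cols, names(tab))
  if (length(missing) > 0L)
    stop("edge table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  for (col in c("subject_mod", "object_mod", "citation", "evidence"))
    if (!col %in% names(tab)) tab[[col]] <- NA_character_
  if (is.null(species)) {
    sp <- unique(tab$species)
    if (length(sp) > 1L)
      stop("edge table mixes species (", paste(sp, collapse = ", "),
           "); pass an explicit species")
    species <- if (length(sp) == 1L) sp else NULL
  }
  if (nrow(tab) == 0L && is.null(species)) species <- "human"
  species <- resolve_species(tab, species)
  bad_rel <- !tab$relation %in% RELATIONS
  if (any(bad_rel))
    stop("unknown relation value in rows: ",
         paste(which(bad_rel), collapse = ", "), " (",
         paste(unique(tab$relation[bad_rel]), collapse = ", "), ")")
  cause_effect_model(tab[, setdiff(.edge_cols, "statement_index")],
                     species = species, statement_count = nrow(tab))
}

#' Write a model as a flat TSV edge table
#'
#' @param model a [cause_effect_model()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_edge_table <- function(model, path) {
  stopifnot(inherits(model, "cause_effect_model"))
  cols <- setdiff(.edge_cols, "statement_index")
  utils::write.table(model$edges[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

## Graph exports ----------------------------------------------------------

model_to_igraph <- function(model) {
  ent <- model$entities
  e <- model$edges
  canon <- edge_triples(e)
  keep <- !duplicated(canon)
  e <- e[keep, , drop = FALSE]
  from <- entity_key(e$subject_function, e$subject_ns, e$subject_id,
                     e$subject_mod)
  to <- entity_key(e$object_function, e$object_ns, e$object_id,
                   e$object_mod)
  # association edges exported once in canonical endpoint order
  sym <- e$relation == "association" & from > to
  tmp <- from[sym]; from[sym] <- to[sym]; to[sym] <- tmp
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, relation = e$relation,
               polarity = relation_polarity(e$relation),
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = ent$key, fun = ent$fun, ns = ent$ns,
                          identifier = ent$id,
                          mod = ifelse(is.na(ent$mod), "", ent$mod),
                          stringsAsFactors = FALSE))
  g
}

#' Export a model to SIF or GraphML
#'
#' SIF rows are `subject relation object` (node tokens are
#' `namespace:identifier`, spaces replaced by underscores; evidence is
#' dropped). GraphML carries function class, namespace, identifier and
#' modification as node attributes and relation/polarity as edge
#' attributes. Association edges are exported once, in lexicographic
#' endpoint order.
#'
#' @param model a [cause_effect_model()].
#' @param path output file path.
#' @param format `"SIF"` or `"GraphML"`.
#' @return the path, invisibly.
#' @export
export_graph <- function(model, path, format = c("SIF", "GraphML")) {
  format <- match.arg(format)
  if (format == "SIF") {
    e <- model$edges[!duplicated(edge_triples(model$edges)), ,
                     drop = FALSE]
    tok <- function(ns, id) paste0(ns, ":", gsub("[[:space:]]+", "_", id))
    from <- tok(e$subject_ns, e$subject_id)
    to <- tok(e$object_ns, e$object_id)
    sym <- e$relation == "association" & from > to
    tmp <- from[sym]; from[sym] <- to[sym]; to[sym] <- tmp
    writeLines(paste(from, e$relation, to), path)
  } else {
    igraph::write_graph(model_to_igraph(model), path, format = "graphml")
  }
  invisible(path)
}

#' Re-import a GraphML export
#'
#' @param path a GraphML file written by [export_graph()].
#' @return an igraph graph with the exported node/edge attributes.
#' @export
import_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
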