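test_that("BEL statements parse into typed edges with correct polarity", {
  m <- parse_bel_script(c(
    "# SPECIES: mouse",
    'SET Citation = "pmid:1"',
    'SET Evidence = "Ptgs2 increases amyloid-beta peptides"',
    'p(MGI:Ptgs2) increases a(CHEBI:"amyloid-beta")',
    "UNSET Evidence",
    "act(p(MGI:Akt1, pmod(P, S, 473))) decreases bp(GOBP:autophagy)",
    "a(MESH:microglia) increases p(MGI:Tnf)"))
  expect_equal(model_stats(m)$n_edges, 3)
  expect_equal(m$species, "mouse")
  e <- m$edges
  expect_equal(e$subject_function[1], "protein")
  expect_equal(e$object_function[1], "chemical")
  expect_equal(e$object_id[1], "amyloid-beta")
  expect_equal(e$polarity, c(1L, -1L, 1L))
  expect_equal(e$citation[1], "pmid:1")
  expect_match(e$evidence[1], "amyloid-beta peptides")
  expect_true(is.na(e$evidence[2]))
  # act/pmod are decorations on the entity, not extra nodes
  expect_equal(e$subject_mod[2], "act+pmod(P,S,473)")
  expect_false(any(grepl("pmod", m$entities$id)))
  # MESH abundance is a cell population
  expect_equal(e$subject_function[3], "cell_population")
})

test_that("greek amyloid-beta shorthand is normalised to an ASCII key", {
  m <- parse_bel_script("p(MGI:Ptgs2) increases a(CHEBI:\"Aβ\")",
                        species = "mouse")
  expect_equal(m$edges$object_id, "amyloid-beta")
})

test_that("parse errors carry line numbers and name the offence", {
  expect_error(parse_bel_script(c("# SPECIES: human",
                                  "p(HGNC:TNF) explodes p(HGNC:NFKB1)")),
               "line 2.*unsupported relation 'explodes'")
  expect_error(parse_bel_script("p(HGNC:TNF increases", species = "human"),
               "line 1")
  expect_error(parse_bel_script(c("p(HGNC:TNF) increases p(MGI:Tnf)")),
               "mixes HGNC and MGI")
  expect_warning(parse_bel_script(c("# SPECIES: human",
                                    'SET CellLine = "x"',
                                    "p(HGNC:TNF) increases p(HGNC:NFKB1)")),
                 "CellLine")
})

test_that("empty documents give empty models", {
  m <- parse_bel_script("")
  expect_equal(model_stats(m)$n_nodes, 0)
  expect_equal(model_stats(m)$n_edges, 0)
  expect_equal(model_stats(m)$n_statements, 0)
})

test_that("write/parse round-trips preserve the model", {
  models <- list(
    make_model(edge_row("TNF", "increases", "NFKB1"),
               edge_row("NFKB1", "decreases", "bp:apoptosis"),
               edge_row("IL4", "association", "chem:celecoxib")),
    parse_bel_script(c("# SPECIES: mouse",
                       "act(p(MGI:Akt1, pmod(P))) decreases bp(GOBP:autophagy)",
                       'p(MGI:Ptgs2) increases a(CHEBI:"amyloid-beta")')),
    celecoxib_models()$human)
  for (m in models) {
    m2 <- parse_bel_script(write_bel_script(m))
    expect_equal(sort(crossbel:::edge_triples(m2$edges)),
                 sort(crossbel:::edge_triples(m$edges)))
    expect_equal(m2$species, m$species)
  }
  # deterministic ordering contract
  m <- make_model(edge_row("B", "decreases", "C"),
                  edge_row("A", "increases", "B"))
  lines <- write_bel_script(m)
  expect_equal(lines[-1], sort(lines[-1]))
})

test_that("edge tables load with multiset statement semantics", {
  tab <- rbind(edge_row("TNF", "increases", "NFKB1"),
               edge_row("TNF", "increases", "NFKB1"),
               edge_row("NFKB1", "decreases", "bp:autophagy"))
  m <- load_edge_table(tab)
  s <- model_stats(m)
  expect_equal(s$n_edges, 2)       # duplicate row is one edge...
  expect_equal(s$n_statements, 3)  # ...but three statements
  expect_equal(s$n_nodes, 3)
  expect_equal(relation_polarity(m$edges$relation[3]), -1L)
  # equivalence with the BEL path
  m2 <- parse_bel_script(write_bel_script(m))
  expect_equal(sort(unique(crossbel:::edge_triples(m2$edges))),
               sort(unique(crossbel:::edge_triples(m$edges))))
})

test_that("edge table schema violations are reported per row", {
  tab <- edge_row("TNF", "increases", "NFKB1")
  expect_error(load_edge_table(tab[, setdiff(names(tab), "relation")]),
               "missing mandatory column.*relation")
  bad <- rbind(edge_row("TNF", "increases", "NFKB1"),
               edge_row("A", "modulates", "B"))
  expect_error(load_edge_table(bad), "rows: 2.*modulates")
})

test_that("model validation enforces species/namespace coherence", {
  bad <- edge_row("Tnf", "increases", "Il4", species = "mouse")
  bad$subject_ns <- "HGNC"
  expect_error(cause_effect_model(bad, "mouse"),
               "namespace/species conflict")
  expect_error(entity("bioprocess", "GOBP", "autophagy", mod = "pmod(P)"),
               "only allowed on protein/gene")
  expect_error(entity("protein", "HGNC", ""), "non-empty")
})

test_that("graph exports carry the expected structure", {
  m <- make_model(edge_row("TNF", "increases", "NFKB1"),
                  edge_row("ZZZ", "association", "AAA"),
                  edge_row("NFKB1", "decreases", "bp:autophagy"))
  sif <- tempfile(fileext = ".sif")
  export_graph(m, sif, "SIF")
  lines <- readLines(sif)
  expect_length(lines, 3)
  expect_true("HGNC:TNF increases HGNC:NFKB1" %in% lines)
  # association exported once, canonical lexicographic orientation
  expect_true("HGNC:AAA association HGNC:ZZZ" %in% lines)
  gml <- tempfile(fileext = ".graphml")
  export_graph(m, gml, "GraphML")
  g <- import_graphml(gml)
  expect_equal(sort(igraph::E(g)$polarity), c(-1, 0, 1))
  expect_setequal(igraph::V(g)$fun,
                  c("protein", "bioprocess"))
  expect_error(export_graph(m, tempfile(), "DOT"))
})

test_that("model stats agree with generator bookkeeping", {
  m <- generate_model(n_nodes = 50, n_edges = 120, seed = 11)
  s <- model_stats(m)
  expect_equal(s$n_nodes, 50)
  expect_equal(s$n_edges, 120)
  expect_equal(unname(s$nodes_by_function["protein"]), 50L)
})
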