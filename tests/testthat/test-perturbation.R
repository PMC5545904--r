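om <- orthology_map()

chain_model <- function(...) make_model(...)

test_that("signs compose multiplicatively along paths", {
  # (+,+) -> +, (+,-) -> -, (-,-) -> +
  m <- make_model(edge_row("A", "increases", "B"),
                  edge_row("B", "increases", "C"),
                  edge_row("C", "decreases", "D"),
                  edge_row("D", "decreases", "E"))
  res <- propagate(m, drug_action("x", data.frame(id = "A", sign = 1)))
  expect_equal(node_sign(res, "B"), "+1")
  expect_equal(node_sign(res, "C"), "+1")
  expect_equal(node_sign(res, "D"), "-1")
  expect_equal(node_sign(res, "E"), "+1")
  # inhibitor flips everything
  res2 <- propagate(m, drug_action("x", data.frame(id = "A", sign = -1)))
  expect_equal(node_sign(res2, "E"), "-1")
  # recorded path signs equal the product of their edge polarities
  expect_equal(sort(unique(res$paths$sign)), c(-1, 1))
})

test_that("conflicting routes surface as conflict, never resolved", {
  m <- make_model(edge_row("A", "increases", "B"),
                  edge_row("A", "increases", "C"),
                  edge_row("B", "increases", "D"),
                  edge_row("C", "decreases", "D"))
  res <- propagate(m, drug_action("x", data.frame(id = "A", sign = 1)))
  expect_equal(node_sign(res, "D"), "conflict")
  expect_equal(res$nodes$n_pos[res$nodes$id == "D"], 1)
  expect_equal(res$nodes$n_neg[res$nodes$id == "D"], 1)
})

test_that("association edges never carry perturbation", {
  m <- make_model(edge_row("A", "increases", "B"),
                  edge_row("B", "association", "C"))
  res <- propagate(m, drug_action("x", data.frame(id = "A", sign = 1)))
  expect_equal(node_sign(res, "C"), "unreached")
})

test_that("cycles terminate under the simple-path rule", {
  # the Nfkb1 -> Ptgs2 -> amyloid-beta -> Nfkb1 self-regulatory loop
  m <- make_model(edge_row("Nfkb1", "increases", "Ptgs2",
                           species = "mouse"),
                  edge_row("Ptgs2", "increases", "chem:amyloid-beta",
                           species = "mouse"),
                  edge_row("chem:amyloid-beta", "increases", "Nfkb1",
                           species = "mouse"), species = "mouse")
  res <- propagate(m, drug_action("x", data.frame(id = "Nfkb1",
                                                  sign = 1)),
                   max_len = 10)
  expect_true(all(res$paths$length <= 3))
  expect_equal(node_sign(res, "amyloid-beta"), "+1")
})

test_that("monotone reach: longer horizons only add reached nodes", {
  gp <- random_pair(n_edges = 15, seed = 13)
  act <- drug_action("x", data.frame(
    id = gp$human$edges$subject_id[1], sign = -1))
  reached <- function(res)
    res$nodes$id[res$nodes$status != "unreached"]
  prev <- character(0)
  for (len in 1:5) {
    cur <- reached(propagate(gp$human, act, max_len = len))
    expect_true(all(prev %in% cur),
                info = paste("max_len", len))
    prev <- cur
  }
})

test_that("propagation matches the exhaustive igraph oracle", {
  for (seed in 1:4) {
    m <- generate_model(n_nodes = 10, n_edges = 24, seed = seed)
    targets <- unique(m$edges$subject_id)[1:2]
    act <- drug_action("x", data.frame(id = targets, sign = c(-1, 1)))
    for (len in c(2, 4, 6)) {
      got <- propagate(m, act, max_len = len)
      oracle <- brute_propagate_signs(m, act, max_len = len)
      got_status <- stats::setNames(got$nodes$status, got$nodes$id)
      expect_equal(sort(names(oracle)),
                   sort(names(got_status[got_status != "unreached"])))
      for (v in names(oracle))
        expect_equal(unname(got_status[v]), unname(oracle[v]),
                     info = sprintf("seed %d len %d node %s",
                                    seed, len, v))
    }
  }
})

test_that("missing targets warn, all-missing errors", {
  m <- make_model(edge_row("A", "increases", "B"))
  act <- drug_action("x", data.frame(id = c("A", "NOPE"),
                                     sign = c(1, 1)))
  expect_warning(res <- propagate(m, act), "NOPE")
  expect_equal(node_sign(res, "B"), "+1")
  expect_error(
    suppressWarnings(propagate(m, drug_action("x", data.frame(
      id = "NOPE", sign = 1)))), "none of the drug targets")
  # human-cased target symbols resolve by species casefolding
  mm <- make_model(edge_row("Ptgs2", "increases", "Tnf",
                            species = "mouse"), species = "mouse")
  res2 <- propagate(mm, drug_action("x", data.frame(id = "PTGS2",
                                                    sign = -1)))
  expect_equal(node_sign(res2, "Tnf"), "-1")
})

test_that("cross-species outcome buckets are assigned correctly", {
  h <- make_model(edge_row("GENEA", "increases", "GENEB"),
                  edge_row("GENEA", "increases", "GENEC"),
                  edge_row("GENEA", "increases", "HUMONLY"))
  m <- make_model(edge_row("Genea", "increases", "Geneb",
                           species = "mouse"),
                  edge_row("Genea", "decreases", "Genec",
                           species = "mouse"),
                  edge_row("Genea", "increases", "Mouseonly",
                           species = "mouse"), species = "mouse")
  act <- drug_action("x", data.frame(id = "GENEA", sign = 1))
  cmp <- compare_perturbation(propagate(h, act), propagate(m, act), om)
  out <- stats::setNames(cmp$outcome, cmp$node)
  expect_equal(unname(out["GENEB"]), "agree")
  expect_equal(unname(out["GENEC"]), "disagree")
  expect_equal(unname(out["HUMONLY"]), "a_only")
  expect_equal(unname(out["MOUSEONLY"]), "b_only")
  # identical outcomes -> all agree
  same <- compare_perturbation(propagate(h, act), propagate(h, act), om)
  expect_true(all(same$outcome == "agree"))
})

test_that("drug actions load from YAML and TSV", {
  y <- tempfile(fileext = ".yaml")
  writeLines(c("drug: celecoxib", "targets:",
               "  - {id: PTGS2, sign: -1}",
               "  - {id: PDPK1, sign: -1}"), y)
  a <- load_drug_action(y)
  expect_equal(a$drug, "celecoxib")
  expect_equal(a$targets$sign, c(-1L, -1L))
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("drug\tid\tsign", "celecoxib\tPTGS2\t-1"), tsv)
  expect_equal(load_drug_action(tsv)$targets$id, "PTGS2")
  expect_error(drug_action("x", data.frame(id = "A", sign = 0)),
               "\\+1 or -1")
})
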