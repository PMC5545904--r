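om <- orthology_map()

test_that("level stratification follows endpoint function classes", {
  e <- rbind(edge_row("TNF", "increases", "NFKB1"),
             edge_row("PTGS2", "increases", "bp:inflammatory response"),
             edge_row("cell:microglia", "increases", "TNF"),
             edge_row("PTGS2", "increases", "chem:amyloid-beta"))
  expect_equal(stratify_level(e),
               c("molecular", "cellular", "cellular", "molecular"))
})

test_that("single-edge classification matches the category definitions", {
  mouse <- make_model(edge_row("Nfkb1", "increases", "Ptgs2",
                               species = "mouse"),
                      edge_row("Tnf", "decreases", "Il4",
                               species = "mouse"),
                      edge_row("Gsk3b", "association", "Mapt",
                               species = "mouse"),
                      species = "mouse")
  cl <- function(s, rel, o)
    classify_edge(edge_row(s, rel, o), mouse, om)
  expect_equal(cl("NFKB1", "increases", "PTGS2")$category, "consistent")
  expect_equal(cl("TNF", "increases", "IL4")$category, "contradictory")
  expect_equal(cl("AKT1", "increases", "TSC2")$category,
               "unique_to_human")
  # reversed orientation is not a match for directed edges
  expect_equal(cl("PTGS2", "increases", "NFKB1")$category,
               "unique_to_human")
  # correlative mouse support for a polar human claim: nonpolar match
  r <- cl("GSK3B", "increases", "MAPT")
  expect_equal(r$category, "consistent")
  expect_true(r$nonpolar_match)
  # association edges match either orientation
  expect_equal(classify_edge(edge_row("MAPT", "association", "GSK3B"),
                             mouse, om)$category, "consistent")
  # demotion switch for nonpolar support
  expect_equal(cl2 <- classify_edge(edge_row("GSK3B", "increases", "MAPT"),
                                    mouse, om,
                                    nonpolar_as_consistent = FALSE)$category,
               "unique_to_human")
})

test_that("orthology gaps classify as unique with a note, no error", {
  strict <- orthology_map(policy = "table_only")
  mouse <- make_model(edge_row("Tnf", "increases", "Il4",
                               species = "mouse"), species = "mouse")
  r <- classify_edge(edge_row("TNF", "increases", "IL4"), mouse, strict)
  expect_equal(r$category, "unique_to_human")
  expect_equal(r$note, "no-orthology")
})

test_that("mixed evidence resolves to consistent with a flag", {
  mouse <- make_model(edge_row("Tnf", "increases", "Il4",
                               species = "mouse"),
                      edge_row("Tnf", "decreases", "Il4",
                               species = "mouse"), species = "mouse")
  r <- classify_edge(edge_row("TNF", "increases", "IL4"), mouse, om)
  expect_equal(r$category, "consistent")
  expect_true(r$mixed_evidence)
})

test_that("strict mode requires matching decorations", {
  mouse <- make_model(edge_row("Pdpk1", "increases", "Akt1",
                               species = "mouse",
                               o_mod = "pmod(P)"), species = "mouse")
  h <- edge_row("PDPK1", "increases", "AKT1")
  expect_equal(classify_edge(h, mouse, om)$category, "consistent")
  expect_equal(classify_edge(h, mouse, om, strict = TRUE)$category,
               "unique_to_human")
  h_mod <- edge_row("PDPK1", "increases", "AKT1", o_mod = "pmod(P)")
  expect_equal(classify_edge(h_mod, mouse, om, strict = TRUE)$category,
               "consistent")
})

test_that("self-comparison of orthologous twins is 100% consistent", {
  gp <- generate_model_pair(n_edges = 40, p_consistent = 1,
                            p_contradictory = 0, p_unique = 0, seed = 3)
  cmp <- compare_models(gp$human, gp$mouse, om)
  expect_true(all(cmp$records$category == "consistent"))
  expect_equal(nrow(cmp$mouse_only), 0)
  sm <- cmp$summary
  expect_true(all(sm$percent[sm$category == "consistent" &
                               sm$denominator > 0] == 100))
})

test_that("classification agrees with the brute-force matcher", {
  for (seed in 1:5) {
    gp <- random_pair(n_edges = 18, seed = seed)
    recs <- compare_models(gp$human, gp$mouse, om)$records
    for (i in seq_len(nrow(recs))) {
      expect_equal(recs$category[i],
                   brute_classify(recs[i, ], gp$mouse),
                   info = sprintf("seed %d edge %d", seed, i))
    }
  }
})

test_that("categories partition the scope and counts sum per level", {
  gp <- random_pair(n_edges = 60, seed = 9)
  cmp <- compare_models(gp$human, gp$mouse, om)
  expect_equal(nrow(cmp$records), 60)  # each in-scope edge exactly once
  sm <- cmp$summary
  for (lv in c("molecular", "cellular", "all")) {
    rows <- sm[sm$level == lv, ]
    expect_equal(sum(rows$count), rows$denominator[1])
  }
  expect_equal(sum(sm$count[sm$level %in% c("molecular", "cellular")]),
               sum(sm$count[sm$level == "all"]))
})

test_that("role swap exchanges the unique categories and keeps the rest", {
  gp <- random_pair(n_edges = 30, seed = 21)
  fwd <- compare_models(gp$human, gp$mouse, om)
  rev <- compare_models(gp$mouse, gp$human, om)
  count_of <- function(cmp, cat)
    sum(cmp$records$category == cat)
  expect_equal(count_of(fwd, "consistent"), count_of(rev, "consistent"))
  expect_equal(count_of(fwd, "contradictory"),
               count_of(rev, "contradictory"))
  expect_equal(count_of(fwd, "unique_to_human"), nrow(rev$mouse_only))
  expect_equal(nrow(fwd$mouse_only), count_of(rev, "unique_to_human"))
})

test_that("scope restriction and empty scope behave", {
  gp <- random_pair(n_edges = 20, seed = 2)
  sub <- gp$human$edges[1:5, ]
  cmp <- compare_models(gp$human, gp$mouse, om, scope = sub)
  expect_equal(nrow(cmp$records), 5)
  empty <- compare_models(gp$human, gp$mouse, om,
                          scope = gp$human$edges[0, ])
  expect_equal(nrow(empty$records), 0)
  expect_true(all(empty$summary$denominator == 0))
  expect_true(all(is.na(empty$summary$percent)))
})

test_that("integer percentages use half-away-from-zero rounding", {
  expect_equal(round_half_away(c(2.5, -2.5, 2.4, 57.58, 15.15)),
               c(3, -3, 2, 58, 15))
  # the 9/5/19 split over 33 molecular interactions prints 27/15/58
  expect_equal(round_half_away(100 * c(9, 5, 19) / 33), c(27, 15, 58))
})
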