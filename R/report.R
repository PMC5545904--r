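## Pipeline orchestration -------------------------------------------------

read_model_input <- function(x, species = NULL) {
  if (inherits(x, "cause_effect_model")) return(x)
  if (grepl("\\.bel$", x)) parse_bel_script(readLines(x), species = species)
  else load_edge_table(x, species = species)
}

#' Run the full cross-species comparison pipeline
#'
#' Orchestrates parse -> model stats -> edge concordance -> expression
#' concordance -> enrichment -> perturbation over a configuration list
#' (or YAML file). Every stage runs only when its inputs are configured;
#' skipped stages are marked `"skipped"` in the report. The report is
#' deterministic given the configuration and seed; the timestamp is
#' isolated in its own field so the rest can be compared byte-for-byte.
#'
#' Configuration fields: `human_model`, `mouse_model` (BEL/TSV paths or
#' model objects); `orthology` (TSV path, optional), `ortho_policy`;
#' `scope` (edge TSV restricting the comparison, optional); `human_de`,
#' `mouse_de` (named accession -> TSV path lists); `alpha`,
#' `use_adjusted`; `gene_sets` (GMT path), `query_human`, `query_mouse`
#' (gene list files, one symbol per line; default: the models' gene
#' symbols), `q_threshold`; `drug` (YAML/TSV path or [drug_action()]),
#' `max_len`; `seed`; `out` (JSON output path, optional).
#'
#' @param config a named list, or path to a YAML file with these fields.
#' @return the report as a nested list (invisibly written to
#'   `config$out` as JSON when given).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(ortho_policy = "table_then_casefold", alpha = 0.05,
         use_adjusted = FALSE, q_threshold = 0.05, max_len = 6L,
         seed = 1L), config)
  set.seed(cfg$seed)
  report <- list(config = cfg[setdiff(names(cfg), c("human_model",
                                                    "mouse_model"))],
                 timestamp = format(Sys.time(), tz = "UTC"))
  map <- if (!is.null(cfg$orthology))
    load_orthology_table(cfg$orthology, policy = cfg$ortho_policy)
  else orthology_map(policy = cfg$ortho_policy)

  have_models <- !is.null(cfg$human_model) && !is.null(cfg$mouse_model)
  if (have_models) {
    human <- read_model_input(cfg$human_model, "human")
    mouse <- read_model_input(cfg$mouse_model, "mouse")
    report$model_stats <- list(human = model_stats(human),
                               mouse = model_stats(mouse))
    scope <- if (!is.null(cfg$scope)) load_edge_table(cfg$scope)$edges
    cmp <- compare_models(human, mouse, map, scope = scope)
    report$concordance <- list(
      summary = cmp$summary,
      n_records = nrow(cmp$records),
      n_unique_to_mouse = nrow(cmp$mouse_only),
      records = cmp$records[, c("human_triple", "level", "category",
                                "nonpolar_match", "mixed_evidence")])
  } else {
    report$model_stats <- "skipped"
    report$concordance <- "skipped"
  }

  if (!is.null(cfg$human_de) && !is.null(cfg$mouse_de)) {
    load_all <- function(paths, species) {
      do.call(rbind, lapply(names(paths), function(acc)
        load_de_table(paths[[acc]], species = species, accession = acc)))
    }
    hc <- load_all(cfg$human_de, "human")
    mc <- load_all(cfg$mouse_de, "mouse")
    ct <- concordance_table(hc, mc, map, alpha = cfg$alpha,
                            use_adjusted = cfg$use_adjusted)
    report$expression <- c(summarize_concordance(ct),
                           list(genes = ct))
  } else {
    report$expression <- "skipped"
  }

  if (!is.null(cfg$gene_sets) && have_models) {
    sets <- read_gmt(cfg$gene_sets)
    model_genes <- function(model) {
      ent <- model$entities
      sort(unique(toupper(ent$id[ent$ns %in% c("HGNC", "MGI")])))
    }
    qh <- if (!is.null(cfg$query_human)) readLines(cfg$query_human)
          else model_genes(human)
    qm <- if (!is.null(cfg$query_mouse)) readLines(cfg$query_mouse)
          else model_genes(mouse)
    universe <- unique(c(unlist(sets, use.names = FALSE), qh, qm))
    res_h <- ora(qh, sets, universe)
    res_m <- ora(qm, sets, universe)
    report$enrichment <- list(
      human = res_h, mouse = res_m,
      partition = shared_unique_sets(res_h, res_m, cfg$q_threshold))
  } else {
    report$enrichment <- "skipped"
  }

  if (!is.null(cfg$drug) && have_models) {
    action <- if (inherits(cfg$drug, "drug_action")) cfg$drug
              else load_drug_action(cfg$drug)
    res_h <- propagate(human, action, max_len = cfg$max_len)
    res_m <- propagate(mouse, action, max_len = cfg$max_len)
    agreement <- compare_perturbation(res_h, res_m, map)
    report$perturbation <- list(
      drug = action$drug,
      human_nodes = res_h$nodes, mouse_nodes = res_m$nodes,
      agreement = agreement,
      n_disagree = sum(agreement$outcome == "disagree"))
  } else {
    report$perturbation <- "skipped"
  }

  if (!is.null(cfg$out)) {
    dir.create(dirname(cfg$out), recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, cfg$out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  report
}
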