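## Ground-truth synthetic fixtures ---------------------------------------

#' Largest-remainder apportionment
#'
#' Splits `n` into integer counts proportional to `props` so that the
#' counts sum exactly to `n`: floors first, then the leftover units go to
#' the largest fractional remainders (ties to the earlier category).
#' This makes generated category counts exact rather than sampled.
#'
#' @param n total count.
#' @param props nonnegative proportions summing to 1.
#' @return integer vector of counts summing to `n`.
#' @examples
#' apportion(33, c(0.27, 0.15, 0.58))  # 9, 5, 19
#' @export
apportion <- function(n, props) {
  stopifnot(n >= 0, all(props >= 0), abs(sum(props) - 1) < 1e-8)
  raw <- n * props
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    rem <- raw - counts
    give <- order(-rem, seq_along(rem))[seq_len(left)]
    counts[give] <- counts[give] + 1
  }
  as.integer(counts)
}

.mouse_ify <- function(edges, map = orthology_map()) {
  # translate a human edge table into mouse identifier space
  for (side in c("subject", "object")) {
    ns <- edges[[paste0(side, "_ns")]]
    id <- edges[[paste0(side, "_id")]]
    genic <- ns == "HGNC"
    id[genic] <- vapply(id[genic],
                        function(s) map_symbol(s, map, to = "mouse")[1L],
                        character(1))
    ns[genic] <- "MGI"
    edges[[paste0(side, "_ns")]] <- ns
    edges[[paste0(side, "_id")]] <- id
  }
  edges$species <- "mouse"
  edges
}

.flip_relation <- c(increases = "decreases", decreases = "increases",
                    directlyIncreases = "directlyDecreases",
                    directlyDecreases = "directlyIncreases")

# sample `n` distinct ordered (subject, object) index pairs without
# self-loops, rejecting duplicates by resampling
sample_pairs <- function(n, subj_pool, obj_pool, taken = character(0)) {
  out <- matrix(character(0), ncol = 2)
  guard <- 0L
  while (nrow(out) < n) {
    guard <- guard + 1L
    if (guard > 10000L * max(n, 1L))
      stop("cannot place ", n, " distinct edges over the node pool")
    s <- sample(subj_pool, 1L)
    o <- sample(obj_pool, 1L)
    if (s == o) next
    key <- paste(s, o)
    if (key %in% taken) next
    taken <- c(taken, key)
    out <- rbind(out, c(s, o))
  }
  list(pairs = out, taken = taken)
}

#' Generate one random causal model with exact size
#'
#' Builds a polar model over synthetic gene symbols with exactly
#' `n_nodes` nodes and `n_edges` distinct edges: a random chain first so
#' every node participates, then random distinct ordered pairs.
#'
#' @param n_nodes,n_edges model size; requires
#'   `n_nodes - 1 <= n_edges <= n_nodes * (n_nodes - 1)`.
#' @param species `"human"` or `"mouse"`.
#' @param seed RNG seed.
#' @return a [cause_effect_model()].
#' @export
generate_model <- function(n_nodes, n_edges, species = "human",
                           seed = 1L) {
  stopifnot(n_nodes >= 2, n_edges >= n_nodes - 1,
            n_edges <= n_nodes * (n_nodes - 1))
  set.seed(seed)
  ns <- if (species == "human") "HGNC" else "MGI"
  syms <- casefold_symbol(sprintf("SYG%04d", seq_len(n_nodes)),
                          to = species)
  chain <- sample(syms)
  pairs <- cbind(chain[-n_nodes], chain[-1L])
  taken <- paste(pairs[, 1L], pairs[, 2L])
  extra <- sample_pairs(n_edges - (n_nodes - 1L), syms, syms, taken)
  pairs <- rbind(pairs, extra$pairs)
  edges <- data.frame(
    subject_function = "protein", subject_ns = ns,
    subject_id = pairs[, 1L], subject_mod = NA_character_,
    relation = sample(c("increases", "decreases"), nrow(pairs),
                      replace = TRUE),
    object_function = "protein", object_ns = ns,
    object_id = pairs[, 2L], object_mod = NA_character_,
    species = species, stringsAsFactors = FALSE)
  cause_effect_model(edges, species = species)
}

#' Generate a paired human/mouse model with known edge labels
#'
#' The human model gets `n_edges` polar edges over synthetic HGNC-style
#' symbols (molecular endpoints) and synthetic bioprocess / cell
#' population nodes (cellular endpoints), with exactly
#' `round(n_edges * cellular_fraction)` cellular edges. Each human edge
#' is assigned a ground-truth label by largest-remainder apportionment of
#' the `consistent` / `contradictory` / `unique_to_human` proportions —
#' counts are exact, never sampled. The mouse model is built by
#' orthology-translating each human edge and keeping its sign
#' (consistent), flipping it (contradictory) or omitting it
#' (unique_to_human), plus `n_mouse_only` extra edges over mouse-only
#' symbols. Identical seeds give identical output.
#'
#' The defaults mirror the observed cytokine-pathway comparison: 73
#' interactions of which 33 are molecular, with the molecular
#' consistent/contradictory/unique split of 27/15/58 percent.
#'
#' @param n_edges number of human edges.
#' @param p_consistent,p_contradictory,p_unique label proportions,
#'   summing to 1.
#' @param n_mouse_only extra mouse-specific edges.
#' @param cellular_fraction fraction of human edges with a bioprocess or
#'   cell-population endpoint.
#' @param seed RNG seed.
#' @return list: `human`, `mouse` ([cause_effect_model()]s), `truth`
#'   (data.frame `human_triple`, `label`, `level`), `counts` (named
#'   integer vector of generated label counts).
#' @export
generate_model_pair <- function(n_edges = 73,
                                p_consistent = 0.27,
                                p_contradictory = 0.15,
                                p_unique = 0.58,
                                n_mouse_only = 0L,
                                cellular_fraction = 40 / 73,
                                seed = 1L) {
  stopifnot(n_edges >= 1,
            abs(p_consistent + p_contradictory + p_unique - 1) < 1e-8,
            cellular_fraction >= 0, cellular_fraction <= 1)
  set.seed(seed)
  counts <- apportion(n_edges,
                      c(p_consistent, p_contradictory, p_unique))
  names(counts) <- c("consistent", "contradictory", "unique_to_human")
  n_cellular <- apportion(n_edges,
                          c(1 - cellular_fraction, cellular_fraction))[2L]
  n_mol_nodes <- max(6L, ceiling(1.5 * sqrt(2 * n_edges)))
  mol_pool <- sprintf("SYG%04d", seq_len(n_mol_nodes))
  n_cell_nodes <- max(4L, ceiling(sqrt(2 * max(n_cellular, 1L))))
  bp_pool <- sprintf("GOBP:synthetic process %d",
                     seq_len(ceiling(n_cell_nodes / 2)))
  cp_pool <- sprintf("MESH:synthetic cell type %d",
                     seq_len(floor(n_cell_nodes / 2) + 1L))
  cell_pool <- c(bp_pool, cp_pool)
  taken <- character(0)
  mol <- sample_pairs(n_edges - n_cellular, mol_pool, mol_pool, taken)
  cel <- sample_pairs(n_cellular, mol_pool, cell_pool, mol$taken)
  split_cell <- function(tok) {
    ns <- sub(":.*$", "", tok)
    id <- sub("^[^:]*:", "", tok)
    fun <- ifelse(ns == "GOBP", "bioprocess", "cell_population")
    list(ns = ns, id = id, fun = fun)
  }
  mk_edges <- function(pairs, cellular) {
    n <- nrow(pairs)
    if (n == 0L) return(NULL)
    obj <- if (cellular) split_cell(pairs[, 2L])
           else list(ns = rep("HGNC", n), id = pairs[, 2L],
                     fun = rep("protein", n))
    data.frame(
      subject_function = "protein", subject_ns = "HGNC",
      subject_id = pairs[, 1L], subject_mod = NA_character_,
      relation = sample(c("increases", "decreases"), n, replace = TRUE),
      object_function = obj$fun, object_ns = obj$ns, object_id = obj$id,
      object_mod = NA_character_, species = "human",
      stringsAsFactors = FALSE)
  }
  h_edges <- rbind(mk_edges(mol$pairs, FALSE), mk_edges(cel$pairs, TRUE))
  label <- sample(rep(names(counts), counts))
  keep <- label %in% c("consistent", "contradictory")
  m_edges <- .mouse_ify(h_edges[keep, , drop = FALSE])
  flip <- label[keep] == "contradictory"
  m_edges$relation[flip] <- unname(.flip_relation[m_edges$relation[flip]])
  if (n_mouse_only > 0L) {
    mo_pool <- sprintf("Mog%04d", seq_len(max(
      6L, ceiling(1.5 * sqrt(2 * n_mouse_only)))))
    mo <- sample_pairs(n_mouse_only, mo_pool, mo_pool)
    m_edges <- rbind(m_edges, data.frame(
      subject_function = "protein", subject_ns = "MGI",
      subject_id = mo$pairs[, 1L], subject_mod = NA_character_,
      relation = sample(c("increases", "decreases"), n_mouse_only,
                        replace = TRUE),
      object_function = "protein", object_ns = "MGI",
      object_id = mo$pairs[, 2L], object_mod = NA_character_,
      species = "mouse", stringsAsFactors = FALSE))
  }
  human <- cause_effect_model(h_edges, species = "human")
  mouse <- cause_effect_model(m_edges, species = "mouse")
  list(human = human, mouse = mouse,
       truth = data.frame(human_triple = edge_triples(h_edges),
                          label = label,
                          level = stratify_level(h_edges),
                          stringsAsFactors = FALSE),
       counts = counts)
}

#' Generate DE call tables with known concordance categories
#'
#' Constructs per-gene calls that force each gene's six-way concordance
#' category at the given alpha under the classification rules:
#' significant p-values are drawn strictly below alpha, non-significant
#' ones strictly above; `inconsistent_within_species` genes get one up-
#' and one down-regulated significant call in two datasets of the same
#' species (which therefore requires >= 2 datasets there);
#' `contradictory_between_species` genes are significant in opposite
#' directions across species. Category counts are exact by construction.
#' The default layout mirrors the study design of three datasets per
#' species.
#'
#' @param counts named integer vector over the six categories in
#'   [CONCORDANCE_CATEGORIES] (unnamed vectors are taken in that order).
#' @param n_human_datasets,n_mouse_datasets datasets per species.
#' @param alpha significance threshold the construction targets.
#' @param effect absolute log fold change of significant calls.
#' @param seed RNG seed.
#' @return list: `human`, `mouse` (named lists of GEO2R-layout
#'   data.frames, one per synthetic accession), `truth` (data.frame
#'   `gene_symbol`, `category`).
#' @export
generate_expression_tables <- function(counts = c(31, 14, 19, 17, 7, 12),
                                       n_human_datasets = 3L,
                                       n_mouse_datasets = 3L,
                                       alpha = 0.05, effect = 1.5,
                                       seed = 1L) {
  if (is.null(names(counts))) names(counts) <- CONCORDANCE_CATEGORIES
  stopifnot(setequal(names(counts), CONCORDANCE_CATEGORIES),
            all(counts >= 0), n_human_datasets >= 1L,
            n_mouse_datasets >= 1L)
  counts <- counts[CONCORDANCE_CATEGORIES]
  if (counts[["inconsistent_within_species"]] > 0L &&
      max(n_human_datasets, n_mouse_datasets) < 2L)
    stop("inconsistent_within_species genes need >= 2 datasets in ",
         "at least one species")
  set.seed(seed)
  n_genes <- sum(counts)
  genes <- sprintf("SYEX%03d", seq_len(n_genes))
  category <- sample(rep(names(counts), counts))
  p_sig <- function(k) stats::runif(k, alpha * 0.01, alpha * 0.9)
  p_ns <- function(k) stats::runif(k, alpha * 1.2, 0.99)
  lfc_sig <- function(dir, k = length(dir))
    dir * (effect + stats::runif(k, 0, 0.5))
  lfc_ns <- function(k) stats::runif(k, -0.2, 0.2) + 0.01
  blank <- function(sp, nds) {
    lapply(seq_len(nds), function(d)
      data.frame(Gene.symbol = casefold_symbol(genes, sp),
                 logFC = lfc_ns(n_genes), P.Value = p_ns(n_genes),
                 stringsAsFactors = FALSE))
  }
  hum <- blank("human", n_human_datasets)
  mou <- blank("mouse", n_mouse_datasets)
  set_call <- function(tabs, d, g, dir) {
    tabs[[d]]$logFC[g] <- lfc_sig(dir, 1L)
    tabs[[d]]$P.Value[g] <- p_sig(1L)
    tabs
  }
  incon_species <- if (n_human_datasets >= 2L && n_mouse_datasets >= 2L)
    "either" else if (n_human_datasets >= 2L) "human" else "mouse"
  for (g in seq_len(n_genes)) {
    dir <- sample(c(-1, 1), 1L)
    switch(category[g],
      same_pattern = {
        hum <- set_call(hum, 1L, g, dir)
        mou <- set_call(mou, 1L, g, dir)
      },
      human_only = { hum <- set_call(hum, 1L, g, dir) },
      mouse_only = { mou <- set_call(mou, 1L, g, dir) },
      inconsistent_within_species = {
        sp <- if (incon_species == "either")
          sample(c("human", "mouse"), 1L) else incon_species
        if (sp == "human") {
          hum <- set_call(hum, 1L, g, 1)
          hum <- set_call(hum, 2L, g, -1)
        } else {
          mou <- set_call(mou, 1L, g, 1)
          mou <- set_call(mou, 2L, g, -1)
        }
      },
      contradictory_between_species = {
        hum <- set_call(hum, 1L, g, dir)
        mou <- set_call(mou, 1L, g, -dir)
      },
      non_significant = NULL)
  }
  names(hum) <- sprintf("SYNH%d", seq_len(n_human_datasets))
  names(mou) <- sprintf("SYNM%d", seq_len(n_mouse_datasets))
  list(human = hum, mouse = mou,
       truth = data.frame(gene_symbol = genes, category = category,
                          stringsAsFactors = FALSE))
}
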