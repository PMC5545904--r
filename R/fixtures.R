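## Built-in celecoxib case-study fixtures --------------------------------

crossbel_extdata <- function(file) {
  path <- system.file("extdata", file, package = "crossbel")
  if (!nzchar(path)) stop("bundled file not found: ", file)
  path
}

#' Celecoxib case-study models
#'
#' Curated human and mouse cause-and-effect models around the two
#' celecoxib targets, PTGS2 (cyclooxygenase-2) and PDPK1. The mouse model
#' encodes the interactions reported from transgenic mouse experiments
#' (Pdpk1 sustaining Il4/Ins and inhibiting Ccr2, M1 macrophages and
#' insulin resistance; the Ptgs2 / amyloid-beta / Tnf / Nfkb1
#' self-regulatory loop; the Gsk3b--tau axis). The human model encodes
#' the normal-physiology pathways whose perturbation is predicted upon
#' celecoxib administration (the PDPK1--AKT1--TSC2--RHEB--MTOR--autophagy
#' cascade, the AMPK branch, IL-4 and insulin signalling, and the PTGS2
#' amyloid route).
#'
#' @return list with `human` and `mouse` [cause_effect_model()]s.
#' @examples
#' mods <- celecoxib_models()
#' model_stats(mods$mouse)
#' @export
celecoxib_models <- function() {
  list(human = load_edge_table(crossbel_extdata("celecoxib_human_edges.tsv")),
       mouse = load_edge_table(crossbel_extdata("celecoxib_mouse_edges.tsv")))
}

#' Celecoxib drug action
#'
#' Celecoxib inhibits both of its main targets, PTGS2 and PDPK1.
#'
#' @return a [drug_action()].
#' @export
celecoxib_action <- function() {
  drug_action("celecoxib",
              data.frame(id = c("PTGS2", "PDPK1"), sign = c(-1L, -1L)))
}

#' Bundled human--mouse orthology table
#'
#' Curated HGNC/MGI symbol pairs for the genes of the celecoxib case
#' study.
#'
#' @inheritParams orthology_map
#' @return an [orthology_map()].
#' @export
neuroinflammation_orthology <- function(policy = c("table_then_casefold",
                                                   "table_only")) {
  load_orthology_table(crossbel_extdata("hgnc_mgi_orthology.tsv"),
                       policy = match.arg(policy))
}

#' Path to the bundled example gene-set collection
#'
#' A small synthetic GMT of neuroinflammation-themed gene sets for
#' demonstrating [ora()].
#'
#' @return file path.
#' @export
neuroinflammation_gmt <- function() {
  crossbel_extdata("neuroinflammation_sets.gmt")
}
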