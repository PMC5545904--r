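#' @keywords internal
"_PACKAGE"

## Controlled vocabularies -----------------------------------------------

#' Supported entity function classes
#' @export
ENTITY_FUNCTIONS <- c("protein", "gene", "chemical", "bioprocess",
                      "cell_population", "complex")

#' Supported namespaces
#' @export
NAMESPACES <- c("HGNC", "MGI", "CHEBI", "GOBP", "MESH", "OTHER")

#' Supported causal relations
#' @export
RELATIONS <- c("increases", "directlyIncreases", "decreases",
               "directlyDecreases", "association", "causesNoChange")

# namespaces that pin an entity to one species
.species_ns <- c(HGNC = "human", MGI = "mouse")

# function classes that count as molecular endpoints
.molecular_functions <- c("protein", "gene", "chemical", "complex")

#' Polarity of a causal relation
#'
#' Maps each supported relation to its effect sign: `increases` and
#' `directlyIncreases` to +1, `decreases` and `directlyDecreases` to -1,
#' `association` and `causesNoChange` to 0. The mapping is total over
#' [RELATIONS]; any other input is an error.
#'
#' @param relation character vector of relation keywords.
#' @return integer vector of signs in \{-1, 0, 1\}.
#' @examples
#' relation_polarity(c("increases", "decreases", "association"))
#' @export
relation_polarity <- function(relation) {
  pol <- c(increases = 1L, directlyIncreases = 1L,
           decreases = -1L, directlyDecreases = -1L,
           association = 0L, causesNoChange = 0L)
  bad <- setdiff(unique(relation), names(pol))
  if (length(bad) > 0L)
    stop("unsupported relation(s): ", paste(bad, collapse = ", "))
  unname(pol[relation])
}

#' Construct an entity
#'
#' An entity is a typed node of a cause-and-effect model: a function class
#' (protein, gene, chemical, bioprocess, cell population or complex), a
#' namespace, an identifier, and an optional modification tag such as a
#' phosphorylation (`pmod(P)`) or an activity wrapper (`act`).
#' Modifications are decorations on the entity, never separate nodes, and
#' are only allowed on proteins and genes.
#'
#' @param fun function class, one of [ENTITY_FUNCTIONS].
#' @param ns namespace, one of [NAMESPACES].
#' @param id identifier string (non-empty; may contain spaces/unicode).
#' @param mod optional modification/activity tag (`NA` for none).
#' @return a one-row data.frame with columns `fun`, `ns`, `id`, `mod`.
#' @examples
#' entity("protein", "HGNC", "PTGS2")
#' entity("chemical", "CHEBI", "amyloid-beta")
#' @export
entity <- function(fun, ns, id, mod = NA_character_) {
  fun <- match.arg(fun, ENTITY_FUNCTIONS)
  ns <- match.arg(ns, NAMESPACES)
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id))
    stop("entity identifier must be a non-empty string")
  if (!is.na(mod) && !fun %in% c("protein", "gene"))
    stop("modification tags are only allowed on protein/gene entities, not ",
         fun)
  data.frame(fun = fun, ns = ns, id = id, mod = mod,
             stringsAsFactors = FALSE)
}

# canonical string for an entity; `with_mod` controls whether the
# modification decoration takes part in identity (strict matching)
entity_key <- function(fun, ns, id, mod = NA_character_, with_mod = TRUE) {
  base <- paste0(fun, "|", ns, ":", id)
  if (with_mod) {
    mod <- ifelse(is.na(mod) | mod == "", "", paste0("|", mod))
    paste0(base, mod)
  } else base
}

# species implied by a namespace (NA when species-neutral)
namespace_species <- function(ns) {
  out <- .species_ns[ns]
  unname(out)
}
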