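#' @import methods
NULL

setClassUnion("DNAStringOrNULL", c("DNAString", "NULL"))

#' GenomeAnnotation: one taxon's annotated circular mitogenome
#'
#' Container for a single circular (or linear) mitochondrial genome:
#' genome length, an ordered table of gene records and, optionally, the
#' nucleotide sequence.
#'
#' The \code{genes} slot is a \code{data.frame} with columns \code{gene}
#' (canonical token), \code{strand} (\code{"+"}/\code{"-"} on the majority
#' strand), \code{start}, \code{stop} (1-based inclusive positions on the
#' majority strand; genes may span the origin, in which case
#' \code{stop < start}), \code{size} (nt, computed on the circle),
#' \code{category} (\code{PCG}/\code{tRNA}/\code{rRNA}/\code{noncoding}),
#' \code{anticodon}, \code{start_codon}, \code{stop_codon} (optional,
#' \code{NA} when absent).
#'
#' @slot taxonId character(1) free-text taxon identifier.
#' @slot accession character(1) sequence accession, may be \code{NA}.
#' @slot genomeLength integer(1) genome length in nt.
#' @slot circular logical(1).
#' @slot genes data.frame of gene records sorted by start.
#' @slot sequence \code{DNAString} of length \code{genomeLength}, or NULL.
#'
#' @aliases GenomeAnnotation-class
#' @exportClass GenomeAnnotation
setClass("GenomeAnnotation",
  representation(taxonId = "character", accession = "character",
                 genomeLength = "integer", circular = "logical",
                 genes = "data.frame", sequence = "DNAStringOrNULL"),
  prototype(accession = NA_character_, circular = TRUE, sequence = NULL))

setValidity("GenomeAnnotation", function(object) {
  g <- object@genes
  need <- c("gene", "strand", "start", "stop", "size", "category")
  if (!all(need %in% names(g)))
    return(paste("genes table must have columns:", paste(need, collapse = ", ")))
  if (any(!g$strand %in% c("+", "-"))) return("strand must be '+' or '-'")
  if (any(g$start < 1L) || any(g$stop < 1L))
    return("coordinates must be positive")
  if (any(g$stop > object@genomeLength) || any(g$start > object@genomeLength))
    return("coordinates exceed genome length")
  L <- object@genomeLength
  expect <- circularSize(g$start, g$stop, L)
  if (any(g$size != expect))
    return("size column inconsistent with circular coordinates")
  if (!object@circular && any(g$stop < g$start))
    return("origin-spanning gene (stop < start) in a non-circular genome")
  coding <- g$gene[g$category != "noncoding"]
  if (anyDuplicated(coding))
    return(paste("duplicated gene:", coding[duplicated(coding)][1L]))
  if (sum(g$gene == "CR") > 1L) return("at most one CR allowed")
  if (!is.null(object@sequence) && length(object@sequence) != L)
    return("sequence length != genomeLength")
  TRUE
})

#' GeneOrder: signed circular permutation of the canonical genes
#'
#' A circular gene order: gene tokens with transcription-strand signs
#' (+1 majority, -1 minority), stored in canonical rotation (beginning at
#' \code{cox1}). The control region may optionally be carried as an extra
#' locus (see \code{includeCR} arguments downstream).
#'
#' @slot taxonId character(1).
#' @slot genes character vector of tokens in circular reading order.
#' @slot signs integer vector of +1/-1, one per gene.
#'
#' @aliases GeneOrder-class
#' @exportClass GeneOrder
setClass("GeneOrder",
  representation(taxonId = "character", genes = "character",
                 signs = "integer"))

setValidity("GeneOrder", function(object) {
  if (length(object@genes) != length(object@signs))
    return("genes and signs differ in length")
  if (any(!object@signs %in% c(-1L, 1L))) return("signs must be +1/-1")
  if (anyDuplicated(object@genes))
    return(paste("duplicated token:", object@genes[duplicated(object@genes)][1L]))
  bad <- setdiff(object@genes, c(mitoGeneTokens(), mitoNoncodingLoci()))
  if (length(bad) > 0L)
    return(paste("unknown token(s):", paste(bad, collapse = ", ")))
  TRUE
})

#' RearrangementEvent: one gene-order rearrangement
#'
#' @slot kind one of \code{"transposition"}, \code{"inversion"},
#'   \code{"inverse_transposition"}, \code{"tdrl"}.
#' @slot genes tokens involved (for tdrl, the duplicated block).
#' @slot description human-readable summary.
#' @slot params replay parameters: for moves, \code{anchor} (token after
#'   which the block is reinserted, or \code{".origin"}) and \code{signs};
#'   for tdrl, \code{keep1} (logical: which block genes survive from the
#'   first tandem copy).
#'
#' @aliases RearrangementEvent-class
#' @exportClass RearrangementEvent
setClass("RearrangementEvent",
  representation(kind = "character", genes = "character",
                 description = "character", params = "list"),
  prototype(params = list()))

setValidity("RearrangementEvent", function(object) {
  kinds <- c("transposition", "inversion", "inverse_transposition", "tdrl")
  if (!object@kind %in% kinds)
    return(paste("kind must be one of:", paste(kinds, collapse = ", ")))
  TRUE
})

#' EventScenario: an ordered list of events transforming one order into another
#'
#' @slot source,target \code{GeneOrder} objects.
#' @slot events list of \code{RearrangementEvent}.
#' @slot resolved logical(1): TRUE if replaying \code{events} on
#'   \code{source} reproduces \code{target} exactly.
#'
#' @aliases EventScenario-class
#' @exportClass EventScenario
setClass("EventScenario",
  representation(source = "GeneOrder", target = "GeneOrder",
                 events = "list", resolved = "logical"))

#' BoundaryCatalog: classified gene boundaries across a taxon panel
#'
#' Produced by \code{\link{classifyBoundaries}}. The \code{boundaries}
#' slot is a long data.frame with one row per (taxon, boundary): columns
#' \code{taxon}, \code{left}, \code{right} (signed tokens, canonical
#' reading direction), \code{key} (matching key under the chosen
#' signed/unsigned convention) and \code{status}
#' (\code{"plesiomorphic"}/\code{"derived"}).
#'
#' @slot boundaries data.frame, one row per taxon x boundary.
#' @slot ancestorKeys character: boundary keys of the ancestral order.
#' @slot signed logical(1): whether strand signs entered boundary identity.
#' @slot includeCR logical(1): whether CR was carried as a locus.
#'
#' @aliases BoundaryCatalog-class
#' @exportClass BoundaryCatalog
setClass("BoundaryCatalog",
  representation(boundaries = "data.frame", ancestorKeys = "character",
                 signed = "logical", includeCR = "logical"))

# ---- show methods ----

setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation:", object@taxonId,
      if (!is.na(object@accession)) paste0("(", object@accession, ")"), "\n")
  cat("  ", object@genomeLength, " bp, ",
      if (object@circular) "circular" else "linear", ", ",
      nrow(object@genes), " annotated loci, sequence ",
      if (is.null(object@sequence)) "absent" else "present", "\n", sep = "")
  tab <- table(object@genes$category)
  cat("  ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n", sep = "")
})

setMethod("show", "GeneOrder", function(object) {
  cat("GeneOrder:", object@taxonId, "(", length(object@genes), "loci )\n")
  cat(" ", paste0(ifelse(object@signs < 0L, "-", ""), object@genes,
                  collapse = " "), "\n")
})

setMethod("show", "RearrangementEvent", function(object) {
  cat(object@kind, ": ", object@description, "\n", sep = "")
})

setMethod("show", "EventScenario", function(object) {
  cat("EventScenario:", object@source@taxonId, "->", object@target@taxonId,
      "|", length(object@events), "event(s),",
      if (object@resolved) "replays exactly" else "UNRESOLVED residue", "\n")
  for (e in object@events) cat("  - ", e@kind, ": ", e@description, "\n",
                               sep = "")
})

setMethod("show", "BoundaryCatalog", function(object) {
  s <- boundarySummary(object)
  cat("BoundaryCatalog over", length(unique(object@boundaries$taxon)),
      "taxa (", if (object@signed) "signed" else "sign-insensitive",
      "matching,", if (object@includeCR) "CR included" else "CR excluded",
      ")\n")
  cat("  derived total:", s$derived_total, "| unique:", s$unique,
      "| shared types:", s$shared_types, "repeated", s$shared_repeats,
      "times\n")
})

# ---- basic accessors ----

#' Accessors for GenomeAnnotation and GeneOrder
#'
#' @param x a \code{GenomeAnnotation} or \code{GeneOrder}.
#' @return \code{taxonId}: character(1); \code{genomeLength}: integer(1);
#'   \code{genes}: the gene table (data.frame); \code{genomeSequence}: a
#'   \code{DNAString} or NULL; \code{orderTokens}: signed token vector
#'   (\code{"-"} prefix marks minority strand).
#' @name accessors
NULL

#' @rdname accessors
#' @export
taxonId <- function(x) x@taxonId

#' @rdname accessors
#' @export
genomeLength <- function(x) x@genomeLength

#' @rdname accessors
#' @export
genes <- function(x) x@genes

#' @rdname accessors
#' @export
genomeSequence <- function(x) x@sequence

#' @rdname accessors
#' @export
orderTokens <- function(x) {
  stopifnot(is(x, "GeneOrder"))
  paste0(ifelse(x@signs < 0L, "-", ""), x@genes)
}

#' @rdname accessors
#' @param scenario an \code{EventScenario}.
#' @export
scenarioEvents <- function(scenario) scenario@events
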