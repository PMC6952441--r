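## Packaged fixtures: the tarantula annotation table, the ancestral
## arthropod gene order, the 17-taxon spider order panel and the
## reference topology used for synapomorphy mapping.

fixturePath <- function(file) {
  p <- system.file("extdata", file, package = "mitocomp")
  if (!nzchar(p)) stop("fixture not found: ", file)
  p
}

#' Packaged fixtures
#'
#' \code{lyrognathusCrotalusAnnotation}: the annotated mitogenome table
#' of the tarantula \emph{Lyrognathus crotalus} (accession MN072398),
#' 13,866 bp, 37 genes plus control region.
#' \code{ancestralArthropodOrder}: the ancestral arthropod
#' (\emph{Limulus polyphemus}) 37-gene order (plus CR as a 38th locus).
#' \code{spiderOrderPanel}: the 17-taxon spider gene-order panel plus
#' the Limulus outgroup; rows not fixed by published coordinates are
#' reconstructions from the published narrative (see the provenance
#' column and the \code{provenance} attribute).
#' \code{referenceTopology}: the reference tree (ML-1 style topology)
#' used for synapomorphy mapping, as an \code{ape::phylo}.
#' \code{olSequence}: the printed 27-nt light-strand replication origin
#' (OL) sequence.
#'
#' @return See above; \code{spiderOrderPanel} returns a named list of
#'   \code{\linkS4class{GeneOrder}} (CR included as a locus).
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
lyrognathusCrotalusAnnotation <- function() {
  readGeneTable(fixturePath("lyrognathus_crotalus_gene_table.tsv"))
}

#' @rdname fixtures
#' @param includeCR carry CR as an extra locus? Default TRUE.
#' @export
ancestralArthropodOrder <- function(includeCR = TRUE) {
  o <- spiderOrderPanel()[["Limulus_polyphemus"]]
  if (!includeCR) o <- dropCR(o)
  o
}

#' @rdname fixtures
#' @export
spiderOrderPanel <- function() {
  tab <- utils::read.delim(fixturePath("spider_gene_orders.tsv"),
                           comment.char = "#", stringsAsFactors = FALSE)
  orders <- lapply(seq_len(nrow(tab)), function(i)
    geneOrder(strsplit(tab$order[i], "\\s+")[[1L]], taxonId = tab$taxon[i]))
  names(orders) <- tab$taxon
  attr(orders, "provenance") <- tab[, c("taxon", "family", "group",
                                        "provenance")]
  orders
}

#' @rdname fixtures
#' @export
referenceTopology <- function() {
  ape::read.tree(fixturePath("ml1_tree.nwk"))
}

#' @rdname fixtures
#' @export
olSequence <- function() "TCCTCCTCCGCGGAAAAGAGAGGAGGA"
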