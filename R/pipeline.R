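#' Run the full comparative-mitogenomics analysis
#'
#' Orchestrates the pipeline stages over a set of annotated genomes and
#' a gene-order panel: annotation arithmetic (spacers/overlaps),
#' composition and skews (when sequence is available), codon usage,
#' boundary classification against the ancestor, conserved blocks,
#' synapomorphy mapping, event inference and the breakpoint-distance
#' gene-order tree. Stages can be toggled; disabling one never changes
#' another stage's numbers. When \code{outDir} is given, per-stage TSVs
#' and a JSON master report are written.
#'
#' @param genomes list of \code{GenomeAnnotation} (default: the packaged
#'   tarantula annotation).
#' @param panel named list of \code{GeneOrder} including the ancestor
#'   (default: the packaged spider panel).
#' @param ancestorId name of the ancestral order within \code{panel}.
#' @param tree reference topology for synapomorphy mapping (tips =
#'   panel taxa minus the ancestor).
#' @param stages character vector of stages to run; any of
#'   \code{"annotation"}, \code{"composition"}, \code{"codon"},
#'   \code{"boundaries"}, \code{"events"}, \code{"phylogeny"}.
#' @param signed,includeCR boundary-identity conventions for the
#'   boundary stage.
#' @param outDir optional output directory.
#' @return list of per-stage results (invisibly when \code{outDir} is
#'   used).
#' @export
runAll <- function(genomes = list(lyrognathusCrotalusAnnotation()),
                   panel = spiderOrderPanel(),
                   ancestorId = "Limulus_polyphemus",
                   tree = referenceTopology(),
                   stages = c("annotation", "composition", "codon",
                              "boundaries", "events", "phylogeny"),
                   signed = TRUE, includeCR = FALSE, outDir = NULL) {
  if (length(genomes) == 0L) stop("usage: at least one genome required")
  if (!ancestorId %in% names(panel))
    stop("ancestor '", ancestorId, "' not in panel")
  res <- list()
  if ("annotation" %in% stages) {
    res$annotation <- lapply(genomes, function(g) list(
      taxon = g@taxonId, genome_length = g@genomeLength,
      gene_table = g@genes, spacers = spacerReport(g),
      total_by_category = tapply(g@genes$size, g@genes$category, sum)))
  }
  if ("composition" %in% stages) {
    withSeq <- Filter(function(g) !is.null(g@sequence), genomes)
    res$composition <- lapply(withSeq, partitionComposition)
    if (length(res$composition) == 0L)
      message("composition stage: no genome carries sequence; skipped")
  }
  if ("codon" %in% stages) {
    res$codon <- startStopTable(genomes)
    withSeq <- Filter(function(g) !is.null(g@sequence), genomes)
    res$codon$usage <- lapply(withSeq, function(g) {
      pcgs <- g@genes$gene[g@genes$category == "PCG"]
      cc <- codonCounts(paste0(vapply(pcgs, function(p)
        as.character(geneSequence(g, p)), character(1L)), collapse = ""),
        label = g@taxonId)
      codonUsageSummary(cc)
    })
  }
  anc <- panel[[ancestorId]]
  taxa <- panel[names(panel) != ancestorId]
  if ("boundaries" %in% stages) {
    catalog <- classifyBoundaries(taxa, anc, signed = signed,
                                  includeCR = includeCR)
    res$boundaries <- list(
      catalog = catalog, summary = boundarySummary(catalog),
      blocks = conservedBlocks(taxa, anc, signed = signed,
                               includeCR = includeCR),
      synapomorphies = if (!is.null(tree)) {
        tr <- asPhylo(tree)
        tr <- ape::drop.tip(tr, setdiff(tr$tip.label, names(taxa)))
        synapomorphicBoundaries(catalog, tr)
      })
  }
  if ("events" %in% stages) {
    res$events <- lapply(taxa, function(o) inferEvents(anc, o))
  }
  if ("phylogeny" %in% stages) {
    res$phylogeny <- geneOrderTree(taxa, signed = signed)
  }
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(res$boundaries)) {
      utils::write.table(res$boundaries$catalog@boundaries,
                         file.path(outDir, "boundary_catalog.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(res$boundaries$blocks,
                         file.path(outDir, "conserved_blocks.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(res$phylogeny))
      ape::write.tree(res$phylogeny, file.path(outDir, "gene_order_tree.nwk"))
    master <- list(
      stages = stages,
      boundary_summary = if (!is.null(res$boundaries))
        res$boundaries$summary[c("derived_total", "unique", "shared_types",
                                 "shared_repeats")],
      events = if (!is.null(res$events)) lapply(res$events, function(s)
        vapply(s@events, function(e) e@description, character(1L))))
    jsonlite::write_json(master, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    return(invisible(res))
  }
  res
}
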