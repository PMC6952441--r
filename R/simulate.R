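## Synthetic-data generation with known ground truth: gene orders
## evolved by logged rearrangement events, codon alignments under a
## simple mutation-selection process, and fully annotated artificial
## genomes with planted control-region features.

#' Simulate gene orders along a tree with logged events
#'
#' Starting from \code{rootOrder} (default: the ancestral arthropod
#' fixture), rearrangement events are drawn independently on every
#' branch and applied; the per-branch truth log allows exact replay.
#' Event kinds are drawn from \code{kindWeights}; single-gene moves pick
#' a uniformly random gene and destination, inversions flip a short
#' contiguous block (1-3 genes), and TDRLs duplicate a contiguous block
#' of 3-6 genes and lose a random copy of each gene. The canonical
#' anchor gene (\code{cox1}) and the control region never move.
#'
#' @param tree \code{phylo}, Newick string/file, or an integer number of
#'   taxa (a random coalescent-shaped topology is drawn).
#' @param eventsPerBranch expected events per branch (Poisson), or an
#'   exact integer count when \code{fixedCount = TRUE}.
#' @param kindWeights named weights for
#'   transposition/inversion/inverse_transposition/tdrl.
#' @param rootOrder \code{GeneOrder} at the root.
#' @param seed integer seed; identical inputs give identical output.
#' @param fixedCount use \code{eventsPerBranch} as an exact count?
#' @return list: \code{tree}, \code{tips} (named list of
#'   \code{GeneOrder}), \code{truth} (per-branch event lists, named
#'   "parent->child"), \code{node_orders}.
#' @export
evolveOrders <- function(tree = 6L, eventsPerBranch = 1,
                         kindWeights = c(transposition = 0.5,
                                         inversion = 0.2,
                                         inverse_transposition = 0.15,
                                         tdrl = 0.15),
                         rootOrder = ancestralArthropodOrder(includeCR = FALSE),
                         seed = 1L, fixedCount = FALSE) {
  set.seed(seed)
  if (is.numeric(tree)) {
    nt <- as.integer(tree)
    tree <- ape::rtree(nt, br = NULL)
    tree$tip.label <- paste0("t", seq_len(nt))
  } else tree <- asPhylo(tree)
  ntip <- length(tree$tip.label)
  nodeOrders <- vector("list", ntip + tree$Nnode)
  root <- ntip + 1L
  nodeOrders[[root]] <- canonicalRotation(rootOrder)
  truth <- list()
  # preorder: parents before children
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  for (k in seq_len(nrow(edges))) {
    parent <- edges[k, 1L]; child <- edges[k, 2L]
    ord <- nodeOrders[[parent]]
    nEv <- if (fixedCount) as.integer(eventsPerBranch) else
      stats::rpois(1L, eventsPerBranch)
    evs <- list()
    if (nEv > 0L) for (j in seq_len(nEv)) {
      ev <- randomEvent(ord, kindWeights)
      ord <- applyEvent(ord, ev)
      evs[[length(evs) + 1L]] <- ev
    }
    truth[[paste0(parent, "->", child)]] <- evs
    nodeOrders[[child]] <- ord
  }
  tips <- nodeOrders[seq_len(ntip)]
  names(tips) <- tree$tip.label
  for (i in seq_len(ntip)) tips[[i]]@taxonId <- tree$tip.label[i]
  list(tree = tree, tips = tips, truth = truth, node_orders = nodeOrders)
}

randomEvent <- function(order, kindWeights) {
  kinds <- names(kindWeights)
  kind <- sample(kinds, 1L, prob = kindWeights)
  n <- length(order@genes)
  movable <- setdiff(order@genes[-1L], "CR")
  if (kind %in% c("transposition", "inverse_transposition")) {
    g <- sample(movable, 1L)
    anchors <- setdiff(order@genes, g)
    anchor <- sample(anchors, 1L)
    s <- order@signs[match(g, order@genes)]
    newSign <- if (kind == "inverse_transposition") -s else s
    makeEvent(kind, g,
              paste0(sub("_", " ", kind), " of ", g, " to after ", anchor),
              params = list(anchor = anchor,
                            signs = if (kind == "inverse_transposition")
                              -newSign else newSign))
  } else if (kind == "inversion") {
    len <- sample(1:3, 1L)
    start <- sample(2:(n - len), 1L)
    blk <- order@genes[start:(start + len - 1L)]
    blk <- setdiff(blk, "CR")
    if (length(blk) == 0L) blk <- sample(movable, 1L)
    # keep block contiguous: if CR fell inside, fall back to one gene
    idx <- match(blk, order@genes)
    if (length(blk) > 1L && any(diff(idx) != 1L)) blk <- blk[1L]
    makeEvent("inversion", blk,
              paste0("inversion of ", paste(blk, collapse = "-")))
  } else {
    len <- sample(3:6, 1L)
    start <- sample(2:(n - len), 1L)
    blk <- order@genes[start:(start + len - 1L)]
    if ("CR" %in% blk) blk <- setdiff(blk, "CR")
    idx <- match(blk, order@genes)
    if (any(diff(idx) != 1L) || length(blk) < 3L)
      return(randomEvent(order, kindWeights))  # redraw near CR
    keep1 <- sample(c(TRUE, FALSE), length(blk), replace = TRUE)
    if (all(keep1) || all(!keep1)) keep1[1L] <- !keep1[1L]
    anchor <- order@genes[idx[1L] - 1L]
    makeEvent("tdrl", blk,
              paste0("tandem duplication-random loss over block ",
                     paste(blk, collapse = "-")),
              params = list(anchor = anchor, keep1 = keep1))
  }
}

# ---- codon-sequence simulation ----

stationaryCodon <- function(gc3, gc12, gc) {
  bases <- c("A", "C", "G", "T")
  p12 <- c((1 - gc12) / 2, gc12 / 2, gc12 / 2, (1 - gc12) / 2)
  p3 <- c((1 - gc3) / 2, gc3 / 2, gc3 / 2, (1 - gc3) / 2)
  repeat {
    cdn <- paste0(sample(bases, 1L, prob = p12),
                  sample(bases, 1L, prob = p12),
                  sample(bases, 1L, prob = p3))
    if (gc[[cdn]] != "*") return(cdn)
  }
}

mutateCodons <- function(codons, branchLength, omega, kappa, gc3, gc) {
  bases <- c("A", "C", "G", "T")
  p3 <- c((1 - gc3) / 2, gc3 / 2, gc3 / 2, (1 - gc3) / 2)
  names(p3) <- bases
  nAttempt <- stats::rpois(1L, branchLength * 3L * length(codons))
  if (nAttempt == 0L) return(codons)
  for (a in seq_len(nAttempt)) {
    i <- sample.int(length(codons), 1L)
    pos <- sample.int(3L, 1L)
    cdn <- codons[i]
    cb <- substr(cdn, pos, pos)
    alt <- setdiff(bases, cb)
    w <- vapply(alt, function(b) {
      ts <- transitionPair(cb, b)
      wt <- if (ts) kappa else 1
      if (pos == 3L) wt * 4 * p3[[b]] else wt
    }, numeric(1L))
    nb <- sample(alt, 1L, prob = w)
    mut <- cdn
    substr(mut, pos, pos) <- nb
    if (gc[[mut]] == "*") next
    accept <- if (gc[[mut]] == gc[[cdn]]) 1 else omega
    if (stats::runif(1L) < accept) codons[i] <- mut
  }
  codons
}

#' Simulate an aligned coding-sequence panel with known parameters
#'
#' Star-phylogeny codon simulation: one stationary ancestral sequence
#' per gene, then each taxon evolves independently for
#' \code{branchLength} expected mutation attempts per nucleotide site
#' under a simple mutation-selection process (third-position GC bias
#' \code{gc3}, transition/transversion weight \code{kappa},
#' nonsynonymous acceptance probability \code{omega}; mutations to stop
#' codons rejected). No indels, no rate heterogeneity: a calibration
#' instrument for the estimators, not a biological model.
#'
#' @param genes named integer vector: gene -> number of codons.
#' @param nTaxa taxa per gene.
#' @param omega nonsynonymous/synonymous acceptance ratio; may be a
#'   single value or one per gene.
#' @param kappa transition/transversion weight.
#' @param gc3 target third-position GC fraction.
#' @param gc12 first/second-position GC fraction of the ancestor.
#' @param branchLength expected mutation attempts per site per branch.
#' @param seed integer seed.
#' @param codeId NCBI translation table id.
#' @return list: \code{alignments} (gene -> named character vector of
#'   CDS), \code{params} (the generating values).
#' @export
simulateCdsPanel <- function(genes = c(gene1 = 300L), nTaxa = 4L,
                             omega = 0.3, kappa = 2, gc3 = 0.2,
                             gc12 = 0.35, branchLength = 0.1, seed = 1L,
                             codeId = "5") {
  set.seed(seed)
  gc <- as.list(codeTable(codeId))
  omega <- rep_len(omega, length(genes))
  names(omega) <- names(genes)
  alignments <- list()
  for (g in names(genes)) {
    anc <- vapply(seq_len(genes[[g]]), function(i)
      stationaryCodon(gc3, gc12, gc), character(1L))
    seqs <- vapply(seq_len(nTaxa), function(t)
      paste0(mutateCodons(anc, branchLength, omega[[g]], kappa, gc3, gc),
             collapse = ""), character(1L))
    names(seqs) <- paste0("t", seq_len(nTaxa))
    alignments[[g]] <- seqs
  }
  list(alignments = alignments,
       params = list(genes = genes, nTaxa = nTaxa, omega = omega,
                     kappa = kappa, gc3 = gc3, gc12 = gc12,
                     branchLength = branchLength, seed = seed))
}

# ---- whole-genome construction ----

randomSeq <- function(n, atFraction = 0.7) {
  if (n <= 0L) return("")
  paste0(sample(c("A", "T", "G", "C"), n, replace = TRUE,
                prob = c(atFraction / 2, atFraction / 2,
                         (1 - atFraction) / 2, (1 - atFraction) / 2)),
         collapse = "")
}

randomCds <- function(nCodons, gc, atFraction = 0.7) {
  body <- character(nCodons - 2L)
  for (i in seq_along(body)) {
    repeat {
      cdn <- randomSeq(3L, atFraction)
      if (!is.na(match(cdn, names(gc))) && gc[[cdn]] != "*") break
    }
    body[i] <- cdn
  }
  paste0("ATG", paste0(body, collapse = ""), "TAA")
}

buildControlRegion <- function(length = 365L, atFraction = 0.68,
                               plantedRepeats = list(c("ATTTTTATTC", 2L),
                                                     c("CATATA", 6L)),
                               plantedHairpin = c(stem = 7L, loop = 13L)) {
  pieces <- character(0L)
  if (!is.null(plantedHairpin)) {
    stem <- randomSeq(plantedHairpin[["stem"]], atFraction = 0.3)
    loop <- randomSeq(plantedHairpin[["loop"]], atFraction = 0.8)
    rcStem <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(stem)))
    pieces <- c(pieces, paste0(stem, loop, rcStem))
  }
  for (pr in plantedRepeats)
    pieces <- c(pieces, strrep(pr[[1L]], as.integer(pr[[2L]])))
  spacerN <- max(0L, length - sum(nchar(pieces)) - 4L * length(pieces))
  per <- spacerN %/% (length(pieces) + 1L)
  out <- randomSeq(per, atFraction)
  for (p in pieces) out <- paste0(out, p, "GGCC",
                                  randomSeq(per, atFraction))
  # GGCC separators stop planted arrays from extending into the flanks
  if (nchar(out) < length) out <- paste0(out, randomSeq(length - nchar(out),
                                                        atFraction))
  out
}

#' Build a fully annotated synthetic genome
#'
#' Lays the genes of \code{order} on a circle with a configurable
#' intergenic pattern, generates per-gene sequences (PCGs in frame with
#' ATG/TAA, no internal stops on the coding strand; minority-strand
#' genes placed as reverse complements) and a control region with
#' planted tandem repeats and a planted stem-loop. With
#' \code{originOffset > 0} the coordinate origin is rotated so that a
#' gene spans the origin.
#'
#' @param order a \code{GeneOrder} (may include CR).
#' @param ign intergenic nucleotides between consecutive genes
#'   (recycled; negative values create overlaps).
#' @param pcgCodons codons per protein-coding gene.
#' @param trnaSize,rrnaSize tRNA/rRNA lengths (nt).
#' @param crModel list passed to the control-region builder: components
#'   \code{length}, \code{atFraction}, \code{plantedRepeats},
#'   \code{plantedHairpin}.
#' @param originOffset rotate coordinates by this many nt (default 0).
#' @param seed integer seed.
#' @param codeId NCBI translation table id.
#' @param taxonId taxon label.
#' @return A \code{\linkS4class{GenomeAnnotation}} with sequence.
#' @export
buildGenome <- function(order = ancestralArthropodOrder(includeCR = TRUE),
                        ign = 2L, pcgCodons = 100L, trnaSize = 60L,
                        rrnaSize = 500L, crModel = list(),
                        originOffset = 0L, seed = 1L, codeId = "5",
                        taxonId = "synthetic") {
  set.seed(seed)
  gc <- as.list(codeTable(codeId))
  toks <- order@genes
  signs <- order@signs
  n <- length(toks)
  ign <- rep_len(as.integer(ign), n)
  crDefaults <- list(length = 365L, atFraction = 0.68,
                     plantedRepeats = list(c("ATTTTTATTC", 2L),
                                           c("CATATA", 6L)),
                     plantedHairpin = c(stem = 7L, loop = 13L))
  crModel <- utils::modifyList(crDefaults, crModel)
  cat_ <- geneCategory(toks)
  seqs <- character(n)
  for (i in seq_len(n)) {
    seqs[i] <- switch(cat_[i],
      PCG = randomCds(pcgCodons, gc),
      tRNA = randomSeq(trnaSize),
      rRNA = randomSeq(rrnaSize),
      noncoding = if (toks[i] == "CR")
        do.call(buildControlRegion, crModel) else randomSeq(30L))
  }
  sizes <- nchar(seqs)
  if (any(-ign >= sizes)) stop("requested overlap exceeds gene size")
  starts <- integer(n); stops <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    starts[i] <- pos
    stops[i] <- pos + sizes[i] - 1L
    pos <- stops[i] + 1L + ign[i]
  }
  L <- stops[n] + ign[n]
  if (L < stops[n]) stop("terminal overlap would wrap the origin")
  chars <- strsplit(randomSeq(L), "")[[1L]]
  for (i in seq_len(n)) {
    s <- seqs[i]
    if (signs[i] < 0L)
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    chars[starts[i]:stops[i]] <- strsplit(s, "")[[1L]]
  }
  if (originOffset > 0L) {
    off <- originOffset %% L
    chars <- c(chars[(off + 1L):L], chars[seq_len(off)])
    starts <- ((starts - off - 1L) %% L) + 1L
    stops <- ((stops - off - 1L) %% L) + 1L
  }
  genes <- data.frame(gene = toks,
                      strand = ifelse(signs < 0L, "-", "+"),
                      start = starts, stop = stops,
                      stringsAsFactors = FALSE)
  GenomeAnnotation(taxonId = taxonId, genomeLength = L, genes = genes,
                   sequence = paste0(chars, collapse = ""),
                   circular = TRUE)
}
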