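#' Construct a GeneOrder from signed tokens
#'
#' @param tokens character vector of gene tokens in circular reading
#'   order; a \code{"-"} prefix marks the minority strand. May include
#'   \code{CR} as an extra locus.
#' @param taxonId character(1).
#' @return A \code{\linkS4class{GeneOrder}} in canonical rotation
#'   (starting at \code{cox1}; if \code{cox1} is absent, at the
#'   alphabetically first token).
#' @export
geneOrder <- function(tokens, taxonId = "taxon") {
  tokens <- trimws(tokens)
  signs <- ifelse(startsWith(tokens, "-"), -1L, 1L)
  genes_ <- sub("^[-+]", "", tokens)
  checkGeneTokens(genes_)
  o <- new("GeneOrder", taxonId = taxonId, genes = genes_, signs = signs)
  canonicalRotation(o)
}

#' @rdname geneOrder
#' @param x a \code{GeneOrder}.
#' @export
canonicalRotation <- function(x) {
  anchor <- if ("cox1" %in% x@genes) "cox1" else sort(x@genes)[1L]
  i <- match(anchor, x@genes)
  idx <- c(seq_along(x@genes), seq_along(x@genes))[i:(i + length(x@genes) - 1L)]
  new("GeneOrder", taxonId = x@taxonId, genes = x@genes[idx],
      signs = x@signs[idx])
}

#' Are two gene orders equal (up to rotation)?
#'
#' @param a,b \code{GeneOrder} objects.
#' @return logical(1).
#' @export
sameOrder <- function(a, b) {
  a <- canonicalRotation(a); b <- canonicalRotation(b)
  identical(a@genes, b@genes) && identical(a@signs, b@signs)
}

#' Extract the signed circular gene order of an annotated genome
#'
#' Genes are sorted by start position on the circle; the sign records the
#' transcription strand. The control region is excluded by default (set
#' \code{includeCR = TRUE} to carry it as an extra locus); OL is always
#' excluded.
#'
#' @param genome a \code{GenomeAnnotation}.
#' @param includeCR keep CR as a locus? Default FALSE.
#' @return A \code{\linkS4class{GeneOrder}} in canonical rotation.
#' @export
extractGeneOrder <- function(genome, includeCR = FALSE) {
  g <- genome@genes
  keep <- g$gene %in% mitoGeneTokens() | (includeCR & g$gene == "CR")
  g <- g[keep, ]
  missing <- setdiff(mitoGeneTokens(), g$gene)
  if (length(missing) > 0L)
    stop("missing canonical gene(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(g$gene))
    stop("duplicated gene: ", g$gene[duplicated(g$gene)][1L])
  g <- g[order(g$start), ]
  geneOrder(paste0(ifelse(g$strand == "-", "-", ""), g$gene),
            taxonId = genome@taxonId)
}

dropCR <- function(order) {
  keep <- order@genes != "CR"
  if (all(keep)) return(order)
  canonicalRotation(new("GeneOrder", taxonId = order@taxonId,
                        genes = order@genes[keep],
                        signs = order@signs[keep]))
}

# boundary key for the adjacency (a, b): under signed matching the
# adjacency read from the opposite strand, (-b, -a), is the same physical
# junction, so the key is the lexicographically smaller of the two
# readings; unsigned keys drop the signs and reading direction entirely.
boundaryKey <- function(leftGene, leftSign, rightGene, rightSign, signed) {
  if (signed) {
    f1 <- paste0(ifelse(leftSign < 0L, "-", ""), leftGene, "|",
                 ifelse(rightSign < 0L, "-", ""), rightGene)
    f2 <- paste0(ifelse(rightSign > 0L, "-", ""), rightGene, "|",
                 ifelse(leftSign > 0L, "-", ""), leftGene)
    pmin(f1, f2)
  } else {
    paste0(pmin(leftGene, rightGene), "|", pmax(leftGene, rightGene))
  }
}

#' Boundaries (signed adjacencies) of a circular gene order
#'
#' One boundary per consecutive gene pair on the circle, read in
#' canonical direction: an order over n loci yields exactly n boundaries.
#'
#' @param order a \code{GeneOrder}.
#' @param signed does strand enter boundary identity? Default TRUE.
#' @return data.frame: \code{left}, \code{right} (signed tokens),
#'   \code{key} (matching key).
#' @export
boundaries <- function(order, signed = TRUE) {
  n <- length(order@genes)
  i <- seq_len(n)
  j <- c(i[-1L], 1L)
  data.frame(
    left = paste0(ifelse(order@signs[i] < 0L, "-", ""), order@genes[i]),
    right = paste0(ifelse(order@signs[j] < 0L, "-", ""), order@genes[j]),
    key = boundaryKey(order@genes[i], order@signs[i], order@genes[j],
                      order@signs[j], signed),
    stringsAsFactors = FALSE)
}

#' Classify each taxon's boundaries against an ancestral order
#'
#' A boundary is plesiomorphic iff its key occurs among the ancestor's
#' boundaries, derived otherwise. All orders must cover the same token
#' universe (CR is dropped from all orders unless \code{includeCR}).
#'
#' @param orders list of \code{GeneOrder} (the taxon panel).
#' @param ancestor a \code{GeneOrder}.
#' @param signed strand-sensitive boundary identity? Default TRUE.
#' @param includeCR carry CR as a locus (only meaningful when all orders
#'   have it)? Default FALSE.
#' @return A \code{\linkS4class{BoundaryCatalog}}.
#' @export
classifyBoundaries <- function(orders, ancestor, signed = TRUE,
                               includeCR = FALSE) {
  prep <- function(o) if (includeCR) o else dropCR(o)
  ancestor <- prep(ancestor)
  orders <- lapply(orders, prep)
  universe <- sort(ancestor@genes)
  for (o in orders) {
    if (!identical(sort(o@genes), universe))
      stop("taxon ", o@taxonId, " does not share the ancestor's gene set")
  }
  ancKeys <- boundaries(ancestor, signed = signed)$key
  rows <- lapply(orders, function(o) {
    b <- boundaries(o, signed = signed)
    b$taxon <- o@taxonId
    b$status <- ifelse(b$key %in% ancKeys, "plesiomorphic", "derived")
    b
  })
  new("BoundaryCatalog",
      boundaries = do.call(rbind, rows)[, c("taxon", "left", "right",
                                            "key", "status")],
      ancestorKeys = ancKeys, signed = signed, includeCR = includeCR)
}

#' Cross-taxon tallies of a boundary catalog
#'
#' @param catalog a \code{\linkS4class{BoundaryCatalog}}.
#' @return list: \code{per_taxon} (data.frame taxon/derived/plesiomorphic),
#'   \code{derived_total} (sum of per-taxon derived counts),
#'   \code{unique} (derived boundary types found in exactly one taxon),
#'   \code{shared_types} (derived types in >= 2 taxa),
#'   \code{shared_repeats} (total occurrences of shared types, so that
#'   \code{derived_total == unique + shared_repeats}),
#'   \code{type_counts} (named vector: occurrences per derived type),
#'   \code{identical_groups} (list of taxon groups with identical
#'   boundary sets).
#' @export
boundarySummary <- function(catalog) {
  b <- catalog@boundaries
  der <- b[b$status == "derived", ]
  perTaxon <- do.call(rbind, lapply(split(b, b$taxon), function(d)
    data.frame(taxon = d$taxon[1L], derived = sum(d$status == "derived"),
               plesiomorphic = sum(d$status == "plesiomorphic"),
               stringsAsFactors = FALSE)))
  rownames(perTaxon) <- NULL
  typeCounts <- if (nrow(der) > 0L) table(der$key) else table(character())
  uniqueN <- sum(typeCounts == 1L)
  sharedTypes <- sum(typeCounts >= 2L)
  sharedRepeats <- sum(typeCounts[typeCounts >= 2L])
  sig <- vapply(split(b$key, b$taxon), function(k)
    paste(sort(k), collapse = ";"), character(1L))
  groups <- split(names(sig), sig)
  groups <- unname(groups[order(vapply(groups, function(g) g[1L],
                                       character(1L)))])
  list(per_taxon = perTaxon,
       derived_total = sum(perTaxon$derived),
       unique = uniqueN, shared_types = sharedTypes,
       shared_repeats = sharedRepeats,
       type_counts = c(typeCounts),
       identical_groups = groups)
}

#' Conserved plesiomorphic blocks of the ancestral order
#'
#' Maximal runs of consecutive ancestral genes whose internal boundaries
#' are retained in every taxon of \code{scope}. For each block,
#' \code{retained_in} lists the panel taxa that retain all of the
#' block's internal boundaries. Blocks are labelled A, B, ... in
#' ancestral reading order.
#'
#' @param orders list of \code{GeneOrder} (the full panel).
#' @param ancestor a \code{GeneOrder}.
#' @param scope character vector of taxon ids defining which taxa must
#'   retain a boundary (default: all panel taxa).
#' @param signed,includeCR as in \code{\link{classifyBoundaries}}.
#' @param minGenes smallest block size reported (default 2).
#' @return data.frame: \code{label}, \code{genes} (space-separated signed
#'   run), \code{n_genes}, \code{retained_in} (comma-separated taxa).
#' @export
conservedBlocks <- function(orders, ancestor, scope = NULL, signed = TRUE,
                            includeCR = FALSE, minGenes = 2L) {
  prep <- function(o) if (includeCR) o else dropCR(o)
  ancestor <- prep(ancestor)
  orders <- lapply(orders, prep)
  ids <- vapply(orders, taxonId, character(1L))
  if (is.null(scope)) scope <- ids
  stopifnot(all(scope %in% ids))
  ancB <- boundaries(ancestor, signed = signed)
  taxKeys <- lapply(orders, function(o) boundaries(o, signed = signed)$key)
  names(taxKeys) <- ids
  retainedMat <- vapply(taxKeys, function(k) ancB$key %in% k,
                        logical(nrow(ancB)))
  inScope <- retainedMat[, scope, drop = FALSE]
  keep <- rowSums(inScope) == length(scope)   # boundary kept by all of scope
  n <- length(ancestor@genes)
  if (all(keep)) {
    runs <- list(seq_len(n))   # whole circle is one block
  } else {
    # runs of consecutive kept boundaries, circularly
    idx <- which(keep)
    if (length(idx) == 0L) return(data.frame(label = character(),
      genes = character(), n_genes = integer(), retained_in = character(),
      stringsAsFactors = FALSE))
    brk <- which(!keep)
    runs <- list()
    start <- brk[length(brk)] %% n + 1L  # first boundary after a break
    cur <- c()
    i <- start
    repeat {
      if (keep[i]) cur <- c(cur, i)
      else if (length(cur) > 0L) { runs[[length(runs) + 1L]] <- cur; cur <- c() }
      i <- i %% n + 1L
      if (i == start) break
    }
    if (length(cur) > 0L) runs[[length(runs) + 1L]] <- cur
  }
  rows <- list()
  for (r in runs) {
    # boundary i joins gene i and i+1; a run of k boundaries spans k+1 genes
    genesIdx <- if (length(r) == n) seq_len(n) else c(r[1L], r %% n + 1L)
    if (length(genesIdx) < minGenes) next
    tokens <- paste0(ifelse(ancestor@signs[genesIdx] < 0L, "-", ""),
                     ancestor@genes[genesIdx])
    retained <- ids[vapply(ids, function(t)
      all(retainedMat[r, t]), logical(1L))]
    rows[[length(rows) + 1L]] <- data.frame(
      genes = paste(tokens, collapse = " "), n_genes = length(genesIdx),
      retained_in = paste(retained, collapse = ","),
      firstBoundary = r[1L], stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(data.frame(label = character(),
    genes = character(), n_genes = integer(), retained_in = character(),
    stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$firstBoundary), ]
  out$label <- LETTERS[seq_len(nrow(out))]
  rownames(out) <- NULL
  out[, c("label", "genes", "n_genes", "retained_in")]
}

#' Map derived boundaries onto tree clades (synapomorphy assignment)
#'
#' A derived boundary type is synapomorphic for the smallest clade
#' containing all taxa that possess it, provided every tip of that clade
#' possesses it (strict, homoplasy-free criterion) and the clade has at
#' least two tips. A type possessed by a single tip is autapomorphic;
#' one whose smallest containing clade includes non-possessing tips is
#' homoplastic/partial.
#'
#' @param catalog a \code{\linkS4class{BoundaryCatalog}}.
#' @param tree an \code{ape::phylo} (rooted) or a Newick file path /
#'   string; tip labels must be catalog taxa.
#' @return data.frame: \code{key}, \code{n_taxa}, \code{status},
#'   \code{clade_tips} (comma-separated; for synapomorphic and
#'   autapomorphic types).
#' @export
synapomorphicBoundaries <- function(catalog, tree) {
  tree <- asPhylo(tree)
  b <- catalog@boundaries
  der <- b[b$status == "derived", ]
  if (nrow(der) == 0L)
    return(data.frame(key = character(), n_taxa = integer(),
                      status = character(), clade_tips = character(),
                      stringsAsFactors = FALSE))
  tips <- tree$tip.label
  extra <- setdiff(tips, unique(b$taxon))
  if (length(extra) > 0L)
    stop("tree tips absent from catalog: ", paste(extra, collapse = ", "))
  rows <- lapply(split(der$taxon, der$key), function(poss) {
    poss <- intersect(unique(poss), tips)
    if (length(poss) == 0L) return(NULL)
    if (length(poss) == 1L)
      return(data.frame(n_taxa = 1L, status = "autapomorphic",
                        clade_tips = poss, stringsAsFactors = FALSE))
    node <- ape::getMRCA(tree, poss)
    cladeTips <- ape::extract.clade(tree, node)$tip.label
    if (setequal(cladeTips, poss))
      data.frame(n_taxa = length(poss), status = "synapomorphic",
                 clade_tips = paste(sort(cladeTips), collapse = ","),
                 stringsAsFactors = FALSE)
    else
      data.frame(n_taxa = length(poss), status = "homoplastic",
                 clade_tips = NA_character_, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  out <- do.call(rbind, rows)
  out$key <- names(rows)
  rownames(out) <- NULL
  out[, c("key", "n_taxa", "status", "clade_tips")]
}

asPhylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    if (file.exists(tree)) return(ape::read.tree(tree))
    return(ape::read.tree(text = tree))
  }
  stop("tree must be a phylo object, Newick string or file path")
}
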