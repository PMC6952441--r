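#' CodonCounts: codon tallies for a gene or genome
#'
#' @slot label character(1) gene or genome label.
#' @slot counts named integer(64), one entry per codon.
#' @slot codeId NCBI translation table identifier (default "5",
#'   invertebrate mitochondrial).
#'
#' @aliases CodonCounts-class
#' @exportClass CodonCounts
setClass("CodonCounts",
  representation(label = "character", counts = "integer", codeId = "character"))

setValidity("CodonCounts", function(object) {
  if (length(object@counts) != 64L || is.null(names(object@counts)))
    return("counts must be a named integer(64)")
  if (any(object@counts < 0L)) return("counts must be non-negative")
  TRUE
})

setMethod("show", "CodonCounts", function(object) {
  cat("CodonCounts:", object@label, "|", sum(object@counts), "codons,",
      "code", object@codeId, "\n")
})

allCodons <- function() {
  b <- c("T", "C", "A", "G")
  paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L), rep(b, 16L))
}

codeTable <- function(codeId = "5") {
  Biostrings::getGeneticCode(codeId)
}

senseFamilies <- function(codeId = "5") {
  gc <- codeTable(codeId)
  sense <- gc[gc != "*"]
  split(names(sense), unname(sense))
}

#' Build a CodonCounts object
#'
#' @param x named integer/numeric of codon counts (missing codons fill
#'   with 0), or a character/DNAString coding sequence scanned in frame
#'   from its first base (a trailing partial codon is dropped with a
#'   message).
#' @param label label carried into the object.
#' @param codeId NCBI translation table id (default "5").
#' @param includeStop count stop codons too? Default FALSE (in-frame stop
#'   codons at the end are dropped; internal stops are counted only when
#'   \code{includeStop = TRUE}).
#' @return A \code{\linkS4class{CodonCounts}}.
#' @export
codonCounts <- function(x, label = "cds", codeId = "5", includeStop = FALSE) {
  codons <- allCodons()
  if (is.numeric(x)) {
    counts <- structure(integer(64L), names = codons)
    stopifnot(!is.null(names(x)))
    nm <- toupper(chartr("U", "T", names(x)))
    stopifnot(all(nm %in% codons))
    counts[nm] <- as.integer(x)
  } else {
    if (is(x, "DNAString")) x <- as.character(x)
    x <- toupper(chartr("U", "T", x))
    n <- nchar(x)
    if (n %% 3L != 0L) {
      message("dropping trailing partial codon (", n %% 3L, " nt) of ",
              label)
      x <- substr(x, 1L, n - n %% 3L)
    }
    cv <- substring(x, seq(1L, nchar(x), 3L), seq(3L, nchar(x), 3L))
    gc <- codeTable(codeId)
    if (!includeStop) {
      isStop <- !is.na(match(cv, names(gc))) & gc[cv] == "*"
      cv <- cv[!isStop]
    }
    cv <- cv[cv %in% codons]  # codons with ambiguity codes excluded
    counts <- structure(integer(64L), names = codons)
    tab <- table(cv)
    counts[names(tab)] <- as.integer(tab)
  }
  new("CodonCounts", label = label, counts = counts, codeId = codeId)
}

#' Extract in-frame codon counts for an annotated PCG
#'
#' Reads the gene's transcription-direction sequence in frame from the
#' annotated start. Trailing 1-2 nt (incomplete stop codon) are dropped
#' with a message; the terminal stop codon is excluded by default.
#'
#' @param genome a \code{GenomeAnnotation} with sequence.
#' @param gene a PCG token.
#' @inheritParams codonCounts
#' @return A \code{\linkS4class{CodonCounts}}.
#' @export
extractCodons <- function(genome, gene, codeId = "5", includeStop = FALSE) {
  g <- genome@genes
  i <- match(gene, g$gene)
  if (is.na(i)) stop("gene not annotated: ", gene)
  if (g$category[i] != "PCG") stop(gene, " is not a protein-coding gene")
  if (g$size[i] < 6L) stop("PCG shorter than 6 nt: ", gene)
  codonCounts(geneSequence(genome, gene), label = gene, codeId = codeId,
              includeStop = includeStop)
}

#' First and last codon of an annotated PCG
#'
#' @param genome a \code{GenomeAnnotation} with sequence.
#' @param gene a PCG token.
#' @return character(2): start codon and stop codon (\code{NA} when the
#'   annotated range ends in a partial codon).
#' @export
observedStartStop <- function(genome, gene) {
  s <- as.character(geneSequence(genome, gene))
  n <- nchar(s)
  start <- substr(s, 1L, 3L)
  stop_ <- if (n %% 3L == 0L) substr(s, n - 2L, n) else NA_character_
  c(start = start, stop = stop_)
}

#' Start/stop codon table across genomes
#'
#' Tabulates annotated (or, when sequence is available and annotation
#' lacks them, observed) start and stop codons of every PCG across a
#' panel of genomes, plus a frequency summary of start-codon classes
#' (ATN, TTG, TTA, TTT, GTG, CTG, CTA, other).
#'
#' @param genomes list of \code{GenomeAnnotation}.
#' @return list with \code{table} (long data.frame: taxon, gene,
#'   start_codon, stop_codon) and \code{start_classes} (named integer).
#' @export
startStopTable <- function(genomes) {
  rows <- lapply(genomes, function(gn) {
    g <- gn@genes[gn@genes$category == "PCG", ]
    sc <- g$start_codon
    pc <- g$stop_codon
    if (!is.null(gn@sequence)) {
      for (k in seq_len(nrow(g))) {
        obs <- observedStartStop(gn, g$gene[k])
        if (is.na(sc[k])) sc[k] <- obs["start"]
        if (is.na(pc[k])) pc[k] <- obs["stop"]
      }
    }
    data.frame(taxon = gn@taxonId, gene = g$gene, start_codon = sc,
               stop_codon = pc, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  cls <- function(x) {
    if (is.na(x)) return("missing")
    x <- toupper(x)
    if (grepl("^AT[ACGT]$", x)) return("ATN")
    if (x %in% c("TTG", "TTA", "TTT", "GTG", "CTG", "CTA")) return(x)
    "other"
  }
  classes <- vapply(tab$start_codon, cls, character(1L))
  list(table = tab, start_classes = c(table(classes)))
}

#' Relative synonymous codon usage
#'
#' For codon \eqn{c} in synonymous family \eqn{F}:
#' \deqn{RSCU(c) = count(c) \cdot |F| / \sum_{c' \in F} count(c').}
#' Families with zero total usage get \code{NA}. Stop codons are excluded.
#'
#' @param counts a \code{\linkS4class{CodonCounts}}.
#' @return named numeric over sense codons.
#' @export
rscu <- function(counts) {
  fam <- senseFamilies(counts@codeId)
  out <- numeric(0L)
  for (f in fam) {
    tot <- sum(counts@counts[f])
    v <- if (tot == 0L) rep(NA_real_, length(f)) else
      counts@counts[f] * length(f) / tot
    names(v) <- f
    out <- c(out, v)
  }
  out[order(names(out))]
}

#' High-frequency codons (RSCU > 1)
#'
#' @param counts a \code{\linkS4class{CodonCounts}}.
#' @param excludeSingletons drop single-codon families (default TRUE).
#' @return character vector of codons.
#' @export
highFrequencyCodons <- function(counts, excludeSingletons = TRUE) {
  fam <- senseFamilies(counts@codeId)
  keep <- unlist(fam[lengths(fam) > if (excludeSingletons) 1L else 0L])
  r <- rscu(counts)
  r <- r[names(r) %in% keep]
  sort(names(r)[!is.na(r) & r > 1])
}

#' Effective number of codons (Wright's estimator)
#'
#' Wright's homozygosity-based ENc. For each synonymous family with
#' \eqn{n \ge 2} codons sampled, \eqn{\hat F = (n \sum \hat p_i^2 - 1)/(n - 1)};
#' \eqn{\bar F_k} averages \eqn{\hat F} over the \eqn{k}-fold degenerate
#' families, and
#' \deqn{ENc = \sum_k N_k / \bar F_k,}
#' summing over the degeneracy classes of the genetic code
#' (\eqn{N_k} = number of \eqn{k}-fold amino acids; for the standard code
#' this is the familiar \eqn{2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 +
#' 3/\bar F_6}). A class with no usable family borrows the mean
#' \eqn{\hat F} of all usable families. The result is capped at 61.
#'
#' @param counts a \code{\linkS4class{CodonCounts}}.
#' @return numeric(1) in [20, 61].
#' @export
enc <- function(counts) {
  fam <- senseFamilies(counts@codeId)
  deg <- lengths(fam)
  Fhat <- rep(NA_real_, length(fam))
  for (i in seq_along(fam)) {
    cts <- counts@counts[fam[[i]]]
    n <- sum(cts)
    if (deg[i] == 1L) { Fhat[i] <- 1; next }
    if (n < 2L) next
    p <- cts / n
    Fhat[i] <- (n * sum(p^2) - 1) / (n - 1)
  }
  usable <- !is.na(Fhat) & deg > 1L
  if (!any(usable)) stop("no synonymous family with >= 2 codons sampled")
  encv <- 0
  for (k in sort(unique(deg))) {
    idx <- deg == k
    Nk <- sum(idx)
    if (k == 1L) { encv <- encv + Nk; next }
    Fk <- Fhat[idx & usable]
    Fbar <- if (length(Fk) > 0L) mean(Fk) else mean(Fhat[usable])
    # homozygosity cannot fall below 1/k; guard degenerate estimates
    Fbar <- max(Fbar, 1 / k * 1e-6)
    encv <- encv + Nk / Fbar
  }
  min(encv, 61)
}

#' Positional GC fractions of in-frame codons
#'
#' Percentage of G+C at each codon position, count-weighted;
#' \code{gc12 = (gc1 + gc2)/2}.
#'
#' @param counts a \code{\linkS4class{CodonCounts}} (or anything
#'   \code{\link{codonCounts}} accepts).
#' @param ... passed to \code{codonCounts} when \code{counts} is raw.
#' @return named numeric: \code{gc1}, \code{gc2}, \code{gc3}, \code{gc12},
#'   \code{gc_overall}, in percent.
#' @export
positionalGC <- function(counts, ...) {
  if (!is(counts, "CodonCounts")) counts <- codonCounts(counts, ...)
  cts <- counts@counts[counts@counts > 0L]
  if (length(cts) == 0L) stop("no codons")
  n <- sum(cts)
  gcAt <- function(pos) {
    lt <- substr(names(cts), pos, pos)
    100 * sum(cts[lt %in% c("G", "C")]) / n
  }
  gc1 <- gcAt(1L); gc2 <- gcAt(2L); gc3 <- gcAt(3L)
  c(gc1 = gc1, gc2 = gc2, gc3 = gc3, gc12 = (gc1 + gc2) / 2,
    gc_overall = (gc1 + gc2 + gc3) / 3)
}

#' Neutrality regression of GC12 on GC3
#'
#' Ordinary least-squares fit \code{gc12 ~ gc3} with the Pearson
#' correlation. A slope near 1 indicates mutation pressure alone shapes
#' codon composition; a slope near 0, selection.
#'
#' @param gc3,gc12 numeric vectors (percent or fraction, consistently).
#' @return list: \code{slope}, \code{intercept}, \code{r}, \code{p_value},
#'   \code{n_points}.
#' @export
neutralityFit <- function(gc3, gc12) {
  stopifnot(length(gc3) == length(gc12))
  if (length(gc3) < 3L) stop("need at least 3 points")
  if (stats::sd(gc3) == 0) stop("zero variance in GC3")
  fit <- stats::lm(gc12 ~ gc3)
  ct <- stats::cor.test(gc3, gc12)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r = unname(ct$estimate), p_value = ct$p.value,
       n_points = length(gc3))
}

#' One-stop codon-usage summary
#'
#' @param counts a \code{\linkS4class{CodonCounts}}.
#' @return list: \code{rscu}, \code{enc}, positional GC components, and
#'   \code{high_frequency_codons}.
#' @export
codonUsageSummary <- function(counts) {
  gc <- positionalGC(counts)
  list(label = counts@label, rscu = rscu(counts), enc = enc(counts),
       gc1 = gc[["gc1"]], gc2 = gc[["gc2"]], gc3 = gc[["gc3"]],
       gc12 = gc[["gc12"]], gc_overall = gc[["gc_overall"]],
       high_frequency_codons = highFrequencyCodons(counts))
}
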