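#' Nucleotide composition and strand skews
#'
#' Counts A/C/G/T, AT and GC percentages, and the strand skews
#' AT skew = (A - T)/(A + T), GC skew = (G - C)/(G + C). IUPAC ambiguity
#' codes are counted separately (\code{ambiguous}) and excluded from both
#' the numerators and denominators of the percentages and skews.
#'
#' @param seq a \code{DNAString}, \code{character(1)} or
#'   \code{GenomeAnnotation} with sequence.
#' @param label partition label carried into the result.
#' @return data.frame with one row: \code{partition}, \code{A}, \code{C},
#'   \code{G}, \code{T}, \code{ambiguous}, \code{at_percent},
#'   \code{gc_percent}, \code{at_skew}, \code{gc_skew}. Percentages are
#'   kept at full precision; round only for display.
#' @examples
#' composition("AAAT")$at_skew   # (3-1)/4 = 0.5
#' @export
composition <- function(seq, label = "sequence") {
  if (is(seq, "GenomeAnnotation")) {
    if (is.null(seq@sequence)) stop("genome has no sequence")
    seq <- seq@sequence
  }
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  if (length(seq) == 0L) stop("empty sequence")
  f <- Biostrings::letterFrequency(seq, c("A", "C", "G", "T"))
  a <- f[["A"]]; c_ <- f[["C"]]; g <- f[["G"]]; t <- f[["T"]]
  n <- a + c_ + g + t
  amb <- length(seq) - n
  if (n == 0L) stop("sequence contains no unambiguous bases")
  data.frame(partition = label, A = a, C = c_, G = g, T = t,
             ambiguous = amb,
             at_percent = 100 * (a + t) / n,
             gc_percent = 100 * (g + c_) / n,
             at_skew = if (a + t > 0) (a - t) / (a + t) else NA_real_,
             gc_skew = if (g + c_ > 0) (g - c_) / (g + c_) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Per-class composition of an annotated genome
#'
#' One composition summary per gene category (PCG, tRNA, rRNA, noncoding)
#' plus the whole genome. Category partitions concatenate the
#' transcription-direction sequences of their genes (minority-strand genes
#' reverse-complemented first), matching how gene-class AT content is
#' conventionally reported; the whole-genome row uses the deposited
#' majority strand. Categories with no genes are omitted with a message.
#'
#' @param genome a \code{GenomeAnnotation} with sequence.
#' @return data.frame, one row per partition (see \code{\link{composition}}).
#' @export
partitionComposition <- function(genome) {
  if (is.null(genome@sequence)) stop("genome has no sequence")
  out <- list(composition(genome@sequence, "genome"))
  for (cat_ in c("PCG", "tRNA", "rRNA", "noncoding")) {
    gs <- genome@genes$gene[genome@genes$category == cat_]
    if (length(gs) == 0L) {
      message("partition '", cat_, "' has no genes; omitted")
      next
    }
    seqs <- lapply(gs, function(g) geneSequence(genome, g))
    out[[length(out) + 1L]] <-
      composition(do.call(Biostrings::xscat, seqs), cat_)
  }
  do.call(rbind, out)
}
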