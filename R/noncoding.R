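## Control-region analysis: exact tandem repeats, inverted-repeat
## stem-loops, and cross-taxon motif scans.

isPrimitive <- function(motif) {
  u <- nchar(motif)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u %/% 2L)) {
    if (u %% d != 0L) next
    if (identical(strrep(substr(motif, 1L, d), u %/% d), motif)) return(FALSE)
  }
  TRUE
}

#' Exact tandem repeat detection
#'
#' Reports all maximal primitive exact tandem arrays: runs of
#' \code{copies >= minCopies} exact copies of a unit (plus a possibly
#' empty partial trailing copy), where the unit is not itself a
#' repetition of a shorter unit and the array can be extended in neither
#' direction. Overlapping arrays of different unit lengths are all
#' reported. Deterministic order: by start, then unit length.
#'
#' @param seq character(1) or \code{DNAString}.
#' @param minUnit,maxUnit unit length bounds (nt).
#' @param minCopies minimum number of full copies (>= 2).
#' @return data.frame: \code{motif}, \code{unit_length}, \code{copies},
#'   \code{start} (1-based), \code{partial_tail}, \code{span}.
#' @examples
#' findTandemRepeats("GGCATATACATATAGG", 2, 6, 2)
#' @export
findTandemRepeats <- function(seq, minUnit = 2L, maxUnit = 12L,
                              minCopies = 2L) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  minCopies <- max(2L, as.integer(minCopies))
  stopifnot(minUnit >= 1L, minUnit <= maxUnit)
  maxUnit <- min(maxUnit, n %/% 2L)
  ch <- strsplit(s, "")[[1L]]
  hits <- list()
  for (u in seq(minUnit, maxUnit)) {
    # matchlen[i]: common prefix length of s[i..] and s[i+u..]
    matchlen <- integer(n)
    for (i in seq(n - u, 1L)) {
      matchlen[i] <- if (ch[i] == ch[i + u])
        1L + (if (i + u + 1L <= n) matchlen[i + 1L] else 0L) else 0L
    }
    i <- 1L
    while (i + u - 1L <= n - u) {
      span <- u + matchlen[i]
      copies <- span %/% u
      if (copies >= minCopies) {
        motif <- substr(s, i, i + u - 1L)
        leftMax <- i == 1L || ch[i - 1L] != ch[i - 1L + u]
        if (leftMax && isPrimitive(motif)) {
          hits[[length(hits) + 1L]] <- data.frame(
            motif = motif, unit_length = u, copies = copies, start = i,
            partial_tail = span %% u, span = span, stringsAsFactors = FALSE)
        }
        # skip ahead: interior positions of this array restart the same run
        i <- i + (copies - minCopies) * u + 1L
      } else i <- i + 1L
    }
  }
  if (length(hits) == 0L)
    return(data.frame(motif = character(), unit_length = integer(),
                      copies = integer(), start = integer(),
                      partial_tail = integer(), span = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$unit_length), ]
  rownames(out) <- NULL
  out
}

complementBase <- function(x) chartr("ACGT", "TGCA", x)

#' Inverted-repeat (stem-loop) detection
#'
#' Finds maximal Watson-Crick stem pairings (A-T and G-C only by
#' default; G-T wobble off): positions \code{stem5_start + k} pair with
#' \code{stem3_end - k} for \code{k = 0..stem_length-1}, enclosing a loop
#' of at least \code{minLoop} nt. Hits are maximal along their pairing
#' diagonal; the best hit is the longest stem, ties broken by the
#' smallest loop then leftmost position.
#'
#' @param seq character(1) or \code{DNAString}.
#' @param minStem minimum stem length (bp).
#' @param minLoop minimum loop length (nt).
#' @param maxMismatch allowed non-pairing positions inside the stem
#'   (terminal pairs must match). Default 0.
#' @param wobble allow G-T pairs (default FALSE).
#' @return data.frame sorted best-first: \code{stem_length},
#'   \code{loop_length}, \code{stem5_start}, \code{stem3_end},
#'   \code{mismatches}.
#' @export
findHairpin <- function(seq, minStem = 5L, minLoop = 3L, maxMismatch = 0L,
                        wobble = FALSE) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  if (n < 2L * minStem + minLoop) stop("sequence shorter than 2*minStem + minLoop")
  ch <- strsplit(s, "")[[1L]]
  pairs_ <- function(a, b) {
    ok <- (a == "A" & b == "T") | (a == "T" & b == "A") |
          (a == "G" & b == "C") | (a == "C" & b == "G")
    if (wobble) ok <- ok | (a == "G" & b == "T") | (a == "T" & b == "G")
    ok
  }
  hits <- list()
  for (cc in 3:(2L * n - 1L)) {      # cc = i + j of a paired position pair
    iMax <- (cc - minLoop - 1L) %/% 2L   # innermost allowed 5' position
    iMin <- max(1L, cc - n)
    if (iMax < iMin) next
    idx <- iMin:iMax
    comp <- pairs_(ch[idx], ch[cc - idx])
    # maximal windows with <= maxMismatch mismatches, ends matching
    wins <- list()
    a <- 1L
    while (a <= length(idx)) {
      if (!comp[a]) { a <- a + 1L; next }
      mm <- 0L; b <- a; lastTrue <- a
      while (b < length(idx)) {
        if (!comp[b + 1L]) {
          if (mm + 1L > maxMismatch) break
          mm <- mm + 1L
        } else lastTrue <- b + 1L
        b <- b + 1L
      }
      wins[[length(wins) + 1L]] <- c(a, lastTrue)
      a <- if (maxMismatch == 0L) lastTrue + 1L else a + 1L
    }
    # drop contained windows
    if (length(wins) > 1L) {
      keep <- rep(TRUE, length(wins))
      for (p in seq_along(wins)) for (q in seq_along(wins)) {
        if (p != q && keep[p] && wins[[q]][1L] <= wins[[p]][1L] &&
            wins[[q]][2L] >= wins[[p]][2L] &&
            !identical(wins[[q]], wins[[p]])) keep[p] <- FALSE
      }
      wins <- wins[keep]
    }
    for (w in wins) {
      stem <- w[2L] - w[1L] + 1L
      if (stem < minStem) next
      i0 <- idx[w[1L]]
      j0 <- cc - i0
      mism <- sum(!comp[w[1L]:w[2L]])
      loop <- (cc - 2L * idx[w[2L]]) - 1L
      hits[[length(hits) + 1L]] <- data.frame(
        stem_length = stem, loop_length = loop, stem5_start = i0,
        stem3_end = j0, mismatches = mism, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(stem_length = integer(), loop_length = integer(),
                      stem5_start = integer(), stem3_end = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[out$stem3_end <= n, , drop = FALSE]
  out <- out[order(-out$stem_length, out$loop_length, out$stem5_start), ]
  rownames(out) <- NULL
  out
}

#' Motif occurrence scan across a panel of sequences
#'
#' Exact matching on the given strand (optionally also the reverse
#' complement). Default counting is non-overlapping left-to-right;
#' \code{overlapping = TRUE} counts every occurrence.
#'
#' @param panel named character vector or list: taxon -> sequence.
#' @param motif character(1), non-empty.
#' @param overlapping count overlapping occurrences? Default FALSE.
#' @param bothStrands also scan the reverse complement? Default FALSE.
#' @return named integer vector: occurrences per taxon.
#' @export
motifScan <- function(panel, motif, overlapping = FALSE,
                      bothStrands = FALSE) {
  stopifnot(nchar(motif) > 0L)
  motif <- toupper(motif)
  countIn <- function(s) {
    s <- toupper(as.character(s))
    one <- function(subject) {
      if (overlapping) {
        m <- gregexpr(paste0("(?=", motif, ")"), subject, perl = TRUE)[[1L]]
      } else {
        m <- gregexpr(motif, subject, fixed = TRUE)[[1L]]
      }
      if (m[1L] == -1L) 0L else length(m)
    }
    total <- one(s)
    if (bothStrands) {
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      total <- total + one(rc)
    }
    total
  }
  vapply(panel, countIn, integer(1L))
}
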