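## Pairwise synonymous / nonsynonymous substitution estimation (NG86),
## transition/transversion curves and an entropy-based saturation index.

transitionPair <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
  (a == "C" & b == "T") | (a == "T" & b == "C")
}

# fraction of the 9 single-nucleotide changes of a codon that are
# synonymous, per position; changes producing a stop codon count as
# nonsynonymous
codonSynFractions <- function(codon, gc) {
  bases <- c("A", "C", "G", "T")
  aa <- gc[[codon]]
  vapply(1:3, function(pos) {
    alt <- setdiff(bases, substr(codon, pos, pos))
    syn <- vapply(alt, function(b) {
      mut <- codon
      substr(mut, pos, pos) <- b
      aam <- gc[[mut]]
      aam != "*" && aam == aa
    }, logical(1L))
    sum(syn) / 3
  }, numeric(1L))
}

# classify the changes along one mutational pathway between two codons;
# returns c(sd, nd) or NULL if the path passes through a stop codon
pathwayChanges <- function(a, b, ord, gc) {
  sd <- 0; nd <- 0
  cur <- a
  for (pos in ord) {
    nxt <- cur
    substr(nxt, pos, pos) <- substr(b, pos, pos)
    if (gc[[nxt]] == "*" && nxt != b) return(NULL)
    if (gc[[cur]] != "*" && gc[[nxt]] != "*" && gc[[cur]] == gc[[nxt]])
      sd <- sd + 1 else nd <- nd + 1
    cur <- nxt
  }
  c(sd, nd)
}

# average synonymous/nonsynonymous difference counts between two codons
# over all shortest pathways (stop-crossing pathways excluded when any
# stop-free pathway exists)
codonPairChanges <- function(a, b, gc) {
  diffPos <- which(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
  if (length(diffPos) == 0L) return(c(sd = 0, nd = 0))
  perms <- if (length(diffPos) == 1L) list(diffPos) else {
    pp <- list()
    permute <- function(v, acc) {
      if (length(v) == 0L) pp[[length(pp) + 1L]] <<- acc
      else for (i in seq_along(v)) permute(v[-i], c(acc, v[i]))
    }
    permute(diffPos, integer(0L))
    pp
  }
  res <- lapply(perms, function(ord) pathwayChanges(a, b, ord, gc))
  ok <- res[!vapply(res, is.null, logical(1L))]
  if (length(ok) == 0L) ok <- lapply(perms, function(ord) {
    # all pathways cross a stop: fall back to counting all of them
    sd <- 0; nd <- 0; cur <- a
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      if (gc[[cur]] != "*" && gc[[nxt]] != "*" && gc[[cur]] == gc[[nxt]])
        sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  })
  m <- do.call(rbind, ok)
  c(sd = mean(m[, 1L]), nd = mean(m[, 2L]))
}

jukesCantor <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)  # saturated
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori (1986) Ka/Ks for a pair of in-frame coding sequences
#'
#' Proportions of synonymous and nonsynonymous differences per site with
#' Jukes-Cantor correction. Synonymous site fractions are computed per
#' codon and averaged over the two sequences; multiple-substitution
#' pathways between differing codons are averaged over all shortest
#' pathways (pathways through stop codons are excluded whenever a
#' stop-free pathway exists). Codons containing gaps or ambiguity codes
#' in either sequence are dropped from both.
#'
#' @param cdsA,cdsB character(1) or \code{DNAString}, equal length,
#'   multiple of 3, aligned codon-wise.
#' @param codeId NCBI translation table id (default "5").
#' @return list: \code{ka}, \code{ks} (substitutions/site, \code{NA} when
#'   the correction is undefined, i.e. saturated), \code{ratio} (ka/ks,
#'   \code{NA} if \code{ks} is 0 or undefined), \code{syn_sites},
#'   \code{nonsyn_sites}, \code{syn_diffs}, \code{nonsyn_diffs},
#'   \code{codons_compared}.
#' @export
ng86KaKs <- function(cdsA, cdsB, codeId = "5") {
  a <- toupper(as.character(cdsA)); b <- toupper(as.character(cdsB))
  if (nchar(a) != nchar(b)) stop("sequences must be the same length")
  if (nchar(a) %% 3L != 0L) stop("length must be a multiple of 3")
  gc <- as.list(codeTable(codeId))
  starts <- seq(1L, nchar(a), 3L)
  ca <- substring(a, starts, starts + 2L)
  cb <- substring(b, starts, starts + 2L)
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  # stop codons (e.g. a terminal TAA) carry no NG86 site definition
  clean <- clean & vapply(ca, function(x) gc[[x]] != "*", logical(1L)) &
                   vapply(cb, function(x) gc[[x]] != "*", logical(1L))
  ca <- ca[clean]; cb <- cb[clean]
  if (length(ca) == 0L) stop("no comparable codons")
  # per-codon synonymous site totals, precomputed once per genetic code
  synTab <- vapply(names(gc), function(x)
    if (gc[[x]] == "*") NA_real_ else sum(codonSynFractions(x, gc)),
    numeric(1L))
  S <- (sum(synTab[ca]) + sum(synTab[cb])) / 2
  N <- 3 * length(ca) - S
  sd <- 0; nd <- 0
  for (i in seq_along(ca)) {
    if (ca[i] == cb[i]) next
    ch <- codonPairChanges(ca[i], cb[i], gc)
    sd <- sd + ch[["sd"]]; nd <- nd + ch[["nd"]]
  }
  pS <- if (S > 0) sd / S else NA_real_
  pN <- if (N > 0) nd / N else NA_real_
  ks <- jukesCantor(pS); ka <- jukesCantor(pN)
  ratio <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  list(ka = ka, ks = ks, ratio = ratio, syn_sites = S, nonsyn_sites = N,
       syn_diffs = sd, nonsyn_diffs = nd, codons_compared = length(ca))
}

#' Mean pairwise Ka/Ks per gene and purifying-selection ranking
#'
#' @param panel named list: gene -> named character vector of aligned
#'   in-frame coding sequences (one per taxon, equal length within a
#'   gene).
#' @param codeId NCBI translation table id.
#' @return data.frame sorted by ascending mean pairwise ka/ks: columns
#'   \code{gene}, \code{mean_ratio}, \code{sd_ratio}, \code{n_pairs},
#'   \code{tied} (flag for alphabetical tie-breaks).
#' @export
kaksGeneRanking <- function(panel, codeId = "5") {
  rows <- lapply(names(panel), function(g) {
    seqs <- panel[[g]]
    if (length(seqs) < 2L) {
      return(data.frame(gene = g, mean_ratio = NA_real_, sd_ratio = NA_real_,
                        n_pairs = 0L, stringsAsFactors = FALSE))
    }
    prs <- utils::combn(length(seqs), 2L)
    ratios <- apply(prs, 2L, function(ij)
      ng86KaKs(seqs[[ij[1L]]], seqs[[ij[2L]]], codeId)$ratio)
    ratios <- ratios[!is.na(ratios)]
    data.frame(gene = g, mean_ratio = mean(ratios),
               sd_ratio = stats::sd(ratios), n_pairs = length(ratios),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mean_ratio, out$gene), ]
  out$tied <- duplicated(out$mean_ratio) |
    duplicated(out$mean_ratio, fromLast = TRUE)
  rownames(out) <- NULL
  out
}

#' Transitions, transversions and K2P distance per sequence pair
#'
#' For every pair in the alignment: raw transition and transversion
#' counts over gap-free site pairs and the Kimura two-parameter distance
#' \eqn{d = -\frac12 \ln((1-2P-Q)\sqrt{1-2Q})}. Pairs whose logarithm
#' argument is non-positive are flagged saturated (distance \code{NA}).
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences.
#' @return data.frame: \code{taxonA}, \code{taxonB}, \code{k2p_distance},
#'   \code{ts_count}, \code{tv_count}, \code{sites}, \code{saturated}.
#' @export
tsTvCurve <- function(alignment) {
  stopifnot(length(alignment) >= 2L)
  nm <- names(alignment) %||% paste0("seq", seq_along(alignment))
  mats <- strsplit(toupper(alignment), "")
  if (length(unique(lengths(mats))) != 1L)
    stop("alignment sequences differ in length")
  prs <- utils::combn(length(alignment), 2L)
  rows <- apply(prs, 2L, function(ij) {
    x <- mats[[ij[1L]]]; y <- mats[[ij[2L]]]
    ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 1L) stop("pair with no complete sites")
    diff <- x != y
    ts <- sum(diff & transitionPair(x, y))
    tv <- sum(diff) - ts
    P <- ts / n; Q <- tv / n
    arg1 <- 1 - 2 * P - Q; arg2 <- 1 - 2 * Q
    sat <- arg1 <= 0 || arg2 <= 0
    d <- if (sat) NA_real_ else -0.5 * log(arg1 * sqrt(arg2))
    data.frame(taxonA = nm[ij[1L]], taxonB = nm[ij[2L]], k2p_distance = d,
               ts_count = ts, tv_count = tv, sites = n, saturated = sat,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# exact expected per-site entropy of n iid draws from base frequencies f
expectedSaturatedEntropy <- function(n, f) {
  stopifnot(n >= 1L, length(f) == 4L)
  f <- f / sum(f)
  total <- 0
  for (n1 in 0:n) for (n2 in 0:(n - n1)) for (n3 in 0:(n - n1 - n2)) {
    n4 <- n - n1 - n2 - n3
    cnt <- c(n1, n2, n3, n4)
    pr <- exp(lgamma(n + 1) - sum(lgamma(cnt + 1)) +
                sum(ifelse(cnt > 0, cnt * log(f), 0)))
    p <- cnt[cnt > 0] / n
    total <- total + pr * (-sum(p * log(p)))
  }
  total
}

#' Entropy-based substitution saturation index
#'
#' \eqn{I_{ss} = H_{obs} / H_{fss}}: the mean per-site Shannon entropy of
#' the alignment divided by the expected per-site entropy under full
#' saturation, where each of the \eqn{n} sequences draws its base
#' independently from the alignment-wide base frequencies (computed
#' exactly by enumerating base compositions of \eqn{n}). A constant
#' alignment gives 0; a fully saturated one tends to 1.
#'
#' @param alignment named character vector of equal-length sequences
#'   (>= 4).
#' @return list: \code{iss}, \code{h_obs}, \code{h_fss}, \code{n_otus},
#'   \code{n_sites}.
#' @export
saturationIndex <- function(alignment) {
  if (length(alignment) < 4L) stop("need at least 4 OTUs")
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  keep <- apply(m, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, keep, drop = FALSE]
  if (ncol(m) == 0L) stop("no complete sites")
  n <- nrow(m)
  siteH <- apply(m, 2L, function(col) {
    p <- table(col) / n
    -sum(p * log(p))
  })
  hObs <- mean(siteH)
  f <- table(factor(m, levels = c("A", "C", "G", "T"))) / length(m)
  hFss <- expectedSaturatedEntropy(n, as.numeric(f))
  list(iss = hObs / hFss, h_obs = hObs, h_fss = hFss, n_otus = n,
       n_sites = ncol(m))
}
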