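# Independent brute-force oracles used to freeze expected values.

# O(n^3) tandem-array scanner: every (start, unit) pair extended directly
bruteTandem <- function(s, minUnit, maxUnit, minCopies) {
  n <- nchar(s)
  hits <- list()
  for (u in seq(minUnit, min(maxUnit, n %/% 2L))) {
    for (i in seq_len(n - 2L * u + 1L)) {
      motif <- substr(s, i, i + u - 1L)
      # left-maximality
      if (i > u && substr(s, i - u, i - 1L) == motif) next
      if (i > 1L && substr(s, i - 1L, i - 1L) ==
          substr(s, i + u - 1L, i + u - 1L)) next
      # primitivity
      prim <- TRUE
      for (d in seq_len(u %/% 2L)) {
        if (u %% d == 0L &&
            strrep(substr(motif, 1L, d), u %/% d) == motif) prim <- FALSE
      }
      if (!prim) next
      copies <- 1L
      while (i + (copies + 1L) * u - 1L <= n &&
             substr(s, i + copies * u, i + (copies + 1L) * u - 1L) == motif)
        copies <- copies + 1L
      if (copies < minCopies) next
      tail_ <- 0L
      while (i + copies * u + tail_ <= n &&
             substr(s, i + copies * u + tail_, i + copies * u + tail_) ==
             substr(motif, tail_ + 1L, tail_ + 1L))
        tail_ <- tail_ + 1L
      hits[[length(hits) + 1L]] <- data.frame(
        motif = motif, unit_length = u, copies = copies, start = i,
        partial_tail = tail_, span = copies * u + tail_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(motif = character(), unit_length = integer(),
                      copies = integer(), start = integer(),
                      partial_tail = integer(), span = integer()))
  out <- unique(do.call(rbind, hits))
  out <- out[order(out$start, out$unit_length), ]
  rownames(out) <- NULL
  out
}

# exhaustive NG86 oracle for a pair of short codon sequences: site counts
# by direct per-position enumeration, difference counts by enumerating
# every substitution pathway
ng86Oracle <- function(a, b, codeId = "5") {
  gc <- as.list(Biostrings::getGeneticCode(codeId))
  bases <- c("A", "C", "G", "T")
  codons <- function(x) substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  ca <- codons(a); cb <- codons(b)
  syn1 <- function(cdn) {
    aa <- gc[[cdn]]
    sum(vapply(1:3, function(pos) {
      alt <- setdiff(bases, substr(cdn, pos, pos))
      mean(vapply(alt, function(bb) {
        m <- cdn; substr(m, pos, pos) <- bb
        gc[[m]] != "*" && gc[[m]] == aa
      }, logical(1)))
    }, numeric(1)))
  }
  S <- (sum(vapply(ca, syn1, numeric(1))) +
        sum(vapply(cb, syn1, numeric(1)))) / 2
  N <- 3 * length(ca) - S
  sd <- 0; nd <- 0
  for (i in seq_along(ca)) {
    if (ca[i] == cb[i]) next
    dp <- which(strsplit(ca[i], "")[[1]] != strsplit(cb[i], "")[[1]])
    perms <- if (length(dp) == 1) list(dp) else {
      if (length(dp) == 2) list(dp, rev(dp)) else {
        out <- list()
        for (x in seq_along(dp)) for (y in seq_along(dp)) for (z in seq_along(dp))
          if (length(unique(c(x, y, z))) == 3)
            out[[length(out) + 1]] <- dp[c(x, y, z)]
        out
      }
    }
    walk <- function(ord) {
      cur <- ca[i]; sdd <- 0; ndd <- 0; stopHit <- FALSE
      for (pos in ord) {
        nxt <- cur; substr(nxt, pos, pos) <- substr(cb[i], pos, pos)
        if (gc[[nxt]] == "*" && nxt != cb[i]) stopHit <- TRUE
        if (gc[[cur]] == gc[[nxt]] && gc[[cur]] != "*" && gc[[nxt]] != "*")
          sdd <- sdd + 1 else ndd <- ndd + 1
        cur <- nxt
      }
      list(sd = sdd, nd = ndd, stopHit = stopHit)
    }
    res <- lapply(perms, walk)
    ok <- Filter(function(r) !r$stopHit, res)
    if (length(ok) == 0) ok <- res
    sd <- sd + mean(vapply(ok, `[[`, numeric(1), "sd"))
    nd <- nd + mean(vapply(ok, `[[`, numeric(1), "nd"))
  }
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else
    -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, sd = sd, nd = nd, ks = jc(sd / S), ka = jc(nd / N))
}

randomOrder <- function(seed, n = 12L, taxon = "t") {
  set.seed(seed)
  toks <- sample(mitoGeneTokens(), n)
  toks[1L] <- "cox1"
  toks <- unique(c("cox1", toks))
  signs <- sample(c("", "-"), length(toks), replace = TRUE)
  geneOrder(paste0(signs, toks), taxonId = taxon)
}

sixCladeTaxa <- function() {
  c("Lyrognathus_crotalus", "Ornithoctonus_huwena", "Calisoga_longitarsis",
    "Phyxioschema_suthepium", "Hypochilus_thorelli", "Pholcus_phalangioides")
}
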