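# NG86 Ka/Ks, transition/transversion curves and saturation index.

test_that("NG86 handles identical pairs and the single-synonymous-change case", {
  same <- ng86KaKs(strrep("ATG", 10), strrep("ATG", 10))
  expect_equal(same$ka, 0)
  expect_equal(same$ks, 0)
  expect_true(is.na(same$ratio))
  # one Lys->Lys third-position change over 30 codons
  a <- strrep("AAA", 30)
  b <- paste0(strrep("AAA", 29), "AAG")
  k <- ng86KaKs(a, b)
  expect_gt(k$ks, 0)
  expect_equal(k$ka, 0)
  expect_equal(k$syn_diffs, 1)
  expect_equal(k$nonsyn_diffs, 0)
})

test_that("NG86 equals the exhaustive enumeration oracle on small differences", {
  set.seed(10)
  gcTab <- Biostrings::getGeneticCode("5")
  sense <- names(gcTab)[gcTab != "*"]
  for (rep_ in 1:25) {
    n <- 8L
    a <- sample(sense, n, replace = TRUE)
    b <- a
    for (j in sample(n, sample(1:2, 1))) b[j] <- sample(sense, 1)
    A <- paste0(a, collapse = ""); B <- paste0(b, collapse = "")
    got <- ng86KaKs(A, B)
    want <- ng86Oracle(A, B)
    expect_equal(got$syn_sites, want$S, tolerance = 1e-9)
    expect_equal(got$syn_diffs, want$sd, tolerance = 1e-9)
    expect_equal(got$nonsyn_diffs, want$nd, tolerance = 1e-9)
    expect_equal(got$ks, want$ks, tolerance = 1e-9)
    expect_equal(got$ka, want$ka, tolerance = 1e-9)
    # symmetry
    rev_ <- ng86KaKs(B, A)
    expect_equal(rev_$ks, got$ks, tolerance = 1e-12)
    expect_equal(rev_$ka, got$ka, tolerance = 1e-12)
  }
})

test_that("Ka and Ks are non-decreasing as differing codons accumulate", {
  base <- rep("CTT", 40)
  seqA <- paste0(base, collapse = "")
  prevKa <- 0; prevKs <- 0
  cur <- base
  for (i in 1:6) {
    cur[i] <- if (i %% 2 == 0) "CTC" else "ATT"  # alternate syn / nonsyn
    k <- ng86KaKs(seqA, paste0(cur, collapse = ""))
    expect_gte(k$ks + 1e-12, prevKs)
    expect_gte(k$ka + 1e-12, prevKa)
    prevKs <- k$ks; prevKa <- k$ka
  }
})

test_that("equal synonymous and nonsynonymous rates give ka/ks near one", {
  p <- simulateCdsPanel(genes = c(g = 1500L), nTaxa = 4L, omega = 1,
                        kappa = 1, gc3 = 0.5, gc12 = 0.5,
                        branchLength = 0.08, seed = 21)
  r <- kaksGeneRanking(p$alignments)
  expect_equal(r$mean_ratio, 1, tolerance = 0.25)
})

test_that("gene ranking recovers simulated omega ordering", {
  p <- simulateCdsPanel(genes = c(fast = 500L, slow = 500L), nTaxa = 4L,
                        omega = c(0.8, 0.1), branchLength = 0.12, seed = 5)
  r <- kaksGeneRanking(p$alignments)
  expect_equal(r$gene, c("slow", "fast"))
  single <- kaksGeneRanking(p$alignments["fast"])
  expect_equal(nrow(single), 1L)
})

test_that("ts/tv counts and K2P distances match the reference implementation", {
  al0 <- c(a = "ACGTACGT", b = "ACGTACGT")
  t0 <- tsTvCurve(al0)
  expect_equal(c(t0$k2p_distance, t0$ts_count, t0$tv_count), c(0, 0, 0))
  t1 <- tsTvCurve(c(a = "AAAA", b = "GAAA"))
  expect_equal(t1$ts_count, 1L)
  expect_equal(t1$tv_count, 0L)
  set.seed(6)
  for (i in 1:5) {
    al <- vapply(1:4, function(j)
      paste0(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""),
      character(1))
    names(al) <- paste0("t", 1:4)
    got <- tsTvCurve(al)
    bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(al), "")))
    ref <- as.matrix(ape::dist.dna(bin, model = "K80"))
    for (r in seq_len(nrow(got))) {
      want <- ref[got$taxonA[r], got$taxonB[r]]
      if (is.infinite(want) || is.nan(want)) {
        expect_true(got$saturated[r])   # log argument collapsed
      } else {
        expect_equal(got$k2p_distance[r], want, tolerance = 1e-9)
      }
    }
  }
})

test_that("simulated transition bias appears in the ts/tv curve", {
  p <- simulateCdsPanel(genes = c(g = 800L), nTaxa = 6L, omega = 1,
                        kappa = 4, gc3 = 0.5, gc12 = 0.5,
                        branchLength = 0.05, seed = 8)
  tt <- tsTvCurve(p$alignments$g)
  expect_gt(sum(tt$ts_count), sum(tt$tv_count))
})

test_that("saturation index hits its limits and the mixture midpoint", {
  inv <- setNames(rep(strrep("ACGT", 50), 5), paste0("t", 1:5))
  expect_equal(saturationIndex(inv)$iss, 0)
  set.seed(9)
  sat <- vapply(1:8, function(i)
    paste0(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = ""),
    character(1))
  names(sat) <- paste0("t", 1:8)
  expect_equal(saturationIndex(sat)$iss, 1, tolerance = 0.05)
  half <- vapply(1:8, function(i)
    paste0(strrep("ACGT", 75),
           paste0(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")),
    character(1))
  names(half) <- paste0("t", 1:8)
  expect_equal(saturationIndex(half)$iss, 0.5, tolerance = 0.07)
  expect_error(saturationIndex(sat[1:3]), "4 OTUs")
})
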