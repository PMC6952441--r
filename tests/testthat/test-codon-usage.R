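# Codon extraction, RSCU, ENc, positional GC and the neutrality fit.

test_that("codon scanning reads frame, drops stops and partial tails", {
  cc <- suppressMessages(codonCounts("ATGAAATAA"))
  expect_equal(unname(cc@counts[c("ATG", "AAA")]), c(1L, 1L))
  expect_equal(sum(cc@counts), 2L)  # terminal TAA excluded by default
  ccs <- codonCounts("ATGAAATAA", includeStop = TRUE)
  expect_equal(sum(ccs@counts), 3L)
  expect_message(codonCounts("ATGAAAT"), "partial")
})

test_that("minus-strand genes yield the same codons as their plus-strand twin", {
  cds <- "ATGCTAGGTTTACCCATTTAA"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tstrand\tstart\tstop",
               sprintf("nad3\t+\t1\t%d", nchar(cds)),
               sprintf("nad1\t-\t%d\t%d", nchar(cds) + 3L,
                       2L * nchar(cds) + 2L)), f)
  g <- readGeneTable(f, genomeLength = 2L * nchar(cds) + 4L)
  g@sequence <- Biostrings::DNAString(paste0(cds, "GG", rc, "GG"))
  expect_equal(extractCodons(g, "nad3")@counts, extractCodons(g, "nad1")@counts)
  expect_error(extractCodons(g, "trnA"), "not annotated|not a protein")
})

test_that("start/stop tabulation reproduces the annotated codon table", {
  g <- lyrognathusCrotalusAnnotation()
  st <- startStopTable(list(g))
  tab <- st$table
  expect_equal(tab$start_codon[tab$gene == "cox3"], "TTG")
  expect_equal(tab$start_codon[tab$gene == "nad4"], "TTG")
  atn <- setdiff(tab$gene, c("cox3", "nad4"))
  expect_true(all(grepl("^AT[ACGT]$", tab$start_codon[tab$gene %in% atn])))
  expect_equal(unname(st$start_classes[["TTG"]]), 2L)
  expect_equal(unname(st$start_classes[["ATN"]]), 11L)
  # nad4L stop codon was not determinable and stays missing
  expect_true(is.na(tab$stop_codon[tab$gene == "nad4L"]))
})

test_that("a planted GTG start codon is detected in a synthetic panel", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tstrand\tstart\tstop", "cox2\t+\t1\t9"), f)
  g <- readGeneTable(f, genomeLength = 12L)
  g@sequence <- Biostrings::DNAString("GTGAAATAAGGG")
  st <- startStopTable(list(g))
  expect_equal(unname(st$start_classes[["GTG"]]), 1L)
})

test_that("RSCU matches its defining formula and sums to family size", {
  # uniform usage in every family -> all RSCU exactly 1
  uni <- codonCounts(setNames(rep(10, 64), mitocomp:::allCodons()))
  r <- rscu(uni)
  expect_true(all(abs(r - 1) < 1e-12))
  # a 2-fold family used 10:0 -> RSCU 2 and 0
  skew <- codonCounts(c(AAA = 10, AAG = 0, ATG = 3))
  r2 <- rscu(skew)
  expect_equal(unname(r2[c("AAA", "AAG")]), c(2, 0))
  # random counts against direct formula evaluation
  set.seed(1)
  fam <- mitocomp:::senseFamilies("5")
  cnt <- setNames(rpois(64, 8), mitocomp:::allCodons())
  r3 <- rscu(codonCounts(cnt))
  for (f in fam) {
    tot <- sum(cnt[f])
    if (tot == 0) next
    expect_equal(unname(r3[f]), unname(cnt[f] * length(f) / tot))
    expect_equal(sum(r3[f]), length(f))
  }
})

test_that("ENc spans its bounds and errors without usable families", {
  uni <- codonCounts(setNames(rep(100, 64), mitocomp:::allCodons()))
  expect_equal(enc(uni), 61)
  one <- setNames(rep(0, 64), mitocomp:::allCodons())
  for (f in mitocomp:::senseFamilies("5")) one[f[1]] <- 50
  expect_equal(enc(codonCounts(one)), 20)
  set.seed(2)
  for (i in 1:20) {
    cnt <- codonCounts(setNames(rpois(64, sample(1:20, 1)),
                                mitocomp:::allCodons()))
    e <- enc(cnt)
    expect_gte(e, 20); expect_lte(e, 61)
  }
  empty <- codonCounts(c(ATG = 1))
  expect_error(enc(empty), "family")
})

test_that("positional GC matches letter counting and survives codon shuffling", {
  expect_equal(unname(positionalGC(codonCounts(c(GGG = 10)))[1:3]),
               c(100, 100, 100))
  expect_equal(unname(positionalGC(codonCounts(c(ATA = 10)))[1:3]),
               c(0, 0, 0))
  set.seed(3)
  cdns <- paste0(sample(c("A", "C", "G", "T"), 60, TRUE),
                 sample(c("A", "C", "G", "T"), 60, TRUE),
                 sample(c("A", "C", "G", "T"), 60, TRUE))
  gcTab <- Biostrings::getGeneticCode("5")
  cdns <- cdns[gcTab[cdns] != "*"]
  seq_ <- paste0(cdns, collapse = "")
  got <- positionalGC(codonCounts(seq_, includeStop = TRUE))
  byHand <- function(k) {
    lt <- substring(cdns, k, k)
    100 * mean(lt %in% c("G", "C"))
  }
  expect_equal(unname(got["gc1"]), byHand(1))
  expect_equal(unname(got["gc2"]), byHand(2))
  expect_equal(unname(got["gc3"]), byHand(3))
  expect_equal(unname(got["gc12"]), (byHand(1) + byHand(2)) / 2)
  shuf <- paste0(sample(cdns), collapse = "")
  expect_equal(positionalGC(codonCounts(shuf, includeStop = TRUE)), got)
})

test_that("neutrality regression recovers generating slopes", {
  gc3 <- c(10, 20, 30, 40)
  fit <- neutralityFit(gc3, 0.5 * gc3)
  expect_equal(fit$slope, 0.5, tolerance = 1e-9)
  expect_equal(fit$r, 1)
  set.seed(4)
  gc3 <- runif(40, 8, 35)
  gc12 <- 20 + 0.25 * gc3 + rnorm(40, 0, 0.5)
  fit2 <- neutralityFit(gc3, gc12)
  expect_lt(abs(fit2$slope - 0.25), 0.05)
  expect_error(neutralityFit(rep(10, 5), 1:5), "variance")
  expect_error(neutralityFit(1:2, 1:2), "3 points")
})

test_that("high-frequency codons are the RSCU > 1 set without singleton families", {
  cnt <- codonCounts(c(TTA = 30, TTG = 1, CTT = 1, CTC = 1, CTA = 1,
                       CTG = 1, ATG = 50), codeId = "1")
  hf <- highFrequencyCodons(cnt)
  expect_true("TTA" %in% hf)
  expect_false("ATG" %in% hf)  # single-codon Met family is excluded
})
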