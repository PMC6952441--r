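# Annotation arithmetic on circular coordinates, gene-table and GenBank
# round trips, spacer and overlap accounting.

test_that("gene-table parsing computes circular sizes and validates tokens", {
  g <- lyrognathusCrotalusAnnotation()
  tab <- genes(g)
  expect_equal(nrow(tab), 38L)
  expect_equal(tab$size[tab$gene == "cox1"], 1557L)
  expect_equal(tab$start[tab$gene == "cox1"], 7797L)

  # degenerate single-gene table: start == stop is a 1 nt gene
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tstrand\tstart\tstop", "trnA\t+\t5\t5"), f)
  one <- readGeneTable(f, genomeLength = 100L)
  expect_equal(genes(one)$size, 1L)

  # origin-spanning gene: size counted by walking the circle
  writeLines(c("gene\tstrand\tstart\tstop", "cytb\t+\t13800\t50"), f)
  wrap <- readGeneTable(f, genomeLength = 13865L)
  expect_equal(genes(wrap)$size, 116L)

  # unknown token is a hard error naming the vocabulary
  writeLines(c("gene\tstrand\tstart\tstop", "frobnitz\t+\t1\t10"), f)
  expect_error(readGeneTable(f, genomeLength = 100L), "vocabulary|token")

  # size-column mismatches are warned about and recomputed
  writeLines(c("gene\tstrand\tstart\tstop\tsize", "cox1\t+\t1\t90\t80"), f)
  expect_warning(fixed <- readGeneTable(f, genomeLength = 200L), "disagrees")
  expect_equal(genes(fixed)$size, 90L)
})

test_that("stop < start without a circular genome is rejected", {
  expect_error(
    GenomeAnnotation("t", 100L,
                     data.frame(gene = "cox1", strand = "+",
                                start = 90, stop = 10),
                     circular = FALSE),
    "circular")
})

test_that("spacer report reproduces the published IGN values", {
  g <- lyrognathusCrotalusAnnotation()
  sp <- spacerReport(g)
  ign <- function(a, b) sp$ign[sp$upstream_gene == a & sp$downstream_gene == b]
  expect_equal(ign("cox1", "cox2"), 48L)     # intergenic spacer
  expect_equal(ign("trnC", "cox1"), -28L)    # 28 nt overlap
  expect_equal(ign("trnE", "trnF"), -39L)
  expect_equal(ign("trnQ", "CR"), 0L)        # abutting loci
})

test_that("pairwise overlap is symmetric, circular-aware and self-consistent", {
  g <- lyrognathusCrotalusAnnotation()
  expect_equal(geneOverlap(g, "trnE", "trnF"), 39L)
  expect_equal(geneOverlap(g, "trnE", "trnR"), 26L)
  expect_equal(geneOverlap(g, "trnC", "cox1"), 28L)
  expect_equal(geneOverlap(g, "trnC", "trnY"), 35L)
  expect_equal(geneOverlap(g, "trnF", "trnE"), geneOverlap(g, "trnE", "trnF"))
  expect_equal(geneOverlap(g, "cox1", "cox1"),
               genes(g)$size[genes(g)$gene == "cox1"])
  expect_equal(geneOverlap(g, "cox1", "rrnS"), 0L)
  # overlap of ranges that meet only across the origin
  expect_equal(pairwiseOverlap(95L, 10L, 5L, 20L, 100L), 6L)
})

test_that("exclusive-residue accounting clamps at zero", {
  g <- lyrognathusCrotalusAnnotation()
  # the published text claims 4 nt remain for trnE; its own coordinates
  # leave none (overlaps with trnR and trnF cover it) - computed value wins
  expect_equal(exclusiveResidues(g, "trnE"), 0L)
  expect_equal(exclusiveResidues(g, "trnC"), 0L)
  expect_gt(exclusiveResidues(g, "cox1"), 1400L)
})

test_that("circular coverage identity holds on synthetic genomes", {
  for (seed in 1:3) {
    g <- buildGenome(seed = seed, ign = c(3L, 0L, 5L))
    sp <- spacerReport(g)
    tab <- genes(g)
    covered <- unique(unlist(lapply(seq_len(nrow(tab)), function(i)
      mitocomp:::circularPositions(tab$start[i], tab$stop[i],
                                   genomeLength(g)))))
    expect_equal(length(covered) + sum(pmax(sp$ign, 0L)), genomeLength(g))
  }
})

test_that("gene table and GenBank writers round-trip all fields", {
  g <- buildGenome(seed = 9)
  f <- tempfile(fileext = ".tsv")
  writeGeneTable(g, f)
  g2 <- readGeneTable(f)
  expect_equal(genes(g2), genes(g))
  expect_equal(genomeLength(g2), genomeLength(g))

  gb <- tempfile(fileext = ".gb")
  writeGenBank(g, gb)
  g3 <- readGenBank(gb)
  expect_equal(genes(g3)[, c("gene", "strand", "start", "stop", "size")],
               genes(g)[, c("gene", "strand", "start", "stop", "size")])
  expect_equal(as.character(genomeSequence(g3)),
               as.character(genomeSequence(g)))
  # complement() features land on the minority strand
  expect_true(all(genes(g3)$strand[genes(g3)$gene == "nad1"] == "-"))
})

test_that("FASTA export writes the genome and transcription-direction genes", {
  g <- buildGenome(seed = 3)
  f1 <- tempfile(fileext = ".fa")
  writeGenomeFasta(g, f1)
  whole <- Biostrings::readDNAStringSet(f1)
  expect_equal(unname(as.character(whole[1])),
               as.character(genomeSequence(g)))
  f2 <- tempfile(fileext = ".fa")
  writeGenomeFasta(g, f2, perGene = TRUE)
  per <- Biostrings::readDNAStringSet(f2)
  expect_equal(length(per), nrow(genes(g)))
  expect_equal(as.character(per[["cox1"]]),
               as.character(geneSequence(g, "cox1")))
})

test_that("ambiguous tRNA-Leu/Ser without anticodon is a hard error", {
  gb <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       test 300 bp DNA circular",
    "FEATURES             Location/Qualifiers",
    "     tRNA            10..70",
    "                     /product=\"tRNA-Leu\"",
    "//"), gb)
  expect_error(readGenBank(gb), "anticodon")
})
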