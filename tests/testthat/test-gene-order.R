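# Signed circular gene orders, boundary classification, conserved
# blocks and synapomorphy mapping.

test_that("gene orders canonicalise, compare by rotation and round-trip", {
  o <- geneOrder(c("trnA", "-cox1", "cox2"))
  expect_equal(o@genes[1L], "cox1")
  rot <- geneOrder(c("cox2", "trnA", "-cox1"))
  expect_true(sameOrder(o, rot))
  expect_false(sameOrder(o, geneOrder(c("-cox1", "trnA", "cox2"))))
  expect_error(geneOrder(c("cox1", "cox1")), "duplicated")
  # synthetic genome built from a known order round-trips
  ord <- ancestralArthropodOrder(includeCR = TRUE)
  g <- buildGenome(order = ord, seed = 2)
  expect_true(sameOrder(extractGeneOrder(g, includeCR = TRUE), ord))
  # origin-spanning layout does not change the extracted order
  g2 <- buildGenome(order = ord, seed = 2, originOffset = 1000L)
  expect_true(sameOrder(extractGeneOrder(g2, includeCR = TRUE), ord))
})

test_that("the tarantula order places trnI on the minority strand between rrnS and trnQ", {
  g <- lyrognathusCrotalusAnnotation()
  o <- extractGeneOrder(g, includeCR = TRUE)
  toks <- orderTokens(o)
  i <- match("-trnI", toks)
  expect_false(is.na(i))
  expect_equal(toks[i - 1L], "-rrnS")
  expect_equal(toks[i + 1L], "-trnQ")
  expect_error(extractGeneOrder(
    GenomeAnnotation("x", 1000L, data.frame(gene = "cox1", strand = "+",
                                            start = 1, stop = 99))),
    "missing")
})

test_that("an order over n loci yields n boundaries and swaps change three", {
  anc <- ancestralArthropodOrder(includeCR = FALSE)
  b <- boundaries(anc)
  expect_equal(nrow(b), 37L)
  expect_equal(anyDuplicated(b$key), 0L)
  # swapping two adjacent genes changes exactly 3 boundaries
  toks <- orderTokens(anc)
  swapped <- geneOrder(replace(toks, 5:6, toks[6:5]), "swap")
  expect_equal(breakpointDistance(anc, swapped), 3L)
})

test_that("boundary classification is rotation-invariant and exact on the ancestor", {
  anc <- ancestralArthropodOrder(includeCR = FALSE)
  cat0 <- classifyBoundaries(list(anc), anc)
  s0 <- boundarySummary(cat0)
  expect_equal(s0$derived_total, 0L)
  expect_equal(s0$per_taxon$plesiomorphic, 37L)
  toks <- orderTokens(anc)
  rot <- geneOrder(c(toks[10:37], toks[1:9]), "rot")
  catR <- classifyBoundaries(list(rot), anc)
  expect_equal(boundarySummary(catR)$derived_total, 0L)
})

test_that("derived tallies satisfy the unique-plus-repeats identity on random panels", {
  for (seed in 1:5) {
    sim <- evolveOrders(tree = 6, eventsPerBranch = 1.5, seed = seed)
    cat_ <- classifyBoundaries(sim$tips, ancestralArthropodOrder(FALSE))
    s <- boundarySummary(cat_)
    expect_equal(s$derived_total, s$unique + s$shared_repeats)
    expect_true(all(s$per_taxon$derived + s$per_taxon$plesiomorphic == 37L))
  }
})

test_that("taxa with identical orders receive identical boundary sets", {
  panel <- spiderOrderPanel()
  cat_ <- classifyBoundaries(panel[names(panel) != "Limulus_polyphemus"],
                             panel[["Limulus_polyphemus"]])
  s <- boundarySummary(cat_)
  grp <- s$identical_groups
  m1 <- grp[vapply(grp, function(g) "Lyrognathus_crotalus" %in% g,
                   logical(1))][[1]]
  expect_setequal(m1, c("Lyrognathus_crotalus", "Hypochilus_thorelli",
                        "Pholcus_phalangioides"))
})

test_that("conserved blocks split when an internal boundary is destroyed", {
  anc <- ancestralArthropodOrder(includeCR = FALSE)
  whole <- conservedBlocks(list(anc), anc)
  expect_equal(nrow(whole), 1L)
  expect_equal(whole$n_genes, 37L)
  # break one boundary inside the block in one taxon
  toks <- orderTokens(anc)
  # move the 4th gene far away: boundaries 3-4 and 4-5 break
  moved <- geneOrder(c(toks[1:3], toks[5:20], toks[4], toks[21:37]), "mv")
  blocks <- conservedBlocks(list(anc, moved), anc)
  expect_gt(nrow(blocks), 1L)
  joined <- paste(blocks$genes, collapse = " | ")
  expect_false(grepl(paste(toks[3:5], collapse = " "), joined, fixed = TRUE))
})

test_that("synapomorphies map to the smallest clade possessing them", {
  anc <- ancestralArthropodOrder(includeCR = FALSE)
  tree <- ape::read.tree(text = "((a,b),(c,d));")
  toks <- orderTokens(anc)
  der <- geneOrder(c(toks[1:10], toks[12:20], toks[11], toks[21:37]), "der")
  orders <- list(a = der, b = der, c = anc, d = anc)
  for (t in names(orders)) orders[[t]]@taxonId <- t
  cat_ <- classifyBoundaries(orders, anc)
  syn <- synapomorphicBoundaries(cat_, tree)
  hits <- syn[syn$status == "synapomorphic", ]
  expect_true(all(hits$clade_tips == "a,b"))
  expect_equal(nrow(hits), 3L)  # one relocation creates three new junctions
  # a boundary in one tip only is autapomorphic, not synapomorphic
  solo <- orders
  toks2 <- orderTokens(anc)
  solo$d <- geneOrder(c(toks2[1:5], toks2[7:25], toks2[6], toks2[26:37]), "d")
  cat2 <- classifyBoundaries(solo, anc)
  syn2 <- synapomorphicBoundaries(cat2, tree)
  expect_true(any(syn2$status == "autapomorphic"))
  expect_true(all(syn2$clade_tips[syn2$status == "autapomorphic"] == "d"))
})
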