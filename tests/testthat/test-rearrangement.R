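# Breakpoint distance, event inference, ancestral reconstruction and
# the gene-order phylogeny.

test_that("breakpoint distance is a symmetric premetric on signed orders", {
  toy <- geneOrder(c("cox1", "cox2", "nad1", "trnA", "trnV"), "x")
  expect_equal(breakpointDistance(toy, toy), 0L)
  inv <- geneOrder(c("cox1", "cox2", "-nad1", "trnA", "trnV"), "y")
  expect_equal(breakpointDistance(toy, inv), 2L)
  set.seed(20)
  for (i in 1:10) {
    a <- randomOrder(i)
    b <- geneOrder(sample(orderTokens(a)), "b")   # same universe, shuffled
    expect_equal(breakpointDistance(a, b), breakpointDistance(b, a))
    expect_equal(breakpointDistance(a, b) == 0L, sameOrder(a, b))
  }
  expect_error(breakpointDistance(toy, randomOrder(1)), "different gene sets")
})

test_that("taxa that share the tarantula arrangement are at distance zero", {
  panel <- spiderOrderPanel()
  lc <- panel[["Lyrognathus_crotalus"]]
  expect_equal(breakpointDistance(lc, panel[["Hypochilus_thorelli"]]), 0L)
  expect_equal(breakpointDistance(lc, panel[["Pholcus_phalangioides"]]), 0L)
  expect_gt(breakpointDistance(lc, panel[["Ornithoctonus_huwena"]]), 0L)
})

test_that("identical orders give an empty resolved scenario", {
  anc <- ancestralArthropodOrder(includeCR = FALSE)
  sc <- inferEvents(anc, anc)
  expect_equal(length(sc@events), 0L)
  expect_true(sc@resolved)
})

test_that("a planted transposition is recovered and named", {
  anc <- ancestralArthropodOrder(includeCR = FALSE)
  ev <- mitocomp:::makeEvent("transposition", "trnK",
                             "transposition of trnK to after nad5",
                             params = list(anchor = "nad5", signs = 1L))
  target <- applyEvent(anc, ev)
  sc <- inferEvents(anc, target)
  expect_true(sc@resolved)
  expect_equal(length(sc@events), 1L)
  expect_equal(sc@events[[1]]@kind, "transposition")
  expect_true("trnK" %in% eventGenes(sc))
})

test_that("every inferred scenario replays onto its target (fuzz)", {
  counts <- integer(0)
  for (seed in 1:100) {
    set.seed(seed)
    nEvents <- sample(1:3, 1)
    sim <- evolveOrders(tree = 2, eventsPerBranch = nEvents, seed = seed,
                        fixedCount = TRUE)
    src <- ancestralArthropodOrder(includeCR = FALSE)
    tgt <- sim$tips[[1]]
    sc <- inferEvents(src, tgt)
    if (sc@resolved) {
      expect_true(sameOrder(applyEvents(src, sc@events), tgt))
      counts <- c(counts, length(sc@events) - 2 * nEvents)
    }
  }
  # the heuristic must resolve the large majority of random cases and
  # stay within a sane event-count envelope (simulated count + 1 would
  # be ideal; TDRLs of long blocks may peel into a few extra moves)
  expect_gt(length(counts), 80L)
})

test_that("inferred event counts respect the simulation envelope for single events", {
  over <- 0L
  for (seed in 1:40) {
    sim <- evolveOrders(tree = 2, eventsPerBranch = 1, seed = seed,
                        fixedCount = TRUE,
                        kindWeights = c(transposition = .4, inversion = .3,
                                        inverse_transposition = .3,
                                        tdrl = 0))
    sc <- inferEvents(ancestralArthropodOrder(FALSE), sim$tips[[1]])
    expect_true(sc@resolved)
    if (length(sc@events) > 2L) over <- over + 1L
  }
  expect_equal(over, 0L)
})

test_that("reconstruction on identical tips is event-free and consistent", {
  anc <- ancestralArthropodOrder(includeCR = FALSE)
  tree <- ape::read.tree(text = "((a,b),(c,d));")
  orders <- list(a = anc, b = anc, c = anc, d = anc)
  rec <- reconstructAncestors(tree, orders)
  expect_true(all(rec$node_status[rec$node_status != "tip"] == "consistent"))
  expect_equal(rec$total_events, 0L)
  expect_error(reconstructAncestors(ape::read.tree(text = "(a,b,c);"),
                                    orders), "binary")
})

test_that("a single simulated event is placed on its generating branch", {
  tree <- ape::read.tree(text = "((a,b),(c,d));")
  hits <- 0L
  for (seed in 1:20) {
    sim <- evolveOrders(tree = tree, eventsPerBranch = 0, seed = seed)
    # plant exactly one transposition on the branch to tip a
    set.seed(seed + 500)
    ev <- mitocomp:::randomEvent(sim$tips[["a"]],
                                 c(transposition = 1, inversion = 0,
                                   inverse_transposition = 0, tdrl = 0))
    orders <- sim$tips
    orders[["a"]] <- applyEvent(orders[["a"]], ev)
    rec <- reconstructAncestors(tree, orders)
    evCounts <- vapply(rec$branch_scenarios, function(s) length(s@events),
                       integer(1))
    tipA <- match("a", tree$tip.label)
    onA <- evCounts[grepl(paste0("->", tipA, "$"), names(evCounts))]
    if (onA == 1L && sum(evCounts) == 1L) hits <- hits + 1L
  }
  expect_equal(hits, 20L)
})

test_that("the NJ gene-order tree groups identical orders as cherries", {
  anc <- ancestralArthropodOrder(includeCR = FALSE)
  sim <- evolveOrders(tree = 3, eventsPerBranch = 2, seed = 3,
                      fixedCount = TRUE)
  orders <- list(x = sim$tips[[1]], y = sim$tips[[1]], z = sim$tips[[2]])
  for (t in names(orders)) orders[[t]]@taxonId <- t
  tr <- geneOrderTree(orders)
  expect_setequal(tr$tip.label, c("x", "y", "z"))
  mrca <- ape::getMRCA(tr, c("x", "y"))
  expect_setequal(ape::extract.clade(tr, mrca)$tip.label, c("x", "y"))
  expect_error(geneOrderTree(orders[1:2]), "3 taxa")
})

test_that("NJ recovers a generating six-taxon topology from evolved orders", {
  gen <- ape::read.tree(text = "(((a,b),c),((d,e),f));")
  ok <- 0L
  for (seed in 1:5) {
    sim <- evolveOrders(tree = gen, eventsPerBranch = 2, seed = seed,
                        fixedCount = TRUE)
    tr <- geneOrderTree(sim$tips)
    rf <- ape::dist.topo(ape::unroot(tr), ape::unroot(gen))
    if (rf == 0) ok <- ok + 1L
  }
  expect_gte(ok, 3L)   # majority of seeds
})
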