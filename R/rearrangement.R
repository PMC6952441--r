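## Rearrangement-event inference and gene-order phylogenetics:
## breakpoint distance, greedy event inference (transposition /
## inversion / inverse transposition / single TDRL), ancestral
## reconstruction on a tree, and a breakpoint-distance NJ phylogeny.

#' Breakpoint distance between two circular signed gene orders
#'
#' The number of adjacencies of \code{a} absent from \code{b}
#' (symmetric, since both orders have the same number of adjacencies).
#' Zero iff the canonical orders are equal.
#'
#' @param a,b \code{GeneOrder} objects over the same token universe.
#' @param signed strand-sensitive adjacency identity? Default TRUE.
#' @return integer distance.
#' @export
breakpointDistance <- function(a, b, signed = TRUE) {
  if (!setequal(a@genes, b@genes))
    stop("orders are over different gene sets")
  ka <- boundaries(a, signed = signed)$key
  kb <- boundaries(b, signed = signed)$key
  sum(!ka %in% kb)
}

# ---- event application ----

makeEvent <- function(kind, genes, description, params = list()) {
  new("RearrangementEvent", kind = kind, genes = genes,
      description = description, params = params)
}

removeBlock <- function(order, block) {
  idx <- match(block, order@genes)
  if (anyNA(idx)) stop("block gene absent: ",
                       paste(block[is.na(idx)], collapse = ", "))
  keep <- setdiff(seq_along(order@genes), idx)
  list(genes = order@genes[keep], signs = order@signs[keep],
       blockSigns = order@signs[idx])
}

insertAfter <- function(genes, signs, block, blockSigns, anchor) {
  if (identical(anchor, ".origin")) pos <- 0L
  else {
    pos <- match(anchor, genes)
    if (is.na(pos)) stop("anchor gene absent: ", anchor)
  }
  list(genes = append(genes, block, after = pos),
       signs = append(signs, blockSigns, after = pos))
}

#' Apply a rearrangement event to a gene order
#'
#' @param order a \code{GeneOrder}.
#' @param event a \code{RearrangementEvent} with replay parameters.
#' @return the rearranged \code{GeneOrder} (canonical rotation).
#' @export
applyEvent <- function(order, event) {
  g <- event@genes
  p <- event@params
  if (event@kind == "inversion") {
    idx <- match(g, order@genes)
    stopifnot(!anyNA(idx), all(diff(idx) == 1L) || length(idx) == 1L)
    genes_ <- order@genes; signs_ <- order@signs
    genes_[idx] <- rev(order@genes[idx])
    signs_[idx] <- -rev(order@signs[idx])
    return(canonicalRotation(new("GeneOrder", taxonId = order@taxonId,
                                 genes = genes_, signs = signs_)))
  }
  if (event@kind %in% c("transposition", "inverse_transposition")) {
    rem <- removeBlock(order, g)
    blk <- g; bs <- p$signs %||% rem$blockSigns
    if (event@kind == "inverse_transposition") {
      blk <- rev(blk); bs <- -rev(bs)
    }
    ins <- insertAfter(rem$genes, rem$signs, blk, bs, p$anchor)
    return(canonicalRotation(new("GeneOrder", taxonId = order@taxonId,
                                 genes = ins$genes, signs = ins$signs)))
  }
  if (event@kind == "tdrl") {
    rem <- removeBlock(order, g)
    if (!is.null(p$newTokens)) {
      # resulting arrangement of the block recorded explicitly
      newBlk <- sub("^-", "", p$newTokens)
      stopifnot(setequal(newBlk, g))
      newSigns <- ifelse(startsWith(p$newTokens, "-"), -1L, 1L)
    } else {
      # duplicate the block in tandem, then lose one copy of each gene:
      # genes with keep1 survive in the first copy, the rest in the second
      keep1 <- p$keep1
      stopifnot(length(keep1) == length(g))
      newBlk <- c(g[keep1], g[!keep1])
      newSigns <- c(rem$blockSigns[keep1], rem$blockSigns[!keep1])
    }
    ins <- insertAfter(rem$genes, rem$signs, newBlk, newSigns, p$anchor)
    return(canonicalRotation(new("GeneOrder", taxonId = order@taxonId,
                                 genes = ins$genes, signs = ins$signs)))
  }
  stop("unknown event kind: ", event@kind)
}

#' @rdname applyEvent
#' @param events list of \code{RearrangementEvent}.
#' @export
applyEvents <- function(order, events) {
  for (e in events) order <- applyEvent(order, e)
  order
}

# ---- event inference ----

dropGeneFromOrder <- function(order, gene) {
  rem <- removeBlock(order, gene)
  canonicalRotation(new("GeneOrder", taxonId = order@taxonId,
                        genes = rem$genes, signs = rem$signs))
}

neighborsOf <- function(order, gene) {
  n <- length(order@genes)
  i <- match(gene, order@genes)
  c(left = order@genes[(i - 2L) %% n + 1L],
    right = order@genes[i %% n + 1L])
}

displacedGenes <- function(cur, target) {
  vapply(cur@genes, function(g) {
    cur@signs[match(g, cur@genes)] != target@signs[match(g, target@genes)] ||
      !identical(unname(neighborsOf(cur, g)), unname(neighborsOf(target, g)))
  }, logical(1L))
}

# two-subsequence partition test: can the source block be turned into the
# target arrangement by one tandem duplication-random loss?
tdrlPartition <- function(pos) {
  last1 <- 0L; last2 <- 0L
  for (p in pos) {
    ok1 <- p > last1; ok2 <- p > last2
    if (ok1 && (!ok2 || last1 >= last2)) last1 <- p
    else if (ok2) last2 <- p
    else return(FALSE)
  }
  TRUE
}

# look for a contiguous window of displaced genes (consecutive in cur,
# not containing fixed loci) that one TDRL turns into the target
# arrangement; widest valid window wins, ties leftmost
findTDRL <- function(cur, target, fixed) {
  disp <- displacedGenes(cur, target)
  disp[cur@genes %in% fixed] <- FALSE
  disp[1L] <- FALSE  # the canonical anchor stays put
  r <- rle(disp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= 3L)
  cand <- list()
  for (k in runs) {
    len <- r$lengths[k]
    for (w in seq(len, 3L)) for (i0 in seq(starts[k], ends[k] - w + 1L)) {
      win <- i0:(i0 + w - 1L)
      blkSrc <- cur@genes[win]
      tpos <- sort(match(blkSrc, target@genes))
      if (any(diff(tpos) != 1L)) next      # not contiguous in target
      blkTgt <- target@genes[tpos]
      if (!all(cur@signs[match(blkTgt, cur@genes)] ==
               target@signs[tpos])) next   # TDRL preserves strands
      # trim genes that do not change relative position within the window
      while (length(blkSrc) > 1L &&
             blkSrc[length(blkSrc)] == blkTgt[length(blkTgt)]) {
        blkSrc <- blkSrc[-length(blkSrc)]; blkTgt <- blkTgt[-length(blkTgt)]
      }
      while (length(blkSrc) > 1L && blkSrc[1L] == blkTgt[1L]) {
        blkSrc <- blkSrc[-1L]; blkTgt <- blkTgt[-1L]
      }
      if (length(blkSrc) < 3L) next
      # a window fixable by relocating one gene is a transposition
      singleMove <- any(vapply(seq_along(blkSrc), function(d)
        identical(blkSrc[blkSrc != blkSrc[d]], blkTgt[blkTgt != blkSrc[d]]),
        logical(1L)))
      if (singleMove) next
      if (!tdrlPartition(match(blkTgt, blkSrc))) next
      i1 <- match(blkSrc[1L], cur@genes)
      anchor <- if (i1 == 1L) ".origin" else cur@genes[i1 - 1L]
      newTokens <- paste0(
        ifelse(target@signs[match(blkTgt, target@genes)] < 0L, "-", ""),
        blkTgt)
      ev <- makeEvent("tdrl", blkSrc,
        paste0("tandem duplication-random loss over block ",
               paste(blkSrc, collapse = "-")),
        params = list(anchor = anchor, newTokens = newTokens))
      # must genuinely simplify the comparison
      if (breakpointDistance(applyEvent(cur, ev), target) <=
          breakpointDistance(cur, target) - 2L)
        cand[[length(cand) + 1L]] <- ev
    }
    if (length(cand) > 0L) break
  }
  if (length(cand) == 0L) return(NULL)
  cand[[which.max(vapply(cand, function(e) length(e@genes), integer(1L)))]]
}

#' Infer a rearrangement scenario between two gene orders
#'
#' Greedy heuristic. Each round: (1) any maximal run of consecutively
#' displaced genes (three or more) that a single tandem
#' duplication-random loss (TDRL) turns into its target arrangement --
#' same strands, two-subsequence partition test -- is resolved as one
#' TDRL; (2) otherwise the single gene whose removal most reduces the
#' adjacency mismatch is peeled and relocated to its target position,
#' classified as a transposition (position moved, strand kept),
#' inversion (position kept, strand flipped) or inverse transposition
#' (both); ties break alphabetically. When neither rule makes progress
#' the scenario is returned with an unresolved residue. Every resolved
#' scenario replays: applying its events to \code{source} reproduces
#' \code{target}. TDRL is attempted source-to-target only (the event is
#' asymmetric). When both orders carry the control region it is treated
#' as an immovable landmark by default (it is not a gene, and events
#' are conventionally described relative to it).
#'
#' @param source,target \code{GeneOrder} objects over the same tokens.
#' @param fixed tokens pinned in place (never peeled or covered by a
#'   TDRL); default: \code{"CR"} when present in both orders.
#' @return An \code{\linkS4class{EventScenario}}.
#' @export
inferEvents <- function(source, target,
                        fixed = intersect("CR", intersect(source@genes,
                                                          target@genes))) {
  if (!setequal(source@genes, target@genes))
    stop("orders are over different gene sets")
  cur <- canonicalRotation(source)
  target <- canonicalRotation(target)
  events <- list()
  maxIter <- length(cur@genes) + 2L
  for (step in seq_len(maxIter)) {
    if (sameOrder(cur, target)) break
    td <- if (cur@genes[1L] == target@genes[1L])
      findTDRL(cur, target, fixed) else NULL
    if (!is.null(td)) {
      cur <- applyEvent(cur, td)
      events[[length(events) + 1L]] <- td
      next
    }
    d0 <- breakpointDistance(cur, target)
    # rank single-gene candidates by how much their removal shrinks the
    # mismatch; accept the first whose relocation strictly improves
    cands <- sort(setdiff(cur@genes, fixed))
    dg <- vapply(cands, function(g)
      breakpointDistance(dropGeneFromOrder(cur, g),
                         dropGeneFromOrder(target, g)), numeric(1L))
    cands <- cands[dg < d0][order(dg[dg < d0])]
    best <- NULL
    for (g in cands) {
      trial <- relocateGeneEvent(cur, target, g, d0)
      if (!is.null(trial)) { best <- trial; break }
    }
    if (is.null(best)) {
      bev <- findBlockMove(cur, target, fixed, d0)
      if (is.null(bev)) break
      cur <- applyEvent(cur, bev)
      events[[length(events) + 1L]] <- bev
      next
    }
    cur <- applyEvent(cur, best)
    events[[length(events) + 1L]] <- best
  }
  new("EventScenario", source = canonicalRotation(source), target = target,
      events = events, resolved = sameOrder(cur, target))
}

# build the single-gene relocation event for g; NULL unless it strictly
# reduces the breakpoint distance
relocateGeneEvent <- function(cur, target, g, d0) {
  sCur <- cur@signs[match(g, cur@genes)]
  sTgt <- target@signs[match(g, target@genes)]
  moved <- !identical(unname(neighborsOf(cur, g)),
                      unname(neighborsOf(target, g)))
  flipped <- sCur != sTgt
  kind <- if (moved && flipped) "inverse_transposition"
          else if (moved) "transposition"
          else if (flipped) "inversion"
          else "transposition"
  tPos <- match(g, target@genes)
  anchor <- if (tPos == 1L) ".origin" else target@genes[tPos - 1L]
  # an adjacent swap has two equivalent single-gene descriptions:
  # record the partner so reports can name either gene as the mover
  swap <- NA_character_
  if (kind == "transposition") {
    nc <- unname(neighborsOf(cur, g)); nt <- unname(neighborsOf(target, g))
    dgG <- breakpointDistance(dropGeneFromOrder(cur, g),
                              dropGeneFromOrder(target, g))
    for (h in nc) {
      if (h != g && h %in% nt &&
          breakpointDistance(dropGeneFromOrder(cur, h),
                             dropGeneFromOrder(target, h)) == dgG) {
        swap <- h; break
      }
    }
  }
  ev <- if (kind == "inversion")
    makeEvent("inversion", g, paste0("inversion of ", g, " in place"))
  else
    makeEvent(kind, g,
      paste0(sub("_", " ", kind), " of ", g, " to after ",
             if (anchor == ".origin") "origin" else anchor,
             if (flipped) " (strand flipped)" else "",
             if (!is.na(swap)) paste0(" (adjacent swap with ", swap,
                                      "; either gene may be described",
                                      " as the mover)") else ""),
      params = c(list(anchor = anchor,
                      signs = if (kind == "inverse_transposition") -sTgt
                              else sTgt),
                 if (!is.na(swap)) list(swappedWith = swap)))
  if (breakpointDistance(applyEvent(cur, ev), target) >= d0) return(NULL)
  ev
}

# relocation of a short contiguous block (2-3 genes) that the target
# keeps contiguous, either intact or reversed-and-flipped
findBlockMove <- function(cur, target, fixed, d0) {
  disp <- displacedGenes(cur, target)
  disp[cur@genes %in% fixed] <- FALSE
  disp[1L] <- FALSE
  n <- length(cur@genes)
  for (len in 2:3) {
    for (i0 in seq_len(n - len + 1L)) {
      idx <- i0:(i0 + len - 1L)
      if (!all(disp[idx])) next
      blk <- cur@genes[idx]
      bSigns <- cur@signs[idx]
      tpos <- match(blk, target@genes)
      intact <- all(diff(tpos) == 1L) &&
        all(target@signs[tpos] == bSigns)
      revFlip <- all(diff(rev(tpos)) == 1L) &&
        all(target@signs[tpos] == -bSigns)
      ev <- NULL
      if (intact) {
        anchor <- if (tpos[1L] == 1L) ".origin" else
          target@genes[tpos[1L] - 1L]
        ev <- makeEvent("transposition", blk,
          paste0("transposition of block ", paste(blk, collapse = "-"),
                 " to after ",
                 if (anchor == ".origin") "origin" else anchor),
          params = list(anchor = anchor, signs = bSigns))
      } else if (revFlip) {
        tFirst <- tpos[len]  # target position of the block's new head
        samePlace <- identical(
          target@genes[max(tFirst - 1L, 1L)],
          if (i0 == 1L) NA_character_ else cur@genes[i0 - 1L])
        if (samePlace) {
          ev <- makeEvent("inversion", blk,
            paste0("inversion of block ", paste(blk, collapse = "-")))
        } else {
          anchor <- if (tFirst == 1L) ".origin" else
            target@genes[tFirst - 1L]
          ev <- makeEvent("inverse_transposition", blk,
            paste0("inverse transposition of block ",
                   paste(blk, collapse = "-"), " to after ",
                   if (anchor == ".origin") "origin" else anchor),
            params = list(anchor = anchor, signs = bSigns))
        }
      }
      if (!is.null(ev) &&
          breakpointDistance(applyEvent(cur, ev), target) < d0)
        return(ev)
    }
  }
  NULL
}

#' Genes involved in a scenario's events
#'
#' Union of the tokens covered by the scenario's events, including
#' recorded adjacent-swap partners (an adjacent transposition can name
#' either gene as the mover).
#'
#' @param scenario an \code{EventScenario}.
#' @return character vector of tokens.
#' @export
eventGenes <- function(scenario) {
  unique(unlist(lapply(scenario@events, function(e)
    c(e@genes, e@params$swappedWith))))
}

# ---- ancestral reconstruction ----

scenarioCost <- function(sc) {
  length(sc@events) + if (sc@resolved) 0L else 1000L
}

#' Ancestral gene-order reconstruction on a binary tree
#'
#' Parsimony reconstruction over the set of arrangements observed at the
#' tips: a bottom-up (postorder) pass scores every candidate order at
#' every internal node by the minimal total inferred event count in its
#' subtree (directed event costs from \code{\link{inferEvents}}), and a
#' top-down pass fixes each node to the candidate that minimises the
#' cost of the branch from its parent plus its subtree -- the standard
#' two-pass minimisation, with deterministic tie-breaks (prefer the
#' parent's order, then the lexicographically smallest token string).
#' Node labels: \code{consistent} when the choice is the unique
#' minimiser at that node, \code{one_consistent} when chosen from a tie,
#' \code{fallback} when one of its branch scenarios has an unresolved
#' residue (its order is then a copy of the cheaper child state). The
#' three labels map onto the green/yellow/red node colouring convention
#' of tree-based rearrangement reconstructions.
#'
#' @param tree rooted binary \code{phylo}, Newick string or file path.
#' @param leafOrders named list tip label -> \code{GeneOrder}.
#' @return list: \code{tree} (phylo), \code{node_orders} (list indexed by
#'   node number), \code{node_status} (character by node),
#'   \code{node_colors}, \code{branch_scenarios} (list of
#'   \code{EventScenario} named "parent->child"), \code{total_events}.
#' @export
reconstructAncestors <- function(tree, leafOrders) {
  tree <- asPhylo(tree)
  if (!ape::is.rooted(tree) || !ape::is.binary(tree))
    stop("tree must be rooted and binary; resolve externally")
  ntip <- length(tree$tip.label)
  if (!all(tree$tip.label %in% names(leafOrders)))
    stop("every tip needs a gene order")
  nNode <- ntip + tree$Nnode
  tipOrders <- lapply(tree$tip.label, function(t)
    canonicalRotation(leafOrders[[t]]))
  # candidate states: the distinct tip arrangements
  sig <- vapply(tipOrders, function(o) paste(orderTokens(o), collapse = " "),
                character(1L))
  states <- tipOrders[!duplicated(sig)]
  stateSig <- sig[!duplicated(sig)]
  ord <- order(stateSig)
  states <- states[ord]; stateSig <- stateSig[ord]
  m <- length(states)
  # directed event-cost matrix between states
  costM <- matrix(0, m, m)
  scen <- vector("list", m * m)
  for (i in seq_len(m)) for (j in seq_len(m)) if (i != j) {
    sc <- inferEvents(states[[i]], states[[j]])
    costM[i, j] <- scenarioCost(sc)
    scen[[(i - 1L) * m + j]] <- sc
  }
  po <- ape::reorder.phylo(tree, "postorder")$edge
  subCost <- matrix(Inf, nNode, m)
  for (i in seq_len(ntip)) subCost[i, match(sig[i], stateSig)] <- 0
  kidsOf <- split(po[, 2L], po[, 1L])
  for (node in unique(po[, 1L])) {
    kids <- kidsOf[[as.character(node)]]
    for (s in seq_len(m)) {
      tot <- 0
      for (kid in kids)
        tot <- tot + min(costM[s, ] + subCost[kid, ])
      subCost[node, s] <- tot
    }
  }
  root <- ntip + 1L
  pick <- function(scores, preferred = NA_integer_) {
    best <- which(scores == min(scores))
    tie <- length(best) > 1L
    choice <- if (tie && !is.na(preferred) && preferred %in% best) preferred
              else best[1L]  # states sorted lexicographically
    list(choice = choice, tie = tie)
  }
  nodeState <- integer(nNode)
  nodeStatus <- rep(NA_character_, nNode)
  nodeStatus[seq_len(ntip)] <- "tip"
  nodeState[seq_len(ntip)] <- match(sig, stateSig)
  pr <- pick(subCost[root, ])
  nodeState[root] <- pr$choice
  nodeStatus[root] <- if (pr$tie) "one_consistent" else "consistent"
  # preorder: parents fixed before children
  pre <- po[rev(seq_len(nrow(po))), , drop = FALSE]
  for (k in seq_len(nrow(pre))) {
    node <- pre[k, 2L]
    if (node <= ntip) next
    parent <- pre[k, 1L]
    ps <- nodeState[parent]
    pk <- pick(costM[ps, ] + subCost[node, ], preferred = ps)
    nodeState[node] <- pk$choice
    nodeStatus[node] <- if (pk$tie) "one_consistent" else "consistent"
  }
  nodeOrders <- states[nodeState]
  branchScenarios <- list()
  for (k in seq_len(nrow(po))) {
    parent <- po[k, 1L]; kid <- po[k, 2L]
    i <- nodeState[parent]; j <- nodeState[kid]
    sc <- if (i == j)
      new("EventScenario", source = states[[i]], target = states[[j]],
          events = list(), resolved = TRUE)
    else scen[[(i - 1L) * m + j]]
    branchScenarios[[paste0(parent, "->", kid)]] <- sc
    if (!sc@resolved) nodeStatus[parent] <- "fallback"
  }
  total <- sum(vapply(branchScenarios, function(s) length(s@events),
                      integer(1L)))
  statusColor <- c(consistent = "green", one_consistent = "yellow",
                   fallback = "red", tip = NA)
  list(tree = tree, node_orders = nodeOrders, node_status = nodeStatus,
       node_colors = unname(statusColor[nodeStatus]),
       branch_scenarios = branchScenarios, total_events = total)
}

# ---- gene-order phylogeny ----

#' Breakpoint-distance neighbor-joining gene-order phylogeny
#'
#' Neighbor-joining on the pairwise breakpoint-distance matrix of the
#' orders. Taxa with identical orders (distance 0) are collapsed before
#' NJ and re-attached as a zero-branch-length ladder, resolving what
#' would otherwise be polytomies; ties break by taxon name. Note this is
#' a distance method: same input/output contract as likelihood
#' gene-order inference (orders in, Newick out), different estimator.
#'
#' @param leafOrders named list taxon -> \code{GeneOrder}.
#' @param signed strand-sensitive adjacencies? Default TRUE.
#' @return an \code{ape::phylo} tree.
#' @export
geneOrderTree <- function(leafOrders, signed = TRUE) {
  if (length(leafOrders) < 3L) stop("need at least 3 taxa")
  nm <- names(leafOrders)
  stopifnot(!is.null(nm), !anyDuplicated(nm))
  n <- length(nm)
  D <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- breakpointDistance(leafOrders[[i]], leafOrders[[j]], signed = signed)
    D[i, j] <- d; D[j, i] <- d
  }
  # collapse identical-order groups (deterministic: sorted by name)
  reps <- character(0L); groupOf <- list()
  for (t in sort(nm)) {
    placed <- FALSE
    for (r in reps) {
      if (D[r, t] == 0) {
        groupOf[[r]] <- c(groupOf[[r]], t); placed <- TRUE; break
      }
    }
    if (!placed) { reps <- c(reps, t); groupOf[[t]] <- t }
  }
  if (length(reps) >= 3L) {
    tr <- ape::nj(stats::as.dist(D[reps, reps]))
    tr$edge.length[tr$edge.length < 0] <- 0
    nwk <- ape::write.tree(tr)
  } else if (length(reps) == 2L) {
    nwk <- paste0("(", reps[1L], ":", D[reps[1L], reps[2L]] / 2, ",",
                  reps[2L], ":", D[reps[1L], reps[2L]] / 2, ");")
  } else {
    nwk <- paste0("(", reps[1L], ":0);")
  }
  # re-attach identical taxa as zero-length ladders
  for (r in reps) {
    grp <- sort(groupOf[[r]])
    if (length(grp) == 1L) next
    lad <- grp[1L]
    for (m in grp[-1L]) lad <- paste0("(", lad, ":0,", m, ":0):0")
    # replace the representative tip label (word boundary via delimiters)
    rEsc <- gsub("([^[:alnum:]_])", "\\\\\\1", r)
    nwk <- sub(paste0("([(,])", rEsc, "(:)"),
               paste0("\\1", sub("(:0)$", "", lad), "\\2"), nwk)
  }
  ape::read.tree(text = nwk)
}
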