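#' Construct a GenomeAnnotation
#'
#' Low-level constructor. Gene sizes are recomputed from the circular
#' coordinates; a supplied \code{size} column is cross-checked and, on
#' mismatch, the recomputed value wins with a warning.
#'
#' @param taxonId character(1).
#' @param genomeLength integer(1), total length in nt.
#' @param genes data.frame with columns \code{gene}, \code{strand},
#'   \code{start}, \code{stop}; optional \code{size}, \code{anticodon},
#'   \code{start_codon}, \code{stop_codon}.
#' @param sequence optional \code{DNAString} or character(1).
#' @param accession optional character(1).
#' @param circular logical(1), default TRUE.
#' @return A \code{\linkS4class{GenomeAnnotation}}.
#' @export
GenomeAnnotation <- function(taxonId, genomeLength, genes, sequence = NULL,
                             accession = NA_character_, circular = TRUE) {
  genomeLength <- as.integer(genomeLength)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  checkGeneTokens(genes$gene)
  if (any(genes$start <= 0L) || any(genes$stop <= 0L))
    stop("coordinates must be positive integers")
  if (!circular && any(genes$stop < genes$start))
    stop("stop < start requires a circular genome")
  genes$start <- as.integer(genes$start)
  genes$stop <- as.integer(genes$stop)
  expect <- circularSize(genes$start, genes$stop, genomeLength)
  if (!is.null(genes$size)) {
    bad <- which(!is.na(genes$size) & as.integer(genes$size) != expect)
    if (length(bad) > 0L)
      warning("size column disagrees with coordinates for: ",
              paste0(genes$gene[bad], " (stated ", genes$size[bad],
                     ", computed ", expect[bad], ")", collapse = ", "),
              "; recomputed values used")
  }
  genes$size <- expect
  genes$category <- geneCategory(genes$gene)
  for (col in c("anticodon", "start_codon", "stop_codon")) {
    if (is.null(genes[[col]])) genes[[col]] <- NA_character_
    genes[[col]][!nzchar(trimws(ifelse(is.na(genes[[col]]), "",
                                       genes[[col]])))] <- NA_character_
  }
  genes <- genes[order(genes$start, genes$stop),
                 c("gene", "strand", "start", "stop", "size", "category",
                   "anticodon", "start_codon", "stop_codon")]
  rownames(genes) <- NULL
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  new("GenomeAnnotation", taxonId = taxonId, accession = accession,
      genomeLength = genomeLength, circular = circular, genes = genes,
      sequence = sequence)
}

#' Read / write a TSV gene table
#'
#' The gene-table dialect mirrors a mitogenome annotation table: one row
#' per locus, columns \code{gene}, \code{strand}, \code{start}, \code{stop}
#' and optionally \code{size}, \code{anticodon}, \code{start_codon},
#' \code{stop_codon}. Comment lines starting with \code{#} may carry
#' \code{genome_length}, \code{taxon}, \code{accession} and
#' \code{circular} headers as \code{# key: value}.
#'
#' @param path file path.
#' @param taxonId,genomeLength,circular overrides for values not present in
#'   the file header; \code{genomeLength} defaults to the maximum stop.
#' @return \code{readGeneTable}: a \code{\linkS4class{GenomeAnnotation}};
#'   \code{writeGeneTable}: invisibly, the path.
#' @export
readGeneTable <- function(path, taxonId = NULL, genomeLength = NULL,
                          circular = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", h))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- trimws(m[3L])
  }
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)],
                           stringsAsFactors = FALSE)
  need <- c("gene", "strand", "start", "stop")
  if (!all(need %in% names(tab)))
    stop("gene table needs columns: ", paste(need, collapse = ", "))
  if (is.null(taxonId)) taxonId <- meta$taxon %||% basename(path)
  if (is.null(genomeLength))
    genomeLength <- as.integer(meta$genome_length %||% max(tab$stop))
  if (is.null(circular))
    circular <- as.logical(meta$circular %||% TRUE)
  GenomeAnnotation(taxonId = taxonId, genomeLength = genomeLength,
                   genes = tab, accession = meta$accession %||% NA_character_,
                   circular = circular)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readGeneTable
#' @param genome a \code{GenomeAnnotation}.
#' @export
writeGeneTable <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# taxon: ", genome@taxonId),
               if (!is.na(genome@accession))
                 paste0("# accession: ", genome@accession),
               paste0("# genome_length: ", genome@genomeLength),
               paste0("# circular: ", genome@circular)), con)
  utils::write.table(genome@genes[, c("gene", "strand", "start", "stop",
                                      "size", "anticodon", "start_codon",
                                      "stop_codon")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- GenBank flat file (single record) ----

#' Read / write a GenBank flat file
#'
#' Minimal single-record GenBank parser for annotated mitogenomes:
#' understands the LOCUS/ACCESSION lines, \code{CDS}, \code{tRNA},
#' \code{rRNA}, \code{D-loop} and \code{misc_feature} features with plain
#' or \code{complement(a..b)} locations, the qualifiers \code{/gene},
#' \code{/product}, \code{/codon_start}, \code{/anticodon}, and the ORIGIN
#' sequence block. Feature names are mapped onto the canonical 37-token
#' vocabulary through a synonym map (see \code{\link{geneSynonyms}});
#' unknown names are a hard error. tRNA-Leu/tRNA-Ser features without an
#' anticodon qualifier cannot be disambiguated into L1/L2 (S1/S2) and
#' raise an error demanding a manual mapping.
#'
#' @param path file path.
#' @param synonyms named character vector mapping upper-cased feature names
#'   to canonical tokens; defaults to \code{geneSynonyms()}.
#' @param taxonId optional override for the record's organism/locus name.
#' @return \code{readGenBank}: a \code{\linkS4class{GenomeAnnotation}}.
#' @export
readGenBank <- function(path, synonyms = geneSynonyms(), taxonId = NULL) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)[1L]
  if (is.na(locus)) stop("not a GenBank flat file: no LOCUS line")
  lf <- strsplit(trimws(locus), "\\s+")[[1L]]
  locusName <- lf[2L]
  genomeLength <- as.integer(lf[3L])
  circular <- any(grepl("circular", locus))
  accLine <- grep("^ACCESSION", lines, value = TRUE)
  accession <- if (length(accLine) > 0L)
    strsplit(trimws(accLine[1L]), "\\s+")[[1L]][2L] else NA_character_
  orgLine <- grep("^\\s+ORGANISM", lines, value = TRUE)
  organism <- if (length(orgLine) > 0L)
    trimws(sub("^\\s+ORGANISM\\s+", "", orgLine[1L])) else locusName

  fstart <- grep("^FEATURES", lines)
  oline <- grep("^ORIGIN", lines)
  fend <- if (length(oline) > 0L) oline[1L] - 1L else length(lines)
  feat <- if (length(fstart) > 0L) lines[(fstart[1L] + 1L):fend] else character()

  # split the feature table into individual features
  isKey <- grepl("^ {5}\\S", feat)
  idx <- cumsum(isKey)
  rows <- list()
  for (i in seq_len(max(c(idx, 0L)))) {
    block <- feat[idx == i]
    key <- strsplit(trimws(block[1L]), "\\s+")[[1L]]
    type <- key[1L]
    if (!type %in% c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature")) next
    loc <- paste0(key[-1L], collapse = "")
    quals <- trimws(block[-1L])
    # location may continue on qualifier-free lines
    cont <- quals[!grepl("^/", quals)]
    if (length(cont) > 0L) loc <- paste0(loc, paste0(cont, collapse = ""))
    quals <- quals[grepl("^/", quals)]
    strand <- if (grepl("complement", loc)) "-" else "+"
    nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1L]]
    if (length(nums) < 2L) next
    start <- as.integer(nums[1L])
    stop_ <- as.integer(nums[length(nums)])
    getq <- function(name) {
      q <- grep(paste0("^/", name, "="), quals, value = TRUE)
      if (length(q) == 0L) return(NA_character_)
      gsub("\"", "", sub(paste0("^/", name, "="), "", q[1L]))
    }
    geneName <- getq("gene")
    product <- getq("product")
    anticodon <- getq("anticodon")
    if (!is.na(anticodon)) {
      m <- regmatches(anticodon, regexec("seq:([A-Za-z]{3})", anticodon))[[1L]]
      anticodon <- if (length(m) == 2L) toupper(m[2L]) else
        toupper(gsub("[^A-Za-z]", "", anticodon))
    }
    label <- if (type == "D-loop") "CR" else (geneName %||NA% product)
    if (is.na(label)) next
    rows[[length(rows) + 1L]] <- data.frame(
      type = type, label = label, strand = strand, start = start,
      stop = stop_, anticodon = anticodon, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no usable features in ", path)
  tab <- do.call(rbind, rows)

  tab$gene <- mapSynonym(tab$label, tab$anticodon, synonyms)
  tab <- tab[, c("gene", "strand", "start", "stop", "anticodon")]

  seqchar <- NULL
  if (length(oline) > 0L) {
    sl <- lines[(oline[1L] + 1L):length(lines)]
    sl <- sl[!grepl("^//", sl)]
    seqchar <- toupper(gsub("[^A-Za-z]", "", paste0(sl, collapse = "")))
    if (nchar(seqchar) == 0L) seqchar <- NULL
  }
  GenomeAnnotation(taxonId = taxonId %||% organism,
                   genomeLength = genomeLength, genes = tab,
                   sequence = seqchar, accession = accession,
                   circular = circular)
}

`%||NA%` <- function(a, b) if (is.na(a)) b else a

mapSynonym <- function(labels, anticodons, synonyms) {
  out <- character(length(labels))
  for (i in seq_along(labels)) {
    lab <- toupper(trimws(labels[i]))
    lab <- sub("^TRNA-LEU.*$", "TRNA-LEU", lab)
    lab <- sub("^TRNA-SER.*$", "TRNA-SER", lab)
    if (lab %in% c("TRNA-LEU", "TRNA-SER")) {
      ac <- anticodons[i]
      if (is.na(ac)) {
        # allow disambiguation hints like tRNA-Leu(UAG)
        m <- regmatches(labels[i],
                        regexec("\\(([ACGUTacgut]{3})\\)", labels[i]))[[1L]]
        if (length(m) == 2L) ac <- toupper(chartr("U", "T", m[2L]))
      }
      if (is.na(ac))
        stop("ambiguous ", labels[i], " without anticodon qualifier; ",
             "supply an explicit synonym mapping", call. = FALSE)
      ac <- toupper(chartr("U", "T", ac))
      out[i] <- if (lab == "TRNA-LEU") {
        if (ac == "TAG") "trnL1" else if (ac == "TAA") "trnL2" else
          stop("unrecognised Leu anticodon: ", ac)
      } else {
        if (ac == "GCT") "trnS1" else if (ac == "TGA") "trnS2" else
          stop("unrecognised Ser anticodon: ", ac)
      }
    } else if (lab %in% names(synonyms)) {
      out[i] <- unname(synonyms[lab])
    } else {
      stop("unknown gene/product name in GenBank record: ", labels[i],
           "; extend the synonym map. Canonical vocabulary:\n  ",
           paste(c(mitoGeneTokens(), mitoNoncodingLoci()), collapse = " "),
           call. = FALSE)
    }
  }
  out
}

#' @rdname readGenBank
#' @param genome a \code{GenomeAnnotation} (sequence optional).
#' @export
writeGenBank <- function(genome, path) {
  g <- genome@genes
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w(sprintf("LOCUS       %s %d bp    DNA     %s     INV",
            gsub("\\s", "_", genome@taxonId), genome@genomeLength,
            if (genome@circular) "circular" else "linear"))
  w("DEFINITION  ", genome@taxonId, " mitochondrion.")
  if (!is.na(genome@accession)) w("ACCESSION   ", genome@accession)
  w("  ORGANISM  ", genome@taxonId)
  w("FEATURES             Location/Qualifiers")
  loc <- function(i) {
    s <- paste0(g$start[i], "..", g$stop[i])
    if (g$strand[i] == "-") paste0("complement(", s, ")") else s
  }
  aa1to3 <- c(A = "Ala", C = "Cys", D = "Asp", E = "Glu", F = "Phe",
              G = "Gly", H = "His", I = "Ile", K = "Lys", L1 = "Leu",
              L2 = "Leu", M = "Met", N = "Asn", P = "Pro", Q = "Gln",
              R = "Arg", S1 = "Ser", S2 = "Ser", T = "Thr", V = "Val",
              W = "Trp", Y = "Tyr")
  for (i in seq_len(nrow(g))) {
    cat_ <- g$category[i]
    if (cat_ == "PCG") {
      w("     CDS             ", loc(i))
      w("                     /gene=\"", g$gene[i], "\"")
    } else if (cat_ == "tRNA") {
      code <- sub("^trn", "", g$gene[i])
      w("     tRNA            ", loc(i))
      w("                     /product=\"tRNA-", aa1to3[[code]], "\"")
      w("                     /gene=\"", g$gene[i], "\"")
      if (!is.na(g$anticodon[i]))
        w("                     /anticodon=\"(pos:complement,aa:",
          aa1to3[[code]], ",seq:", tolower(g$anticodon[i]), ")\"")
    } else if (cat_ == "rRNA") {
      w("     rRNA            ", loc(i))
      w("                     /gene=\"", g$gene[i], "\"")
    } else if (g$gene[i] == "CR") {
      w("     D-loop          ", loc(i))
    } else {
      w("     misc_feature    ", loc(i))
      w("                     /gene=\"", g$gene[i], "\"")
    }
  }
  if (!is.null(genome@sequence)) {
    w("ORIGIN")
    s <- tolower(as.character(genome@sequence))
    starts <- seq(1L, nchar(s), by = 60L)
    for (p in starts) {
      chunk <- substr(s, p, min(p + 59L, nchar(s)))
      blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                          pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
      w(formatC(p, width = 9L), " ", paste(blocks, collapse = " "))
    }
  }
  w("//")
  invisible(path)
}

# ---- spacers and overlaps ----

#' Intergenic spacer / overlap report
#'
#' For consecutive annotated loci \eqn{i, i+1} (sorted by start on the
#' majority strand, with circular closure between the last and first
#' locus), the intergenic nucleotide count is
#' \code{ign = start(i+1) - stop(i) - 1}; negative values are overlaps.
#' Strand is ignored: both strands share the coordinate system.
#'
#' @param genome a \code{GenomeAnnotation}.
#' @return data.frame with columns \code{upstream_gene},
#'   \code{downstream_gene}, \code{ign}.
#' @export
spacerReport <- function(genome) {
  g <- genome@genes
  L <- genome@genomeLength
  n <- nrow(g)
  up <- seq_len(n)
  down <- c(seq_len(n)[-1L], 1L)
  ign <- integer(n)
  for (i in seq_len(n)) {
    j <- down[i]
    raw <- g$start[j] - g$stop[i] - 1L
    if (i == n && genome@circular) {
      # closing pair: walk forward across the origin; a gene already
      # spanning the origin has its stop on the far side of position 1
      wraps <- g$stop[i] < g$start[i]
      raw <- g$start[j] + (if (wraps) 0L else L) - g$stop[i] - 1L
    }
    ign[i] <- raw
  }
  data.frame(upstream_gene = g$gene[up], downstream_gene = g$gene[down],
             ign = ign, stringsAsFactors = FALSE)
}

#' Circular-aware overlap between two genes
#'
#' Size of the intersection of the two genes' position sets on the circle;
#' symmetric in its arguments.
#'
#' @param startA,stopA,startB,stopB 1-based inclusive coordinates (a gene
#'   may span the origin, i.e. stop < start).
#' @param genomeLength circle length in nt.
#' @return integer overlap in nt.
#' @export
pairwiseOverlap <- function(startA, stopA, startB, stopB, genomeLength) {
  a <- circularPositions(startA, stopA, genomeLength)
  b <- circularPositions(startB, stopB, genomeLength)
  length(intersect(a, b))
}

#' Overlap between two named genes of a genome
#'
#' @param genome a \code{GenomeAnnotation}.
#' @param geneA,geneB gene tokens present in the annotation.
#' @return integer overlap in nt.
#' @export
geneOverlap <- function(genome, geneA, geneB) {
  g <- genome@genes
  ia <- match(geneA, g$gene); ib <- match(geneB, g$gene)
  if (is.na(ia) || is.na(ib)) stop("gene not annotated")
  pairwiseOverlap(g$start[ia], g$stop[ia], g$start[ib], g$stop[ib],
                  genome@genomeLength)
}

#' Residues of a gene not covered by any other annotated locus
#'
#' The number of positions belonging exclusively to \code{gene}; clamped
#' at zero by construction.
#'
#' @param genome a \code{GenomeAnnotation}.
#' @param gene a gene token.
#' @return integer count.
#' @export
exclusiveResidues <- function(genome, gene) {
  g <- genome@genes
  i <- match(gene, g$gene)
  if (is.na(i)) stop("gene not annotated: ", gene)
  mine <- circularPositions(g$start[i], g$stop[i], genome@genomeLength)
  others <- unlist(lapply(seq_len(nrow(g))[-i], function(j)
    circularPositions(g$start[j], g$stop[j], genome@genomeLength)))
  length(setdiff(mine, others))
}

# ---- per-gene sequence extraction ----

#' Extract a gene's transcription-direction sequence
#'
#' Slices the annotated range from the genome sequence (circular-aware)
#' and reverse-complements minority-strand genes, so the result reads in
#' transcription direction.
#'
#' @param genome a \code{GenomeAnnotation} with sequence.
#' @param gene a gene token.
#' @return A \code{DNAString}.
#' @export
geneSequence <- function(genome, gene) {
  if (is.null(genome@sequence)) stop("genome has no sequence")
  g <- genome@genes
  i <- match(gene, g$gene)
  if (is.na(i)) stop("gene not annotated: ", gene)
  pos <- circularPositions(g$start[i], g$stop[i], genome@genomeLength)
  s <- genome@sequence[pos]
  if (g$strand[i] == "-") s <- Biostrings::reverseComplement(s)
  s
}

#' Export genome or per-gene FASTA
#'
#' @param genome a \code{GenomeAnnotation} with sequence.
#' @param path output file.
#' @param perGene if TRUE, write one record per annotated locus
#'   (transcription-direction sequence); otherwise the whole genome.
#' @return invisibly, the path.
#' @export
writeGenomeFasta <- function(genome, path, perGene = FALSE) {
  if (is.null(genome@sequence)) stop("genome has no sequence")
  if (perGene) {
    seqs <- Biostrings::DNAStringSet(lapply(genome@genes$gene, function(g)
      geneSequence(genome, g)))
    names(seqs) <- genome@genes$gene
  } else {
    seqs <- Biostrings::DNAStringSet(genome@sequence)
    names(seqs) <- genome@taxonId
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
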