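#' Canonical mitochondrial gene vocabulary
#'
#' The 37 canonical genes of the animal mitochondrial genome: 13
#' protein-coding genes (PCGs), 22 tRNAs (IUPAC single-letter code with
#' L1/L2 and S1/S2 disambiguated by anticodon) and the two rRNAs, plus the
#' special noncoding loci \code{CR} (control region / A+T-rich region) and
#' \code{OL} (light-strand replication origin).
#'
#' @return Character vector of gene tokens.
#' @export
mitoGeneTokens <- function() {
  c(mitoPCGs(), mitoTRNAs(), c("rrnL", "rrnS"))
}

#' @rdname mitoGeneTokens
#' @export
mitoPCGs <- function() {
  c("cox1", "cox2", "cox3", "nad1", "nad2", "nad3", "nad4", "nad4L",
    "nad5", "nad6", "atp6", "atp8", "cytb")
}

#' @rdname mitoGeneTokens
#' @export
mitoTRNAs <- function() {
  paste0("trn", c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L1", "L2",
                  "M", "N", "P", "Q", "R", "S1", "S2", "T", "V", "W", "Y"))
}

#' @rdname mitoGeneTokens
#' @export
mitoNoncodingLoci <- function() c("CR", "OL")

geneCategory <- function(gene) {
  out <- rep(NA_character_, length(gene))
  out[gene %in% mitoPCGs()] <- "PCG"
  out[gene %in% mitoTRNAs()] <- "tRNA"
  out[gene %in% c("rrnL", "rrnS")] <- "rRNA"
  out[gene %in% mitoNoncodingLoci()] <- "noncoding"
  out
}

checkGeneTokens <- function(genes) {
  known <- c(mitoGeneTokens(), mitoNoncodingLoci())
  bad <- setdiff(genes, known)
  if (length(bad) > 0L) {
    stop("unknown gene token(s): ", paste(bad, collapse = ", "),
         "\nThe 37-gene vocabulary (plus CR, OL) is:\n  ",
         paste(known, collapse = " "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Default gene-name synonym map for GenBank feature tables
#'
#' Maps common GenBank product/gene spellings onto the canonical tokens.
#' Users can extend or override entries via the \code{synonyms} argument of
#' \code{\link{readGenBank}}. tRNA-Leu and tRNA-Ser are ambiguous without an
#' anticodon qualifier and are resolved by anticodon
#' (Leu: anticodon TAG -> trnL1 (CUN), TAA -> trnL2 (UUR);
#'  Ser: anticodon GCT -> trnS1 (AGN), TGA -> trnS2 (UCN)).
#'
#' @return Named character vector: names are upper-cased synonyms, values
#'   canonical tokens.
#' @export
geneSynonyms <- function() {
  syn <- c(
    COX1 = "cox1", COI = "cox1", CO1 = "cox1", COX2 = "cox2", COII = "cox2",
    CO2 = "cox2", COX3 = "cox3", COIII = "cox3", CO3 = "cox3",
    ND1 = "nad1", ND2 = "nad2", ND3 = "nad3", ND4 = "nad4", ND4L = "nad4L",
    ND5 = "nad5", ND6 = "nad6", NAD4L = "nad4L",
    ATP6 = "atp6", ATP8 = "atp8", ATPASE6 = "atp6", ATPASE8 = "atp8",
    CYTB = "cytb", COB = "cytb", CYB = "cytb",
    `16S` = "rrnL", RRNL = "rrnL", `L-RRNA` = "rrnL", `12S` = "rrnS",
    RRNS = "rrnS", `S-RRNA` = "rrnS",
    `D-LOOP` = "CR", `CONTROL REGION` = "CR", CR = "CR", OL = "OL"
  )
  aa3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
           H = "HIS", I = "ILE", K = "LYS", M = "MET", N = "ASN", P = "PRO",
           Q = "GLN", R = "ARG", T = "THR", V = "VAL", W = "TRP", Y = "TYR")
  trn <- structure(paste0("trn", names(aa3)), names = paste0("TRNA-", aa3))
  # canonical tokens map to themselves
  self <- structure(c(mitoGeneTokens(), mitoNoncodingLoci()),
                    names = toupper(c(mitoGeneTokens(), mitoNoncodingLoci())))
  c(syn, trn, self)
}

# ---- circular coordinate helpers (1-based inclusive throughout) ----

circularSize <- function(start, stop, genomeLength) {
  ((stop - start) %% genomeLength) + 1L
}

# positions covered by a gene, walking the circle from start to stop
circularPositions <- function(start, stop, genomeLength) {
  n <- circularSize(start, stop, genomeLength)
  ((start - 1L + seq_len(n) - 1L) %% genomeLength) + 1L
}
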