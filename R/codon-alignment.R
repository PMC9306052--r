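#' CodonPairAlignment: a pair of in-frame aligned coding sequences
#'
#' Container for two gap-aligned coding sequences kept in frame. This is
#' the unit on which all pairwise substitution statistics (Ka, Ks, 4DTv)
#' are computed. Gaps must occur in whole-codon units, so every aligned
#' column triplet is either a complete codon or \code{"---"}.
#'
#' @slot geneId1,geneId2 gene identifiers of the two members.
#' @slot seq1,seq2 aligned nucleotide strings over \{A,C,G,T,-,N\};
#'   equal length, divisible by 3.
#'
#' @seealso [codonPairAlignment()], [computeKaKs()], [compute4DTv()]
#' @export
setClass("CodonPairAlignment",
  representation(geneId1 = "character", geneId2 = "character",
                 seq1 = "character", seq2 = "character"),
  validity = function(object) {
    msg <- character(0)
    s1 <- object@seq1; s2 <- object@seq2
    if (length(s1) != 1L || length(s2) != 1L)
      return("seq1 and seq2 must each be a single string")
    if (nchar(s1) != nchar(s2))
      msg <- c(msg, "aligned sequences must have equal length")
    if (nchar(s1) %% 3L != 0L)
      msg <- c(msg, "alignment length must be divisible by 3")
    if (grepl("[^ACGTN-]", s1) || grepl("[^ACGTN-]", s2))
      msg <- c(msg, "alphabet must be {A,C,G,T,N,-}")
    if (length(msg) == 0L && nchar(s1) > 0L) {
      for (s in c(s1, s2)) {
        starts <- seq.int(1L, nchar(s), by = 3L)
        cod <- substring(s, starts, starts + 2L)
        has_gap <- grepl("-", cod, fixed = TRUE)
        if (any(has_gap & cod != "---"))
          msg <- c(msg, "gaps must occur in whole-codon units")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a CodonPairAlignment
#'
#' @param seq1,seq2 aligned, in-frame nucleotide strings (equal length,
#'   multiple of 3; gaps only as whole \code{"---"} codons).
#' @param geneId1,geneId2 gene identifiers.
#' @return A [CodonPairAlignment-class] object.
#' @examples
#' aln <- codonPairAlignment("ATGGGA", "ATGGGT")
#' computeKaKs(aln)
#' @export
codonPairAlignment <- function(seq1, seq2, geneId1 = "gene1",
                               geneId2 = "gene2") {
  methods::new("CodonPairAlignment",
               geneId1 = as.character(geneId1),
               geneId2 = as.character(geneId2),
               seq1 = toupper(as.character(seq1)),
               seq2 = toupper(as.character(seq2)))
}

#' @describeIn CodonPairAlignment-class number of codon columns
#' @param x a CodonPairAlignment
#' @export
setMethod("length", "CodonPairAlignment",
          function(x) nchar(x@seq1) %/% 3L)

setMethod("show", "CodonPairAlignment", function(object) {
  cat("CodonPairAlignment:", object@geneId1, "vs", object@geneId2, "\n")
  cat(" ", length(object), "codon columns\n")
  w <- min(60L, nchar(object@seq1))
  cat("  ", substr(object@seq1, 1, w), "\n  ", substr(object@seq2, 1, w),
      if (nchar(object@seq1) > w) "...\n" else "\n", sep = "")
})

# Codon index vectors for both sequences plus usability mask: a column
# is usable when both codons are gap-free, N-free and non-stop.
.aln_codons <- function(aln) {
  c1 <- .codon_indices(aln@seq1)
  c2 <- .codon_indices(aln@seq2)
  usable <- !is.na(c1) & !is.na(c2) & !.IS_STOP[ifelse(is.na(c1), 1L, c1)] &
    !.IS_STOP[ifelse(is.na(c2), 1L, c2)]
  list(c1 = c1, c2 = c2, usable = usable)
}

.translate_cds <- function(cds, label) {
  if (nchar(cds) %% 3L != 0L)
    stop(label, ": CDS length not divisible by 3")
  idx <- .codon_indices(cds)
  if (anyNA(idx))
    stop(label, ": CDS contains non-ACGT codon at codon ",
         which(is.na(idx))[1])
  aa <- .AA[idx]
  if (any(aa == "*"))
    stop(label, ": internal stop codon at codon ", which(aa == "*")[1])
  paste(aa, collapse = "")
}

#' Map a protein alignment back onto coding sequences
#'
#' Expands an aligned amino-acid pair into a codon alignment: each
#' residue is replaced by its source codon and each gap by
#' \code{"---"}. The coding sequences must translate exactly (standard
#' genetic code) to the ungapped proteins.
#'
#' @param protein1,protein2 aligned amino-acid strings (equal length,
#'   gaps as \code{"-"}).
#' @param cds1,cds2 ungapped coding sequences, lengths three times the
#'   ungapped protein lengths.
#' @param geneId1,geneId2 gene identifiers.
#' @return A [CodonPairAlignment-class].
#' @examples
#' backtranslateCodonAlignment("MK", "MK", "ATGAAA", "ATGAAG")
#' @export
backtranslateCodonAlignment <- function(protein1, protein2, cds1, cds2,
                                        geneId1 = "gene1",
                                        geneId2 = "gene2") {
  if (nchar(protein1) != nchar(protein2))
    stop("aligned proteins must have equal length")
  expand <- function(prot, cds, label) {
    ungapped <- gsub("-", "", prot, fixed = TRUE)
    trans <- .translate_cds(cds, label)
    if (nchar(trans) != nchar(ungapped))
      stop(label, ": CDS translates to ", nchar(trans),
           " residues but protein has ", nchar(ungapped))
    ta <- strsplit(trans, "")[[1]]
    pa <- strsplit(ungapped, "")[[1]]
    bad <- which(ta != pa)
    if (length(bad))
      stop(label, ": translation mismatch at residue ", bad[1],
           " (CDS gives ", ta[bad[1]], ", protein has ", pa[bad[1]], ")")
    res <- strsplit(prot, "")[[1]]
    starts <- seq.int(1L, nchar(cds), by = 3L)
    codons <- substring(cds, starts, starts + 2L)
    out <- character(length(res))
    k <- 0L
    for (i in seq_along(res)) {
      if (res[i] == "-") out[i] <- "---"
      else { k <- k + 1L; out[i] <- codons[k] }
    }
    paste(out, collapse = "")
  }
  codonPairAlignment(expand(protein1, cds1, geneId1),
                     expand(protein2, cds2, geneId2),
                     geneId1, geneId2)
}
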