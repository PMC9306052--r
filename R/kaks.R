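#' Fourfold-degenerate codon columns of a pair alignment
#'
#' A codon column qualifies as a fourfold-degenerate (4D) site when both
#' codons are gap-free, N-free and non-stop, both belong to a
#' fourfold-degenerate codon family (any third-position nucleotide
#' encodes the same amino acid), and the first two codon positions are
#' identical across the two sequences. The last condition guards
#' against scoring third positions whose degeneracy class differs
#' between the two codons.
#'
#' @param aln a [CodonPairAlignment-class].
#' @return Integer vector of qualifying codon-column indices (1-based).
#' @examples
#' fourfoldSites(codonPairAlignment("GGAGAA", "GGTGAA"))
#' @export
fourfoldSites <- function(aln) {
  stopifnot(methods::is(aln, "CodonPairAlignment"))
  cc <- .aln_codons(aln)
  ok <- cc$usable
  ok[ok] <- .FOURFOLD[cc$c1[ok]] & .FOURFOLD[cc$c2[ok]] &
    .PREFIX[cc$c1[ok]] == .PREFIX[cc$c2[ok]]
  which(ok)
}

#' Third-position transversion rate at fourfold-degenerate sites (4DTv)
#'
#' Counts, over the columns returned by [fourfoldSites()], the fraction
#' whose third-position nucleotides differ by a transversion
#' (purine/pyrimidine exchange). Transitions do not count. With
#' \code{correct = TRUE} an HKY-style multiple-hit correction
#' \eqn{-\frac{1}{2}\log(1 - 2\,v)} is applied; it is undefined (NA)
#' when the raw proportion reaches 0.5. The raw proportion is the
#' primary statistic; correction is off by default.
#'
#' @param aln a [CodonPairAlignment-class].
#' @param correct logical; also compute the corrected distance.
#' @return A list with \code{n_4d_sites}, \code{n_transversions},
#'   \code{raw_4dtv} and \code{corrected_4dtv} (both NA when no 4D site
#'   exists; \code{corrected_4dtv} NA unless \code{correct}).
#' @examples
#' compute4DTv(codonPairAlignment("GGA", "GGT"))
#' @export
compute4DTv <- function(aln, correct = FALSE) {
  idx <- fourfoldSites(aln)
  c1 <- .codon_indices(aln@seq1)[idx]
  c2 <- .codon_indices(aln@seq2)[idx]
  n4 <- length(idx)
  ntv <- sum(.THIRD_PURINE[c1] != .THIRD_PURINE[c2])
  raw <- if (n4 > 0L) ntv / n4 else NA_real_
  corrected <- NA_real_
  if (correct && n4 > 0L && !is.na(raw) && raw < 0.5)
    corrected <- -0.5 * log(1 - 2 * raw)
  list(n_4d_sites = n4, n_transversions = ntv,
       raw_4dtv = raw, corrected_4dtv = corrected)
}

.jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - (4 / 3) * p))
}

#' NG86-style Ka/Ks for a codon pair alignment
#'
#' Nei--Gojobori (1986) counting with equal-weight pathway averaging:
#' synonymous and nonsynonymous site counts per codon are obtained by
#' enumerating all three single-nucleotide changes at each position
#' (changes to stop codons count as nonsynonymous), averaged across the
#' two sequences; observed differences in codons that differ at more
#' than one position are averaged over all minimal substitution
#' pathways with equal weights, excluding pathways that pass through a
#' stop codon. Raw proportions pS = Sd/S and pN = Nd/N are corrected
#' for multiple hits with the Jukes--Cantor formula
#' \eqn{d = -\frac{3}{4}\log(1 - \frac{4}{3} p)}; a proportion at or
#' beyond the 3/4 saturation boundary yields an NA distance (a
#' first-class "saturated" value, not an error). Columns containing a
#' gap, an N or a stop codon are excluded from all counts.
#'
#' @param aln a [CodonPairAlignment-class] with at least one usable
#'   (gap-free, N-free, non-stop) codon column.
#' @return A list with fields \code{S}, \code{N} (site counts),
#'   \code{Sd}, \code{Nd} (differences), \code{pS}, \code{pN},
#'   \code{Ks}, \code{Ka}, \code{omega} (Ka/Ks; NA when Ks is 0 or NA)
#'   and \code{n_codons_used}.
#' @examples
#' computeKaKs(codonPairAlignment(strrep("TTT", 10),
#'                                paste0(strrep("TTT", 9), "TTC")))
#' @export
computeKaKs <- function(aln) {
  stopifnot(methods::is(aln, "CodonPairAlignment"))
  cc <- .aln_codons(aln)
  c1 <- cc$c1[cc$usable]
  c2 <- cc$c2[cc$usable]
  n <- length(c1)
  if (n == 0L)
    stop("no usable codon columns (all contain gaps, N or stop codons)")
  S <- sum((.SYN_SITES[c1] + .SYN_SITES[c2]) / 2)
  N <- 3 * n - S
  Sd <- sum(.SD_MAT[cbind(c1, c2)])
  Nd <- sum(.ND_MAT[cbind(c1, c2)])
  pS <- Sd / S
  pN <- Nd / N
  Ks <- .jc_correct(pS)
  Ka <- .jc_correct(pN)
  omega <- if (is.na(Ks) || Ks == 0) NA_real_ else Ka / Ks
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       Ks = Ks, Ka = Ka, omega = omega, n_codons_used = n)
}

#' Substitution statistics table for a list of pair alignments
#'
#' Runs [computeKaKs()] and [compute4DTv()] on each alignment and
#' returns one row per pair in the standard output layout.
#'
#' @param alignments list of [CodonPairAlignment-class] objects.
#' @param correct4dtv logical, passed to [compute4DTv()].
#' @return data.frame with columns gene1, gene2, n_codons_used, S, N,
#'   Sd, Nd, Ks, Ka, omega, n_4d_sites, raw_4dtv, corrected_4dtv.
#' @export
kaksTable <- function(alignments, correct4dtv = FALSE) {
  rows <- lapply(alignments, function(aln) {
    k <- computeKaKs(aln)
    f <- compute4DTv(aln, correct = correct4dtv)
    data.frame(gene1 = aln@geneId1, gene2 = aln@geneId2,
               n_codons_used = k$n_codons_used, S = k$S, N = k$N,
               Sd = k$Sd, Nd = k$Nd, Ks = k$Ks, Ka = k$Ka,
               omega = k$omega, n_4d_sites = f$n_4d_sites,
               raw_4dtv = f$raw_4dtv, corrected_4dtv = f$corrected_4dtv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write / read a substitution statistics table
#'
#' Tab-separated, \code{NA} encodes the undefined (saturated) flag.
#' @param tab data.frame from [kaksTable()].
#' @param path file path.
#' @export
writeKaksTable <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeKaksTable
#' @export
readKaksTable <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
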