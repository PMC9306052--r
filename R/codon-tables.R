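# Internal codon lookup tables, built once at install time from the
# standard genetic code.  All downstream codon statistics are table
# lookups over integer codon indices (1..64, ordering of
# Biostrings::GENETIC_CODE).

.CODONS <- names(Biostrings::GENETIC_CODE)
.AA <- unname(Biostrings::GENETIC_CODE)
.NT <- c("T", "C", "A", "G")
.IS_STOP <- .AA == "*"
.PURINE <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)

# codon index -> nucleotide at each position (character matrix 64 x 3)
.CODON_NT <- do.call(rbind, strsplit(.CODONS, ""))

.codon_index <- function(codon) match(codon, .CODONS)

# All single-nucleotide neighbours of a codon, by position.
.mutate_codon <- function(codon, pos, nt) {
  s <- strsplit(codon, "")[[1]]
  s[pos] <- nt
  paste(s, collapse = "")
}

# Per-codon synonymous site count (NG86): at each position, the fraction
# of the 3 possible single-nucleotide changes that preserve the amino
# acid.  Changes to stop codons count as nonsynonymous.
.SYN_SITES <- vapply(seq_len(64), function(i) {
  if (.IS_STOP[i]) return(NA_real_)
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(.NT, .CODON_NT[i, pos])) {
      j <- .codon_index(.mutate_codon(.CODONS[i], pos, nt))
      if (!.IS_STOP[j] && .AA[j] == .AA[i]) s <- s + 1 / 3
    }
  }
  s
}, numeric(1))

# Fourfold-degenerate family: every third-position variant encodes the
# same amino acid.
.FOURFOLD <- vapply(seq_len(64), function(i) {
  if (.IS_STOP[i]) return(FALSE)
  variants <- vapply(.NT, function(nt)
    .codon_index(.mutate_codon(.CODONS[i], 3L, nt)), integer(1))
  length(unique(.AA[variants])) == 1L && !any(.IS_STOP[variants])
}, logical(1))

# Prefix id (first two codon positions) and third-position purine flag,
# used by the 4DTv classifier.
.PREFIX <- substr(.CODONS, 1L, 2L)
.THIRD_PURINE <- unname(.PURINE[.CODON_NT[, 3]])

# Synonymous / nonsynonymous difference counts for every codon pair,
# averaging over all minimal substitution pathways with equal weight;
# pathways passing through a stop codon are excluded (if every pathway
# is blocked, the average falls back to all pathways).
.perm_list <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (k in seq_along(v)) {
    for (rest in .perm_list(v[-k])) out[[length(out) + 1L]] <- c(v[k], rest)
  }
  out
}

.path_counts <- function(i, j) {
  diffs <- which(.CODON_NT[i, ] != .CODON_NT[j, ])
  if (length(diffs) == 0L) return(c(0, 0))
  orders <- .perm_list(diffs)
  step_counts <- function(ord, allow_stop) {
    cur <- .CODONS[i]
    sd <- 0; nd <- 0
    for (pos in ord) {
      nxt <- .mutate_codon(cur, pos, .CODON_NT[j, pos])
      a <- .codon_index(cur); b <- .codon_index(nxt)
      if (!allow_stop && .IS_STOP[b] && nxt != .CODONS[j]) return(NULL)
      if (.AA[a] == .AA[b]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(orders, step_counts, allow_stop = FALSE))
  if (length(res) == 0L) res <- lapply(orders, step_counts, allow_stop = TRUE)
  m <- do.call(rbind, res)
  colMeans(m)
}

.SD_MAT <- matrix(NA_real_, 64, 64)
.ND_MAT <- matrix(NA_real_, 64, 64)
for (.i in seq_len(64)) {
  if (.IS_STOP[.i]) next
  for (.j in seq_len(64)) {
    if (.IS_STOP[.j]) next
    cnt <- .path_counts(.i, .j)
    .SD_MAT[.i, .j] <- cnt[1]
    .ND_MAT[.i, .j] <- cnt[2]
  }
}
rm(.i, .j)

# Synonymous and nonsynonymous single-nucleotide neighbour lists, used
# by the sequence simulator (indices into .CODONS; stops excluded).
.SYN_NEIGHBORS <- lapply(seq_len(64), function(i) {
  if (.IS_STOP[i]) return(integer(0))
  out <- integer(0)
  for (pos in 1:3) for (nt in setdiff(.NT, .CODON_NT[i, pos])) {
    j <- .codon_index(.mutate_codon(.CODONS[i], pos, nt))
    if (!.IS_STOP[j] && .AA[j] == .AA[i]) out <- c(out, j)
  }
  out
})
.NONSYN_NEIGHBORS <- lapply(seq_len(64), function(i) {
  if (.IS_STOP[i]) return(integer(0))
  out <- integer(0)
  for (pos in 1:3) for (nt in setdiff(.NT, .CODON_NT[i, pos])) {
    j <- .codon_index(.mutate_codon(.CODONS[i], pos, nt))
    if (!.IS_STOP[j] && .AA[j] != .AA[i]) out <- c(out, j)
  }
  out
})
.N_SYN_NEIGHBORS <- lengths(.SYN_NEIGHBORS)
.N_NONSYN_NEIGHBORS <- lengths(.NONSYN_NEIGHBORS)
.SENSE_CODONS <- which(!.IS_STOP)

# Split a gapless in-frame nucleotide string into codon index vector
# (NA for codons containing N or other non-ACGT letters).
.codon_indices <- function(seq) {
  n <- nchar(seq)
  starts <- seq.int(1L, n, by = 3L)
  match(substring(seq, starts, starts + 2L), .CODONS)
}
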