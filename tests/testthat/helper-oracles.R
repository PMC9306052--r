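# Independent oracles used by the tests. These deliberately avoid the
# package's lookup tables and DP code: substitution pathways are
# enumerated by recursion over position orders straight from the
# genetic code, and chains by exhaustive search.

oracle_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

# Equal-weight average of synonymous/nonsynonymous step counts over
# all minimal substitution pathways between two sense codons,
# excluding pathways through stop codons (falling back to all
# pathways if every one is blocked).
oracle_path_counts <- function(c1, c2) {
  s1 <- strsplit(c1, "")[[1]]
  s2 <- strsplit(c2, "")[[1]]
  diffs <- which(s1 != s2)
  if (length(diffs) == 0L) return(c(sd = 0, nd = 0))
  walk <- function(cur, remaining, allow_stop) {
    if (length(remaining) == 0L) return(list(c(0, 0)))
    out <- list()
    for (k in seq_along(remaining)) {
      pos <- remaining[k]
      v <- strsplit(cur, "")[[1]]
      v[pos] <- s2[pos]
      nxt <- paste(v, collapse = "")
      if (!allow_stop && oracle_aa(nxt) == "*" && nxt != c2) next
      step <- if (oracle_aa(cur) == oracle_aa(nxt)) c(1, 0) else c(0, 1)
      for (tail in walk(nxt, remaining[-k], allow_stop))
        out[[length(out) + 1L]] <- step + tail
    }
    out
  }
  paths <- walk(c1, diffs, allow_stop = FALSE)
  if (length(paths) == 0L) paths <- walk(c1, diffs, allow_stop = TRUE)
  m <- Reduce(`+`, paths) / length(paths)
  c(sd = m[1], nd = m[2])
}

# NG86 synonymous site count of one codon, from the genetic code.
oracle_syn_sites <- function(codon) {
  s <- strsplit(codon, "")[[1]]
  tot <- 0
  for (pos in 1:3) for (nt in setdiff(c("A", "C", "G", "T"), s[pos])) {
    v <- s; v[pos] <- nt
    mut <- paste(v, collapse = "")
    if (oracle_aa(mut) != "*" && oracle_aa(mut) == oracle_aa(codon))
      tot <- tot + 1 / 3
  }
  tot
}

# Exhaustive best collinear chain score over all anchor subsets, both
# orientations, same scoring model as the chainer. Feasibility: ranks
# strictly increasing on a; strictly increasing (plus) or decreasing
# (minus) on b; consecutive gaps <= max_gap.
oracle_best_chain <- function(ra, rb, params) {
  n <- length(ra)
  best <- -Inf
  for (minus in c(FALSE, TRUE)) {
    ext <- function(last, score) {
      best <<- max(best, score)
      for (j in seq_len(n)) {
        da <- ra[j] - ra[last]
        db <- if (minus) rb[last] - rb[j] else rb[j] - rb[last]
        if (da < 1 || db < 1) next
        if (da > params$max_gap || db > params$max_gap) next
        ext(j, score + params$match_score +
              params$gap_penalty * ((da - 1) + (db - 1)))
      }
    }
    for (s in seq_len(n)) ext(s, params$match_score)
  }
  best
}

# Minimal 12-column hit table for a set of gene pairs.
mk_hits <- function(q, s, bitscore = 500, evalue = 1e-50) {
  n <- length(q)
  data.frame(qseqid = q, sseqid = s, pident = rep(90, n),
             length = rep(100L, n), mismatch = rep(0L, n),
             gapopen = rep(0L, n), qstart = rep(1L, n),
             qend = rep(100L, n), sstart = rep(1L, n),
             send = rep(100L, n), evalue = rep(evalue, n),
             bitscore = rep(bitscore, n), stringsAsFactors = FALSE)
}

# Annotation with one gene per rank position on given chromosomes.
mk_ann <- function(ids, chrom) {
  pos <- stats::ave(seq_along(ids), chrom, FUN = seq_along)
  buildGeneRanks(data.frame(gene_id = ids, chromosome = chrom,
                            start = (pos - 1) * 100,
                            end = (pos - 1) * 100 + 50,
                            strand = "+", stringsAsFactors = FALSE))
}
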