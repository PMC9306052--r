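#' Synteny chaining parameters
#'
#' Parameters of the MCScanX-style collinearity chainer. The anchor
#' minimum of 5 genes per block is the field-standard block definition;
#' scoring mimics MCScanX defaults.
#'
#' @param min_block_genes minimum anchors per reported block (>= 2).
#' @param max_gap maximum rank gap between consecutive anchors, on
#'   either chromosome (rank units).
#' @param match_score score contributed by each anchor.
#' @param gap_penalty penalty per skipped rank unit (negative).
#' @param max_hits_per_query best hits kept per query gene before
#'   chaining.
#' @param evalue_cutoff maximum hit E-value retained.
#' @param tandem_rank_dist within-genome hits between genes at most
#'   this many ranks apart on one chromosome are treated as tandem
#'   duplicates and collapsed to the best-scoring representative.
#' @return A named list of class \code{"SyntenyParams"}.
#' @export
syntenyParams <- function(min_block_genes = 5L, max_gap = 25L,
                          match_score = 50, gap_penalty = -1,
                          max_hits_per_query = 5L,
                          evalue_cutoff = 1e-10,
                          tandem_rank_dist = 5L) {
  stopifnot(min_block_genes >= 2L, max_gap >= 1L, gap_penalty <= 0)
  structure(list(min_block_genes = as.integer(min_block_genes),
                 max_gap = as.integer(max_gap),
                 match_score = match_score, gap_penalty = gap_penalty,
                 max_hits_per_query = as.integer(max_hits_per_query),
                 evalue_cutoff = evalue_cutoff,
                 tandem_rank_dist = as.integer(tandem_rank_dist)),
            class = "SyntenyParams")
}

#' Assign dense per-chromosome rank orders to gene models
#'
#' Sorts genes by (chromosome, start, gene_id) and assigns rank 0..n-1
#' independently within each chromosome. Internal coordinates are
#' 0-based half-open.
#'
#' @param annotation data.frame with columns gene_id, chromosome,
#'   start, end, and optionally strand.
#' @return The annotation sorted, with a dense integer \code{rank}
#'   column added.
#' @export
buildGeneRanks <- function(annotation) {
  req <- c("gene_id", "chromosome", "start", "end")
  if (!all(req %in% names(annotation)))
    stop("annotation needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(annotation$gene_id))
    stop("duplicate gene_id: ",
         annotation$gene_id[duplicated(annotation$gene_id)][1])
  if (any(annotation$start >= annotation$end))
    stop("gene coordinates must satisfy start < end")
  ord <- order(annotation$chromosome, annotation$start,
               annotation$gene_id)
  annotation <- annotation[ord, , drop = FALSE]
  annotation$rank <- stats::ave(seq_len(nrow(annotation)),
                                annotation$chromosome,
                                FUN = function(i) seq_along(i) - 1L)
  rownames(annotation) <- NULL
  annotation
}

#' Read gene models from GFF3 or BED
#'
#' GFF3 \code{gene} features are read with 1-based inclusive
#' coordinates and converted to the package's 0-based half-open
#' convention; BED6 is read natively. Gene ids come from the GFF3
#' \code{ID} attribute or BED name column.
#'
#' @param path file path (format guessed from the extension unless
#'   given).
#' @param format "gff3" or "bed".
#' @return A ranked annotation data.frame (see [buildGeneRanks()]).
#' @export
readGeneModels <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
              else "gff3"
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    ids <- if (!is.null(gr$name)) gr$name else
      paste0("gene_", seq_along(gr))
  } else {
    gr <- rtracklayer::import(path, format = "GFF3")
    gr <- gr[gr$type == "gene"]
    if (length(gr) == 0L) stop("no gene features in ", path)
    ids <- gr$ID
  }
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "+"
  ann <- data.frame(gene_id = as.character(ids),
                    chromosome = as.character(
                      GenomicRanges::seqnames(gr)),
                    start = BiocGenerics::start(gr) - 1,
                    end = BiocGenerics::end(gr),
                    strand = strand, stringsAsFactors = FALSE)
  buildGeneRanks(ann)
}

#' Read 12-column tabular homology hits
#'
#' Standard tabular hit format: qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore.
#' @param path file path.
#' @return data.frame with those column names.
#' @export
readHomologyHits <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:12] <- c("qseqid", "sseqid", "pident", "length",
                       "mismatch", "gapopen", "qstart", "qend",
                       "sstart", "send", "evalue", "bitscore")
  df
}

# E-value filter, self-hit removal, per-query top hits, and for
# within-genome mode (x,y)/(y,x) deduplication and tandem collapse.
.filter_hits <- function(hits, ranks_a, ranks_b, params, within) {
  hits <- hits[hits$evalue <= params$evalue_cutoff, , drop = FALSE]
  hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
  unknown <- setdiff(c(hits$qseqid, hits$sseqid),
                     c(ranks_a$gene_id, ranks_b$gene_id))
  if (length(unknown))
    stop("hit references unknown gene id: ", unknown[1])
  # top hits per query, by descending bitscore (ties: subject id)
  ord <- order(hits$qseqid, -hits$bitscore, hits$sseqid)
  hits <- hits[ord, , drop = FALSE]
  keep <- stats::ave(seq_len(nrow(hits)), hits$qseqid,
                     FUN = seq_along) <= params$max_hits_per_query
  hits <- hits[keep, , drop = FALSE]
  if (within && nrow(hits)) {
    key <- ifelse(hits$qseqid < hits$sseqid,
                  paste(hits$qseqid, hits$sseqid),
                  paste(hits$sseqid, hits$qseqid))
    ord <- order(key, -hits$bitscore)
    hits <- hits[ord, , drop = FALSE]
    hits <- hits[!duplicated(key[ord]), , drop = FALSE]
    # tandem collapse: same-chromosome nearby pairs
    qi <- match(hits$qseqid, ranks_a$gene_id)
    si <- match(hits$sseqid, ranks_a$gene_id)
    tandem <- !is.na(qi) & !is.na(si) &
      ranks_a$chromosome[qi] == ranks_a$chromosome[si] &
      abs(ranks_a$rank[qi] - ranks_a$rank[si]) <= params$tandem_rank_dist
    hits <- hits[!tandem, , drop = FALSE]
  }
  hits
}

# Best chain by DP over anchors ordered by rank_a, for one orientation.
# Returns list(idx, score) of the best chain, or NULL.
.best_chain <- function(ra, rb, params, minus) {
  n <- length(ra)
  if (n == 0L) return(NULL)
  o <- order(ra, if (minus) -rb else rb)
  ra <- ra[o]; rb <- rb[o]
  score <- rep(params$match_score, n)
  prev <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1L)) {
      da <- ra[j] - ra[i]
      db <- if (minus) rb[i] - rb[j] else rb[j] - rb[i]
      if (da < 1L || db < 1L) next
      if (da > params$max_gap || db > params$max_gap) next
      cand <- score[i] + params$match_score +
        params$gap_penalty * ((da - 1L) + (db - 1L))
      if (cand > score[j] + 1e-9) { score[j] <- cand; prev[j] <- i }
    }
  }
  jbest <- which.max(score)
  idx <- integer(0)
  j <- jbest
  while (!is.na(j)) { idx <- c(j, idx); j <- prev[j] }
  list(idx = o[idx], score = score[jbest])
}

#' Chain homology hits into collinear synteny blocks
#'
#' MCScanX-style block detection: per chromosome pair, anchors (hits
#' surviving E-value/top-hit/tandem filters) are chained by dynamic
#' programming maximizing \eqn{\sum \mathrm{match} +
#' \mathrm{gap\_penalty} \cdot \mathrm{gaps}}, separately for plus
#' (both ranks increasing) and minus (second rank decreasing)
#' orientation, with consecutive-anchor rank gaps bounded by
#' \code{max_gap}. Chains are accepted greedily by descending score
#' (ties: more anchors, then lexicographic chromosome pair), removing
#' their anchors, until no chain reaches \code{min_block_genes}
#' anchors.
#'
#' @param hits homology hit data.frame (see [readHomologyHits()]).
#' @param ranks_a,ranks_b ranked annotations from [buildGeneRanks()];
#'   pass the same object twice for within-genome mode (detected
#'   automatically, triggering self-hit/tandem handling).
#' @param params a [syntenyParams()] list.
#' @return A \code{SyntenyBlocks} object (see
#'   [SyntenyBlocks-class]).
#' @export
chainSyntenyBlocks <- function(hits, ranks_a, ranks_b,
                               params = syntenyParams()) {
  within <- identical(ranks_a$gene_id, ranks_b$gene_id)
  hits <- .filter_hits(hits, ranks_a, ranks_b, params, within)
  ia <- match(hits$qseqid, ranks_a$gene_id)
  ib <- match(hits$sseqid, ranks_b$gene_id)
  if (within) {
    # orient each pair so both members resolve
    swap <- is.na(ia) | is.na(ib)
    if (any(swap)) stop("within-genome mode requires one annotation")
  }
  anchors <- data.frame(gene_a = hits$qseqid, gene_b = hits$sseqid,
                        chrom_a = ranks_a$chromosome[ia],
                        chrom_b = ranks_b$chromosome[ib],
                        rank_a = ranks_a$rank[ia],
                        rank_b = ranks_b$rank[ib],
                        stringsAsFactors = FALSE)
  if (within) {
    # canonical chromosome-pair orientation for a self comparison
    flip <- anchors$chrom_a > anchors$chrom_b |
      (anchors$chrom_a == anchors$chrom_b &
         anchors$rank_a > anchors$rank_b)
    anchors[flip, c("gene_a", "gene_b", "chrom_a", "chrom_b",
                    "rank_a", "rank_b")] <-
      anchors[flip, c("gene_b", "gene_a", "chrom_b", "chrom_a",
                      "rank_b", "rank_a")]
  }
  anchors <- anchors[order(anchors$chrom_a, anchors$chrom_b,
                           anchors$rank_a, anchors$rank_b,
                           anchors$gene_a, anchors$gene_b), ,
                     drop = FALSE]
  blocks <- list(); block_anchors <- list()
  cp <- unique(anchors[, c("chrom_a", "chrom_b")])
  cp <- cp[order(cp$chrom_a, cp$chrom_b), , drop = FALSE]
  bid <- 0L
  for (k in seq_len(nrow(cp))) {
    sub <- anchors[anchors$chrom_a == cp$chrom_a[k] &
                     anchors$chrom_b == cp$chrom_b[k], , drop = FALSE]
    repeat {
      best <- NULL; best_orient <- NA_character_
      for (orient in c("plus", "minus")) {
        ch <- .best_chain(sub$rank_a, sub$rank_b, params,
                          minus = orient == "minus")
        if (is.null(ch)) next
        if (length(ch$idx) < params$min_block_genes) next
        if (is.null(best) || ch$score > best$score + 1e-9 ||
            (abs(ch$score - best$score) <= 1e-9 &&
               length(ch$idx) > length(best$idx))) {
          best <- ch; best_orient <- orient
        }
      }
      if (is.null(best)) break
      bid <- bid + 1L
      sel <- sub[best$idx, , drop = FALSE]
      # a gene participates in at most one anchor per block
      sel <- sel[!duplicated(sel$gene_a) & !duplicated(sel$gene_b), ,
                 drop = FALSE]
      blocks[[bid]] <- data.frame(
        block_id = sprintf("block_%04d", bid),
        chrom_a = cp$chrom_a[k], chrom_b = cp$chrom_b[k],
        orientation = best_orient, n_anchors = nrow(sel),
        score = best$score, stringsAsFactors = FALSE)
      block_anchors[[bid]] <- data.frame(
        block_id = sprintf("block_%04d", bid),
        gene_a = sel$gene_a, gene_b = sel$gene_b,
        rank_a = sel$rank_a, rank_b = sel$rank_b,
        stringsAsFactors = FALSE)
      used <- paste(sel$gene_a, sel$gene_b) # remove chained anchors
      sub <- sub[!(paste(sub$gene_a, sub$gene_b) %in% used), ,
                 drop = FALSE]
      sub <- sub[!(sub$gene_a %in% sel$gene_a) &
                   !(sub$gene_b %in% sel$gene_b), , drop = FALSE]
      if (nrow(sub) < params$min_block_genes) break
    }
  }
  bl <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(block_id = character(0), chrom_a = character(0),
               chrom_b = character(0), orientation = character(0),
               n_anchors = integer(0), score = numeric(0))
  an <- if (length(block_anchors)) do.call(rbind, block_anchors) else
    data.frame(block_id = character(0), gene_a = character(0),
               gene_b = character(0), rank_a = integer(0),
               rank_b = integer(0))
  # deterministic ordering and ids: sort by score desc, anchors, chrom
  if (nrow(bl)) {
    ord <- order(-bl$score, -bl$n_anchors, bl$chrom_a, bl$chrom_b)
    bl <- bl[ord, , drop = FALSE]
    newid <- sprintf("block_%04d", seq_len(nrow(bl)))
    an$block_id <- newid[match(an$block_id, bl$block_id)]
    bl$block_id <- newid
    an <- an[order(an$block_id, an$rank_a), , drop = FALSE]
    rownames(bl) <- rownames(an) <- NULL
  }
  methods::new("SyntenyBlocks", blocks = bl, anchors = an,
               params = unclass(params))
}

#' SyntenyBlocks: collinear blocks and their anchor gene pairs
#'
#' Result container of [chainSyntenyBlocks()]. Validity enforces the
#' block contract: every block has at least \code{min_block_genes}
#' anchors, anchor ranks strictly increase along the first chromosome
#' and strictly increase (plus) or decrease (minus) along the second,
#' and consecutive rank gaps never exceed \code{max_gap}.
#'
#' @slot blocks data.frame (block_id, chrom_a, chrom_b, orientation,
#'   n_anchors, score).
#' @slot anchors data.frame (block_id, gene_a, gene_b, rank_a, rank_b).
#' @slot params the chaining parameter list.
#' @export
setClass("SyntenyBlocks",
  representation(blocks = "data.frame", anchors = "data.frame",
                 params = "list"),
  validity = function(object) {
    bl <- object@blocks; an <- object@anchors; p <- object@params
    for (i in seq_len(nrow(bl))) {
      a <- an[an$block_id == bl$block_id[i], , drop = FALSE]
      if (nrow(a) != bl$n_anchors[i])
        return("anchor count mismatch")
      if (nrow(a) < p$min_block_genes)
        return("block below min_block_genes")
      a <- a[order(a$rank_a), , drop = FALSE]
      if (any(diff(a$rank_a) < 1L))
        return("rank_a not strictly increasing")
      db <- diff(a$rank_b)
      if (bl$orientation[i] == "plus" && any(db < 1L))
        return("rank_b not strictly increasing in plus block")
      if (bl$orientation[i] == "minus" && any(db > -1L))
        return("rank_b not strictly decreasing in minus block")
      if (any(abs(diff(a$rank_a)) > p$max_gap) ||
          any(abs(db) > p$max_gap))
        return("rank gap exceeds max_gap")
      if (anyDuplicated(a$gene_a) || anyDuplicated(a$gene_b))
        return("gene repeated within a block")
    }
    TRUE
  })

setMethod("show", "SyntenyBlocks", function(object) {
  cat("SyntenyBlocks:", nrow(object@blocks), "blocks,",
      nrow(object@anchors), "anchors\n")
  if (nrow(object@blocks))
    print(utils::head(object@blocks, 5))
})

#' @describeIn SyntenyBlocks-class block table accessor
#' @param x a SyntenyBlocks object
#' @export
blocks <- function(x) x@blocks

#' @describeIn SyntenyBlocks-class anchor table accessor
#' @export
anchors <- function(x) x@anchors

#' Homoeolog pairs across subgenomes
#'
#' Returns anchors of blocks whose two chromosomes carry different
#' subgenome labels, oriented with the A-subgenome member first.
#' A pair appearing in several qualifying blocks is kept once, from
#' the highest-scoring block.
#'
#' @param synteny a [SyntenyBlocks-class].
#' @param subgenome_map named character vector, chromosome ->
#'   "A"/"B" (outgroup chromosomes may be absent only if no block
#'   touches them).
#' @return data.frame (gene_a, gene_b, chrom_a, chrom_b, block_id)
#'   with gene_a on the A subgenome.
#' @export
homoeologPairs <- function(synteny, subgenome_map) {
  bl <- blocks(synteny); an <- anchors(synteny)
  chroms <- unique(c(bl$chrom_a, bl$chrom_b))
  missing <- setdiff(chroms, names(subgenome_map))
  if (length(missing))
    stop("chromosome without subgenome label: ", missing[1])
  la <- subgenome_map[bl$chrom_a]; lb <- subgenome_map[bl$chrom_b]
  keep <- bl$block_id[la != lb]
  an <- an[an$block_id %in% keep, , drop = FALSE]
  if (nrow(an) == 0L)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      chrom_a = character(0), chrom_b = character(0),
                      block_id = character(0)))
  bidx <- match(an$block_id, bl$block_id)
  an$chrom_a <- bl$chrom_a[bidx]; an$chrom_b <- bl$chrom_b[bidx]
  an$score <- bl$score[bidx]
  flip <- subgenome_map[an$chrom_a] == "B"
  an[flip, c("gene_a", "gene_b", "chrom_a", "chrom_b")] <-
    an[flip, c("gene_b", "gene_a", "chrom_b", "chrom_a")]
  key <- ifelse(an$gene_a < an$gene_b,
                paste(an$gene_a, an$gene_b),
                paste(an$gene_b, an$gene_a))
  an <- an[order(-an$score, an$block_id), , drop = FALSE]
  an <- an[!duplicated(key[order(-an$score, an$block_id)]), ,
           drop = FALSE]
  rownames(an) <- NULL
  an[, c("gene_a", "gene_b", "chrom_a", "chrom_b", "block_id")]
}

#' WGD paralog pairs anchored by a single outgroup copy
#'
#' Identifies focal-genome gene pairs retained from a whole-genome
#' duplication: an outgroup gene that anchors (in focal-vs-outgroup
#' blocks) to exactly two distinct focal genes, where those two focal
#' genes also form an anchor in the focal-vs-focal blocks.
#'
#' @param within_blocks [SyntenyBlocks-class] of the focal genome
#'   against itself.
#' @param outgroup_blocks [SyntenyBlocks-class] of the focal genome
#'   (gene_a side) against the outgroup (gene_b side).
#' @return data.frame (copy1, copy2, outgroup_gene), each focal pair
#'   once, copy1 < copy2 lexicographically.
#' @export
wgdParalogPairs <- function(within_blocks, outgroup_blocks) {
  oa <- anchors(outgroup_blocks)
  wa <- anchors(within_blocks)
  if (nrow(oa) == 0L || nrow(wa) == 0L)
    return(data.frame(copy1 = character(0), copy2 = character(0),
                      outgroup_gene = character(0)))
  by_out <- split(oa$gene_a, oa$gene_b)
  by_out <- lapply(by_out, unique)
  two <- by_out[lengths(by_out) == 2L]
  if (length(two) == 0L)
    return(data.frame(copy1 = character(0), copy2 = character(0),
                      outgroup_gene = character(0)))
  wkey <- unique(ifelse(wa$gene_a < wa$gene_b,
                        paste(wa$gene_a, wa$gene_b),
                        paste(wa$gene_b, wa$gene_a)))
  rows <- lapply(names(two), function(og) {
    g <- sort(two[[og]])
    if (paste(g[1], g[2]) %in% wkey)
      data.frame(copy1 = g[1], copy2 = g[2], outgroup_gene = og,
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out))
    return(data.frame(copy1 = character(0), copy2 = character(0),
                      outgroup_gene = character(0)))
  out <- out[!duplicated(paste(out$copy1, out$copy2)), , drop = FALSE]
  out <- out[order(out$copy1, out$copy2), , drop = FALSE]
  rownames(out) <- NULL
  out
}
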