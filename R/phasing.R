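#' Chromosome-level distance matrix from per-gene Ks values
#'
#' Summarizes single-copy syntenic ortholog divergence into a
#' chromosome-by-chromosome distance: the mean Ks over the gene
#' alignments of each chromosome pair (NA/saturated values excluded).
#' Chromosome pairs with data but fewer than \code{min_genes} usable
#' values are flagged missing; if more than \code{max_missing_frac} of
#' the pairs that have any data fall below the threshold, the matrix
#' is rejected. Pairs with no alignments at all are structurally
#' absent (NA) -- in an allopolyploid most chromosome pairs share no
#' orthologs, which is expected, not an error.
#'
#' @param ks_pairs data.frame with columns chrom_1, chrom_2, ks (one
#'   row per gene alignment).
#' @param min_genes minimum usable Ks values per chromosome pair.
#' @param max_missing_frac tolerated fraction of below-threshold pairs
#'   among pairs that have data.
#' @return list(labels, d) where d is a symmetric matrix with zero
#'   diagonal and NA for absent pairs.
#' @export
chromosomeDistances <- function(ks_pairs, min_genes = 10L,
                                max_missing_frac = 0.1) {
  stopifnot(all(c("chrom_1", "chrom_2", "ks") %in% names(ks_pairs)))
  labels <- sort(unique(c(ks_pairs$chrom_1, ks_pairs$chrom_2)))
  n <- length(labels)
  d <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  diag(d) <- 0
  key <- paste(pmin(ks_pairs$chrom_1, ks_pairs$chrom_2),
               pmax(ks_pairs$chrom_1, ks_pairs$chrom_2))
  grp <- split(ks_pairs$ks, key)
  n_below <- 0L
  for (g in names(grp)) {
    v <- grp[[g]]
    v <- v[!is.na(v)]
    lab <- strsplit(g, " ")[[1]]
    if (length(v) < min_genes) { n_below <- n_below + 1L; next }
    d[lab[1], lab[2]] <- d[lab[2], lab[1]] <- mean(v)
  }
  if (length(grp) > 0L && n_below / length(grp) > max_missing_frac)
    stop(n_below, " of ", length(grp),
         " chromosome pairs have fewer than ", min_genes,
         " usable Ks values")
  list(labels = labels, d = d)
}

#' Neighbor-joining tree from a chromosome distance matrix
#'
#' Standard neighbor-joining (Q-matrix criterion with Saitou--Nei
#' branch lengths, as implemented in \pkg{ape}); negative branch
#' lengths, which NJ can produce on non-additive input, are clamped to
#' zero with the deficit moved to the adjacent branch so path lengths
#' are preserved where possible.
#'
#' @param d complete symmetric distance matrix with labels (no NA) or
#'   the list returned by [chromosomeDistances()].
#' @return An unrooted \code{phylo} tree (serialize with
#'   [ape::write.tree()]).
#' @export
buildNjTree <- function(d) {
  if (is.list(d) && !is.data.frame(d)) d <- d$d
  if (nrow(d) < 3L) stop("need at least 3 labels for a tree")
  if (anyNA(d)) stop("distance matrix has missing entries")
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- -tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1]
    sib <- which(tr$edge[, 1] == parent &
                   seq_along(tr$edge.length) != e)
    if (length(sib))
      tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + deficit
  }
  tr
}

# Hungarian algorithm (shortest augmenting path, O(n^3)) for a square
# cost matrix; returns for each row the assigned column.
.hungarian <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)  # p[j]: row assigned to column j (0 = none)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    way <- integer(n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in 2:(n + 1)) {
        if (used[j]) next
        cur <- cost[i0, j - 1L] - u[i0 + 0L] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0L) assign[p[j]] <- j - 1L
  assign
}

#' PhasingResult: subgenome assignment of focal chromosomes
#'
#' @slot assignment named character vector, focal chromosome ->
#'   "A"/"B".
#' @slot partner named character vector, focal chromosome -> outgroup
#'   chromosome.
#' @slot margin named numeric vector: distance difference between the
#'   two focal partners of the matched outgroup chromosome (the
#'   support for the A/B call).
#' @slot confidence named character vector, "ok"/"low"/"ambiguous".
#' @slot strict logical; TRUE when the 2-focal-per-outgroup global
#'   matching was used.
#' @export
setClass("PhasingResult",
  representation(assignment = "character", partner = "character",
                 margin = "numeric", confidence = "character",
                 strict = "logical"),
  validity = function(object) {
    a <- object@assignment
    if (!all(a %in% c("A", "B")))
      return("assignment values must be A or B")
    if (!identical(names(a), names(object@partner)) ||
        !identical(names(a), names(object@margin)))
      return("assignment, partner and margin must share names")
    if (object@strict) {
      tab <- table(object@partner)
      if (any(tab != 2L))
        return("each outgroup chromosome needs exactly 2 partners")
    }
    TRUE
  })

setMethod("show", "PhasingResult", function(object) {
  cat("PhasingResult:", sum(object@assignment == "A"), "A +",
      sum(object@assignment == "B"), "B chromosomes",
      if (object@strict) "(strict pairing)\n" else "(fallback)\n")
  print(as.data.frame(object))
})

#' @describeIn PhasingResult-class assignment accessor
#' @param x a PhasingResult
#' @export
assignment <- function(x) x@assignment

#' @describeIn PhasingResult-class coerce to data.frame
#' @param row.names,optional,... ignored
#' @method as.data.frame PhasingResult
#' @export
as.data.frame.PhasingResult <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(chromosome = names(x@assignment),
             subgenome = unname(x@assignment),
             partner = unname(x@partner),
             margin = unname(x@margin),
             confidence = unname(x@confidence),
             stringsAsFactors = FALSE)
}

#' Assign focal chromosomes to subgenomes A and B
#'
#' Matches each outgroup chromosome to its two nearest focal
#' chromosomes by solving a global assignment (Hungarian algorithm on
#' the focal-by-outgroup distance matrix with each outgroup column
#' duplicated) minimizing total distance, each focal chromosome used
#' once. Within each matched pair the focal chromosome closer to the
#' outgroup partner joins subgenome A, the other B -- "A" is by
#' convention the outgroup-proximal subgenome, overridable with
#' \code{seed_partition}. If the strict 2:1 cardinality does not hold,
#' falls back to per-focal nearest-outgroup labeling with a warning.
#'
#' @param dmat list from [chromosomeDistances()] or a distance matrix
#'   covering focal and outgroup chromosomes (NA entries treated as
#'   uninformatively far).
#' @param outgroup_labels character vector of outgroup chromosome ids.
#' @param seed_partition optional character vector of focal
#'   chromosomes that should carry the "A" label; if the matching
#'   disagrees for a majority, labels are flipped globally (partners
#'   and margins are unaffected).
#' @param margin_threshold margins below this are flagged "low";
#'   exactly zero margins "ambiguous".
#' @return A [PhasingResult-class].
#' @export
assignSubgenomes <- function(dmat, outgroup_labels,
                             seed_partition = NULL,
                             margin_threshold = 0.01) {
  if (is.list(dmat) && !is.data.frame(dmat)) dmat <- dmat$d
  labels <- rownames(dmat)
  outgroup_labels <- intersect(labels, outgroup_labels)
  focal <- setdiff(labels, outgroup_labels)
  if (length(outgroup_labels) == 0L || length(focal) == 0L)
    stop("need both focal and outgroup chromosomes in the matrix")
  D <- dmat[focal, outgroup_labels, drop = FALSE]
  big <- 10 * max(D, na.rm = TRUE) + 1
  D[is.na(D)] <- big
  strict <- length(focal) == 2L * length(outgroup_labels)
  if (strict) {
    cost <- D[, rep(seq_along(outgroup_labels), each = 2L),
              drop = FALSE]
    asg <- .hungarian(cost)
    out_idx <- (asg + 1L) %/% 2L
    partner <- stats::setNames(outgroup_labels[out_idx], focal)
    assignv <- stats::setNames(rep(NA_character_, length(focal)),
                               focal)
    margin <- stats::setNames(rep(NA_real_, length(focal)), focal)
    for (og in outgroup_labels) {
      pair <- names(partner)[partner == og]
      dd <- D[pair, og]
      closer <- pair[order(dd, pair)][1]
      farther <- setdiff(pair, closer)
      assignv[closer] <- "A"; assignv[farther] <- "B"
      margin[pair] <- abs(diff(sort(dd)))
    }
  } else {
    warning("strict 2:1 focal:outgroup cardinality violated (",
            length(focal), " focal vs ", length(outgroup_labels),
            " outgroup); falling back to nearest-outgroup labeling")
    partner <- stats::setNames(
      outgroup_labels[apply(D, 1, which.min)], focal)
    assignv <- stats::setNames(rep("A", length(focal)), focal)
    margin <- stats::setNames(apply(D, 1, function(r) {
      s <- sort(r); if (length(s) > 1) s[2] - s[1] else 0
    }), focal)
  }
  if (!is.null(seed_partition)) {
    seeded <- intersect(names(assignv), seed_partition)
    if (length(seeded) &&
        mean(assignv[seeded] == "A") < 0.5)
      assignv[] <- ifelse(assignv == "A", "B", "A")
  }
  conf <- ifelse(margin == 0, "ambiguous",
                 ifelse(margin < margin_threshold, "low", "ok"))
  methods::new("PhasingResult", assignment = assignv,
               partner = partner, margin = margin, confidence = conf,
               strict = strict)
}
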