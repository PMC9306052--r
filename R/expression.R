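#' Expression bias and DEG configuration
#'
#' Thresholds for homoeolog expression bias (HEB) and differential
#' expression. The dominance ratio 2 (A/B >= 2 or <= 0.5, boundary
#' inclusive) and the DEG rule (raw p < 0.05 and |log2 fold change| >=
#' 1) are the field-standard cutoffs this package defaults to.
#'
#' @param dominance_ratio fold-ratio defining a dominant pair (> 1).
#' @param pseudocount FPKM added to numerator and denominator of
#'   ratios (zero-handling).
#' @param expression_floor a pair is testable in a sample only when
#'   the higher-expressed member reaches this FPKM.
#' @param p_threshold DEG p-value cutoff (raw, not adjusted).
#' @param fc_threshold DEG |log2 fold change| cutoff.
#' @return A named list of class \code{"BiasConfig"}.
#' @export
biasConfig <- function(dominance_ratio = 2, pseudocount = 0.1,
                       expression_floor = 1, p_threshold = 0.05,
                       fc_threshold = 1) {
  stopifnot(dominance_ratio > 1, pseudocount >= 0,
            expression_floor >= 0)
  structure(list(dominance_ratio = dominance_ratio,
                 pseudocount = pseudocount,
                 expression_floor = expression_floor,
                 p_threshold = p_threshold,
                 fc_threshold = fc_threshold),
            class = "BiasConfig")
}

#' Homoeolog expression bias of one pair in one sample
#'
#' \eqn{HEB = \log_2((A + c) / (B + c))} with pseudocount c; positive
#' values mean bias toward the A-subgenome copy. Untestable (NA) when
#' neither copy reaches the expression floor.
#'
#' @param expr_a,expr_b FPKM of the A and B copy (vectors allowed).
#' @param config a [biasConfig()].
#' @return Numeric HEB (NA = untestable).
#' @examples
#' computeHeb(20, 10, biasConfig(pseudocount = 0))  # 1
#' @export
computeHeb <- function(expr_a, expr_b, config = biasConfig()) {
  if (any(expr_a < 0) || any(expr_b < 0))
    stop("expression values must be non-negative")
  # difference of logs keeps heb(a, b) == -heb(b, a) exact
  heb <- log2(expr_a + config$pseudocount) -
    log2(expr_b + config$pseudocount)
  heb[pmax(expr_a, expr_b) < config$expression_floor] <- NA_real_
  heb
}

#' Classify a HEB value into a dominance category
#'
#' A_dominant iff \eqn{HEB \ge \log_2(r)}, B_dominant iff
#' \eqn{HEB \le -\log_2(r)} (boundary inclusive: a ratio of exactly 2
#' is dominant under the default), else neutral.
#'
#' @param heb numeric HEB value(s); NA propagates as "untestable".
#' @param config a [biasConfig()].
#' @return Character vector in \{A_dominant, B_dominant, neutral,
#'   untestable\}.
#' @export
classifyDominance <- function(heb, config = biasConfig()) {
  thr <- log2(config$dominance_ratio)
  out <- ifelse(is.na(heb), "untestable",
                ifelse(heb >= thr, "A_dominant",
                       ifelse(heb <= -thr, "B_dominant", "neutral")))
  out
}

#' Per-sample HEB table for homoeolog pairs
#'
#' @param pairs data.frame with gene_a, gene_b (A member first) and
#'   optionally chrom_a, chrom_b.
#' @param expr matrix of FPKM (genes x samples) or
#'   SummarizedExperiment with an "fpkm" assay.
#' @param config a [biasConfig()].
#' @return Long data.frame (gene_a, gene_b, sample, heb, dominance).
#' @export
hebTable <- function(pairs, expr, config = biasConfig()) {
  if (methods::is(expr, "SummarizedExperiment"))
    expr <- SummarizedExperiment::assay(expr, "fpkm")
  missing <- setdiff(c(pairs$gene_a, pairs$gene_b), rownames(expr))
  if (length(missing))
    stop("gene absent from expression matrix: ", missing[1])
  ea <- expr[pairs$gene_a, , drop = FALSE]
  eb <- expr[pairs$gene_b, , drop = FALSE]
  heb <- log2(ea + config$pseudocount) -
    log2(eb + config$pseudocount)
  heb[pmax(ea, eb) < config$expression_floor] <- NA_real_
  out <- data.frame(
    gene_a = rep(pairs$gene_a, times = ncol(expr)),
    gene_b = rep(pairs$gene_b, times = ncol(expr)),
    sample = rep(colnames(expr), each = nrow(pairs)),
    heb = as.vector(heb), stringsAsFactors = FALSE)
  out$dominance <- classifyDominance(out$heb, config)
  out
}

#' Summarize homoeolog expression bias
#'
#' Reports (i) how many pairs are dominant in at least one sample,
#' (ii) among those, the fraction whose majority direction across
#' their dominant samples is toward B (and A; ties counted
#' separately), (iii) per-chromosome-pair counts of majority-A and
#' majority-B pairs, and (iv) per-sample dominance totals. Both the
#' pair-level and the pair-by-sample event tallies are emitted.
#'
#' @param heb_long long table from [hebTable()].
#' @param pair_chromosomes optional data.frame (gene_a, gene_b,
#'   chrom_a, chrom_b) for the per-chromosome breakdown.
#' @return A list; see Details.
#' @export
hebSummary <- function(heb_long, pair_chromosomes = NULL) {
  key <- paste(heb_long$gene_a, heb_long$gene_b)
  dom <- heb_long$dominance
  by_pair <- split(dom, key)
  n_a <- vapply(by_pair, function(d) sum(d == "A_dominant"), 1L)
  n_b <- vapply(by_pair, function(d) sum(d == "B_dominant"), 1L)
  ever <- n_a + n_b > 0L
  direction <- ifelse(n_a > n_b, "A", ifelse(n_b > n_a, "B", "tie"))
  dir_ever <- direction[ever]
  n_ever <- sum(ever)
  pair_dir <- data.frame(
    pair = names(by_pair), n_a_dom = n_a, n_b_dom = n_b,
    direction = direction, stringsAsFactors = FALSE)
  per_sample <- as.data.frame.matrix(
    table(heb_long$sample, heb_long$dominance))
  events <- table(factor(dom, levels = c("A_dominant", "B_dominant",
                                         "neutral", "untestable")))
  out <- list(
    n_pairs = length(by_pair),
    n_pairs_biased = n_ever,
    frac_majority_B = if (n_ever) sum(dir_ever == "B") / n_ever
                      else NA_real_,
    frac_majority_A = if (n_ever) sum(dir_ever == "A") / n_ever
                      else NA_real_,
    n_ties = sum(dir_ever == "tie"),
    frac_events_B = if (sum(events[1:2]) > 0)
      unname(events["B_dominant"] / sum(events[1:2])) else NA_real_,
    pair_direction = pair_dir,
    per_sample = per_sample)
  if (!is.null(pair_chromosomes)) {
    ck <- paste(pair_chromosomes$gene_a, pair_chromosomes$gene_b)
    cp <- paste(pair_chromosomes$chrom_a, pair_chromosomes$chrom_b)
    pair_cp <- cp[match(pair_dir$pair, ck)]
    keep <- !is.na(pair_cp) & pair_dir$direction %in% c("A", "B")
    out$per_chromosome <- as.data.frame.matrix(
      table(pair_cp[keep], pair_dir$direction[keep]))
  }
  out
}

#' Call differentially expressed genes for one contrast
#'
#' log2 fold change from group means with a pseudocount; p-values
#' from Welch's two-sample t-test on log2(FPKM + pseudocount). A gene
#' is a DEG iff raw p < \code{p_threshold} and |log2FC| >=
#' \code{fc_threshold} (both thresholds from the configuration; raw p
#' by design, not FDR-adjusted).
#'
#' @param expr FPKM matrix (genes x samples) or SummarizedExperiment
#'   with an "fpkm" assay.
#' @param treated,control column names (>= 2 each) of the two
#'   replicate groups.
#' @param config a [biasConfig()].
#' @param contrast_id label stored in the output.
#' @return data.frame (gene_id, contrast, log2fc, pvalue, is_deg).
#' @export
callDegs <- function(expr, treated, control, config = biasConfig(),
                     contrast_id = "treated_vs_control") {
  if (methods::is(expr, "SummarizedExperiment"))
    expr <- SummarizedExperiment::assay(expr, "fpkm")
  if (length(treated) < 2L || length(control) < 2L)
    stop("need at least 2 replicates per group")
  tm <- expr[, treated, drop = FALSE]
  cm <- expr[, control, drop = FALSE]
  pc <- config$pseudocount
  log2fc <- log2((rowMeans(tm) + pc) / (rowMeans(cm) + pc))
  lt <- log2(tm + pc); lc <- log2(cm + pc)
  pvalue <- vapply(seq_len(nrow(expr)), function(i) {
    x <- lt[i, ]; y <- lc[i, ]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (isTRUE(all.equal(mean(x), mean(y)))) return(1)
      return(0)
    }
    tryCatch(stats::t.test(x, y)$p.value, error = function(e) 1)
  }, numeric(1))
  data.frame(gene_id = rownames(expr), contrast = contrast_id,
             log2fc = log2fc, pvalue = pvalue,
             is_deg = pvalue < config$p_threshold &
               abs(log2fc) >= config$fc_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Chi-square test of subgenome DEG balance
#'
#' One-degree-of-freedom goodness-of-fit of observed per-subgenome
#' DEG counts against an equal 1:1 expectation.
#'
#' @param count_a,count_b DEG counts from subgenomes A and B.
#' @return list(chi2, pvalue, expected).
#' @examples
#' subgenomeDegChisq(299, 365)  # chi2 ~ 6.56, p ~ 0.010
#' @export
subgenomeDegChisq <- function(count_a, count_b) {
  if (count_a < 0 || count_b < 0) stop("counts must be non-negative")
  total <- count_a + count_b
  if (total == 0) stop("need at least one DEG")
  expected <- total / 2
  chi2 <- (count_a - expected)^2 / expected +
    (count_b - expected)^2 / expected
  list(chi2 = chi2,
       pvalue = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       expected = expected)
}

#' Expression-divergence classes of WGD paralog pairs
#'
#' A gene counts as differentially expressed when it is a DEG in any
#' contrast; each pair is classed by how many of its two members are
#' DEGs (0, 1 or 2).
#'
#' @param pairs data.frame with columns copy1, copy2.
#' @param degs data.frame of [callDegs()] results (possibly several
#'   contrasts row-bound); its gene universe must contain every pair
#'   member.
#' @return list(per_pair, counts) where counts is a named vector over
#'   classes "0","1","2".
#' @export
classifyParalogDivergence <- function(pairs, degs) {
  universe <- unique(degs$gene_id)
  missing <- setdiff(c(pairs$copy1, pairs$copy2), universe)
  if (length(missing))
    stop("gene absent from DEG universe: ", missing[1])
  deg_genes <- unique(degs$gene_id[degs$is_deg])
  k <- (pairs$copy1 %in% deg_genes) + (pairs$copy2 %in% deg_genes)
  per_pair <- data.frame(copy1 = pairs$copy1, copy2 = pairs$copy2,
                         n_deg_members = k, stringsAsFactors = FALSE)
  counts <- table(factor(k, levels = 0:2))
  names(counts) <- c("0", "1", "2")
  list(per_pair = per_pair, counts = c(counts))
}

#' One-sided hypergeometric set enrichment
#'
#' For each annotation term, the probability of drawing at least the
#' observed number of term genes in a study set of its size from the
#' population (over-representation), with Benjamini--Hochberg FDR
#' across terms.
#'
#' @param study character vector of study genes (subset of
#'   population).
#' @param population character vector of background genes.
#' @param annotations named list, term -> character vector of genes
#'   (intersected with the population).
#' @return data.frame (term, n_study, n_term, n_overlap, pvalue, fdr)
#'   sorted by p-value.
#' @export
hypergeomEnrichment <- function(study, population, annotations) {
  study <- unique(study); population <- unique(population)
  if (!all(study %in% population))
    stop("study set must be a subset of the population")
  N <- length(population); n <- length(study)
  rows <- lapply(names(annotations), function(term) {
    g <- intersect(unique(annotations[[term]]), population)
    K <- length(g)
    k <- length(intersect(g, study))
    p <- if (K == 0L) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, n_study = n, n_term = K, n_overlap = k,
               pvalue = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$pvalue, method = "BH")
  out <- out[order(out$pvalue, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
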