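# Seeded synthetic allotetraploid fixtures: codon sequences evolved to
# target synonymous divergences, collinear gene orders with
# fractionation, and expression with planted dominance/DEG effects.

.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# One deterministic sub-seed per simulator stream, so changing e.g.
# expression parameters never perturbs the sequences.
.derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 10007 + sum(utf8ToInt(stream))) %% 2147483647
}

#' Simulation configuration for the synthetic allotetraploid
#'
#' Defaults emulate an allotetraploid grass system: an outgroup genome
#' plus A/B subgenomes separated by a WGD at paralog Ks ~ 0.27, a
#' focal--outgroup ortholog divergence of Ks ~ 0.48, lognormal FPKM
#' with planted dominant homoeolog pairs and planted DEG effects in a
#' 2-tissue x 4-timepoint x 3-replicate salt-stress design.
#'
#' @param seed master seed (mandatory); per-stream seeds for
#'   sequences, gene orders and expression are derived from it.
#' @param n_outgroup_chroms,genes_per_chrom,gene_length_codons genome
#'   dimensions.
#' @param ks_wgd target synonymous divergence between the A and B
#'   homoeologs (the WGD peak).
#' @param ks_outgroup target focal--outgroup ortholog divergence
#'   (averaged over the two subgenomes; A is constructed closer to the
#'   outgroup than B by \code{ks_recent} on each side).
#' @param ks_recent branch-length asymmetry between the A and B
#'   subgenomes (also the scale of a recent species-specific
#'   divergence); guarantees a phasing margin of about
#'   \code{2 * ks_recent}.
#' @param omega_sim relative acceptance rate of nonsynonymous
#'   substitutions (Ka/Ks of the simulated process).
#' @param retained_duplicate_fraction fraction of B-subgenome copies
#'   surviving fractionation.
#' @param frac_a_dominant,frac_b_dominant planted fractions of
#'   homoeolog pairs dominant toward A and B.
#' @param planted_deg_fraction fraction of focal genes given a salt
#'   response.
#' @param deg_effect_log2 planted DEG effect size (log2 units).
#' @param expr_lognormal_mu,expr_lognormal_sigma baseline FPKM
#'   lognormal parameters (natural-log scale).
#' @param replicates biological replicates per condition.
#' @param noise_cv multiplicative replicate noise (coefficient of
#'   variation).
#' @param inversion_fraction fraction of collinear blocks emitted in
#'   inverted orientation.
#' @param noise_hit_fraction spurious homology hits added, as a
#'   fraction of true hits.
#' @return A named list of class \code{"SimConfig"}.
#' @export
simConfig <- function(seed, n_outgroup_chroms = 10L,
                      genes_per_chrom = 60L,
                      gene_length_codons = 300L, ks_wgd = 0.27,
                      ks_outgroup = 0.48, ks_recent = 0.03,
                      omega_sim = 0.2,
                      retained_duplicate_fraction = 0.8,
                      frac_a_dominant = 0.10, frac_b_dominant = 0.15,
                      planted_deg_fraction = 0.05,
                      deg_effect_log2 = 2.0, expr_lognormal_mu = 3.0,
                      expr_lognormal_sigma = 1.0, replicates = 3L,
                      noise_cv = 0.15, inversion_fraction = 0.1,
                      noise_hit_fraction = 0.05) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(frac_a_dominant >= 0, frac_b_dominant >= 0,
            frac_a_dominant + frac_b_dominant <= 1,
            ks_wgd >= 0, ks_outgroup >= 0, ks_recent >= 0,
            retained_duplicate_fraction >= 0,
            retained_duplicate_fraction <= 1)
  structure(as.list(environment()), class = "SimConfig")
}

# Evolve a codon-index vector by `d` expected synonymous substitutions
# per synonymous site; nonsynonymous substitutions accrue at relative
# rate omega on nonsynonymous sites. Substitution counts are Poisson;
# each event picks a codon weighted by its current number of
# (non)synonymous single-nucleotide neighbours, then one neighbour
# uniformly. Stop codons are never created.
.evolve_branch <- function(codons, d, omega) {
  n <- length(codons)
  S <- sum(.SYN_SITES[codons]); N <- 3 * n - S
  n_syn <- stats::rpois(1L, d * S)
  n_non <- stats::rpois(1L, d * N * omega)
  steps <- sample(c(rep(TRUE, n_syn), rep(FALSE, n_non)))
  w_syn <- .N_SYN_NEIGHBORS[codons]
  w_non <- .N_NONSYN_NEIGHBORS[codons]
  for (syn in steps) {
    w <- if (syn) w_syn else w_non
    if (sum(w) == 0L) next
    i <- sample.int(n, 1L, prob = w)
    nb <- if (syn) .SYN_NEIGHBORS[[codons[i]]] else
      .NONSYN_NEIGHBORS[[codons[i]]]
    codons[i] <- nb[sample.int(length(nb), 1L)]
    w_syn[i] <- .N_SYN_NEIGHBORS[codons[i]]
    w_non[i] <- .N_NONSYN_NEIGHBORS[codons[i]]
  }
  list(codons = codons, n_syn = n_syn, n_non = n_non)
}

.codons_to_string <- function(codons) paste(.CODONS[codons],
                                            collapse = "")

.random_ancestor <- function(n_codons)
  sample(.SENSE_CODONS, n_codons, replace = TRUE)

#' Simulate one codon pair at a target synonymous divergence
#'
#' Generates a random ancestor of sense codons and evolves two
#' descendants independently, each over half the target divergence
#' (Poisson substitution counts on synonymous sites; nonsynonymous
#' changes at relative rate \code{omega_sim}; stop-creating changes
#' never proposed). The realized substitution counts are returned so
#' estimator-recovery checks can compare against what actually
#' happened, not just the target.
#'
#' @param ks_target expected synonymous substitutions per synonymous
#'   site between the descendants.
#' @param omega_sim relative nonsynonymous rate.
#' @param n_codons ancestor length.
#' @param seed RNG seed.
#' @return list(alignment = [CodonPairAlignment-class], realized =
#'   per-branch substitution counts, ks_target).
#' @export
simulateCodonPair <- function(ks_target, omega_sim = 0.2,
                              n_codons = 300L, seed = 1L) {
  stopifnot(ks_target >= 0)
  .with_seed(seed, {
    anc <- .random_ancestor(n_codons)
    b1 <- .evolve_branch(anc, ks_target / 2, omega_sim)
    b2 <- .evolve_branch(anc, ks_target / 2, omega_sim)
    list(alignment = codonPairAlignment(
           .codons_to_string(b1$codons), .codons_to_string(b2$codons),
           "copy1", "copy2"),
         realized = list(n_syn = b1$n_syn + b2$n_syn,
                         n_non = b1$n_non + b2$n_non),
         ks_target = ks_target)
  })
}

# Partition n ordered genes into collinear blocks of length 8..15,
# shuffle block order, inverting a fraction of blocks.
.scramble_order <- function(idx, inversion_fraction) {
  n <- length(idx)
  lens <- integer(0)
  while (sum(lens) < n)
    lens <- c(lens, sample(8:15, 1L))
  lens[length(lens)] <- n - sum(lens[-length(lens)])
  if (lens[length(lens)] < 1L) lens <- lens[-length(lens)]
  # merge a short tail into the previous run so every planted
  # collinear run is at least the minimum block length
  if (length(lens) > 1L && lens[length(lens)] < 8L) {
    lens[length(lens) - 1L] <- lens[length(lens) - 1L] +
      lens[length(lens)]
    lens <- lens[-length(lens)]
  }
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  blocks <- Map(function(s, e) idx[s:e], starts, ends)
  inv <- stats::runif(length(blocks)) < inversion_fraction
  blocks[inv] <- lapply(blocks[inv], rev)
  unlist(blocks[sample.int(length(blocks))], use.names = FALSE)
}

.mk_hits <- function(q, s, true = TRUE) {
  n <- length(q)
  data.frame(qseqid = q, sseqid = s,
             pident = rep(if (true) 90 else 60, n),
             length = rep(300L, n), mismatch = rep(30L, n),
             gapopen = rep(0L, n), qstart = rep(1L, n),
             qend = rep(300L, n), sstart = rep(1L, n),
             send = rep(300L, n),
             evalue = rep(if (true) 1e-80 else 1e-12, n),
             bitscore = rep(if (true) 500 else 80, n),
             stringsAsFactors = FALSE)
}

#' Simulate an allotetraploid genome bundle with ground truth
#'
#' Builds an outgroup genome, duplicates it into subgenomes A and B
#' with sequence divergence implied by \code{ks_wgd} (A--B) and
#' \code{ks_outgroup} (focal--outgroup; A constructed closer to the
#' outgroup than B by \code{ks_recent} per branch), removes a fraction
#' of B copies (unbiased fractionation), scrambles gene orders into
#' collinear runs with occasional inversions, and emits homology hits
#' for all true pairs plus random noise hits. Every stage of the
#' pipeline can be scored against the returned truth.
#'
#' @param config a [simConfig()].
#' @param sequences logical; set FALSE to skip sequence evolution
#'   (orders, hits, truth and expression remain available -- useful
#'   for expression-scale studies where only pair structure matters).
#' @return A list (class \code{"AllotetraploidSim"}) with elements
#'   \code{annotation_focal}, \code{annotation_outgroup} (ranked gene
#'   models), \code{hits_within}, \code{hits_outgroup},
#'   \code{sequences} (named codon strings or NULL), \code{truth}
#'   (chromosomes, genes, homoeologs, pairs, planted dominance and
#'   DEG tables) and \code{config}.
#' @export
simulateAllotetraploid <- function(config, sequences = TRUE) {
  stopifnot(inherits(config, "SimConfig"))
  nchr <- config$n_outgroup_chroms
  npg <- config$genes_per_chrom
  glen <- config$gene_length_codons
  delta <- min(config$ks_recent, 0.4 * config$ks_wgd)
  b_a <- config$ks_wgd / 2 - delta
  b_b <- config$ks_wgd / 2 + delta
  b_o <- max(config$ks_outgroup - config$ks_wgd / 2, 0)

  gid <- function(sub, chr, j) sprintf("%s%02dg%03d", sub, chr, j)
  chrom_name <- function(sub, chr) sprintf("chr%s%02d", sub, chr)

  genes <- expand.grid(j = seq_len(npg), chr = seq_len(nchr))
  o_ids <- gid("Ot", genes$chr, genes$j)
  a_ids <- gid("ZjA", genes$chr, genes$j)
  b_ids <- gid("ZjB", genes$chr, genes$j)

  # --- structure stream: fractionation + gene orders ---------------
  struct <- .with_seed(.derive_seed(config$seed, "orders"), {
    retained <- stats::runif(length(b_ids)) <
      config$retained_duplicate_fraction
    # A and B inherit the same post-WGD rearrangement pattern per
    # chromosome (the planted collinear runs); fractionation then
    # thins B within those runs.
    order_a <- lapply(seq_len(nchr), function(chr)
      .scramble_order(which(genes$chr == chr),
                      config$inversion_fraction))
    order_b <- lapply(seq_len(nchr), function(chr) {
      ord <- order_a[[chr]]
      ord[retained[ord]]
    })
    list(retained = retained, order_a = order_a, order_b = order_b)
  })
  retained <- struct$retained

  # --- sequence stream ---------------------------------------------
  seqs <- NULL
  if (sequences) {
    seqs <- .with_seed(.derive_seed(config$seed, "sequences"), {
      out <- vector("list", 3L * length(o_ids))
      nm <- character(3L * length(o_ids))
      k <- 0L
      for (g in seq_along(o_ids)) {
        anc <- .random_ancestor(glen)
        og <- .evolve_branch(anc, b_o, config$omega_sim)$codons
        ag <- .evolve_branch(anc, b_a, config$omega_sim)$codons
        bg <- .evolve_branch(anc, b_b, config$omega_sim)$codons
        out[[k + 1L]] <- og; out[[k + 2L]] <- ag; out[[k + 3L]] <- bg
        nm[k + 1L] <- o_ids[g]; nm[k + 2L] <- a_ids[g]
        nm[k + 3L] <- b_ids[g]
        k <- k + 3L
      }
      stats::setNames(vapply(out, .codons_to_string, character(1)), nm)
    })
    seqs <- seqs[c(o_ids, a_ids, b_ids[retained])]
  }

  # --- annotations ---------------------------------------------------
  mk_ann <- function(ids, chrom, order_idx) {
    pos <- seq_along(order_idx)
    data.frame(gene_id = ids[order_idx], chromosome = chrom,
               start = (pos - 1) * 1000, end = (pos - 1) * 1000 +
                 3 * glen, strand = "+", stringsAsFactors = FALSE)
  }
  ann_o <- do.call(rbind, lapply(seq_len(nchr), function(chr)
    mk_ann(o_ids, chrom_name("O", chr), which(genes$chr == chr))))
  ann_a <- do.call(rbind, lapply(seq_len(nchr), function(chr)
    mk_ann(a_ids, chrom_name("A", chr), struct$order_a[[chr]])))
  ann_b <- do.call(rbind, lapply(seq_len(nchr), function(chr)
    mk_ann(b_ids, chrom_name("B", chr), struct$order_b[[chr]])))
  ann_focal <- buildGeneRanks(rbind(ann_a, ann_b))
  ann_outgroup <- buildGeneRanks(ann_o)

  # --- homology hits -------------------------------------------------
  hits_within <- .mk_hits(a_ids[retained], b_ids[retained])
  hits_outgroup <- rbind(.mk_hits(a_ids, o_ids),
                         .mk_hits(b_ids[retained], o_ids[retained]))
  noise <- .with_seed(.derive_seed(config$seed, "noise"), {
    n_noise_w <- ceiling(config$noise_hit_fraction * nrow(hits_within))
    n_noise_o <- ceiling(config$noise_hit_fraction *
                           nrow(hits_outgroup))
    focal_ids <- c(a_ids, b_ids[retained])
    list(w = .mk_hits(sample(focal_ids, n_noise_w, replace = TRUE),
                      sample(focal_ids, n_noise_w, replace = TRUE),
                      true = FALSE),
         o = .mk_hits(sample(focal_ids, n_noise_o, replace = TRUE),
                      sample(o_ids, n_noise_o, replace = TRUE),
                      true = FALSE))
  })
  hits_within <- rbind(hits_within,
                       noise$w[noise$w$qseqid != noise$w$sseqid, ])
  hits_outgroup <- rbind(hits_outgroup, noise$o)

  # --- planted expression truth -------------------------------------
  plant <- .with_seed(.derive_seed(config$seed, "planting"), {
    hp <- data.frame(gene_a = a_ids, gene_b = b_ids,
                     outgroup_gene = o_ids, retained = retained,
                     chrom_a = chrom_name("A", genes$chr),
                     chrom_b = chrom_name("B", genes$chr),
                     stringsAsFactors = FALSE)
    nr <- sum(retained)
    dom <- rep("none", nrow(hp))
    ridx <- which(retained)
    n_a <- round(config$frac_a_dominant * nr)
    n_b <- round(config$frac_b_dominant * nr)
    pick <- sample(ridx, n_a + n_b)
    dom[pick[seq_len(n_a)]] <- "A"
    dom[pick[n_a + seq_len(n_b)]] <- "B"
    hp$dominance <- dom
    hp$log2_ratio <- ifelse(dom == "none", 0,
                            stats::runif(nrow(hp), 1.5, 3))
    focal_ids <- c(a_ids, b_ids[retained])
    n_deg <- round(config$planted_deg_fraction * length(focal_ids))
    deg_genes <- sample(focal_ids, n_deg)
    deg <- data.frame(gene_id = deg_genes,
                      tissue = sample(c("leaf", "root"), n_deg,
                                      replace = TRUE),
                      direction = sample(c(1, -1), n_deg,
                                         replace = TRUE),
                      stringsAsFactors = FALSE)
    list(homoeologs = hp, deg = deg)
  })

  chrom_truth <- data.frame(
    chromosome = c(chrom_name("O", seq_len(nchr)),
                   chrom_name("A", seq_len(nchr)),
                   chrom_name("B", seq_len(nchr))),
    genome = rep(c("outgroup", "focal", "focal"), each = nchr),
    subgenome = rep(c(NA, "A", "B"), each = nchr),
    outgroup_partner = c(rep(NA, nchr),
                         rep(chrom_name("O", seq_len(nchr)), 2L)),
    stringsAsFactors = FALSE)

  gene_truth <- data.frame(
    gene_id = c(o_ids, a_ids, b_ids),
    genome = rep(c("outgroup", "focal", "focal"),
                 each = length(o_ids)),
    subgenome = rep(c(NA, "A", "B"), each = length(o_ids)),
    retained = c(rep(TRUE, 2L * length(o_ids)), retained),
    stringsAsFactors = FALSE)

  pairs <- rbind(
    data.frame(class = "homoeolog", gene_1 = a_ids[retained],
               gene_2 = b_ids[retained], ks_target = config$ks_wgd,
               stringsAsFactors = FALSE),
    data.frame(class = "ortholog_A", gene_1 = a_ids, gene_2 = o_ids,
               ks_target = b_a + b_o, stringsAsFactors = FALSE),
    data.frame(class = "ortholog_B", gene_1 = b_ids[retained],
               gene_2 = o_ids[retained], ks_target = b_b + b_o,
               stringsAsFactors = FALSE))

  structure(list(
    annotation_focal = ann_focal, annotation_outgroup = ann_outgroup,
    hits_within = hits_within, hits_outgroup = hits_outgroup,
    sequences = seqs,
    truth = list(chromosomes = chrom_truth, genes = gene_truth,
                 pairs = pairs, homoeologs = plant$homoeologs,
                 deg = plant$deg),
    config = config), class = "AllotetraploidSim")
}

#' Simulate the expression matrix for a synthetic fixture
#'
#' Baseline FPKM per homoeolog pair (shared by the two members, so the
#' expression ratio is controlled) drawn lognormal; planted dominant
#' pairs have the dominant member multiplied by \eqn{2^{r}} with the
#' planted log2 ratio r; planted DEG genes get \eqn{\pm} the DEG
#' effect in the treated timepoints (1, 24, 72 h) of their tissue;
#' multiplicative lognormal replicate noise with the configured CV
#' (mean-one parameterization). Design: 2 tissues x \{0, 1, 24, 72\} h
#' x replicates.
#'
#' @param sim an \code{AllotetraploidSim} from
#'   [simulateAllotetraploid()].
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   \code{"fpkm"} and colData columns sample, tissue, timepoint,
#'   replicate.
#' @export
simulateExpression <- function(sim) {
  stopifnot(inherits(sim, "AllotetraploidSim"))
  config <- sim$config
  truth <- sim$truth
  hp <- truth$homoeologs
  focal <- truth$genes[truth$genes$genome == "focal" &
                         truth$genes$retained, , drop = FALSE]
  ids <- focal$gene_id
  tissues <- c("leaf", "root")
  tps <- c(0, 1, 24, 72)
  design <- expand.grid(replicate = seq_len(config$replicates),
                        timepoint = tps, tissue = tissues,
                        stringsAsFactors = FALSE)
  design <- design[, c("tissue", "timepoint", "replicate")]
  design$sample <- sprintf("%s_%sh_r%d", design$tissue,
                           design$timepoint, design$replicate)
  .with_seed(.derive_seed(config$seed, "expression"), {
    base <- stats::setNames(rep(NA_real_, length(ids)), ids)
    ret <- hp[hp$retained, , drop = FALSE]
    pair_base <- stats::rlnorm(nrow(ret),
                               meanlog = config$expr_lognormal_mu,
                               sdlog = config$expr_lognormal_sigma)
    base[ret$gene_a] <- pair_base
    base[ret$gene_b] <- pair_base
    single <- is.na(base)
    base[single] <- stats::rlnorm(sum(single),
                                  meanlog = config$expr_lognormal_mu,
                                  sdlog = config$expr_lognormal_sigma)
    mult <- 2^(ret$log2_ratio)
    base[ret$gene_a[ret$dominance == "A"]] <-
      base[ret$gene_a[ret$dominance == "A"]] *
      mult[ret$dominance == "A"]
    base[ret$gene_b[ret$dominance == "B"]] <-
      base[ret$gene_b[ret$dominance == "B"]] *
      mult[ret$dominance == "B"]
    expected <- matrix(base, nrow = length(ids), ncol = nrow(design),
                       dimnames = list(ids, design$sample))
    deg <- truth$deg[truth$deg$gene_id %in% ids, , drop = FALSE]
    for (i in seq_len(nrow(deg))) {
      cols <- design$tissue == deg$tissue[i] & design$timepoint > 0
      expected[deg$gene_id[i], cols] <-
        expected[deg$gene_id[i], cols] *
        2^(deg$direction[i] * config$deg_effect_log2)
    }
    fpkm <- expected
    if (config$noise_cv > 0) {
      sdlog <- sqrt(log(1 + config$noise_cv^2))
      noise <- matrix(stats::rlnorm(length(expected),
                                    meanlog = -sdlog^2 / 2,
                                    sdlog = sdlog),
                      nrow = nrow(expected))
      fpkm <- expected * noise
    }
    SummarizedExperiment::SummarizedExperiment(
      assays = list(fpkm = fpkm),
      colData = S4Vectors::DataFrame(design, row.names = design$sample))
  })
}

#' Write a simulated fixture to a self-contained directory
#'
#' Emits CDS FASTA, GFF3 annotations, 12-column hit tables, the
#' expression matrix with its sample sheet, and the truth tables as
#' JSON -- the plain-text file set the pipeline stages read.
#'
#' @param sim an \code{AllotetraploidSim}.
#' @param dir output directory (created if needed).
#' @param expr optional SummarizedExperiment from
#'   [simulateExpression()].
#' @return \code{dir}, invisibly.
#' @export
writeFixture <- function(sim, dir, expr = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(sim$sequences)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(sim$sequences),
      file.path(dir, "cds.fa"))
  }
  write_gff <- function(ann, path) {
    lines <- sprintf(
      "%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      ann$chromosome, as.integer(ann$start + 1),
      as.integer(ann$end), ann$strand, ann$gene_id)
    writeLines(c("##gff-version 3", lines), path)
  }
  write_gff(sim$annotation_focal, file.path(dir, "focal.gff3"))
  write_gff(sim$annotation_outgroup, file.path(dir, "outgroup.gff3"))
  utils::write.table(sim$hits_within,
                     file.path(dir, "hits_within.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(sim$hits_outgroup,
                     file.path(dir, "hits_outgroup.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", na = "null")
  if (!is.null(expr)) {
    m <- SummarizedExperiment::assay(expr, "fpkm")
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, "fpkm.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      as.data.frame(SummarizedExperiment::colData(expr)),
      file.path(dir, "samples.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(dir)
}
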