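# End-to-end orchestration: simulate (optional) -> synteny -> codon
# statistics -> Ks dating -> subgenome phasing -> expression bias.
# Stage boundaries are file-based (TSV/FASTA/JSON) so any stage can be
# re-run or swapped independently.

#' Pipeline configuration
#'
#' Either a \code{simulate} block (a [simConfig()]) or a set of input
#' file paths (as written by [writeFixture()]). All stage thresholds
#' live here, defaulting to the field-standard values (hit E-value
#' 1e-10, >= 5 anchors per block, DEG p < 0.05 and |log2FC| >= 1,
#' dominance ratio 2, lambda 6.5e-9).
#'
#' @param out_dir output directory.
#' @param simulate optional [simConfig()]; when present no input
#'   files are needed.
#' @param inputs optional named list of paths: focal_gff,
#'   outgroup_gff, cds_fasta, hits_within, hits_outgroup, fpkm,
#'   samples.
#' @param synteny a [syntenyParams()].
#' @param distribution a [distributionConfig()].
#' @param bias a [biasConfig()].
#' @param lambda_rate substitutions/site/year for dating.
#' @param max_pairs_per_chrom cap on gene alignments per chromosome
#'   pair used for phasing distances.
#' @return A named list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(out_dir, simulate = NULL, inputs = NULL,
                           synteny = syntenyParams(),
                           distribution = distributionConfig(),
                           bias = biasConfig(),
                           lambda_rate = 6.5e-9,
                           max_pairs_per_chrom = 30L) {
  if (is.null(simulate) && is.null(inputs))
    stop("provide either a simulate block or input paths")
  structure(list(out_dir = out_dir, simulate = simulate,
                 inputs = inputs, synteny = synteny,
                 distribution = distribution, bias = bias,
                 lambda_rate = lambda_rate,
                 max_pairs_per_chrom = as.integer(max_pairs_per_chrom)),
            class = "PipelineConfig")
}

# Deterministic fingerprint of a report: djb2-style rolling hash over
# its canonical JSON, excluding timings.
.fingerprint <- function(x) {
  x$timing_sec <- NULL
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10,
                        dataframe = "columns", na = "null")
  h <- 5381
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 33 + b) %% 4294967291
  sprintf("%010.0f", h)
}

#' Validate pipeline inputs
#'
#' Cross-checks FASTA/GFF3 gene ids, sample-sheet completeness
#' (every tissue/timepoint group needs >= 2 replicates for DEG
#' contrasts) and coding-frame validity of the sequences. Returns a
#' pass flag with itemized issues rather than stopping at the first
#' problem.
#'
#' @param config a [pipelineConfig()] with an \code{inputs} block.
#' @return list(pass, issues).
#' @export
validateInputs <- function(config) {
  issues <- character(0)
  add <- function(msg) issues <<- c(issues, msg)
  if (is.null(config$inputs)) {
    return(list(pass = TRUE, issues = character(0)))
  }
  inp <- config$inputs
  for (f in unlist(inp))
    if (!file.exists(f)) add(paste("missing file:", f))
  if (length(issues)) return(list(pass = FALSE, issues = issues))
  ann <- rbind(readGeneModels(inp$focal_gff),
               readGeneModels(inp$outgroup_gff))
  seqs <- NULL
  if (!is.null(inp$cds_fasta)) {
    seqs <- Biostrings::readDNAStringSet(inp$cds_fasta)
    absent <- setdiff(ann$gene_id, names(seqs))
    if (length(absent))
      add(paste("gene in GFF3 absent from FASTA:",
                paste(utils::head(absent, 3), collapse = ", ")))
    badlen <- names(seqs)[Biostrings::width(seqs) %% 3L != 0L]
    if (length(badlen))
      add(paste("CDS length not divisible by 3:",
                paste(utils::head(badlen, 3), collapse = ", ")))
  }
  if (!is.null(inp$samples)) {
    ss <- utils::read.table(inp$samples, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("sample", "tissue", "timepoint", "replicate")
    miss <- setdiff(need, names(ss))
    if (length(miss))
      add(paste("sample sheet missing column:",
                paste(miss, collapse = ", ")))
    else {
      grp <- table(paste(ss$tissue, ss$timepoint))
      low <- names(grp)[grp < 2]
      if (length(low))
        add(paste("replicate group with < 2 replicates:",
                  paste(low, collapse = "; ")))
      if (!is.null(inp$fpkm)) {
        hdr <- strsplit(readLines(inp$fpkm, n = 1L), "\t")[[1]]
        absent <- setdiff(ss$sample, hdr)
        if (length(absent))
          add(paste("sample missing from FPKM matrix:",
                    paste(utils::head(absent, 3), collapse = ", ")))
      }
    }
  }
  list(pass = length(issues) == 0L, issues = issues)
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"),
                  stage, paste0(..., collapse = " ")))
}

#' Run the full analysis pipeline
#'
#' Executes simulation (when configured) then synteny detection,
#' codon-level substitution statistics on anchor pairs, Ks-peak
#' dating, subgenome phasing and the expression-bias stage, writing
#' per-stage TSV outputs and a machine-readable JSON report to
#' \code{out_dir}. The report carries per-stage counts, Ks modes and
#' ages, the phasing table, the HEB summary, DEG counts per contrast,
#' paralog divergence classes and a deterministic fingerprint; the
#' run is fully reproducible from the configuration seed.
#'
#' @param config a [pipelineConfig()].
#' @return The report, invisibly also written to
#'   \code{out_dir/report.json}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(schema_version = "1.0", stages = list())

  # --- stage: inputs / simulation ----------------------------------
  if (!is.null(config$simulate)) {
    .log_stage("simulate", "seed", config$simulate$seed)
    sim <- simulateAllotetraploid(config$simulate)
    expr <- simulateExpression(sim)
    writeFixture(sim, file.path(config$out_dir, "fixture"), expr)
    truth_map <- stats::setNames(sim$truth$chromosomes$subgenome,
                                 sim$truth$chromosomes$chromosome)
  } else {
    val <- validateInputs(config)
    if (!val$pass)
      stop("input validation failed: ",
           paste(val$issues, collapse = " | "))
    inp <- config$inputs
    seqs <- Biostrings::readDNAStringSet(inp$cds_fasta)
    sim <- list(annotation_focal = readGeneModels(inp$focal_gff),
                annotation_outgroup = readGeneModels(inp$outgroup_gff),
                hits_within = readHomologyHits(inp$hits_within),
                hits_outgroup = readHomologyHits(inp$hits_outgroup),
                sequences = stats::setNames(as.character(seqs),
                                            names(seqs)),
                truth = NULL)
    fp <- utils::read.table(inp$fpkm, header = TRUE, sep = "\t",
                            check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(fp[, -1, drop = FALSE])
    rownames(m) <- fp[[1]]
    ss <- utils::read.table(inp$samples, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    expr <- SummarizedExperiment::SummarizedExperiment(
      assays = list(fpkm = m[, ss$sample, drop = FALSE]),
      colData = S4Vectors::DataFrame(ss, row.names = ss$sample))
  }
  report$stages$input <- list(
    n_focal_genes = nrow(sim$annotation_focal),
    n_outgroup_genes = nrow(sim$annotation_outgroup),
    n_hits_within = nrow(sim$hits_within),
    n_hits_outgroup = nrow(sim$hits_outgroup))

  # --- stage: synteny ----------------------------------------------
  .log_stage("synteny", "chaining blocks")
  within_blocks <- chainSyntenyBlocks(sim$hits_within,
                                      sim$annotation_focal,
                                      sim$annotation_focal,
                                      config$synteny)
  outgroup_blocks <- chainSyntenyBlocks(sim$hits_outgroup,
                                        sim$annotation_focal,
                                        sim$annotation_outgroup,
                                        config$synteny)
  methods::validObject(within_blocks)
  methods::validObject(outgroup_blocks)
  utils::write.table(blocks(within_blocks),
                     file.path(config$out_dir, "blocks_within.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(blocks(outgroup_blocks),
                     file.path(config$out_dir, "blocks_outgroup.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$stages$synteny <- list(
    n_blocks_within = nrow(blocks(within_blocks)),
    n_blocks_outgroup = nrow(blocks(outgroup_blocks)),
    n_anchors_within = nrow(anchors(within_blocks)),
    n_anchors_outgroup = nrow(anchors(outgroup_blocks)))

  # --- stage: codon statistics on anchor pairs ---------------------
  .log_stage("codonstats", "Ka/Ks + 4DTv on anchor pairs")
  aln_from_pair <- function(g1, g2)
    codonPairAlignment(sim$sequences[[g1]], sim$sequences[[g2]],
                       g1, g2)
  wa <- anchors(within_blocks)
  oa <- anchors(outgroup_blocks)
  kaks_within <- kaksTable(Map(aln_from_pair, wa$gene_a, wa$gene_b))
  kaks_outgroup <- kaksTable(Map(aln_from_pair, oa$gene_a, oa$gene_b))
  writeKaksTable(kaks_within,
                 file.path(config$out_dir, "kaks_within.tsv"))
  writeKaksTable(kaks_outgroup,
                 file.path(config$out_dir, "kaks_outgroup.tsv"))
  report$stages$codonstats <- list(
    n_pairs_within = nrow(kaks_within),
    n_pairs_outgroup = nrow(kaks_outgroup),
    median_ks_within = stats::median(kaks_within$Ks, na.rm = TRUE),
    median_ks_outgroup = stats::median(kaks_outgroup$Ks,
                                       na.rm = TRUE))

  # --- stage: Ks distributions and dating --------------------------
  .log_stage("wgd_dating", "peak detection")
  kw <- collectKsValues(kaks_within$Ks, config$distribution)
  ko <- collectKsValues(kaks_outgroup$Ks, config$distribution)
  peaks_within <- detectKsPeaks(kw$values, config$distribution,
                                config$lambda_rate)
  peaks_outgroup <- detectKsPeaks(ko$values, config$distribution,
                                  config$lambda_rate)
  events <- summarizeWgd(list(paralogs = peaks_within,
                              orthologs = peaks_outgroup),
                         within = c(TRUE, FALSE))
  # internal consistency: reported age must equal the dating formula
  stopifnot(all(abs(events$age_mya -
                      dateEvent(events$mode_ks,
                                config$lambda_rate)) < 1e-9))
  utils::write.table(events, file.path(config$out_dir, "events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$stages$dating <- list(
    lambda_rate = config$lambda_rate,
    filter_within = kw[c("n_input", "n_na", "n_out_of_range")],
    filter_outgroup = ko[c("n_input", "n_na", "n_out_of_range")],
    events = events)

  # --- stage: subgenome phasing ------------------------------------
  .log_stage("phasing", "chromosome distances + assignment")
  focal_chrom <- stats::setNames(sim$annotation_focal$chromosome,
                                 sim$annotation_focal$gene_id)
  out_chrom <- stats::setNames(sim$annotation_outgroup$chromosome,
                               sim$annotation_outgroup$gene_id)
  ks_pairs <- data.frame(chrom_1 = focal_chrom[kaks_outgroup$gene1],
                         chrom_2 = out_chrom[kaks_outgroup$gene2],
                         ks = kaks_outgroup$Ks,
                         stringsAsFactors = FALSE)
  # cap alignments per chromosome pair (they are exchangeable)
  keykp <- paste(ks_pairs$chrom_1, ks_pairs$chrom_2)
  idx <- unlist(lapply(split(seq_len(nrow(ks_pairs)), keykp),
                       utils::head, config$max_pairs_per_chrom))
  dmat <- chromosomeDistances(ks_pairs[idx, , drop = FALSE])
  phasing <- assignSubgenomes(dmat, unique(out_chrom))
  phase_df <- as.data.frame(phasing)
  utils::write.table(phase_df,
                     file.path(config$out_dir, "phasing.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$stages$phasing <- list(
    n_A = sum(phase_df$subgenome == "A"),
    n_B = sum(phase_df$subgenome == "B"),
    min_margin = min(phase_df$margin), table = phase_df)

  # --- stage: expression bias --------------------------------------
  .log_stage("expression", "HEB, DEGs, paralog classes")
  subg_map <- stats::setNames(phase_df$subgenome, phase_df$chromosome)
  hpairs <- homoeologPairs(within_blocks, subg_map)
  heb <- hebTable(hpairs, expr, config$bias)
  hsum <- hebSummary(heb, hpairs)
  utils::write.table(heb, file.path(config$out_dir, "heb.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cd <- as.data.frame(SummarizedExperiment::colData(expr))
  contrasts <- expand.grid(tissue = unique(cd$tissue),
                           timepoint = setdiff(unique(cd$timepoint), 0),
                           stringsAsFactors = FALSE)
  degs <- do.call(rbind, lapply(seq_len(nrow(contrasts)), function(i) {
    tis <- contrasts$tissue[i]; tp <- contrasts$timepoint[i]
    callDegs(expr,
             treated = cd$sample[cd$tissue == tis &
                                   cd$timepoint == tp],
             control = cd$sample[cd$tissue == tis & cd$timepoint == 0],
             config$bias,
             contrast_id = sprintf("%s_%shr_vs_0h", tis, tp))
  }))
  utils::write.table(degs[degs$is_deg, ],
                     file.path(config$out_dir, "degs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  deg_counts <- table(degs$contrast[degs$is_deg])

  deg_genes <- unique(degs$gene_id[degs$is_deg])
  deg_sub <- subg_map[focal_chrom[deg_genes]]
  chisq <- if (length(deg_genes))
    subgenomeDegChisq(sum(deg_sub == "A"), sum(deg_sub == "B"))
  else list(chi2 = NA, pvalue = NA)

  paralogs <- wgdParalogPairs(within_blocks, outgroup_blocks)
  classes <- classifyParalogDivergence(paralogs, degs)
  utils::write.table(classes$per_pair,
                     file.path(config$out_dir, "paralog_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$stages$expression <- list(
    n_homoeolog_pairs = nrow(hpairs),
    n_pairs_biased = hsum$n_pairs_biased,
    frac_majority_B = hsum$frac_majority_B,
    deg_counts = as.list(deg_counts),
    deg_balance = list(n_A = sum(deg_sub == "A"),
                       n_B = sum(deg_sub == "B"),
                       chi2 = chisq$chi2, pvalue = chisq$pvalue),
    n_wgd_paralog_pairs = nrow(paralogs),
    paralog_classes = as.list(classes$counts))

  report$timing_sec <- as.numeric(difftime(Sys.time(), t0,
                                           units = "secs"))
  report$fingerprint <- .fingerprint(report)
  jsonlite::write_json(report, file.path(config$out_dir,
                                         "report.json"),
                       auto_unbox = TRUE, digits = 10,
                       dataframe = "columns", na = "null")
  .log_stage("done", sprintf("%.1f s", report$timing_sec))
  invisible(report)
}
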