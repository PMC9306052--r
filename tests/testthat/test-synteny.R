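test_that("gene ranks are dense per chromosome and sorted by start", {
  ann <- data.frame(gene_id = c("g1", "g2", "g3", "h1", "h2"),
                    chromosome = c("chr1", "chr1", "chr1", "chr2",
                                   "chr2"),
                    start = c(100, 50, 200, 10, 5),
                    end = c(150, 90, 250, 20, 8),
                    stringsAsFactors = FALSE)
  r <- buildGeneRanks(ann)
  expect_equal(r$rank[match(c("g1", "g2", "g3"), r$gene_id)],
               c(1L, 0L, 2L))
  expect_equal(sort(r$rank[r$chromosome == "chr2"]), c(0L, 1L))
  ann2 <- ann; ann2$gene_id[2] <- "g1"
  expect_error(buildGeneRanks(ann2), "duplicate")
  ann3 <- ann; ann3$end[1] <- 100
  expect_error(buildGeneRanks(ann3), "start < end")
})

test_that("five-anchor diagonals form a block, four-anchor ones do not", {
  ann_a <- mk_ann(paste0("a", 1:20), rep("A1", 20))
  ann_b <- mk_ann(paste0("b", 1:20), rep("B1", 20))
  # perfect 5-anchor diagonal: ranks 0..4 <-> 10..14
  h5 <- mk_hits(paste0("a", 1:5), paste0("b", 11:15))
  bl5 <- chainSyntenyBlocks(h5, ann_a, ann_b)
  expect_equal(nrow(blocks(bl5)), 1L)
  expect_equal(blocks(bl5)$orientation, "plus")
  expect_equal(blocks(bl5)$n_anchors, 5L)
  expect_true(validObject(bl5))
  # boundary: 4 anchors -> no block
  h4 <- mk_hits(paste0("a", 1:4), paste0("b", 11:14))
  expect_equal(nrow(blocks(chainSyntenyBlocks(h4, ann_a, ann_b))), 0L)
  # 6-anchor antidiagonal: ranks 0..5 <-> 20..15
  ann_b2 <- mk_ann(paste0("b", 1:25), rep("B1", 25))
  h6 <- mk_hits(paste0("a", 1:6), paste0("b", 21:16))
  bl6 <- chainSyntenyBlocks(h6, ann_a, ann_b2)
  expect_equal(nrow(blocks(bl6)), 1L)
  expect_equal(blocks(bl6)$orientation, "minus")
  expect_equal(blocks(bl6)$n_anchors, 6L)
})

test_that("hits referencing unknown genes are rejected", {
  ann_a <- mk_ann(paste0("a", 1:5), rep("A1", 5))
  ann_b <- mk_ann(paste0("b", 1:5), rep("B1", 5))
  h <- mk_hits(c(paste0("a", 1:4), "ghost"), paste0("b", 1:5))
  expect_error(chainSyntenyBlocks(h, ann_a, ann_b), "ghost")
})

test_that("DP chain score equals brute force on random small instances", {
  params <- syntenyParams(min_block_genes = 2L, max_gap = 25L)
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    ra <- sample(0:30, n)
    rb <- sample(0:30, n)
    got <- subgenomics:::.best_chain(ra, rb, params, minus = FALSE)
    got_m <- subgenomics:::.best_chain(ra, rb, params, minus = TRUE)
    expect_equal(max(got$score, got_m$score),
                 oracle_best_chain(ra, rb, params),
                 tolerance = 1e-9)
  }
})

test_that("block output is invariant to hit order", {
  cfg <- simConfig(seed = 5, n_outgroup_chroms = 2,
                   genes_per_chrom = 25)
  sim <- simulateAllotetraploid(cfg, sequences = FALSE)
  b1 <- chainSyntenyBlocks(sim$hits_within, sim$annotation_focal,
                           sim$annotation_focal)
  shuffled <- sim$hits_within[rev(seq_len(nrow(sim$hits_within))), ]
  b2 <- chainSyntenyBlocks(shuffled, sim$annotation_focal,
                           sim$annotation_focal)
  expect_equal(blocks(b1), blocks(b2))
  expect_equal(anchors(b1), anchors(b2))
})

test_that("emitted blocks always satisfy the block invariants", {
  for (seed in c(3, 9)) {
    sim <- simulateAllotetraploid(
      simConfig(seed = seed, n_outgroup_chroms = 2,
                genes_per_chrom = 30), sequences = FALSE)
    wb <- chainSyntenyBlocks(sim$hits_within, sim$annotation_focal,
                             sim$annotation_focal)
    ob <- chainSyntenyBlocks(sim$hits_outgroup, sim$annotation_focal,
                             sim$annotation_outgroup)
    expect_true(validObject(wb))
    expect_true(validObject(ob))
  }
})

test_that("homoeolog pairs are routed by subgenome label and deduplicated", {
  ann_a <- mk_ann(c(paste0("a", 1:10), paste0("b", 1:10)),
                  rep(c("chrA1", "chrB1"), each = 10))
  h <- mk_hits(paste0("a", 1:6), paste0("b", 1:6))
  bl <- chainSyntenyBlocks(h, ann_a, ann_a)
  mapAB <- c(chrA1 = "A", chrB1 = "B")
  hp <- homoeologPairs(bl, mapAB)
  expect_equal(nrow(hp), 6L)
  expect_true(all(startsWith(hp$gene_a, "a")))
  expect_true(all(hp$chrom_a == "chrA1"))
  # same-subgenome blocks contribute nothing
  hp2 <- homoeologPairs(bl, c(chrA1 = "A", chrB1 = "A"))
  expect_equal(nrow(hp2), 0L)
  # B-labelled first chromosome gets flipped so A member is first
  hp3 <- homoeologPairs(bl, c(chrA1 = "B", chrB1 = "A"))
  expect_true(all(startsWith(hp3$gene_a, "b")))
  expect_error(homoeologPairs(bl, c(chrA1 = "A")), "without")
})

test_that("WGD paralog triples require exactly two anchored focal copies", {
  ann_f <- mk_ann(c(paste0("x", 1:8), paste0("y", 1:8)),
                  rep(c("chrA1", "chrB1"), each = 8))
  ann_o <- mk_ann(paste0("o", 1:8), rep("chrO1", 8))
  within <- chainSyntenyBlocks(mk_hits(paste0("x", 1:6),
                                       paste0("y", 1:6)),
                               ann_f, ann_f)
  outg <- chainSyntenyBlocks(rbind(mk_hits(paste0("x", 1:6),
                                           paste0("o", 1:6)),
                                   mk_hits(paste0("y", 1:6),
                                           paste0("o", 1:6))),
                             ann_f, ann_o)
  tr <- wgdParalogPairs(within, outg)
  expect_equal(nrow(tr), 6L)
  expect_true(all(tr$copy1 < tr$copy2))
  # an outgroup gene anchored to only one focal gene yields no triple
  outg1 <- chainSyntenyBlocks(mk_hits(paste0("x", 1:6),
                                      paste0("o", 1:6)),
                              ann_f, ann_o)
  expect_equal(nrow(wgdParalogPairs(within, outg1)), 0L)
})

test_that("planted anchors are recovered from the synthetic genome", {
  cfg <- simConfig(seed = 2)
  sim <- simulateAllotetraploid(cfg, sequences = FALSE)
  wb <- chainSyntenyBlocks(sim$hits_within, sim$annotation_focal,
                           sim$annotation_focal)
  hp <- sim$truth$homoeologs[sim$truth$homoeologs$retained, ]
  got <- paste(anchors(wb)$gene_a, anchors(wb)$gene_b)
  want <- paste(hp$gene_a, hp$gene_b)
  expect_gte(mean(want %in% got), 0.95)
})

test_that("GFF3 and BED gene models read into identical ranked tables", {
  sim <- simulateAllotetraploid(
    simConfig(seed = 4, n_outgroup_chroms = 2, genes_per_chrom = 10),
    sequences = FALSE)
  dir <- tempfile(); dir.create(dir)
  gff <- file.path(dir, "g.gff3")
  writeLines(c("##gff-version 3", sprintf(
    "%s\tsim\tgene\t%d\t%d\t.\t+\t.\tID=%s",
    sim$annotation_outgroup$chromosome,
    as.integer(sim$annotation_outgroup$start + 1),
    as.integer(sim$annotation_outgroup$end),
    sim$annotation_outgroup$gene_id)), gff)
  bed <- file.path(dir, "g.bed")
  utils::write.table(
    data.frame(sim$annotation_outgroup$chromosome,
               as.integer(sim$annotation_outgroup$start),
               as.integer(sim$annotation_outgroup$end),
               sim$annotation_outgroup$gene_id, 0, "+"),
    bed, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  g <- readGeneModels(gff)
  b <- readGeneModels(bed)
  expect_equal(g$gene_id, b$gene_id)
  expect_equal(g$start, b$start)
  expect_equal(g$rank, b$rank)
})
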