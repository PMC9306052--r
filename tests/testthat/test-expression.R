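test_that("HEB is a pseudocounted log ratio with an expression floor", {
  pc0 <- biasConfig(pseudocount = 0)
  expect_equal(computeHeb(20, 10, pc0), 1)
  expect_equal(computeHeb(10, 10), 0)
  expect_true(is.na(computeHeb(0.2, 0.3)))  # floor 1 FPKM
  expect_error(computeHeb(-1, 2), "non-negative")
  # antisymmetry, exactly
  set.seed(51)
  a <- runif(200, 0, 50); b <- runif(200, 0, 50)
  expect_identical(computeHeb(a, b), -computeHeb(b, a))
})

test_that("dominance classification is boundary-inclusive and monotone", {
  expect_equal(classifyDominance(1.0), "A_dominant")   # ratio == 2
  expect_equal(classifyDominance(-1.0), "B_dominant")  # ratio == 0.5
  expect_equal(classifyDominance(0.99), "neutral")
  expect_equal(classifyDominance(-0.99), "neutral")
  expect_equal(classifyDominance(NA), "untestable")
  grid <- seq(-3, 3, by = 0.05)
  cls <- classifyDominance(grid)
  # monotone: B_dominant then neutral then A_dominant
  expect_true(all(diff(match(cls, c("B_dominant", "neutral",
                                    "A_dominant"))) >= 0))
  # custom ratio
  expect_equal(classifyDominance(1.2, biasConfig(dominance_ratio = 4)),
               "neutral")
})

test_that("HEB summaries count pairs, directions and chromosomes", {
  pairs <- data.frame(gene_a = paste0("a", 1:4),
                      gene_b = paste0("b", 1:4),
                      chrom_a = c("A1", "A1", "A2", "A2"),
                      chrom_b = c("B1", "B1", "B2", "B2"),
                      stringsAsFactors = FALSE)
  expr <- rbind(
    matrix(c(40, 40, 40, 5, 5, 5, 40, 40, 5, 10, 10, 10),
           nrow = 4, byrow = TRUE,
           dimnames = list(paste0("a", 1:4), paste0("s", 1:3))),
    matrix(c(5, 5, 5, 40, 40, 40, 5, 5, 40, 10, 10, 10),
           nrow = 4, byrow = TRUE,
           dimnames = list(paste0("b", 1:4), paste0("s", 1:3))))
  heb <- hebTable(pairs, expr)
  s <- hebSummary(heb, pairs)
  # a1 majority A, a2 majority B, a3 2-1 A, a4 never dominant
  expect_equal(s$n_pairs_biased, 3L)
  expect_equal(s$frac_majority_A, 2 / 3)
  expect_equal(s$frac_majority_B, 1 / 3)
  expect_equal(s$per_chromosome["A1 B1", "A"], 1)
  expect_equal(s$per_chromosome["A1 B1", "B"], 1)
  # pair dominant in no sample is excluded from the biased set
  expect_false("a4 b4" %in%
                 s$pair_direction$pair[s$pair_direction$direction %in%
                                         c("A", "B")])
})

test_that("DEG calling applies the fold-change and p-value rule", {
  pc0 <- biasConfig(pseudocount = 0)
  expr <- rbind(g1 = c(8, 8, 8, 2, 2, 2),
                g2 = c(5, 5, 5, 5, 5, 5),
                g3 = c(10.2, 9.4, 10.4, 5.3, 5.6, 5.2))
  colnames(expr) <- c(paste0("t", 1:3), paste0("c", 1:3))
  d <- callDegs(expr, paste0("t", 1:3), paste0("c", 1:3), pc0)
  expect_equal(d$log2fc[1], 2)
  expect_true(d$is_deg[1])  # near-zero variance, p ~ 0
  expect_equal(d$log2fc[2], 0)
  expect_false(d$is_deg[2])
  # |log2fc| = 0.93 < 1: not a DEG no matter the p-value
  expect_lt(abs(d$log2fc[3]), 1)
  expect_false(d$is_deg[3])
  expect_error(callDegs(expr, "t1", paste0("c", 1:3), pc0),
               "2 replicates")
  # replicate label permutation within a group changes nothing
  d2 <- callDegs(expr, c("t3", "t1", "t2"), c("c2", "c3", "c1"), pc0)
  expect_equal(d2$pvalue, d$pvalue)
  expect_equal(d2$log2fc, d$log2fc)
  # global rescaling leaves log2fc unchanged (pseudocount-0)
  d3 <- callDegs(expr * 7, paste0("t", 1:3), paste0("c", 1:3), pc0)
  expect_equal(d3$log2fc, d$log2fc)
})

test_that("subgenome balance chi-square matches its closed form", {
  r <- subgenomeDegChisq(299, 365)
  expect_equal(r$chi2, (299 - 332)^2 / 332 + (365 - 332)^2 / 332)
  expect_equal(r$chi2, 6.56, tolerance = 0.001)
  expect_lt(r$pvalue, 0.05)
  expect_equal(subgenomeDegChisq(100, 100)$chi2, 0)
  expect_equal(subgenomeDegChisq(100, 100)$pvalue, 1)
  expect_equal(subgenomeDegChisq(0, 10)$chi2, 10)
  expect_error(subgenomeDegChisq(-1, 5), "non-negative")
  # independent distribution-function oracle: for 1 df,
  # P(X > x) = 2 * pnorm(-sqrt(x))
  for (a in c(5, 50, 299, 1000)) for (b in c(7, 60, 365, 1500)) {
    r <- subgenomeDegChisq(a, b)
    expect_equal(r$pvalue, 2 * pnorm(-sqrt(r$chi2)),
                 tolerance = 1e-8)
  }
})

test_that("paralog pairs are classed by DEG membership across contrasts", {
  degs <- rbind(
    data.frame(gene_id = c("x1", "x2", "y1", "y2"),
               contrast = "leaf_24h", log2fc = c(2, 0, 0, 0),
               pvalue = c(0.01, 0.9, 0.9, 0.9),
               is_deg = c(TRUE, FALSE, FALSE, FALSE)),
    data.frame(gene_id = c("x1", "x2", "y1", "y2"),
               contrast = "root_1h", log2fc = c(0, 0, 0, -3),
               pvalue = c(0.9, 0.9, 0.9, 0.001),
               is_deg = c(FALSE, FALSE, FALSE, TRUE)))
  pairs <- data.frame(copy1 = c("x1", "x2"), copy2 = c("y2", "y1"),
                      stringsAsFactors = FALSE)
  cl <- classifyParalogDivergence(pairs, degs)
  # x1 DEG in leaf only, y2 DEG in root only: any-contrast rule -> 2
  expect_equal(cl$per_pair$n_deg_members, c(2L, 0L))
  expect_equal(unname(cl$counts), c(1L, 0L, 1L))
  expect_error(
    classifyParalogDivergence(
      data.frame(copy1 = "nope", copy2 = "x1"), degs), "nope")
})

test_that("hypergeometric enrichment matches exact combinatorics", {
  population <- paste0("g", 1:100)
  study <- paste0("g", 1:10)
  ann <- list(t_all = paste0("g", 1:10),       # all study genes
              t_none = paste0("g", 90:95),     # disjoint from study
              t_half = paste0("g", 6:15))
  r <- hypergeomEnrichment(study, population, ann)
  expect_equal(r$pvalue[r$term == "t_all"], 1 / choose(100, 10))
  expect_equal(r$pvalue[r$term == "t_none"],
               stats::phyper(-1, 6, 94, 10, lower.tail = FALSE))
  expect_equal(r$pvalue[r$term == "t_none"], 1)
  expect_true(all(r$fdr >= r$pvalue - 1e-15))
  expect_equal(r$term[1], "t_all")  # sorted by p
  expect_error(hypergeomEnrichment(c("zz"), population, ann),
               "subset")
})

test_that("planted dominance direction is recovered above the floor", {
  cfg <- simConfig(seed = 6, n_outgroup_chroms = 4,
                   genes_per_chrom = 50)
  sim <- simulateAllotetraploid(cfg, sequences = FALSE)
  expr <- simulateExpression(sim)
  hp <- sim$truth$homoeologs[sim$truth$homoeologs$retained, ]
  heb <- hebTable(hp[, c("gene_a", "gene_b")], expr)
  s <- hebSummary(heb)
  dir <- setNames(s$pair_direction$direction, s$pair_direction$pair)
  strong <- hp[hp$dominance != "none" & hp$log2_ratio >= 1.5, ]
  got <- dir[paste(strong$gene_a, strong$gene_b)]
  expect_gte(mean(got == strong$dominance), 0.95)
})
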