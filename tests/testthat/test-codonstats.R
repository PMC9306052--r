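test_that("codon alignment validity catches malformed input", {
  expect_error(codonPairAlignment("ATGC", "ATGC"), "divisible by 3")
  expect_error(codonPairAlignment("ATG", "ATGAAA"), "equal length")
  expect_error(codonPairAlignment("A-GAAA", "ATGAAA"),
               "whole-codon")
  expect_error(codonPairAlignment("ATX", "ATG"), "alphabet")
  expect_s4_class(codonPairAlignment("ATG---", "ATGAAA"),
                  "CodonPairAlignment")
})

test_that("backtranslation expands residues and gaps in frame", {
  aln <- backtranslateCodonAlignment("M-K", "MKK", "ATGAAA",
                                     "ATGAAGAAA")
  expect_equal(aln@seq1, "ATG---AAA")
  expect_equal(aln@seq2, "ATGAAGAAA")
  ident <- backtranslateCodonAlignment("MK", "MK", "ATGAAA",
                                       "ATGAAG")
  expect_equal(ident@seq1, "ATGAAA")
  expect_equal(ident@seq2, "ATGAAG")
  expect_error(
    backtranslateCodonAlignment("MA", "MA", "ATGTTT", "ATGGCT"),
    "residue 2")
  expect_error(
    backtranslateCodonAlignment("MK", "MK", "ATGTAAAAA"[1],
                                "ATGAAA"),
    "translates to|stop|length")
})

test_that("fourfold site classification follows family and prefix rules", {
  expect_equal(fourfoldSites(codonPairAlignment("GGA", "GGT")), 1L)
  # Phe: third position is 2-fold degenerate
  expect_length(fourfoldSites(codonPairAlignment("TTT", "TTC")), 0)
  # first codon positions differ
  expect_length(fourfoldSites(codonPairAlignment("GGA", "CGA")), 0)
  # oracle: both codons fourfold (all third-position variants keep the
  # amino acid) and first two positions identical
  set.seed(7)
  sense <- Biostrings::GENETIC_CODE[Biostrings::GENETIC_CODE != "*"]
  for (rep in 1:200) {
    c1 <- sample(names(sense), 1)
    c2 <- sample(names(sense), 1)
    got <- length(fourfoldSites(codonPairAlignment(c1, c2))) == 1L
    four <- function(cod) {
      v <- vapply(c("A", "C", "G", "T"), function(nt)
        oracle_aa(paste0(substr(cod, 1, 2), nt)), "")
      length(unique(v)) == 1L && !any(v == "*")
    }
    want <- four(c1) && four(c2) &&
      substr(c1, 1, 2) == substr(c2, 1, 2)
    expect_identical(got, want, info = paste(c1, c2))
  }
})

test_that("4DTv counts transversions at 4D third positions", {
  same <- compute4DTv(codonPairAlignment("GGAGCC", "GGAGCC"))
  expect_equal(same$raw_4dtv, 0)
  expect_equal(same$n_4d_sites, 2L)
  expect_equal(compute4DTv(codonPairAlignment("GGA", "GGT"))$raw_4dtv,
               1)  # A<->T transversion
  expect_equal(compute4DTv(codonPairAlignment("GGA", "GGG"))$raw_4dtv,
               0)  # A<->G transition
  # no 4D sites -> undefined
  none <- compute4DTv(codonPairAlignment("TTT", "TTC"))
  expect_true(is.na(none$raw_4dtv))
  # correction: -0.5 log(1 - 2v), undefined at saturation
  x <- compute4DTv(codonPairAlignment(paste0("GGA", strrep("GGG", 3)),
                                      paste0("GGT", strrep("GGG", 3))),
                   correct = TRUE)
  expect_equal(x$raw_4dtv, 0.25)
  expect_equal(x$corrected_4dtv, -0.5 * log(1 - 2 * 0.25))
  sat <- compute4DTv(codonPairAlignment("GGA", "GGT"), correct = TRUE)
  expect_true(is.na(sat$corrected_4dtv))
})

test_that("NG86 reproduces hand-verified counts and saturation", {
  ident <- computeKaKs(codonPairAlignment("ATGGGA", "ATGGGA"))
  expect_equal(ident$Ks, 0)
  expect_equal(ident$Ka, 0)
  expect_equal(ident$Sd + ident$Nd, 0)
  k <- computeKaKs(codonPairAlignment(
    strrep("TTT", 10), paste0(strrep("TTT", 9), "TTC")))
  expect_equal(k$S, 10 / 3)
  expect_equal(k$Sd, 1)
  expect_equal(k$pS, 0.3)
  expect_equal(k$Ks, -0.75 * log(0.6))
  expect_equal(k$Ka, 0)
  expect_equal(k$S + k$N, 3 * k$n_codons_used)
  # single-codon saturation: pS = 3 >= 3/4 -> Ks undefined
  sat <- computeKaKs(codonPairAlignment("TTT", "TTC"))
  expect_true(is.na(sat$Ks))
  expect_false(is.na(sat$Ka))
  # no usable columns is an error, distinct from saturation
  expect_error(computeKaKs(codonPairAlignment("---", "AAA")),
               "usable")
})

test_that("NG86 path averaging matches exhaustive enumeration on random toys", {
  set.seed(42)
  sense <- names(
    Biostrings::GENETIC_CODE[Biostrings::GENETIC_CODE != "*"])
  for (rep in 1:30) {
    n <- sample(1:3, 1)
    s1 <- paste(sample(sense, n, replace = TRUE), collapse = "")
    s2 <- paste(sample(sense, n, replace = TRUE), collapse = "")
    k <- computeKaKs(codonPairAlignment(s1, s2))
    starts <- seq(1, nchar(s1), by = 3)
    o <- Reduce(`+`, Map(function(a, b) oracle_path_counts(a, b),
                         substring(s1, starts, starts + 2),
                         substring(s2, starts, starts + 2)))
    expect_equal(k$Sd, unname(o[1]), tolerance = 1e-12)
    expect_equal(k$Nd, unname(o[2]), tolerance = 1e-12)
    so <- sum(vapply(substring(s1, starts, starts + 2),
                     oracle_syn_sites, 1) +
                vapply(substring(s2, starts, starts + 2),
                       oracle_syn_sites, 1)) / 2
    expect_equal(k$S, so, tolerance = 1e-12)
  }
})

test_that("estimates are symmetric in the two sequences", {
  for (seed in 1:10) {
    p <- simulateCodonPair(0.5, n_codons = 60, seed = seed)
    a <- p$alignment
    fwd <- computeKaKs(a)
    rev <- computeKaKs(codonPairAlignment(a@seq2, a@seq1))
    expect_equal(fwd$Ks, rev$Ks, tolerance = 1e-12)
    expect_equal(fwd$Ka, rev$Ka, tolerance = 1e-12)
    f1 <- compute4DTv(a)
    f2 <- compute4DTv(codonPairAlignment(a@seq2, a@seq1))
    expect_identical(f1$raw_4dtv, f2$raw_4dtv)
  }
})

test_that("an extra synonymous difference never decreases Ks", {
  base <- strrep("GGA", 20)
  prev <- computeKaKs(codonPairAlignment(base, base))$Ks
  for (i in 1:6) {
    mutated <- paste0(strrep("GGT", i), strrep("GGA", 20 - i))
    cur <- computeKaKs(codonPairAlignment(base, mutated))$Ks
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("mean 4DTv rises with simulated divergence", {
  means <- vapply(c(0.1, 0.4, 0.8), function(d) {
    mean(vapply(1:25, function(s)
      compute4DTv(
        simulateCodonPair(d, n_codons = 200,
                          seed = 1000 * d + s)$alignment)$raw_4dtv,
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("kaks table round-trips through TSV with NA flags", {
  alns <- list(codonPairAlignment("TTT", "TTC", "g1", "g2"),
               codonPairAlignment(strrep("GGA", 5),
                                  paste0(strrep("GGA", 4), "GGT"),
                                  "g3", "g4"))
  tab <- kaksTable(alns)
  expect_equal(nrow(tab), 2L)
  expect_true(is.na(tab$Ks[1]))
  expect_false(is.na(tab$Ks[2]))
  f <- tempfile(fileext = ".tsv")
  writeKaksTable(tab, f)
  back <- readKaksTable(f)
  expect_equal(back$Ks, tab$Ks)
  expect_equal(back$gene1, tab$gene1)
})
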