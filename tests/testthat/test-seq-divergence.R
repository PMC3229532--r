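test_that("back-translation maps aligned residues to source codons", {
  al <- codonBacktranslate("M-K", "MAK", "ATGAAA", "ATGGCTAAG")
  expect_equal(al$a, "ATG---AAA")
  expect_equal(al$b, "ATGGCTAAG")
  # identical CDSs give identical aligned rows (trailing stop trimmed)
  al2 <- codonBacktranslate("MK", "MK", "ATGAAATGA", "ATGAAATGA")
  expect_equal(al2$a, al2$b)
  expect_equal(al2$a, "ATGAAA")
  expect_error(codonBacktranslate("MK", "MK", "ATGAAAG", "ATGAAA"),
               "mismatch")
  expect_error(codonBacktranslate("MKK", "MKK", "ATGTAAAAA", "ATGAAAAAA"),
               "stop")
})

test_that("random back-translations re-encode to the original proteins", {
  set.seed(3)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  for (rep in 1:5) {
    codA <- sample(sense, 20, replace = TRUE)
    codB <- sample(sense, 20, replace = TRUE)
    protA <- paste(gc[codA], collapse = "")
    protB <- paste(gc[codB], collapse = "")
    al <- codonBacktranslate(protA, protB,
                             paste(codA, collapse = ""),
                             paste(codB, collapse = ""))
    retrA <- as.character(Biostrings::translate(
      Biostrings::DNAString(al$a)))
    expect_equal(retrA, protA)
    expect_equal(al$b, paste(codB, collapse = ""))
  }
})

test_that("Nei-Gojobori hand case and basic structure", {
  expect_equal(neiGojobori(list(a = "ATGAAA", b = "ATGAAA"))[c("Ka", "Ks")],
               list(Ka = 0, Ks = 0))
  ng <- neiGojobori(list(a = "GGGGGGGGG", b = "GGAGGGGGG"))
  # each GGN codon: third position 4-fold, so S = 1 per codon
  expect_equal(ng$S, 3)
  expect_equal(ng$Sd, 1)
  expect_equal(ng$Ka, 0)
  expect_equal(ng$Ks, -0.75 * log(1 - 4 * (1 / 3) / 3), tolerance = 1e-12)
  expect_equal(ng$Ks, 0.440838, tolerance = 1e-5)
})

test_that("multi-difference codons average over stop-free pathways", {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  # every two-difference codon pair vs the independent recursive oracle
  set.seed(1)
  checked <- 0L
  for (c1 in sense) for (c2 in sense) {
    nd <- sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (nd != 2L) next
    oracle <- oracleCodonDiff(c1, c2)
    impl <- dupModes:::codonPairDifferences(c1, c2)
    if (is.null(oracle)) {
      expect_null(impl)
    } else {
      expect_equal(unname(impl), unname(oracle), tolerance = 1e-12)
    }
    checked <- checked + 1L
  }
  expect_gt(checked, 500L)
  # spot-check a three-difference pair against the oracle
  o3 <- oracleCodonDiff("AAA", "CCC")
  i3 <- dupModes:::codonPairDifferences("AAA", "CCC")
  expect_equal(unname(i3), unname(o3), tolerance = 1e-12)
})

test_that("Ka/Ks is symmetric and invariant to codon-block permutation", {
  set.seed(6)
  cfg <- simulationConfig(seed = 6, nCodons = 60L)
  pr <- data.frame(gene_a = "a", gene_b = "b",
                   target_ks = 0.4, target_ka = 0.1,
                   target_promoter_p = 0.1)
  sq <- simulateSequences(pr, cfg)
  a <- sq$cds_a[1]; b <- sq$cds_b[1]
  f <- neiGojobori(list(a = a, b = b))
  r <- neiGojobori(list(a = b, b = a))
  expect_equal(f[c("Ka", "Ks")], r[c("Ka", "Ks")])
  # permute codon blocks identically in both sequences
  k <- nchar(a) / 3
  perm <- sample(k)
  blocks <- function(s) substring(s, 3 * (1:k) - 2, 3 * (1:k))
  pa <- paste(blocks(a)[perm], collapse = "")
  pb <- paste(blocks(b)[perm], collapse = "")
  p <- neiGojobori(list(a = pa, b = pb))
  expect_equal(p[c("Ka", "Ks")], f[c("Ka", "Ks")])
})

test_that("gap and ambiguous codons are excluded from counting", {
  ng <- neiGojobori(list(a = "ATG---GGG", b = "ATGAAAGGA"))
  expect_equal(ng$codons, 2L)
  expect_equal(ng$skipped, 1L)
  ngN <- neiGojobori(list(a = "ATGANG", b = "ATGAAG"))
  expect_equal(ngN$codons, 1L)
  expect_error(neiGojobori(list(a = "---", b = "AAA")), "countable")
  expect_error(neiGojobori(list(a = "AAAA", b = "AAAA")), "divisible")
})

test_that("Jukes-Cantor closed form, domain boundary and monotonicity", {
  a <- paste(rep("A", 100), collapse = "")
  expect_equal(jukesCantorMu(a, a)$mu, 0)
  b10 <- paste(c(rep("C", 10), rep("A", 90)), collapse = "")
  mu <- jukesCantorMu(a, b10)
  expect_equal(mu$p, 0.1)
  expect_equal(mu$mu, -0.75 * log(1 - 0.4 / 3))
  expect_equal(mu$mu, 0.10732, tolerance = 1e-4)
  b75 <- paste(c(rep("C", 75), rep("A", 25)), collapse = "")
  inv <- jukesCantorMu(a, b75)
  expect_true(is.na(inv$mu))
  expect_false(inv$valid)
  # monotone increasing in p on [0, 3/4)
  mus <- vapply(seq(0, 70, by = 10), function(k) {
    b <- paste(c(rep("C", k), rep("A", 100 - k)), collapse = "")
    jukesCantorMu(a, b)$mu
  }, numeric(1))
  expect_true(all(diff(mus) > 0))
  # gaps are ignored; all-gap overlap errors
  expect_equal(jukesCantorMu("A-A", "AC-")$sites, 1L)
  expect_error(jukesCantorMu("--", "AA"), "ungapped")
})

test_that("promoter regions are truncated, capped and strand-aware", {
  # + strand gene with upstream neighbour ending 600 bp before the TSS
  ann <- makeGenomeAnnotation(data.frame(
    gene_id = c("up", "focal", "minus", "far"),
    chromosome = "chr1",
    start = c(1000L, 3600L, 6000L, 10000L),
    end = c(2999L, 4600L, 7000L, 11000L),
    strand = c("+", "+", "-", "+"),
    exon_count = 1L, stringsAsFactors = FALSE),
    chromLengths = c(chr1 = 12000))
  r <- promoterRegion("focal", ann)
  expect_equal(r$width, 600L)  # truncated at the neighbour's end
  expect_equal(c(r$start, r$end), c(3000L, 3599L))
  # no upstream gene within 1000 bp: exactly 1000 bp
  r2 <- promoterRegion("far", ann)
  expect_equal(r2$width, 1000L)
  # minus strand: downstream in chromosome coordinates
  r3 <- promoterRegion("minus", ann)
  expect_equal(c(r3$start, r3$end), c(7001L, 8000L))
  expect_equal(r3$width, 1000L)
  # chromosome edge clips, not errors
  annEdge <- makeGenomeAnnotation(data.frame(
    gene_id = "g", chromosome = "c", start = 301L, end = 900L,
    strand = "+", exon_count = 1L, stringsAsFactors = FALSE))
  expect_equal(promoterRegion("g", annEdge)$start, 1L)
  expect_equal(promoterRegion("g", annEdge)$width, 300L)
})

test_that("promoter extraction reverse-complements minus-strand genes", {
  ann <- makeGenomeAnnotation(data.frame(
    gene_id = c("plus", "minus"),
    chromosome = "chr1",
    start = c(11L, 31L), end = c(20L, 40L),
    strand = c("+", "-"), exon_count = 1L, stringsAsFactors = FALSE),
    chromLengths = c(chr1 = 60))
  seqs <- Biostrings::DNAStringSet(c(
    chr1 = paste(rep(c("A", "C", "G", "T", "A", "C"), each = 10),
                 collapse = "")))
  sPlus <- promoterExtract("plus", ann, seqs, maxLen = 10L)
  expect_equal(as.character(sPlus), paste(rep("A", 10), collapse = ""))
  sMinus <- promoterExtract("minus", ann, seqs, maxLen = 10L)
  # genomic [41, 50] is all A -> reverse complement is all T
  expect_equal(as.character(sMinus), paste(rep("T", 10), collapse = ""))
})

test_that("promoter duplication uses strict >45% gap-inclusive identity", {
  a <- paste(rep("ACGT", 50), collapse = "")
  expect_true(promoterDuplicated(a, a)$duplicated)
  expect_equal(promoterDuplicated(a, a)$identity, 1)
  dis <- promoterDuplicated(paste(rep("A", 40), collapse = ""),
                            paste(rep("C", 40), collapse = ""))
  expect_equal(dis$identity, 0)
  expect_false(dis$duplicated)
  # identity exactly at the threshold is NOT duplicated
  x <- paste(c(rep("A", 45), rep("C", 55)), collapse = "")
  y <- paste(c(rep("A", 45), rep("G", 55)), collapse = "")
  pd <- promoterDuplicated(x, y, aligned = TRUE)
  expect_equal(pd$identity, 0.45)
  expect_false(pd$duplicated)
  expect_error(promoterDuplicated("", a), "empty")
})
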