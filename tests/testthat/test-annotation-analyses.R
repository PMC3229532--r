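test_that("promoter methylation needs two adjacent methylated probes", {
  region <- list(chromosome = "chr1", start = 1000L, end = 2000L,
                 width = 1001L)
  track <- function(pos, m)
    data.frame(chromosome = "chr1", position = pos, methylated = m)
  expect_true(promoterMethylated(region, track(c(1100, 1300, 1500),
                                               c(TRUE, TRUE, FALSE))))
  expect_false(promoterMethylated(region, track(c(1100, 1300, 1500),
                                                c(TRUE, FALSE, TRUE))))
  # zero or one probe in the region: unmethylated, not missing
  expect_false(promoterMethylated(region, track(5000, TRUE)))
  expect_false(promoterMethylated(region, track(c(1100, 5000),
                                                c(TRUE, TRUE))))
  # adjacency is in the track: an unmethylated probe in between breaks it
  expect_false(promoterMethylated(region, track(c(1100, 1200, 1300),
                                                c(TRUE, FALSE, TRUE))))
})

test_that("methylation call is monotone in added methylated probes", {
  region <- list(chromosome = "chr1", start = 0L, end = 10000L,
                 width = 10001L)
  set.seed(12)
  for (rep in 1:20) {
    pos <- sort(sample(10000L, 8))
    met <- runif(8) < 0.4
    tr <- data.frame(chromosome = "chr1", position = pos, methylated = met)
    before <- promoterMethylated(region, tr)
    # add a methylated probe right next to an existing methylated one
    mIdx <- which(met)
    if (!length(mIdx)) next
    newPos <- pos[mIdx[1]] + 1L
    while (newPos %in% pos) newPos <- newPos + 1L
    tr2 <- rbind(tr, data.frame(chromosome = "chr1", position = newPos,
                                methylated = TRUE))
    tr2 <- tr2[order(tr2$position), ]
    after <- promoterMethylated(region, tr2)
    if (before) expect_true(after)
  }
})

test_that("methylation track io and per-gene calls", {
  path <- file.path(tempdir(), "meth.tsv")
  writeLines(c("chr1\t500\t1", "chr1\t100\t0", "chr2\t10\t1"), path)
  tr <- readMethylationTrack(path)
  expect_equal(tr$position[tr$chromosome == "chr1"], c(100L, 500L))
  writeLines(c("chr1\t100\t1", "chr1\t100\t0"), path)
  expect_error(readMethylationTrack(path), "duplicate")

  ann <- rowAnnotation(rep(1L, 4), spacing = 3000L)
  trk <- data.frame(chromosome = "chr1",
                    position = c(3100L, 3200L, 9100L, 9200L),
                    methylated = c(TRUE, TRUE, TRUE, FALSE))
  calls <- promoterMethylationCalls(ann, trk)
  expect_length(calls, 4L)
  expect_type(calls, "logical")
  # cross-check each call against the rule applied to promoterRegion output
  expected <- vapply(geneIds(ann), function(g) {
    r <- promoterRegion(g, ann)
    inR <- trk$position >= r$start & trk$position <= r$end
    any(inR[-nrow(trk)] & inR[-1] &
        trk$methylated[-nrow(trk)] & trk$methylated[-1])
  }, logical(1))
  expect_equal(calls, expected)
})

test_that("pair methylation change and per-class methylated proportions", {
  calls <- c(a1 = TRUE, b1 = TRUE, a2 = TRUE, b2 = FALSE,
             a3 = FALSE, b3 = FALSE)
  pairs <- data.frame(gene_a = c("a1", "a2", "a3"),
                      gene_b = c("b1", "b2", "b3"),
                      mode = c("WGD", "WGD", "TANDEM"))
  mc <- methylationChangeProportion(pairs, calls)
  expect_equal(mc$proportion[mc$mode == "WGD"], 0.5)
  expect_equal(mc$proportion[mc$mode == "TANDEM"], 0)
  # missing call: excluded and counted
  pairs2 <- rbind(pairs,
                  data.frame(gene_a = "a1", gene_b = "zz", mode = "WGD"))
  mc2 <- methylationChangeProportion(pairs2, calls)
  expect_equal(mc2$n_excluded[mc2$mode == "WGD"], 1L)

  mp <- methylatedProportion(calls, c(a1 = "singleton", b1 = "duplicate",
                                      a2 = "singleton", b2 = "duplicate",
                                      a3 = "singleton", b3 = "duplicate"))
  expect_equal(mp$proportion[mp$class == "singleton"], 2 / 3)

  # iid Bernoulli(0.3) calls: expected change proportion 2 * 0.3 * 0.7
  set.seed(5)
  n <- 4000
  cA <- runif(n) < 0.3
  cB <- runif(n) < 0.3
  calls3 <- setNames(c(cA, cB), c(paste0("x", 1:n), paste0("y", 1:n)))
  pr <- data.frame(gene_a = paste0("x", 1:n), gene_b = paste0("y", 1:n),
                   mode = "WGD")
  mc3 <- methylationChangeProportion(pr, calls3)
  expect_equal(mc3$proportion, 0.42, tolerance = 0.06)
})

test_that("Fisher enrichment matches hypergeometric enumeration", {
  # universe of 4 genes, 2 carry the term, subset is exactly those 2
  terms <- list(g1 = "T", g2 = "T")
  res <- fisherEnrichment(c("g1", "g2"), paste0("g", 1:4), terms)
  expect_equal(res$p, 1 / choose(4, 2), tolerance = 1e-12)
  expect_equal(res$p, oracleHyperP(2, 2, 2, 4), tolerance = 1e-12)

  # subset = universe: p = 1 for every term
  terms2 <- list(g1 = "A", g2 = c("A", "B"), g3 = "B")
  resU <- fisherEnrichment(paste0("g", 1:3), paste0("g", 1:3), terms2)
  expect_true(all(resU$p == 1))

  # Bonferroni arithmetic over tested terms
  expect_equal(min(1, 0.04 * 3), 0.12)
  expect_equal(resU$p_corrected, pmin(1, resU$p * nrow(resU)))
  expect_error(fisherEnrichment("zz", "g1", terms), "within universe")
})

test_that("raw enrichment p equals the exhaustive tail over small tables", {
  # fisherEnrichment driven end-to-end on constructed gene sets
  set.seed(2)
  for (rep in 1:50) {
    n <- sample(5:16, 1)
    K <- sample(1:n, 1)        # genes with the term
    m <- sample(1:(n - 1), 1)  # subset size
    universe <- paste0("u", seq_len(n))
    withTerm <- sample(universe, K)
    subset <- sample(universe, m)
    a <- sum(subset %in% withTerm)
    terms <- setNames(as.list(rep("T", K)), withTerm)
    res <- fisherEnrichment(subset, universe, terms)
    expect_equal(res$p, oracleHyperP(a, m, K, n), tolerance = 1e-10)
  }
})

test_that("enrichment type-I rate is controlled at corrected alpha", {
  set.seed(33)
  universe <- paste0("g", 1:60)
  terms <- lapply(setNames(nm = universe), function(g)
    sample(paste0("T", 1:8), 2))
  hits <- 0L
  total <- 0L
  for (rep in 1:40) {
    subset <- sample(universe, 15)
    res <- fisherEnrichment(subset, universe, terms)
    hits <- hits + sum(res$significant)
    total <- total + nrow(res)
  }
  rate <- hits / total
  expect_lte(rate, 0.05 + 2.58 * sqrt(0.05 * 0.95 / total))
})

test_that("family/mode enrichment finds planted bias, skips small families", {
  set.seed(44)
  origins <- setNames(
    sample(c("WGD", "TANDEM", "DISPERSED"), 200, TRUE,
           prob = c(0.2, 0.3, 0.5)),
    paste0("g", 1:200))
  # planted family: 20 genes, 18 of them WGD
  wgdGenes <- names(origins)[origins == "WGD"]
  others <- setdiff(names(origins), wgdGenes)
  fam <- setNames(as.list(rep("FAM1", 20)),
                  c(wgdGenes[1:18], others[1:2]))
  # small family of 9 genes: excluded entirely
  fam9 <- setNames(as.list(rep("FAM9", 9)), others[3:11])
  res <- familyModeEnrichment(c(fam, fam9), origins)
  expect_false("FAM9" %in% res$family)
  top <- res[res$family == "FAM1" & res$mode == "WGD", ]
  expect_true(top$significant)
  # oracle: hypergeometric upper tail for the same table
  expect_equal(top$p,
               oracleHyperP(top$in_mode, top$family_n, top$mode_n, 200),
               tolerance = 1e-10)
})
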