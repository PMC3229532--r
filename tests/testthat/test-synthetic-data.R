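test_that("the generator is bit-reproducible under a fixed seed", {
  cfg <- simulationConfig(seed = 101, eventsPerMode = 6L)
  s1 <- simulateGenome(cfg)
  s2 <- simulateGenome(cfg)
  expect_identical(genes(s1$annotation), genes(s2$annotation))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$hits, s2$hits)
  m1 <- simulateExpression(geneIds(s1$annotation), s1$truth$pairs, cfg)
  m2 <- simulateExpression(geneIds(s2$annotation), s2$truth$pairs, cfg)
  expect_identical(m1, m2)
})

test_that("zero planted events yields an all-singleton genome", {
  cfg <- simulationConfig(seed = 3, eventsPerMode = 0L,
                          genesPerChromosome = 20L)
  sim <- simulateGenome(cfg)
  expect_equal(nrow(sim$truth$pairs), 0L)
  res <- classifyAll(sim$annotation, sim$hits, sim$anchors)
  expect_equal(nrow(res$pairs), 0L)
  expect_setequal(res$singletons, geneIds(sim$annotation))
})

test_that("emitted corpus files reload to the planted ground truth", {
  cfg <- simulationConfig(seed = 9, eventsPerMode = 8L)
  sim <- simulateGenome(cfg)
  dir <- file.path(tempdir(), "corpus")
  m <- simulateExpression(geneIds(sim$annotation), sim$truth$pairs, cfg)
  writeCorpus(sim, dir, expression = m)

  ann <- readGenomeGFF(file.path(dir, "annotation.gff3"))
  gOrig <- genes(sim$annotation)[order(genes(sim$annotation)$gene_id), ]
  gBack <- genes(ann)[order(genes(ann)$gene_id), ]
  rownames(gOrig) <- rownames(gBack) <- NULL
  expect_equal(gBack, gOrig)

  anc <- readAnchors(file.path(dir, "anchors.tsv"),
                     orthologPath = file.path(dir, "ortholog_anchors.tsv"),
                     annotation = ann)
  expect_setequal(ancestralIds(anc), ancestralIds(sim$anchors))
  hits <- readBlastTab(file.path(dir, "hits.tsv"))
  expect_setequal(pkey(hits$query_id, hits$subject_id),
                  pkey(sim$hits$query_id, sim$hits$subject_id))
  expr <- readExpressionMatrix(file.path(dir, "expression.tsv"))
  expect_equal(expr, m, ignore_attr = TRUE, tolerance = 1e-4)

  # running the classifier on the reloaded files recovers the truth
  res <- classifyAll(ann, hits, anc)
  truth <- sim$truth$pairs
  mm <- merge(
    data.frame(k = pkey(truth$gene_a, truth$gene_b), true = truth$mode),
    data.frame(k = pkey(res$pairs$gene_a, res$pairs$gene_b),
               pred = res$pairs$mode), all = TRUE)
  expect_true(all(!is.na(mm$true) & !is.na(mm$pred) & mm$true == mm$pred))
  truthJson <- jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE)
  expect_equal(sort(truthJson$singletons), sim$truth$singletons)
})

test_that("expression targets are honoured, exactly at r = 1", {
  cfg <- simulationConfig(seed = 17, samples = 500L)
  pr <- data.frame(gene_a = c("a1", "a2"), gene_b = c("b1", "b2"),
                   mode = c("WGD", "WGD"), target_r = c(1, 0.5))
  m <- simulateExpression(c("a1", "b1", "a2", "b2", "f1"), pr, cfg)
  expect_equal(cor(m["a1", ], m["b1", ]), 1, tolerance = 1e-12)
  expect_equal(cor(m["a2", ], m["b2", ]), 0.5, tolerance = 0.15)

  # many pairs: mean sample correlation is near the common target
  pr2 <- data.frame(gene_a = paste0("p", 1:500),
                    gene_b = paste0("q", 1:500),
                    mode = "WGD", target_r = 0.5)
  m2 <- simulateExpression(c(pr2$gene_a, pr2$gene_b), pr2, cfg)
  rbar <- mean(vapply(seq_len(500), function(i)
    cor(m2[pr2$gene_a[i], ], m2[pr2$gene_b[i], ]), numeric(1)))
  expect_equal(rbar, 0.5, tolerance = 0.04)
})

test_that("sequence targets: zero divergence and synonymous-only cases", {
  cfg <- simulationConfig(seed = 23, nCodons = 100L)
  pr0 <- data.frame(gene_a = "a", gene_b = "b",
                    target_ks = 0, target_ka = 0, target_promoter_p = 0)
  sq0 <- simulateSequences(pr0, cfg)
  expect_equal(sq0$cds_a, sq0$cds_b)
  ng0 <- neiGojobori(list(a = sq0$cds_a, b = sq0$cds_b))
  expect_equal(c(ng0$Ka, ng0$Ks), c(0, 0))
  expect_equal(sq0$promoter_a, sq0$promoter_b)

  # synonymous-only mutation gives Ka = 0 exactly
  prS <- data.frame(gene_a = "a", gene_b = "b",
                    target_ks = 0.5, target_ka = 0, target_promoter_p = 0)
  sqS <- simulateSequences(prS, cfg)
  ngS <- neiGojobori(list(a = sqS$cds_a, b = sqS$cds_b))
  expect_equal(ngS$Ka, 0)
  expect_gt(ngS$Ks, 0.2)
  # proteins unchanged under synonymous-only evolution
  expect_equal(sqS$protein_a, sqS$protein_b)
  # impossible target errors out
  expect_error(
    simulateSequences(data.frame(gene_a = "a", gene_b = "b",
                                 target_ks = 50, target_ka = 0,
                                 target_promoter_p = 0), cfg),
    "unreachable")
})

test_that("promoter divergence recovers the Jukes-Cantor closed form", {
  cfg <- simulationConfig(seed = 29, nCodons = 10L, promoterLength = 1000L)
  p <- 0.1
  mus <- vapply(1:60, function(i) {
    cfgI <- simulationConfig(seed = 29 + i, nCodons = 10L,
                             promoterLength = 1000L)
    pr <- data.frame(gene_a = "a", gene_b = "b", target_ks = 0,
                     target_ka = 0, target_promoter_p = p)
    sq <- simulateSequences(pr, cfgI)
    jukesCantorMu(sq$promoter_a, sq$promoter_b)$mu
  }, numeric(1))
  truthMu <- -0.75 * log(1 - 4 * p / 3)
  se <- sd(mus) / sqrt(length(mus))
  expect_lt(abs(mean(mus) - truthMu), 3 * se + 1e-4)
})

test_that("methylation track and families have the configured structure", {
  cfg <- simulationConfig(seed = 31, eventsPerMode = 6L,
                          genesPerChromosome = 80L, familyCount = 4L,
                          familySize = 8L)
  sim <- simulateGenome(cfg)
  tr <- simulateMethylation(sim$annotation, cfg)
  expect_true(all(diff(tr$position[tr$chromosome == "chr1"]) ==
                  cfg$probeSpacing))
  expect_equal(mean(tr$methylated), cfg$methylationRate, tolerance = 0.08)

  fams <- simulateFamilies(sim$truth$origins, cfg)
  expect_gt(length(fams$plantedMode), 0L)
  # each planted family is dominated by its planted mode
  byFam <- split(names(fams$families),
                 unlist(fams$families, use.names = FALSE))
  for (f in names(fams$plantedMode)) {
    modes <- sim$truth$origins[byFam[[f]]]
    expect_gte(mean(modes == fams$plantedMode[f], na.rm = TRUE), 0.5)
  }
})

test_that("interference plants overlapping events resolved by priority", {
  cfg <- simulationConfig(seed = 37, eventsPerMode = 10L,
                          interference = TRUE)
  sim <- simulateGenome(cfg)
  tt <- sim$truth$pairs
  wgdGenes <- unique(c(tt$gene_a[tt$mode == "WGD"],
                       tt$gene_b[tt$mode == "WGD"]))
  tandemOfWgd <- tt$mode == "TANDEM" &
    (tt$gene_a %in% wgdGenes | tt$gene_b %in% wgdGenes)
  expect_gt(sum(tandemOfWgd), 0L)
  res <- classifyAll(sim$annotation, sim$hits, sim$anchors)
  shared <- intersect(unique(c(tt$gene_a[tandemOfWgd],
                               tt$gene_b[tandemOfWgd])), wgdGenes)
  expect_true(all(res$origins[shared] == "WGD"))
  expect_mapequal(as.list(res$origins), as.list(sim$truth$origins))
})
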