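#' Simulation configuration for the synthetic corpus
#'
#' Central knobs of the ground-truth generator. Defaults describe the
#' standard validation corpus: 2 chromosomes of 500 genes, 50 planted
#' events of each duplication mode with no interference (each gene takes
#' part in exactly one planted event), 200 expression samples, and
#' per-mode target pair correlations ordered like the study system
#' (tandem/WGD most co-expressed, transposed least).
#'
#' @param seed integer seed used by every simulate* function.
#' @param chromosomes number of chromosomes.
#' @param genesPerChromosome genes per chromosome.
#' @param eventsPerMode planted events per duplication mode.
#' @param wgdBlockSize anchor pairs per collinear WGD block.
#' @param wgdEvents polyploidy event labels cycled over WGD blocks.
#' @param proximalWindow max rank distance for planted proximal pairs.
#' @param samples expression samples (chips).
#' @param targetR named per-mode target pair correlation.
#' @param targetKsRange,targetKaRange uniform ranges for per-pair target
#'   synonymous / nonsynonymous divergence.
#' @param nCodons codons per simulated coding sequence.
#' @param promoterLength simulated promoter length (bp).
#' @param promoterPRange uniform range of per-site promoter substitution
#'   probability.
#' @param probeSpacing methylation probe spacing (bp).
#' @param methylationRate Bernoulli rate of a probe being methylated.
#' @param decoyHits number of non-qualifying decoy homology hits.
#' @param familyCount,familySize,familyBias gene families to plant and
#'   the fraction of each family drawn from its planted mode.
#' @param orthologsPerClass ortholog pairs per class (S-S, S-D, D-D) in
#'   the two-species corpus.
#' @param ecSamples samples per species in the two-species corpus.
#' @param ecSigma named per-class perturbation standard deviations
#'   (ordered so true mean divergence is S-S < S-D < D-D).
#' @param ecFactors,ecNoiseSd latent factors and residual noise of the
#'   species-1 expression model.
#' @param interference also plant overlapping events (a tandem copy of a
#'   WGD gene) to exercise the origin priority rule.
#' @return list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1L,
                             chromosomes = 2L,
                             genesPerChromosome = 500L,
                             eventsPerMode = 50L,
                             wgdBlockSize = 10L,
                             wgdEvents = c("alpha", "beta", "gamma"),
                             proximalWindow = 20L,
                             samples = 200L,
                             targetR = c(WGD = 0.45, TANDEM = 0.45,
                                         PROXIMAL = 0.30,
                                         RETROTRANSPOSED = 0.08,
                                         DNA_TRANSPOSED = 0.10,
                                         DISPERSED = 0.10),
                             targetKsRange = c(0.1, 1.5),
                             targetKaRange = c(0.02, 0.5),
                             nCodons = 200L,
                             promoterLength = 1000L,
                             promoterPRange = c(0.02, 0.4),
                             probeSpacing = 150L,
                             methylationRate = 0.3,
                             decoyHits = 0L,
                             familyCount = 10L,
                             familySize = 20L,
                             familyBias = 0.9,
                             orthologsPerClass = 200L,
                             ecSamples = 100L,
                             ecSigma = c("S-S" = 0.1, "S-D" = 0.3,
                                         "D-D" = 0.6),
                             ecFactors = 4L,
                             ecNoiseSd = 0.5,
                             interference = FALSE) {
  cfg <- as.list(environment())
  stopifnot(cfg$eventsPerMode >= 0L,
            all(abs(cfg$targetR) <= 1),
            cfg$samples >= 3L,
            cfg$eventsPerMode %% cfg$wgdBlockSize == 0L ||
              cfg$eventsPerMode < cfg$wgdBlockSize)
  structure(cfg, class = "SimulationConfig")
}

# pick a random start such that len consecutive slots are free
.allocRun <- function(mask, len) {
  n <- length(mask)
  if (len > n) return(NULL)
  ok <- which(vapply(seq_len(n - len + 1L),
                     function(s) all(mask[s:(s + len - 1L)]), logical(1)))
  if (!length(ok)) return(NULL)
  s <- ok[sample.int(length(ok), 1L)]
  s:(s + len - 1L)
}

.allocPairAtDistance <- function(mask, d) {
  n <- length(mask)
  ok <- which(mask[seq_len(n - d)] & mask[seq_len(n - d) + d])
  if (!length(ok)) return(NULL)
  i <- ok[sample.int(length(ok), 1L)]
  c(i, i + d)
}

#' Simulate an annotated genome with planted duplications
#'
#' Lays out a genome of \code{chromosomes x genesPerChromosome} genes and
#' plants \code{eventsPerMode} duplication events of each mode with known
#' ground truth: WGD anchor pairs in collinear blocks spanning two
#' chromosomes; tandem copies at adjacent ranks; proximal copies at rank
#' distance uniform in [2, window]; retrotransposed copies (intronless,
#' multi-exon ancestral parent) and DNA-based transposed copies
#' (intron-retaining, ancestral parent) on another chromosome, with the
#' parent's ancestral status supported by a cross-species ortholog
#' anchor; dispersed pairs between non-ancestral loci on different
#' chromosomes. Every planted pair emits qualifying homology hits in both
#' directions; optional decoy hits fall above the e-value threshold.
#' Unplanted filler genes get no hits and are therefore singletons.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list: \code{annotation} (\code{GenomeAnnotation}),
#'   \code{anchors} (\code{AnchorCollection}), \code{hits} (data.frame as
#'   from \code{\link{readBlastTab}}), \code{truth} (list with
#'   \code{pairs}, \code{singletons}, \code{origins}).
#' @export
simulateGenome <- function(config = simulationConfig()) {
  set.seed(config$seed)
  nC <- config$chromosomes
  N <- config$genesPerChromosome
  E <- config$eventsPerMode
  chroms <- paste0("chr", seq_len(nC))
  masks <- lapply(seq_len(nC), function(i) rep(TRUE, N))
  ids <- outer(seq_len(N), chroms,
               function(s, ch) sprintf("%s_g%04d", ch, s))
  colnames(ids) <- chroms

  take <- function(chrom, slots) {
    stopifnot(all(masks[[chrom]][slots]))
    masks[[chrom]][slots] <<- FALSE
    ids[slots, chrom]
  }
  fail <- function() stop("more planted genes than available loci")

  pairs <- list()
  addPair <- function(a, b, mode, parental = NA_character_,
                      event = NA_character_, block = NA_character_) {
    pairs[[length(pairs) + 1L]] <<- data.frame(
      gene_a = min(a, b), gene_b = max(a, b), mode = mode,
      parental_copy = parental, event = event, block = block,
      stringsAsFactors = FALSE)
  }

  anchorRows <- list()
  orthoRows <- list()
  exonOverride <- list()
  setExons <- function(gene, k) exonOverride[[gene]] <<- as.integer(k)

  # --- WGD: collinear anchor blocks spanning chromosome pairs ----------
  if (E > 0L) {
    B <- min(config$wgdBlockSize, E)
    nBlocks <- ceiling(E / B)
    planted <- 0L
    for (bl in seq_len(nBlocks)) {
      sz <- min(B, E - planted)
      cA <- ((bl - 1L) %% nC) + 1L
      cB <- (bl %% nC) + 1L
      if (cA == cB) cB <- (cB %% nC) + 1L
      runA <- .allocRun(masks[[cA]], sz)
      runB <- .allocRun(masks[[cB]], sz)
      if (is.null(runA) || is.null(runB)) fail()
      ga <- take(cA, runA)
      gb <- take(cB, runB)
      ev <- config$wgdEvents[((bl - 1L) %% length(config$wgdEvents)) + 1L]
      blid <- sprintf("block%02d", bl)
      for (j in seq_len(sz)) {
        addPair(ga[j], gb[j], "WGD", event = ev, block = blid)
        anchorRows[[length(anchorRows) + 1L]] <- data.frame(
          gene_a = min(ga[j], gb[j]), gene_b = max(ga[j], gb[j]),
          block_id = blid, event = ev, stringsAsFactors = FALSE)
      }
      planted <- planted + sz
    }
  }

  # --- tandem: adjacent ranks ------------------------------------------
  for (k in seq_len(E)) {
    ch <- ((k - 1L) %% nC) + 1L
    sl <- .allocPairAtDistance(masks[[ch]], 1L)
    if (is.null(sl)) fail()
    g <- take(ch, sl)
    addPair(g[1], g[2], "TANDEM")
  }

  # --- proximal: rank distance uniform in [2, window] ------------------
  for (k in seq_len(E)) {
    ch <- ((k - 1L) %% nC) + 1L
    d <- sample(2:config$proximalWindow, 1L)
    sl <- .allocPairAtDistance(masks[[ch]], d)
    if (is.null(sl)) fail()
    g <- take(ch, sl)
    addPair(g[1], g[2], "PROXIMAL")
  }

  # --- transposed (retro and DNA-based) and dispersed ------------------
  single <- function(ch) {
    sl <- .allocRun(masks[[ch]], 1L)
    if (is.null(sl)) fail()
    take(ch, sl)
  }
  for (mode in c("RETROTRANSPOSED", "DNA_TRANSPOSED", "DISPERSED")) {
    for (k in seq_len(E)) {
      cP <- ((k - 1L) %% nC) + 1L
      cC <- (cP %% nC) + 1L
      a <- single(cP)
      b <- single(cC)
      if (mode == "RETROTRANSPOSED") {
        setExons(a, sample(3:6, 1L))
        setExons(b, 1L)
      } else if (mode == "DNA_TRANSPOSED") {
        setExons(a, sample(3:6, 1L))
        setExons(b, sample(2:5, 1L))
      }
      if (mode != "DISPERSED") {
        orthoRows[[length(orthoRows) + 1L]] <- data.frame(
          gene_a = a, gene_b = paste0("spB_", a), stringsAsFactors = FALSE)
        addPair(a, b, mode, parental = a)
      } else addPair(a, b, mode)
    }
  }

  # --- optional interference: tandem copies of WGD genes ---------------
  if (isTRUE(config$interference) && length(anchorRows)) {
    wgdGenes <- unlist(lapply(anchorRows, function(r)
      c(r$gene_a, r$gene_b)), use.names = FALSE)
    planted <- 0L
    for (wg in wgdGenes) {
      if (planted >= 5L) break
      ch <- match(sub("_g.*", "", wg), chroms)
      slot <- as.integer(sub(".*_g", "", wg))
      nb <- c(slot - 1L, slot + 1L)
      nb <- nb[nb >= 1L & nb <= N]
      nb <- nb[masks[[ch]][nb]]
      if (!length(nb)) next
      g <- take(ch, nb[1])
      addPair(wg, g, "TANDEM")
      planted <- planted + 1L
    }
    if (planted == 0L)
      warning("interference requested but no free locus adjacent to a ",
              "WGD gene")
  }

  pairs <- do.call(rbind, pairs)
  if (is.null(pairs))
    pairs <- data.frame(gene_a = character(0), gene_b = character(0),
                        mode = character(0), parental_copy = character(0),
                        event = character(0), block = character(0))

  # --- gene table -------------------------------------------------------
  geneRows <- list()
  for (ch in seq_len(nC)) {
    slot <- seq_len(N)
    geneRows[[ch]] <- data.frame(
      gene_id = ids[, ch],
      chromosome = chroms[ch],
      start = (slot - 1L) * 2000L + 1L,
      end = (slot - 1L) * 2000L + 1000L,
      strand = sample(c("+", "-"), N, replace = TRUE),
      exon_count = sample(1:6, N, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  geneTab <- do.call(rbind, geneRows)
  ov <- unlist(exonOverride)
  if (length(ov))
    geneTab$exon_count[match(names(ov), geneTab$gene_id)] <- ov
  cl <- structure(rep(N * 2000L, nC), names = chroms)
  annotation <- makeGenomeAnnotation(geneTab, chromLengths = cl)

  anchors <- new("AnchorCollection",
    anchors = if (length(anchorRows)) do.call(rbind, anchorRows) else
      data.frame(gene_a = character(0), gene_b = character(0),
                 block_id = character(0), event = character(0)),
    orthologs = if (length(orthoRows)) do.call(rbind, orthoRows) else
      data.frame(gene_a = character(0), gene_b = character(0)))

  # --- homology hits ----------------------------------------------------
  hitRows <- list()
  addHits <- function(a, b, lo = 1e-60, hi = 1e-20) {
    e1 <- 10^stats::runif(1, log10(lo), log10(hi))
    e2 <- 10^stats::runif(1, log10(lo), log10(hi))
    hitRows[[length(hitRows) + 1L]] <<- data.frame(
      query_id = c(a, b), subject_id = c(b, a), evalue = c(e1, e2),
      bitscore = stats::runif(2, 200, 500), stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(pairs)))
    addHits(pairs$gene_a[i], pairs$gene_b[i])
  if (config$decoyHits > 0L) {
    allIds <- geneTab$gene_id
    for (k in seq_len(config$decoyHits)) {
      ab <- sample(allIds, 2L)
      addHits(ab[1], ab[2], lo = 1e-9, hi = 1e-2)
    }
  }
  hits <- do.call(rbind, hitRows)
  if (is.null(hits))
    hits <- data.frame(query_id = character(0), subject_id = character(0),
                       evalue = numeric(0), bitscore = numeric(0))
  hits <- hits[order(hits$query_id, hits$evalue, -hits$bitscore), ,
               drop = FALSE]
  rownames(hits) <- NULL

  planted <- unique(c(pairs$gene_a, pairs$gene_b))
  truth <- list(pairs = pairs,
                singletons = sort(setdiff(geneTab$gene_id, planted)),
                origins = geneOrigins(pairs))
  list(annotation = annotation, anchors = anchors, hits = hits,
       truth = truth)
}

#' Simulate an expression matrix with controlled pair correlations
#'
#' Unpaired genes get i.i.d. standard-normal profiles. For each pair with
#' target correlation r, the second profile is r z + sqrt(1 - r^2) e with
#' z the first profile and e fresh noise, so the population correlation
#' equals the target (and the sample correlation is exactly 1 when
#' r = 1).
#'
#' @param gene_ids all gene ids (matrix rows).
#' @param pairs data.frame with gene_a, gene_b and either a
#'   \code{target_r} column or a \code{mode} column resolved through
#'   \code{config$targetR}.
#' @param config a \code{\link{simulationConfig}}.
#' @return genes x samples numeric matrix, plus attribute
#'   \code{"target_r"} (per-pair targets, same order as \code{pairs}).
#' @export
simulateExpression <- function(gene_ids, pairs, config = simulationConfig()) {
  set.seed(config$seed + 1L)
  S <- config$samples
  target <- if ("target_r" %in% names(pairs)) pairs$target_r
  else unname(config$targetR[pairs$mode])
  if (anyNA(target) || any(abs(target) > 1))
    stop("target r must be defined and within [-1, 1] for every pair")
  m <- matrix(stats::rnorm(length(gene_ids) * S), nrow = length(gene_ids),
              dimnames = list(gene_ids, paste0("chip", seq_len(S))))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$gene_a[i]
    b <- pairs$gene_b[i]
    r <- target[i]
    m[b, ] <- r * m[a, ] + sqrt(1 - r^2) * stats::rnorm(S)
  }
  attr(m, "target_r") <- target
  m
}

.senseCodons <- function() {
  gc <- geneticCode()
  names(gc)[gc != "*"]
}

.fourfoldCodons <- function() {
  cods <- .senseCodons()
  keep <- vapply(cods, function(cd) {
    third <- substr(cd, 3, 3)
    alts <- vapply(setdiff(.NUC, third), function(nt) {
      alt <- cd
      substr(alt, 3, 3) <- nt
      codonAA(alt) == codonAA(cd)
    }, logical(1))
    all(alts)
  }, logical(1))
  cods[keep]
}

#' Simulate coding and promoter sequences with controlled divergence
#'
#' For each pair an ancestral sequence of \code{nCodons} sense codons is
#' drawn; the derived copy receives synonymous changes at third positions
#' of 4-fold degenerate codons (hitting a target synonymous p-distance)
#' and nonsynonymous, non-stop changes at first/second positions of
#' disjoint codons (target nonsynonymous p-distance). Promoter pairs diverge by
#' per-site substitution with the pair's target probability. Targets are
#' drawn uniformly from the config ranges unless the pairs carry
#' \code{target_ks} / \code{target_ka} / \code{target_promoter_p}
#' columns.
#'
#' @param pairs data.frame with gene_a, gene_b (one sequence pair per
#'   row).
#' @param config a \code{\link{simulationConfig}}.
#' @return list of data plus sequences: \code{cds_a}, \code{cds_b},
#'   \code{protein_a}, \code{protein_b}, \code{promoter_a},
#'   \code{promoter_b} (character vectors, one per pair) and
#'   \code{targets} (data.frame of drawn targets and realised mutation
#'   counts).
#' @export
simulateSequences <- function(pairs, config = simulationConfig()) {
  set.seed(config$seed + 2L)
  nP <- nrow(pairs)
  sense <- .senseCodons()
  ff <- .fourfoldCodons()
  kToP <- function(K) 0.75 * (1 - exp(-4 * K / 3))
  ks <- if ("target_ks" %in% names(pairs)) pairs$target_ks
  else stats::runif(nP, config$targetKsRange[1], config$targetKsRange[2])
  ka <- if ("target_ka" %in% names(pairs)) pairs$target_ka
  else stats::runif(nP, config$targetKaRange[1], config$targetKaRange[2])
  pp <- if ("target_promoter_p" %in% names(pairs)) pairs$target_promoter_p
  else stats::runif(nP, config$promoterPRange[1], config$promoterPRange[2])

  cdsA <- cdsB <- protA <- protB <- promA <- promB <- character(nP)
  nSynV <- nNonV <- integer(nP)
  for (i in seq_len(nP)) {
    cods <- sample(sense, config$nCodons, replace = TRUE)
    sAnc <- sum(synonymousSites(cods))
    nAnc <- 3 * length(cods) - sAnc
    pS <- kToP(ks[i])
    pN <- kToP(ka[i])
    if (pS >= 0.75 || pN >= 0.75) stop("unreachable target p")
    nSyn <- round(pS * sAnc)
    nNon <- round(pN * nAnc)
    ffIdx <- which(cods %in% ff)
    if (length(ffIdx) < nSyn)
      stop("unreachable synonymous target: too few 4-fold codons")
    synIdx <- sample(ffIdx, nSyn)
    mut <- cods
    for (j in synIdx) {
      alt <- mut[j]
      substr(alt, 3, 3) <- sample(setdiff(.NUC, substr(alt, 3, 3)), 1L)
      mut[j] <- alt
    }
    nonPool <- setdiff(seq_along(cods), synIdx)
    sites <- expand.grid(codon = nonPool, pos = 1:2)
    sites <- sites[sample.int(nrow(sites)), , drop = FALSE]
    nDone <- 0L
    for (s in seq_len(nrow(sites))) {
      if (nDone >= nNon) break
      j <- sites$codon[s]
      pos <- sites$pos[s]
      cand <- setdiff(.NUC, substr(mut[j], pos, pos))
      alts <- vapply(cand, function(nt) {
        alt <- mut[j]
        substr(alt, pos, pos) <- nt
        alt
      }, character(1))
      alts <- alts[!isStopCodon(alts) & codonAA(alts) != codonAA(mut[j])]
      if (!length(alts)) next
      mut[j] <- alts[sample.int(length(alts), 1L)]
      nDone <- nDone + 1L
    }
    if (nDone < nNon) stop("unreachable nonsynonymous target")
    cdsA[i] <- paste(cods, collapse = "")
    cdsB[i] <- paste(mut, collapse = "")
    protA[i] <- paste(codonAA(cods), collapse = "")
    protB[i] <- paste(codonAA(mut), collapse = "")
    nSynV[i] <- nSyn
    nNonV[i] <- nDone

    L <- config$promoterLength
    anc <- sample(.NUC, L, replace = TRUE)
    der <- anc
    flip <- which(stats::runif(L) < pp[i])
    for (j in flip) der[j] <- sample(setdiff(.NUC, anc[j]), 1L)
    promA[i] <- paste(anc, collapse = "")
    promB[i] <- paste(der, collapse = "")
  }
  list(cds_a = cdsA, cds_b = cdsB, protein_a = protA, protein_b = protB,
       promoter_a = promA, promoter_b = promB,
       targets = data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                            target_ks = ks, target_ka = ka,
                            target_promoter_p = pp,
                            n_synonymous = nSynV, n_nonsynonymous = nNonV))
}

#' Simulate a methylation probe track
#'
#' Probes at regular spacing along each chromosome, methylated
#' independently at the configured Bernoulli rate.
#'
#' @param annotation a \code{GenomeAnnotation} (chromosome lengths must be
#'   set).
#' @param config a \code{\link{simulationConfig}}.
#' @return data.frame (chromosome, position, methylated).
#' @export
simulateMethylation <- function(annotation, config = simulationConfig()) {
  set.seed(config$seed + 3L)
  cl <- chromLengths(annotation)
  if (!length(cl)) stop("annotation has no chromosome lengths")
  rows <- lapply(names(cl), function(ch) {
    pos <- seq(1L, as.integer(cl[[ch]]), by = config$probeSpacing)
    data.frame(chromosome = ch, position = pos,
               methylated = stats::runif(length(pos)) <
                 config$methylationRate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate gene families with planted mode enrichment
#'
#' Each family draws \code{familyBias} of its members from one planted
#' duplication mode (cycled over modes) and the rest uniformly, so family
#'/ mode enrichment tests have known positives.
#'
#' @param origins named character vector of per-gene origins.
#' @param config a \code{\link{simulationConfig}}.
#' @return list: \code{families} (named list gene_id -> family id, as
#'   \code{\link{readTermAnnotation}} returns) and \code{plantedMode}
#'   (named character vector per family).
#' @export
simulateFamilies <- function(origins, config = simulationConfig()) {
  set.seed(config$seed + 4L)
  modes <- intersect(DUPLICATION_MODES, unique(origins))
  genesByMode <- split(names(origins), origins)
  fam <- list()
  planted <- character(0)
  for (f in seq_len(config$familyCount)) {
    mo <- modes[((f - 1L) %% length(modes)) + 1L]
    nBias <- round(config$familyBias * config$familySize)
    pool <- setdiff(genesByMode[[mo]], names(fam))
    rest <- setdiff(names(origins), c(names(fam), pool))
    if (length(pool) < nBias ||
        length(rest) < config$familySize - nBias) next
    members <- c(sample(pool, nBias),
                 sample(rest, config$familySize - nBias))
    fid <- sprintf("FAM%02d", f)
    for (g in members) fam[[g]] <- fid
    planted[fid] <- mo
  }
  list(families = fam, plantedMode = planted)
}

#' Simulate a two-species ortholog expression corpus
#'
#' Species 1 profiles follow a latent-factor model (so co-expression has
#' real structure); species 2 ortholog profiles equal species 1 profiles
#' plus class-dependent perturbation noise with standard deviations
#' ordered S-S < S-D < D-D, so true expression conservation decreases
#' (and divergence d increases) from singleton-singleton to
#' duplicate-duplicate ortholog pairs. With zero perturbation the two
#' species' co-expression matrices are identical and every EC is 1.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list: \code{A}, \code{B} (k x n matrices), \code{classes}
#'   (data.frame class_a, class_b per ortholog pair), \code{class}
#'   (S-S/S-D/D-D per pair).
#' @export
simulateTwoSpecies <- function(config = simulationConfig()) {
  set.seed(config$seed + 5L)
  nPer <- config$orthologsPerClass
  k <- 3L * nPer
  n <- config$ecSamples
  cls <- rep(c("S-S", "S-D", "D-D"), each = nPer)
  L <- matrix(stats::rnorm(k * config$ecFactors), k)
  FF <- matrix(stats::rnorm(config$ecFactors * n), config$ecFactors)
  A <- L %*% FF + config$ecNoiseSd * matrix(stats::rnorm(k * n), k)
  sig <- config$ecSigma[cls]
  B <- A + matrix(stats::rnorm(k * n), k) * sig
  rownames(A) <- paste0("orthA_", seq_len(k))
  rownames(B) <- paste0("orthB_", seq_len(k))
  colnames(A) <- paste0("sA", seq_len(n))
  colnames(B) <- paste0("sB", seq_len(n))
  classes <- data.frame(
    class_a = ifelse(cls == "D-D", "duplicate",
                     ifelse(cls == "S-D", "singleton", "singleton")),
    class_b = ifelse(cls == "S-S", "singleton", "duplicate"),
    stringsAsFactors = FALSE)
  list(A = A, B = B, classes = classes, class = cls)
}

#' Write a simulated corpus to disk
#'
#' Emits the files the readers consume: GFF3 annotation, anchor and
#' ortholog-anchor TSVs, tabular homology hits, an expression TSV, and
#' the ground truth as JSON, so the whole pipeline can be exercised from
#' files alone.
#'
#' @param sim result of \code{\link{simulateGenome}}.
#' @param dir output directory (created if needed).
#' @param expression optional matrix from \code{\link{simulateExpression}}.
#' @return the directory, invisibly.
#' @export
writeCorpus <- function(sim, dir, expression = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGenomeGFF(sim$annotation, file.path(dir, "annotation.gff3"))
  writeAnchors(sim$anchors, file.path(dir, "anchors.tsv"),
               orthologPath = file.path(dir, "ortholog_anchors.tsv"))
  blast <- sim$hits
  out <- data.frame(blast$query_id, blast$subject_id, 100, 100, 0, 0,
                    1, 100, 1, 100,
                    format(blast$evalue, scientific = TRUE),
                    blast$bitscore)
  utils::write.table(out, file.path(dir, "hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(expression))
    writeExpressionMatrix(expression, file.path(dir, "expression.tsv"))
  jsonlite::write_json(
    list(pairs = sim$truth$pairs,
         singletons = sim$truth$singletons,
         origins = as.list(sim$truth$origins)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
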