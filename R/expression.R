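#' Read a gene x sample expression matrix
#'
#' TSV with a header of sample ids and gene ids in the first column. Rows
#' with missing values are dropped with a warning; at least 3 samples are
#' required (a correlation over fewer samples is meaningless).
#'
#' @param path TSV path (plain or gzip).
#' @return numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns.
#' @export
readExpressionMatrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  if (ncol(m) < 3L) stop("expression matrix needs >= 3 samples")
  bad <- rowSums(is.na(m)) > 0L
  if (any(bad)) {
    warning(sum(bad), " gene(s) with missing values dropped")
    m <- m[!bad, , drop = FALSE]
  }
  m
}

#' Write an expression matrix to TSV
#' @param m numeric matrix with gene ids as rownames.
#' @param path output path.
#' @export
writeExpressionMatrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pearson correlation of two expression profiles
#'
#' Plain product-moment correlation across samples (all replicate chips
#' retained; no averaging). Constant profiles have no defined correlation
#' and raise an error; callers exclude such genes upstream.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method \code{"pearson"} (default) or \code{"spearman"}; rank
#'   correlation is provided as a robustness alternative and gives very
#'   similar downstream results on well-behaved data.
#' @return correlation in [-1, 1].
#' @export
pearsonR <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("profiles differ in length")
  if (length(x) < 3L) stop("need >= 3 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant expression profile: correlation undefined")
  stats::cor(x, y, method = method)
}

#' Expression divergence of a gene pair
#'
#' d = 1 - r, the complement of the Pearson correlation of the two genes'
#' expression profiles; d is 0 for identical profiles and 2 for perfectly
#' anti-correlated ones. The divergence transform is pluggable for
#' sensitivity analyses.
#'
#' @param r correlation(s) in [-1, 1].
#' @param transform function mapping r to d; default \code{1 - r}.
#' @return divergence value(s) in [0, 2] under the default transform.
#' @export
expressionDivergence <- function(r, transform = function(r) 1 - r) {
  transform(r)
}

#' Null divergence threshold from random gene pairs
#'
#' Samples \code{n_pairs} distinct unordered random gene pairs from the
#' matrix and returns the requested quantile of their correlation values.
#' In the source framework the 95% quantile of r over 10,000 random pairs
#' defines the "diverged expression" criterion (r below the threshold).
#'
#' @param m expression matrix (genes x samples).
#' @param n_pairs number of random pairs (default 10000); if it exceeds the
#'   number of available pairs, all pairs are used with a warning.
#' @param quantile probability for the r quantile (default 0.95).
#' @param seed optional integer seed for reproducibility.
#' @param method correlation method passed to \code{\link{pearsonR}}.
#' @return list with \code{threshold} (the r quantile) and \code{r}
#'   (the sampled correlations).
#' @export
randomPairThreshold <- function(m, n_pairs = 10000L, quantile = 0.95,
                                seed = NULL,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ng <- nrow(m)
  if (ng < 2L) stop("need >= 2 genes")
  if (!is.null(seed)) set.seed(seed)
  total <- ng * (ng - 1) / 2
  if (n_pairs > total) {
    warning("n_pairs exceeds available pairs; using all ", total, " pairs")
    n_pairs <- total
  }
  # sample unordered pair indices without replacement via linear indexing
  k <- sample(total, n_pairs)
  # invert linear index over the strictly-lower triangle: row i > j
  i <- floor((1 + sqrt(8 * (k - 1) + 1)) / 2) + 1
  j <- k - (i - 1) * (i - 2) / 2
  if (method == "spearman") {
    mm <- t(apply(m, 1L, rank))
  } else mm <- m
  zs <- mm - rowMeans(mm)
  sdr <- sqrt(rowSums(zs^2))
  if (any(sdr == 0)) stop("constant expression profile in matrix")
  zs <- zs / sdr
  r <- rowSums(zs[i, , drop = FALSE] * zs[j, , drop = FALSE])
  list(threshold = unname(stats::quantile(r, quantile)), r = r)
}

#' Pair correlations and divergence for a set of duplicate pairs
#'
#' @param pairs data.frame with gene_a, gene_b (extra columns such as
#'   \code{mode} are carried through).
#' @param m expression matrix.
#' @param method correlation method.
#' @return \code{pairs} with columns \code{r} and \code{d} appended; pairs
#'   with a gene absent from the matrix or with a constant profile get
#'   \code{NA} with a warning.
#' @export
pairExpressionStats <- function(pairs, m,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  r <- rep(NA_real_, nrow(pairs))
  ia <- match(pairs$gene_a, rownames(m))
  ib <- match(pairs$gene_b, rownames(m))
  ok <- !is.na(ia) & !is.na(ib)
  sds <- apply(m, 1L, stats::sd)
  const <- ok & (sds[ia] == 0 | sds[ib] == 0)
  if (any(const)) {
    warning(sum(const), " pair(s) with a constant profile excluded")
    ok <- ok & !const
  }
  for (i in which(ok))
    r[i] <- stats::cor(m[ia[i], ], m[ib[i], ], method = method)
  pairs$r <- r
  pairs$d <- expressionDivergence(r)
  pairs
}

#' Proportion of expression-diverged pairs per duplication mode
#'
#' @param pairs data.frame with columns \code{r} and \code{mode}.
#' @param r_threshold divergence criterion: a pair is diverged iff
#'   \code{r < r_threshold}.
#' @return data.frame (mode, n, divergent, proportion); modes with no
#'   valid pair report \code{NA}.
#' @export
divergenceProportion <- function(pairs, r_threshold) {
  modes <- unique(pairs$mode)
  res <- lapply(modes, function(mo) {
    r <- pairs$r[pairs$mode == mo]
    r <- r[!is.na(r)]
    data.frame(mode = mo, n = length(r), divergent = sum(r < r_threshold),
               proportion = if (length(r)) mean(r < r_threshold) else NA_real_)
  })
  do.call(rbind, res)
}

#' Dual conservation in protein sequence and expression
#'
#' A pair is dually conserved when its Ka is below the 25% quartile of Ka
#' over all valid pairs (or a supplied cutoff) and its expression
#' divergence d is below \code{d_threshold}. The expected proportion under
#' independence is the product of the two pooled marginal proportions,
#' against which per-mode observed proportions are compared.
#'
#' @param pairs data.frame with columns \code{mode}, \code{Ka}, \code{d}.
#' @param ka_quartile Ka cutoff; default the 25% quantile of valid Ka.
#' @param d_threshold expression-conservation cutoff on d.
#' @return list with \code{perMode} (data.frame mode, n, proportion),
#'   \code{expected} (independence expectation), \code{ka_quartile}, and
#'   \code{n_excluded} (pairs lacking Ka or d).
#' @export
dualConservation <- function(pairs, ka_quartile = NULL, d_threshold) {
  valid <- !is.na(pairs$Ka) & !is.na(pairs$d)
  n_excluded <- sum(!valid)
  p <- pairs[valid, , drop = FALSE]
  if (is.null(ka_quartile))
    ka_quartile <- unname(stats::quantile(p$Ka, 0.25))
  consK <- p$Ka < ka_quartile
  consD <- p$d < d_threshold
  expected <- mean(consK) * mean(consD)
  perMode <- do.call(rbind, lapply(unique(p$mode), function(mo) {
    sel <- p$mode == mo
    data.frame(mode = mo, n = sum(sel),
               proportion = mean(consK[sel] & consD[sel]))
  }))
  list(perMode = perMode, expected = expected, ka_quartile = ka_quartile,
       n_excluded = n_excluded)
}

#' Mean expression level per gene
#'
#' @param m expression matrix.
#' @param genes optional gene ids (default all).
#' @return named numeric vector of per-gene means over samples.
#' @export
expressionLevel <- function(m, genes = NULL) {
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(m))
    if (length(miss)) stop("gene(s) not in matrix: ",
                           paste(utils::head(miss, 5), collapse = ", "))
    m <- m[genes, , drop = FALSE]
  }
  rowMeans(m)
}

#' Pairwise two-sample t-tests between groups of expression levels
#'
#' @param groups named list of numeric vectors (e.g. mean expression per
#'   origin class), each of size >= 2.
#' @return data.frame (group1, group2, t, p) for every unordered group
#'   pair, two-sided Welch t-tests.
#' @export
compareLevels <- function(groups) {
  stopifnot(length(groups) >= 2L)
  if (any(lengths(groups) < 2L)) stop("each group needs >= 2 values")
  nm <- names(groups)
  combs <- utils::combn(length(groups), 2L)
  res <- apply(combs, 2L, function(ix) {
    tt <- stats::t.test(groups[[ix[1]]], groups[[ix[2]]])
    data.frame(group1 = nm[ix[1]], group2 = nm[ix[2]],
               t = unname(tt$statistic), p = tt$p.value)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
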