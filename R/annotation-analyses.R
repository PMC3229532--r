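#' Read a methylation probe track
#'
#' BED-like TSV with columns (chromosome, position, methylated 0/1).
#' Probes are ordered by position within each chromosome; duplicate
#' positions on a chromosome are an error.
#'
#' @param path TSV path.
#' @return data.frame (chromosome, position, methylated) sorted by
#'   (chromosome, position).
#' @export
readMethylationTrack <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) stop("methylation track needs 3 columns")
  tr <- data.frame(chromosome = as.character(raw[[1]]),
                   position = as.integer(raw[[2]]),
                   methylated = as.integer(raw[[3]]) == 1L,
                   stringsAsFactors = FALSE)
  tr <- tr[order(tr$chromosome, tr$position), , drop = FALSE]
  if (any(duplicated(tr[c("chromosome", "position")])))
    stop("duplicate probe position on a chromosome")
  rownames(tr) <- NULL
  tr
}

#' Promoter methylation call for one gene
#'
#' A gene is methylated in its promoter when two or more probes that are
#' consecutive in the chromosome's probe track both lie inside the
#' promoter region and are both methylated. Fewer than 2 in-region probes
#' gives an unmethylated (FALSE) call, not a missing one.
#'
#' @param region promoter region from \code{\link{promoterRegion}}.
#' @param track probe track from \code{\link{readMethylationTrack}}.
#' @return logical.
#' @export
promoterMethylated <- function(region, track) {
  tr <- track[track$chromosome == region$chromosome, , drop = FALSE]
  if (region$width == 0L || nrow(tr) < 2L) return(FALSE)
  inReg <- tr$position >= region$start & tr$position <= region$end
  # consecutive-in-track adjacency: probes i and i+1 both in the region
  any(inReg[-nrow(tr)] & inReg[-1L] &
      tr$methylated[-nrow(tr)] & tr$methylated[-1L])
}

#' Promoter methylation calls for an annotation
#'
#' @param annotation a \code{GenomeAnnotation}.
#' @param track methylation probe track.
#' @param maxLen promoter length cap in bp.
#' @return named logical vector over all genes.
#' @export
promoterMethylationCalls <- function(annotation, track, maxLen = 1000L) {
  ids <- geneIds(annotation)
  vapply(ids, function(g)
    promoterMethylated(promoterRegion(g, annotation, maxLen), track),
    logical(1))
}

#' Proportion of duplicate pairs with changed promoter methylation
#'
#' @param pairs data.frame with gene_a, gene_b, mode.
#' @param calls named logical vector of promoter methylation calls.
#' @return data.frame (mode, n, changed, proportion, n_excluded); pairs
#'   with a missing call are excluded and counted.
#' @export
methylationChangeProportion <- function(pairs, calls) {
  ca <- calls[pairs$gene_a]
  cb <- calls[pairs$gene_b]
  ok <- !is.na(ca) & !is.na(cb)
  do.call(rbind, lapply(unique(pairs$mode), function(mo) {
    sel <- ok & pairs$mode == mo
    data.frame(mode = mo, n = sum(sel),
               changed = sum(ca[sel] != cb[sel]),
               proportion = if (any(sel)) mean(ca[sel] != cb[sel])
                            else NA_real_,
               n_excluded = sum(!ok & pairs$mode == mo))
  }))
}

#' Proportion of methylated genes per class
#'
#' @param calls named logical vector of promoter methylation calls.
#' @param classes named character vector (e.g. "singleton"/"duplicate" or
#'   an origin mode) over the same genes.
#' @return data.frame (class, n, methylated, proportion).
#' @export
methylatedProportion <- function(calls, classes) {
  genesBoth <- intersect(names(calls), names(classes))
  cl <- classes[genesBoth]
  me <- calls[genesBoth]
  do.call(rbind, lapply(unique(cl), function(k) {
    sel <- cl == k
    data.frame(class = k, n = sum(sel), methylated = sum(me[sel]),
               proportion = mean(me[sel]))
  }))
}

#' Read a two-column gene-to-term annotation
#'
#' @param path TSV with columns (gene_id, term); one row per association.
#' @return named list: term sets per gene.
#' @export
readTermAnnotation <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L) stop("term annotation needs 2 columns")
  split(raw[[2]], raw[[1]])
}

#' Term enrichment by one-sided Fisher's exact test
#'
#' For every term annotated in the universe, tests over-representation of
#' the term in \code{subset} against \code{universe} with a one-sided
#' Fisher exact test on the 2x2 table, then applies Bonferroni correction
#' over the number of terms tested (terms absent from the universe are
#' skipped).
#'
#' @param subset character vector of genes, a subset of \code{universe}.
#' @param universe character vector of genes.
#' @param terms named list mapping gene_id to a character vector of term
#'   ids (see \code{\link{readTermAnnotation}}).
#' @param alpha significance level on the corrected p-value (default
#'   0.05).
#' @return data.frame per term: counts, \code{odds_ratio}, \code{p},
#'   \code{p_corrected}, \code{significant}, sorted by p.
#' @export
fisherEnrichment <- function(subset, universe, terms, alpha = 0.05) {
  if (!all(subset %in% universe)) stop("subset must be within universe")
  universe <- unique(universe)
  subset <- unique(subset)
  termsU <- terms[intersect(names(terms), universe)]
  allTerms <- sort(unique(unlist(termsU, use.names = FALSE)))
  if (!length(allTerms))
    return(data.frame(term = character(0)))
  geneHas <- function(term) names(termsU)[vapply(termsU, function(tt)
    term %in% tt, logical(1))]
  res <- lapply(allTerms, function(term) {
    withTerm <- geneHas(term)
    a <- sum(subset %in% withTerm)               # in subset, has term
    b <- length(subset) - a                      # in subset, no term
    cc <- length(withTerm) - a                   # not in subset, has term
    d <- length(universe) - length(subset) - cc  # neither
    ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2L, byrow = TRUE),
                             alternative = "greater")
    data.frame(term = term, subset_with = a, subset_n = length(subset),
               universe_with = length(withTerm),
               universe_n = length(universe),
               odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  out <- do.call(rbind, res)
  out$p_corrected <- pmin(1, out$p * nrow(out))
  out$significant <- out$p_corrected < alpha
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-family enrichment with duplication modes
#'
#' For each gene family with at least \code{min_family_size} genes
#' ("more than nine genes" at the default of 10) and each duplication
#' mode, tests whether family membership is over-represented among genes
#' of that mode, over the universe of genes with an origin assignment.
#' Bonferroni correction spans all (family, mode) tests performed.
#'
#' @param families named list mapping gene_id to family id(s).
#' @param origins named character vector of per-gene origins from
#'   \code{\link{classifyAll}}.
#' @param alpha significance level (default 0.05).
#' @param min_family_size minimum family size (default 10).
#' @return data.frame per (family, mode): counts, p, p_corrected,
#'   significant.
#' @export
familyModeEnrichment <- function(families, origins, alpha = 0.05,
                                 min_family_size = 10L) {
  universe <- names(origins)
  fams <- split(rep(names(families), lengths(families)),
                unlist(families, use.names = FALSE))
  fams <- lapply(fams, function(g) intersect(unique(g), universe))
  fams <- fams[lengths(fams) >= min_family_size]
  modes <- unique(origins)
  if (!length(fams) || !length(modes))
    return(data.frame(family = character(0)))
  res <- list()
  for (fam in names(fams)) {
    inFam <- universe %in% fams[[fam]]
    for (mo in modes) {
      inMode <- origins == mo
      a <- sum(inFam & inMode)
      ft <- stats::fisher.test(
        matrix(c(a, sum(inFam) - a, sum(inMode) - a,
                 sum(!inFam & !inMode)), 2L, byrow = TRUE),
        alternative = "greater")
      res[[length(res) + 1L]] <- data.frame(
        family = fam, mode = mo, family_n = sum(inFam),
        in_mode = a, mode_n = sum(inMode), p = ft$p.value)
    }
  }
  out <- do.call(rbind, res)
  out$p_corrected <- pmin(1, out$p * nrow(out))
  out$significant <- out$p_corrected < alpha
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
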