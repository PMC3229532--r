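#' Duplication modes
#'
#' The six mechanistic modes plus UNCLASSIFIED, in priority order: a
#' duplicated gene's unique origin is the highest-priority mode among all
#' duplicate pairs it belongs to (WGD > tandem > proximal >
#' retrotransposed > DNA-based transposed > dispersed).
#'
#' @export
DUPLICATION_MODES <- c("WGD", "TANDEM", "PROXIMAL", "RETROTRANSPOSED",
                       "DNA_TRANSPOSED", "DISPERSED", "UNCLASSIFIED")

#' Classifier configuration
#'
#' @param evalue_max maximum e-value for a protein hit to qualify a
#'   candidate duplicate pair. Default 1e-10, the conventional BLASTP
#'   stringency in the duplicate-gene literature; exposed because studies
#'   differ.
#' @param top_n_hits number of best non-self hits retained per query
#'   (default 5), so a gene may enter up to this many duplication
#'   relationships.
#' @param proximal_window maximum gene-rank distance (inclusive) for a
#'   proximal call, i.e. "within 20 annotated genes" (default 20);
#'   adjacency (distance 1) is tandem.
#' @param retro_min_parent_exons minimum exon count of the parental copy
#'   for a retrotransposition call ("more than two exons" = at least 3).
#' @return a list of class \code{ClassifierConfig}.
#' @export
classifierConfig <- function(evalue_max = 1e-10, top_n_hits = 5L,
                             proximal_window = 20L,
                             retro_min_parent_exons = 3L) {
  stopifnot(top_n_hits >= 1L, proximal_window >= 2L,
            evalue_max >= 0, retro_min_parent_exons >= 1L)
  structure(list(evalue_max = evalue_max,
                 top_n_hits = as.integer(top_n_hits),
                 proximal_window = as.integer(proximal_window),
                 retro_min_parent_exons = as.integer(retro_min_parent_exons)),
            class = "ClassifierConfig")
}

#' Build the candidate duplicate-pair population and the singleton set
#'
#' For each query, its best \code{top_n_hits} non-self hits with
#' \code{evalue <= evalue_max} contribute unordered gene pairs; the pair
#' population is the union over both hit directions, deduplicated. Genes
#' of the universe with no qualifying hit in either direction are deemed
#' singletons.
#'
#' @param hits data.frame from \code{\link{readBlastTab}} (sorted per
#'   query by e-value).
#' @param config a \code{\link{classifierConfig}}.
#' @param universe optional character vector of gene ids over which
#'   singletons are defined; defaults to all genes appearing in \code{hits}.
#' @return list with \code{pairs} (data.frame gene_a, gene_b) and
#'   \code{singletons} (character vector).
#' @export
buildCandidatePairs <- function(hits, config = classifierConfig(),
                                universe = NULL) {
  if (is.null(universe))
    universe <- unique(c(hits$query_id, hits$subject_id))
  keep <- hits[hits$evalue <= config$evalue_max, , drop = FALSE]
  if (nrow(keep)) {
    keep <- keep[order(keep$query_id, keep$evalue, -keep$bitscore), ,
                 drop = FALSE]
    idx <- unlist(lapply(split(seq_len(nrow(keep)), keep$query_id),
                         utils::head, n = config$top_n_hits),
                  use.names = FALSE)
    keep <- keep[sort(idx), , drop = FALSE]
  }
  if (nrow(keep)) {
    a <- pmin(keep$query_id, keep$subject_id)
    b <- pmax(keep$query_id, keep$subject_id)
    dup <- duplicated(pairKey(a, b))
    pairs <- data.frame(gene_a = a[!dup], gene_b = b[!dup],
                        stringsAsFactors = FALSE)
    pairs <- pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
    rownames(pairs) <- NULL
  } else {
    pairs <- data.frame(gene_a = character(0), gene_b = character(0))
  }
  linked <- unique(c(pairs$gene_a, pairs$gene_b))
  list(pairs = pairs, singletons = sort(setdiff(universe, linked)))
}

#' Tandem / proximal test for one gene pair
#'
#' Tandem duplicates are adjacent in gene order on the same chromosome
#' (rank distance 1); proximal duplicates are non-tandem genes within
#' \code{proximal_window} annotated genes of each other (rank distance in
#' [2, window], boundary inclusive). Rank distances are measured over all
#' annotated genes of the chromosome.
#'
#' @param gene_a,gene_b gene ids.
#' @param annotation a \code{GenomeAnnotation}.
#' @param config a \code{\link{classifierConfig}}.
#' @return \code{"TANDEM"}, \code{"PROXIMAL"} or \code{NA_character_}.
#' @export
classifyTandemProximal <- function(gene_a, gene_b, annotation,
                                   config = classifierConfig()) {
  g <- genes(annotation)
  ia <- match(gene_a, g$gene_id)
  ib <- match(gene_b, g$gene_id)
  if (is.na(ia) || is.na(ib))
    stop("unknown gene id: ", if (is.na(ia)) gene_a else gene_b)
  if (g$chromosome[ia] != g$chromosome[ib]) return(NA_character_)
  dr <- abs(g$rank[ia] - g$rank[ib])
  if (dr == 1L) "TANDEM"
  else if (dr >= 2L && dr <= config$proximal_window) "PROXIMAL"
  else NA_character_
}

#' Transposed-duplication test for one gene pair
#'
#' A distant single-gene transposition requires exactly one copy at an
#' ancestral locus (the parental copy) and the other at a non-ancestral
#' locus. The pair is RETROTRANSPOSED when the parent has at least
#' \code{retro_min_parent_exons} exons and the transposed copy is
#' intronless; UNCLASSIFIED when both copies are single-exon; otherwise
#' DNA_TRANSPOSED. Pairs with zero or two ancestral members are not
#' transposed and fall through to dispersed.
#'
#' @param gene_a,gene_b gene ids.
#' @param ancestral character vector of ancestral gene ids.
#' @param annotation a \code{GenomeAnnotation}.
#' @param config a \code{\link{classifierConfig}}.
#' @return list(mode, parental_copy); mode is \code{NA_character_} when
#'   the pair is not a transposition candidate.
#' @export
classifyTransposed <- function(gene_a, gene_b, ancestral, annotation,
                               config = classifierConfig()) {
  g <- genes(annotation)
  excount <- structure(g$exon_count, names = g$gene_id)
  ancA <- gene_a %in% ancestral
  ancB <- gene_b %in% ancestral
  if (ancA == ancB)
    return(list(mode = NA_character_, parental_copy = NA_character_))
  parent <- if (ancA) gene_a else gene_b
  child <- if (ancA) gene_b else gene_a
  pe <- excount[[parent]]
  ce <- excount[[child]]
  mode <- if (pe == 1L && ce == 1L) "UNCLASSIFIED"
  else if (pe >= config$retro_min_parent_exons && ce == 1L) "RETROTRANSPOSED"
  else "DNA_TRANSPOSED"
  list(mode = mode, parental_copy = parent)
}

#' Classify every duplicate pair and assign per-gene origins
#'
#' Implements the full classification procedure: the candidate population
#' is built from qualifying protein hits; syntenic anchor pairs are
#' labelled WGD (anchors are authoritative: an anchor pair absent from the
#' candidate population is kept as WGD); the remaining candidates are
#' tested tandem, then proximal, then transposed; the remainder is
#' dispersed. Each duplicated gene then receives a unique origin, the
#' highest-priority mode among its pairs, with priority
#' WGD > tandem > proximal > retrotransposed > DNA-based transposed >
#' dispersed (> unclassified).
#'
#' @param annotation a \code{GenomeAnnotation}.
#' @param hits data.frame from \code{\link{readBlastTab}}.
#' @param anchors an \code{AnchorCollection}.
#' @param config a \code{\link{classifierConfig}}.
#' @return list with \code{pairs} (data.frame gene_a, gene_b, mode,
#'   parental_copy, event, sorted by (gene_a, gene_b)), \code{origins}
#'   (named character vector, one entry per duplicated gene) and
#'   \code{singletons} (character vector).
#' @export
classifyAll <- function(annotation, hits, anchors,
                        config = classifierConfig()) {
  known <- geneIds(annotation)
  unknown <- unique(c(hits$query_id, hits$subject_id))
  unknown <- setdiff(unknown, known)
  if (length(unknown)) {
    warning(length(unknown),
            " gene(s) in hits absent from annotation; excluded")
    hits <- hits[!(hits$query_id %in% unknown) &
                 !(hits$subject_id %in% unknown), , drop = FALSE]
  }
  cand <- buildCandidatePairs(hits, config, universe = known)
  anc <- anchorPairs(anchors)
  ancKey <- pairKey(anc$gene_a, anc$gene_b)
  candKey <- pairKey(cand$pairs$gene_a, cand$pairs$gene_b)

  extra <- which(!(ancKey %in% candKey))
  if (length(extra))
    message(length(extra),
            " anchor pair(s) not in the candidate population; kept as WGD")

  ancestral <- ancestralIds(anchors)
  rows <- list()

  # anchors first: authoritative WGD calls
  if (nrow(anc))
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = anc$gene_a, gene_b = anc$gene_b, mode = "WGD",
      parental_copy = NA_character_, event = anc$event,
      stringsAsFactors = FALSE)

  rest <- cand$pairs[!(candKey %in% ancKey), , drop = FALSE]
  if (nrow(rest)) {
    mode <- character(nrow(rest))
    parental <- rep(NA_character_, nrow(rest))
    for (i in seq_len(nrow(rest))) {
      tp <- classifyTandemProximal(rest$gene_a[i], rest$gene_b[i],
                                   annotation, config)
      if (!is.na(tp)) { mode[i] <- tp; next }
      tr <- classifyTransposed(rest$gene_a[i], rest$gene_b[i], ancestral,
                               annotation, config)
      if (!is.na(tr$mode)) {
        mode[i] <- tr$mode
        parental[i] <- tr$parental_copy
      } else mode[i] <- "DISPERSED"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = rest$gene_a, gene_b = rest$gene_b, mode = mode,
      parental_copy = parental, event = NA_character_,
      stringsAsFactors = FALSE)
  }

  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(0), gene_b = character(0),
               mode = character(0), parental_copy = character(0),
               event = character(0))
  pairs <- pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
  rownames(pairs) <- NULL

  origins <- geneOrigins(pairs)
  list(pairs = pairs, origins = origins, singletons = cand$singletons)
}

#' Unique per-gene origin by mode priority
#'
#' @param pairs data.frame with columns gene_a, gene_b, mode.
#' @return named character vector: for every gene occurring in a pair, the
#'   highest-priority mode among its pairs.
#' @export
geneOrigins <- function(pairs) {
  if (!nrow(pairs)) return(structure(character(0), names = character(0)))
  prio <- match(c(pairs$mode, pairs$mode), DUPLICATION_MODES)
  gene <- c(pairs$gene_a, pairs$gene_b)
  best <- tapply(prio, gene, min)
  structure(DUPLICATION_MODES[as.integer(best)], names = names(best))
}

#' Write classified pairs / origins to TSV
#'
#' @param result the list returned by \code{\link{classifyAll}}.
#' @param pairsPath output TSV for pair labels (with header).
#' @param originsPath optional output TSV for per-gene origins.
#' @export
writeClassification <- function(result, pairsPath, originsPath = NULL) {
  utils::write.table(result$pairs, pairsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(originsPath))
    utils::write.table(
      data.frame(gene_id = names(result$origins), origin = result$origins),
      originsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(pairsPath)
}
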