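#' Read a GFF3 genome annotation
#'
#' Parses gene and exon features from a GFF3 file (plain or gzip) into a
#' \code{\link{GenomeAnnotation}}. Exon features are attributed to genes by
#' following \code{Parent} chains (exon -> mRNA -> gene or exon -> gene).
#' Genes are ranked per chromosome by start coordinate, with ties broken by
#' (start, end, gene_id); the rank is the 0-based position in that order.
#'
#' @param path path to a GFF3 file; \code{##sequence-region} pragmas, when
#'   present, populate the chromosome lengths.
#' @return a \code{GenomeAnnotation}.
#' @details A gene with no attributable exon feature is given
#'   \code{exon_count = 1} with a warning. Structurally malformed feature
#'   lines (not 9 tab-separated fields, or non-numeric coordinates) raise
#'   an error naming the offending line number.
#' @export
readGenomeGFF <- function(path) {
  lines <- readLines(path)
  seqlens <- numeric(0)
  for (ln in grep("^##sequence-region", lines, value = TRUE)) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) >= 4) seqlens[f[2]] <- as.numeric(f[4])
  }
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      stop("malformed GFF3 line ", i, ": expected 9 fields, got ", length(f))
    if (is.na(suppressWarnings(as.numeric(f[4]))) ||
        is.na(suppressWarnings(as.numeric(f[5]))))
      stop("malformed GFF3 line ", i, ": non-numeric coordinates")
  }
  gff <- rtracklayer::readGFF(path,
                              columns = c("seqid", "type", "start", "end",
                                          "strand"),
                              tags = c("ID", "Parent"))
  gff <- as.data.frame(gff)
  gff$Parent <- vapply(gff$Parent, function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))

  isGene <- gff$type == "gene"
  if (!any(isGene)) stop("no gene features in ", path)
  gid <- as.character(gff$ID[isGene])
  if (anyNA(gid) || any(!nzchar(gid)))
    stop("gene feature without ID attribute in ", path)

  # resolve each feature's owning gene through at most two Parent hops
  owner <- structure(gid, names = gid)
  parentOf <- structure(gff$Parent, names = as.character(gff$ID))
  parentOf <- parentOf[!is.na(names(parentOf)) & nzchar(names(parentOf))]
  resolveGene <- function(p) {
    for (hop in 1:3) {
      if (is.na(p)) return(NA_character_)
      if (p %in% names(owner)) return(owner[[p]])
      p <- if (p %in% names(parentOf)) parentOf[[p]] else NA_character_
    }
    NA_character_
  }
  exParent <- gff$Parent[gff$type == "exon"]
  exGene <- vapply(exParent, resolveGene, character(1))
  exCount <- table(factor(exGene[!is.na(exGene)], levels = gid))
  exon_count <- as.integer(exCount)
  if (any(exon_count == 0L)) {
    warning(sum(exon_count == 0L),
            " gene(s) with no exon records; exon_count set to 1")
    exon_count[exon_count == 0L] <- 1L
  }

  makeGenomeAnnotation(data.frame(
    gene_id = gid,
    chromosome = as.character(gff$seqid[isGene]),
    start = as.integer(gff$start[isGene]),
    end = as.integer(gff$end[isGene]),
    strand = as.character(gff$strand[isGene]),
    exon_count = exon_count,
    stringsAsFactors = FALSE
  ), chromLengths = seqlens)
}

#' Build a GenomeAnnotation from a gene table
#'
#' Computes per-chromosome ranks (0-based order by start, ties broken by
#' end then gene_id) and validates the object.
#'
#' @param genes data.frame with columns gene_id, chromosome, start, end,
#'   strand, exon_count.
#' @param chromLengths optional named numeric vector of chromosome lengths.
#' @return a \code{GenomeAnnotation}.
#' @export
makeGenomeAnnotation <- function(genes, chromLengths = numeric(0)) {
  stopifnot(is.data.frame(genes))
  genes$rank <- NA_integer_
  for (chr in unique(genes$chromosome)) {
    i <- which(genes$chromosome == chr)
    o <- order(genes$start[i], genes$end[i], genes$gene_id[i])
    genes$rank[i[o]] <- seq_along(i) - 1L
  }
  rownames(genes) <- NULL
  new("GenomeAnnotation", genes = genes, chromLengths = chromLengths)
}

#' Write a GenomeAnnotation to GFF3
#'
#' Emits one \code{gene} feature per gene plus \code{exon_count} exon
#' features per gene (the gene span partitioned into that many blocks), so
#' that \code{readGenomeGFF} round-trips the annotation exactly.
#'
#' @param annotation a \code{GenomeAnnotation}
#' @param path output file path
#' @export
writeGenomeGFF <- function(annotation, path) {
  g <- genes(annotation)
  out <- c("##gff-version 3")
  cl <- chromLengths(annotation)
  for (chr in names(cl))
    out <- c(out, sprintf("##sequence-region %s 1 %d", chr, as.integer(cl[chr])))
  lines <- character(0)
  for (i in seq_len(nrow(g))) {
    lines <- c(lines, sprintf(
      "%s\tdupModes\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      g$chromosome[i], g$start[i], g$end[i], g$strand[i], g$gene_id[i]))
    k <- g$exon_count[i]
    width <- g$end[i] - g$start[i] + 1L
    if (width < 2L * k - 1L)
      stop("gene ", g$gene_id[i], " too short for ", k, " exons")
    bounds <- round(seq(g$start[i], g$end[i] + 1L, length.out = k + 1L))
    for (j in seq_len(k)) {
      lines <- c(lines, sprintf(
        "%s\tdupModes\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
        g$chromosome[i], bounds[j], bounds[j + 1L] - 1L, g$strand[i],
        g$gene_id[i], j, g$gene_id[i]))
    }
  }
  writeLines(c(out, lines), path)
  invisible(path)
}

#' Read tabular protein homology hits (BLAST outfmt 6)
#'
#' Reads 12-column tabular hits, drops self-hits, and sorts hits per query
#' by ascending e-value then descending bit score. Columns other than
#' query, subject, e-value and bit score are ignored. All hits are kept at
#' read time; truncation to the top hits per query is the classifier's job.
#'
#' @param path path to a tabular hit file (plain or gzip).
#' @return data.frame with columns \code{query_id}, \code{subject_id},
#'   \code{evalue}, \code{bitscore}.
#' @export
readBlastTab <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character", fill = FALSE)
  if (ncol(raw) < 12L)
    stop("expected >= 12 tab-separated columns (outfmt 6), got ", ncol(raw))
  ev <- suppressWarnings(as.numeric(raw[[11]]))
  if (anyNA(ev))
    stop("non-numeric evalue at row ", which(is.na(ev))[1])
  bs <- suppressWarnings(as.numeric(raw[[12]]))
  if (anyNA(bs))
    stop("non-numeric bitscore at row ", which(is.na(bs))[1])
  hits <- data.frame(query_id = raw[[1]], subject_id = raw[[2]],
                     evalue = ev, bitscore = bs, stringsAsFactors = FALSE)
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  hits <- hits[order(hits$query_id, hits$evalue, -hits$bitscore), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Read syntenic anchor pairs
#'
#' Reads within-species anchor pairs as a headerless TSV with columns
#' (gene_a, gene_b, block_id[, event]) and optionally cross-species
#' ortholog anchors as a TSV with columns (gene_a, gene_b). Anchor pairs
#' are stored unordered and deduplicated. The ancestral gene set derives
#' from both tables (see \code{\link{ancestralIds}}).
#'
#' @param path anchor-pair TSV (may be empty).
#' @param orthologPath optional ortholog anchor TSV.
#' @param annotation optional \code{GenomeAnnotation}; when supplied, anchor
#'   genes absent from it are handled per \code{onMissing}.
#' @param onMissing \code{"warn"} (keep the pair, default) or \code{"fail"}.
#' @return an \code{AnchorCollection}.
#' @export
readAnchors <- function(path, orthologPath = NULL, annotation = NULL,
                        onMissing = c("warn", "fail")) {
  onMissing <- match.arg(onMissing)
  readTsv <- function(p) {
    first <- tryCatch(readLines(p, n = 1L), error = function(e) character(0))
    if (!length(first) || !nzchar(first[1])) return(NULL)
    utils::read.table(p, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, colClasses = "character")
  }
  raw <- readTsv(path)
  anchors <- if (is.null(raw)) {
    data.frame(gene_a = character(0), gene_b = character(0),
               block_id = character(0), event = character(0))
  } else {
    if (ncol(raw) < 3L) stop("anchor file needs >= 3 columns")
    data.frame(
      gene_a = pmin(raw[[1]], raw[[2]]),
      gene_b = pmax(raw[[1]], raw[[2]]),
      block_id = raw[[3]],
      event = if (ncol(raw) >= 4L)
        ifelse(nzchar(raw[[4]]), raw[[4]], NA_character_)
      else NA_character_,
      stringsAsFactors = FALSE)
  }
  anchors <- anchors[!duplicated(pairKey(anchors$gene_a, anchors$gene_b)), ,
                     drop = FALSE]
  rownames(anchors) <- NULL

  orth <- data.frame(gene_a = character(0), gene_b = character(0))
  if (!is.null(orthologPath)) {
    rawO <- readTsv(orthologPath)
    if (!is.null(rawO)) {
      orth <- data.frame(gene_a = rawO[[1]], gene_b = rawO[[2]],
                         stringsAsFactors = FALSE)
      orth <- orth[!duplicated(paste(orth$gene_a, orth$gene_b)), ,
                   drop = FALSE]
      rownames(orth) <- NULL
    }
  }

  if (!is.null(annotation)) {
    known <- geneIds(annotation)
    miss <- setdiff(c(anchors$gene_a, anchors$gene_b), known)
    if (length(miss)) {
      msg <- paste0(length(miss), " anchor gene(s) absent from annotation: ",
                    paste(utils::head(miss, 5), collapse = ", "))
      if (onMissing == "fail") stop(msg) else warning(msg)
    }
  }
  new("AnchorCollection", anchors = anchors, orthologs = orth)
}

#' Write anchor pairs to TSV
#'
#' @param anchors an \code{AnchorCollection}
#' @param path anchor-pair output TSV
#' @param orthologPath optional output TSV for ortholog anchors
#' @export
writeAnchors <- function(anchors, path, orthologPath = NULL) {
  a <- anchorPairs(anchors)
  a$event[is.na(a$event)] <- ""
  utils::write.table(a, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(orthologPath))
    utils::write.table(orthologAnchors(anchors), orthologPath, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
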