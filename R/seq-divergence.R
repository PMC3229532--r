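## Codon machinery for the Nei-Gojobori (1986) unweighted-pathway method.
## The standard genetic code comes from Biostrings; everything downstream
## of it (site fractions, pathway enumeration) is computed here.

.codonEnv <- new.env(parent = emptyenv())

geneticCode <- function() {
  if (is.null(.codonEnv$gc)) .codonEnv$gc <- Biostrings::GENETIC_CODE
  .codonEnv$gc
}

.NUC <- c("A", "C", "G", "T")

codonAA <- function(codon) {
  gc <- geneticCode()
  unname(gc[codon])
}

isStopCodon <- function(codon) codonAA(codon) == "*"

# Synonymous site count of one codon: over the 3 positions, the fraction
# of the 3 possible single-nucleotide changes that preserve the amino
# acid. Changes creating a stop codon count as nonsynonymous (they stay
# in the denominator). Stop codons themselves are never counted.
synonymousSites <- function(codon) {
  if (is.null(.codonEnv$syn)) {
    gc <- geneticCode()
    syn <- numeric(length(gc))
    names(syn) <- names(gc)
    for (cd in names(gc)) {
      if (gc[[cd]] == "*") { syn[cd] <- NA_real_; next }
      s <- 0
      for (pos in 1:3) {
        for (nt in setdiff(.NUC, substr(cd, pos, pos))) {
          alt <- cd
          substr(alt, pos, pos) <- nt
          if (gc[[alt]] == gc[[cd]]) s <- s + 1 / 3
        }
      }
      syn[cd] <- s
    }
    .codonEnv$syn <- syn
  }
  .codonEnv$syn[codon]
}

# Average synonymous / nonsynonymous difference counts between two
# codons: all orderings of the differing positions are enumerated as
# mutational pathways; pathways passing through a stop codon are
# discarded; remaining pathways are averaged. NULL when no pathway is
# stop-free (the codon pair is then skipped entirely).
codonPairDifferences <- function(c1, c2) {
  diffPos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(diffPos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- if (nd == 1L) list(diffPos)
  else if (nd == 2L) list(diffPos, rev(diffPos))
  else {
    p <- list()
    for (i in 1:3) for (j in setdiff(1:3, i))
      p[[length(p) + 1L]] <- diffPos[c(i, j, setdiff(1:3, c(i, j)))]
    p
  }
  tot <- c(sd = 0, nd = 0)
  nOK <- 0L
  for (ord in perms) {
    cur <- c1
    steps <- c(sd = 0, nd = 0)
    ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (isStopCodon(nxt)) { ok <- FALSE; break }
      if (codonAA(nxt) == codonAA(cur)) steps["sd"] <- steps["sd"] + 1
      else steps["nd"] <- steps["nd"] + 1
      cur <- nxt
    }
    if (ok) { tot <- tot + steps; nOK <- nOK + 1L }
  }
  if (nOK == 0L) return(NULL)
  tot / nOK
}

.jc <- function(p) {
  if (is.na(p) || p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Ka and Ks by the Nei-Gojobori method
#'
#' Unweighted-pathway estimates of nonsynonymous (Ka) and synonymous (Ks)
#' substitutions per site on a frame-preserved codon alignment. Per codon,
#' the synonymous site count is the summed fraction of single-nucleotide
#' changes that are synonymous; site totals are averaged over the two
#' sequences. Codons differing at several positions are averaged over all
#' substitution orderings, discarding pathways through stop codons (a
#' codon pair whose pathways all hit stops is skipped). Proportions are
#' corrected with the Jukes-Cantor transform K = -(3/4) ln(1 - 4p/3);
#' estimates with p >= 3/4, or with no countable sites, are flagged
#' invalid (NA), mirroring how uncorrectable pairs are dropped from
#' analyses.
#'
#' @param alignment list with \code{a} and \code{b}: aligned coding
#'   sequences of equal length divisible by 3 (gaps only in whole-codon
#'   units, as produced by \code{\link{codonBacktranslate}}).
#' @return list: \code{Ka}, \code{Ks} (NA when invalid), \code{pN},
#'   \code{pS}, \code{N}, \code{S} (site counts), \code{Nd}, \code{Sd}
#'   (difference counts), \code{codons} (countable codon pairs), and
#'   \code{skipped} (codon pairs excluded for gaps, ambiguity, stops, or
#'   stop-only pathways).
#' @export
neiGojobori <- function(alignment) {
  a <- toupper(alignment$a)
  b <- toupper(alignment$b)
  if (nchar(a) != nchar(b)) stop("aligned sequences differ in length")
  if (nchar(a) %% 3L != 0L) stop("alignment length not divisible by 3")
  nc <- nchar(a) %/% 3L
  S <- N <- Sd <- Nd <- 0
  used <- 0L
  skipped <- 0L
  for (k in seq_len(nc)) {
    c1 <- substr(a, 3 * k - 2, 3 * k)
    c2 <- substr(b, 3 * k - 2, 3 * k)
    if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2) ||
        isStopCodon(c1) || isStopCodon(c2)) { skipped <- skipped + 1L; next }
    dif <- codonPairDifferences(c1, c2)
    if (is.null(dif)) { skipped <- skipped + 1L; next }
    s1 <- unname(synonymousSites(c1))
    s2 <- unname(synonymousSites(c2))
    S <- S + (s1 + s2) / 2
    N <- N + 3 - (s1 + s2) / 2
    Sd <- Sd + dif[["sd"]]
    Nd <- Nd + dif[["nd"]]
    used <- used + 1L
  }
  if (used == 0L) stop("no countable codon pair in alignment")
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  list(Ka = .jc(pN), Ks = .jc(pS), pN = pN, pS = pS,
       N = N, S = S, Nd = Nd, Sd = Sd, codons = used, skipped = skipped)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Maps each aligned amino acid to its source codon; protein gap columns
#' expand to triple-nucleotide gaps, so the resulting DNA alignment is
#' frame-preserved. A trailing stop codon on either CDS is trimmed.
#'
#' @param protein_a,protein_b aligned protein sequences (equal length,
#'   gaps as \code{-}).
#' @param cds_a,cds_b unaligned coding sequences; each must be exactly 3x
#'   its protein's ungapped length (after stop trimming), with no internal
#'   stop codon.
#' @return list(a, b): aligned DNA strings.
#' @export
codonBacktranslate <- function(protein_a, protein_b, cds_a, cds_b) {
  if (nchar(protein_a) != nchar(protein_b))
    stop("protein alignment rows differ in length")
  expand <- function(prot, cds, label) {
    cds <- toupper(cds)
    aa <- strsplit(prot, "")[[1]]
    nAA <- sum(aa != "-")
    if (nchar(cds) == 3L * (nAA + 1L) &&
        isStopCodon(substr(cds, nchar(cds) - 2L, nchar(cds))))
      cds <- substr(cds, 1L, nchar(cds) - 3L)
    if (nchar(cds) != 3L * nAA)
      stop("CDS/protein length mismatch for sequence ", label)
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    if (any(isStopCodon(codons[!grepl("[^ACGT]", codons)])))
      stop("internal stop codon in sequence ", label)
    out <- character(length(aa))
    j <- 0L
    for (i in seq_along(aa)) {
      if (aa[i] == "-") out[i] <- "---"
      else { j <- j + 1L; out[i] <- codons[j] }
    }
    paste(out, collapse = "")
  }
  list(a = expand(protein_a, cds_a, "a"), b = expand(protein_b, cds_b, "b"))
}

#' Jukes-Cantor nucleotide substitution rate
#'
#' mu = -(3/4) ln(1 - 4p/3) where p is the mismatch proportion over
#' ungapped alignment columns. Used for promoter and UTR divergence.
#' p = 0 gives mu = 0 (valid); p >= 3/4 is outside the model's domain and
#' is flagged invalid (NA), mirroring how such pairs are removed from
#' analyses.
#'
#' @param aligned_a,aligned_b aligned nucleotide sequences of equal
#'   length; columns with a gap in either sequence are ignored.
#' @return list: \code{mu} (NA when invalid), \code{p}, \code{sites}
#'   (ungapped columns), \code{valid}.
#' @export
jukesCantorMu <- function(aligned_a, aligned_b) {
  a <- strsplit(toupper(aligned_a), "")[[1]]
  b <- strsplit(toupper(aligned_b), "")[[1]]
  if (length(a) != length(b)) stop("aligned sequences differ in length")
  ok <- a != "-" & b != "-"
  n <- sum(ok)
  if (n == 0L) stop("no ungapped alignment column")
  p <- sum(a[ok] != b[ok]) / n
  mu <- .jc(p)
  list(mu = mu, p = p, sites = n, valid = !is.na(mu))
}

#' Promoter region of a gene
#'
#' Strand-aware upstream region of the transcription start site (the
#' annotated gene start on +, gene end on -), at most \code{maxLen} bp,
#' truncated at the nearest annotated gene boundary upstream and clipped
#' at chromosome ends. The region may be empty when an adjacent gene
#' abuts or overlaps the TSS.
#'
#' @param gene_id gene identifier.
#' @param annotation a \code{GenomeAnnotation}.
#' @param maxLen maximum promoter length in bp (default 1000).
#' @return list(chromosome, start, end, strand, width); \code{width} is 0
#'   for an empty region (then start > end).
#' @export
promoterRegion <- function(gene_id, annotation, maxLen = 1000L) {
  g <- genes(annotation)
  i <- match(gene_id, g$gene_id)
  if (is.na(i)) stop("unknown gene id: ", gene_id)
  chr <- g$chromosome[i]
  others <- g[g$chromosome == chr & g$gene_id != gene_id, , drop = FALSE]
  if (g$strand[i] == "+") {
    tss <- g$start[i]
    lo <- max(1L, tss - maxLen)
    if (nrow(others)) {
      overl <- others$start < tss & others$end >= tss
      if (any(overl)) lo <- tss  # abutting/overlapping gene: empty region
      up <- others$end[others$end < tss]
      if (length(up)) lo <- max(lo, max(up) + 1L)
    }
    region <- list(chromosome = chr, start = lo, end = tss - 1L,
                   strand = "+")
  } else {
    tss <- g$end[i]
    cl <- chromLengths(annotation)
    hi <- tss + maxLen
    if (chr %in% names(cl)) hi <- min(hi, as.integer(cl[[chr]]))
    if (nrow(others)) {
      overl <- others$end > tss & others$start <= tss
      if (any(overl)) hi <- tss
      dn <- others$start[others$start > tss]
      if (length(dn)) hi <- min(hi, min(dn) - 1L)
    }
    region <- list(chromosome = chr, start = tss + 1L, end = hi,
                   strand = "-")
  }
  region$width <- max(0L, region$end - region$start + 1L)
  region
}

#' Extract a promoter sequence
#'
#' @param gene_id gene identifier.
#' @param annotation a \code{GenomeAnnotation}.
#' @param genome a \code{Biostrings::DNAStringSet} named by chromosome.
#' @param maxLen maximum promoter length in bp.
#' @return a \code{DNAString}, reverse-complemented for - strand genes;
#'   empty when the region is empty.
#' @export
promoterExtract <- function(gene_id, annotation, genome, maxLen = 1000L) {
  r <- promoterRegion(gene_id, annotation, maxLen)
  if (!r$chromosome %in% names(genome))
    stop("chromosome ", r$chromosome, " not in genome")
  chrSeq <- genome[[r$chromosome]]
  if (r$width == 0L) return(Biostrings::DNAString(""))
  end <- min(r$end, length(chrSeq))
  if (end < r$start) return(Biostrings::DNAString(""))
  s <- Biostrings::subseq(chrSeq, r$start, end)
  if (r$strand == "-") s <- Biostrings::reverseComplement(s)
  s
}

#' Global pairwise alignment (plumbing)
#'
#' Needleman-Wunsch global alignment with match 1, mismatch 0, gap -1
#' (linear gap cost), via Biostrings. Used to align promoter pairs before
#' the identity calculation; pre-aligned input can bypass it.
#'
#' @param a,b character sequences or XString objects.
#' @return list(a, b): aligned strings of equal length.
#' @export
alignGlobal <- function(a, b) {
  mat <- matrix(0, 4, 4, dimnames = list(.NUC, .NUC))
  diag(mat) <- 1
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(as.character(a)),
    Biostrings::DNAString(as.character(b)),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 1)
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)))
}

#' Promoter duplication call
#'
#' Two promoters are called duplicated (non-disrupted) when their global
#' alignment identity exceeds 45%. Identity is matches divided by total
#' alignment columns, gap columns included; a value of exactly 0.45 is
#' not duplicated (strict inequality).
#'
#' @param seq_a,seq_b promoter sequences (character or XString); both must
#'   be non-empty. Pass \code{aligned = TRUE} if already aligned.
#' @param aligned logical; skip the internal global alignment.
#' @param threshold identity cutoff (default 0.45).
#' @return list(duplicated, identity).
#' @export
promoterDuplicated <- function(seq_a, seq_b, aligned = FALSE,
                               threshold = 0.45) {
  a <- as.character(seq_a)
  b <- as.character(seq_b)
  if (!nzchar(a) || !nzchar(b))
    stop("empty promoter sequence: call undetermined")
  if (!aligned) {
    al <- alignGlobal(a, b)
    a <- al$a
    b <- al$b
  }
  if (nchar(a) != nchar(b)) stop("aligned sequences differ in length")
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  identity <- sum(av == bv & av != "-") / length(av)
  list(duplicated = identity > threshold, identity = identity)
}
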