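# Shared fixtures and independent oracles for the test suite.

# A tiny annotation built directly from a gene table.
tinyAnnotation <- function() {
  makeGenomeAnnotation(data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g6"),
    chromosome = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2"),
    start = c(100L, 5000L, 9000L, 15000L, 200L, 4000L),
    end = c(1099L, 5999L, 9999L, 15999L, 1199L, 4999L),
    strand = c("+", "+", "-", "+", "+", "-"),
    exon_count = c(4L, 1L, 2L, 3L, 5L, 1L),
    stringsAsFactors = FALSE
  ), chromLengths = c(chr1 = 20000, chr2 = 6000))
}

# Annotation with m genes laid out on one chromosome at regular spacing,
# all + strand, exon counts supplied.
rowAnnotation <- function(exons, chrom = "chr1", spacing = 2000L) {
  m <- length(exons)
  makeGenomeAnnotation(data.frame(
    gene_id = sprintf("%s_g%03d", chrom, seq_len(m)),
    chromosome = chrom,
    start = (seq_len(m) - 1L) * spacing + 1L,
    end = (seq_len(m) - 1L) * spacing + 1000L,
    strand = "+",
    exon_count = as.integer(exons),
    stringsAsFactors = FALSE
  ), chromLengths = stats::setNames(m * spacing, chrom))
}

emptyAnchors <- function() {
  new("AnchorCollection")
}

anchorsFromPairs <- function(a, b, block = "b1", event = NA_character_,
                             ortho = character(0)) {
  new("AnchorCollection",
      anchors = data.frame(gene_a = pmin(a, b), gene_b = pmax(a, b),
                           block_id = block, event = event,
                           stringsAsFactors = FALSE),
      orthologs = if (length(ortho))
        data.frame(gene_a = ortho, gene_b = paste0("x_", ortho),
                   stringsAsFactors = FALSE)
      else data.frame(gene_a = character(0), gene_b = character(0)))
}

# Mutual homology hits for a list of pairs, well under any threshold.
hitsForPairs <- function(a, b, evalue = 1e-40) {
  data.frame(query_id = c(a, b), subject_id = c(b, a),
             evalue = evalue, bitscore = 300,
             stringsAsFactors = FALSE)
}

pkey <- function(a, b) paste(pmin(a, b), pmax(a, b))

# --- independent Nei-Gojobori pathway oracle --------------------------
# Recursively enumerates every ordering of the differing codon positions,
# drops orderings that pass through a stop codon, and averages the
# synonymous / nonsynonymous step counts. Written against the genetic
# code directly, independently of the package's implementation.
oracleCodonDiff <- function(c1, c2, code = Biostrings::GENETIC_CODE) {
  positions <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  paths <- list()
  walk <- function(cur, remaining, sd, nd) {
    if (!length(remaining)) {
      paths[[length(paths) + 1L]] <<- c(sd, nd)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (code[[nxt]] == "*") next
      walk(nxt, setdiff(remaining, p),
           sd + (code[[nxt]] == code[[cur]]),
           nd + (code[[nxt]] != code[[cur]]))
    }
  }
  walk(c1, positions, 0L, 0L)
  if (!length(paths)) return(NULL)
  colMeans(do.call(rbind, paths))
}

# one-sided hypergeometric upper-tail p by explicit enumeration
oracleHyperP <- function(a, subsetN, termN, universeN) {
  hi <- min(subsetN, termN)
  x <- a:hi
  sum(choose(termN, x) * choose(universeN - termN, subsetN - x)) /
    choose(universeN, subsetN)
}
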