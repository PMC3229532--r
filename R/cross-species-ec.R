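#' Within-species co-expression matrix
#'
#' Pairwise Pearson correlation matrix between the expression profiles of
#' the k ortholog-indexed genes of one species: entry (i, j) is the
#' correlation of rows i and j. This is the species-specific half of the
#' cross-species expression-conservation construction, which compares
#' co-expression patterns rather than raw profiles and therefore needs no
#' cross-platform normalisation.
#'
#' @param m k x n expression matrix (ortholog-indexed rows).
#' @return k x k symmetric correlation matrix with unit diagonal.
#' @export
coexpressionMatrix <- function(m) {
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant expression profile for gene ",
         rownames(m)[which(sds == 0)[1]])
  C <- stats::cor(t(m))
  dimnames(C) <- list(rownames(m), rownames(m))
  C
}

#' Expression conservation of ortholog pairs
#'
#' Given the two co-expression matrices CA and CB (rows ordered by a
#' shared ortholog index), the expression conservation of ortholog pair i
#' is the Pearson correlation between row i of CA and row i of CB; its
#' expression divergence is d = 1 - EC. The self entry i (which is 1 in
#' both matrices) is excluded by default, since including it mechanically
#' inflates EC; set \code{include_self = TRUE} for sensitivity analysis.
#'
#' @param CA,CB k x k co-expression matrices from
#'   \code{\link{coexpressionMatrix}}, same ortholog order.
#' @param include_self keep the diagonal entry in the correlation
#'   (default FALSE).
#' @return data.frame with one row per ortholog pair: \code{index},
#'   \code{ec}, \code{d}.
#' @export
ecScores <- function(CA, CB, include_self = FALSE) {
  k <- nrow(CA)
  if (!all(dim(CA) == dim(CB))) stop("CA and CB differ in dimension")
  if (k - 1L < 3L && !include_self)
    stop("too few orthologs: need k - 1 >= 3 off-self entries")
  # row-wise correlations, computed from row sums so that excluding the
  # self entry (diagonal, = 1 in both matrices) stays vectorised
  n <- if (include_self) k else k - 1L
  adj <- if (include_self) 0 else 1
  sA <- rowSums(CA) - adj
  sB <- rowSums(CB) - adj
  sAA <- rowSums(CA^2) - adj
  sBB <- rowSums(CB^2) - adj
  sAB <- rowSums(CA * CB) - adj
  num <- sAB - sA * sB / n
  den <- sqrt(pmax(sAA - sA^2 / n, 0) * pmax(sBB - sB^2 / n, 0))
  ec <- ifelse(den > 0, num / den, NA_real_)
  data.frame(index = seq_len(k), ec = ec, d = 1 - ec)
}

#' End-to-end EC from two ortholog-indexed matrices
#'
#' @param A,B expression matrices of species 1 and 2; row i of A and row i
#'   of B are the two members of ortholog pair i (sample counts may
#'   differ).
#' @param classes optional data.frame with columns \code{class_a},
#'   \code{class_b} in {"singleton","duplicate"}; adds the ortholog-pair
#'   class S-S / S-D / D-D.
#' @param include_self see \code{\link{ecScores}}.
#' @return data.frame (index, ec, d[, class]).
#' @export
expressionConservation <- function(A, B, classes = NULL,
                                   include_self = FALSE) {
  if (nrow(A) != nrow(B)) stop("A and B must have the same number of rows")
  sc <- ecScores(coexpressionMatrix(A), coexpressionMatrix(B),
                 include_self = include_self)
  if (!is.null(classes)) {
    stopifnot(nrow(classes) == nrow(A))
    sc$class <- orthologClass(classes$class_a, classes$class_b)
  }
  sc
}

#' Ortholog-pair class from per-gene duplicate status
#' @param class_a,class_b character vectors in {"singleton","duplicate"}.
#' @return "S-S", "S-D" or "D-D" per pair.
#' @export
orthologClass <- function(class_a, class_b) {
  nd <- (class_a == "duplicate") + (class_b == "duplicate")
  c("S-S", "S-D", "D-D")[nd + 1L]
}

#' Contrast expression divergence between ortholog classes
#'
#' Mean d per class (S-S, S-D, D-D) and pairwise two-sample t-tests
#' between classes with at least 2 scores; empty or singleton classes are
#' skipped with a message.
#'
#' @param scores data.frame with columns \code{d} and \code{class}.
#' @return list with \code{means} (named vector, in S-S, S-D, D-D order)
#'   and \code{tests} (data.frame class1, class2, t, p).
#' @export
classContrast <- function(scores) {
  lev <- intersect(c("S-S", "S-D", "D-D"), unique(scores$class))
  byClass <- split(scores$d[!is.na(scores$d)],
                   factor(scores$class[!is.na(scores$d)], levels = lev))
  means <- vapply(byClass, mean, numeric(1))
  usable <- names(byClass)[lengths(byClass) >= 2L]
  skipped <- setdiff(lev, usable)
  if (length(skipped))
    message("class(es) skipped in contrasts (fewer than 2 scores): ",
            paste(skipped, collapse = ", "))
  tests <- NULL
  if (length(usable) >= 2L) {
    combs <- utils::combn(usable, 2L)
    tests <- do.call(rbind, apply(combs, 2L, function(cl) {
      tt <- stats::t.test(byClass[[cl[1]]], byClass[[cl[2]]])
      data.frame(class1 = cl[1], class2 = cl[2],
                 t = unname(tt$statistic), p = tt$p.value)
    }))
    rownames(tests) <- NULL
  }
  list(means = means, tests = tests)
}
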