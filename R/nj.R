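#' Neighbour-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q(i,j) = (r-2) d(i,j) - R_i - R_j` is joined (ties broken by the smallest
#' `(i, j)` index pair in the current node order), branch lengths follow the
#' standard rate-corrected split and are clamped at 0, and distances to the
#' new node are `(d(i,k) + d(j,k) - d(i,j)) / 2`. The result is the unrooted
#' NJ tree as an `ape::phylo` (trifurcating root node); use
#' `midpoint = TRUE` for a midpoint-rooted version.
#'
#' @param D Symmetric distance matrix with zero diagonal and labelled
#'   dimnames; at least 3 taxa.
#' @param midpoint Midpoint-root the result (via [phangorn::midpoint()] when
#'   available, otherwise an error).
#' @return An `ape::phylo` tree whose leaf set equals the matrix labels.
#' @export
nj_tree <- function(D, midpoint = FALSE) {
  D <- as.matrix(D)
  if (any(is.na(D)) || any(!is.finite(D))) stopf("nj_tree: NA/NaN in matrix")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stopf("nj_tree: matrix not symmetric")
  if (any(abs(diag(D)) > 1e-12)) stopf("nj_tree: nonzero diagonal")
  n <- nrow(D)
  if (n < 3) stopf("nj_tree: need at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # node representation: newick fragment per active node
  frag <- labels
  while (length(frag) > 3) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    # smallest (i, j), i < j, among minima
    minQ <- min(Q)
    idx <- which(Q - minQ <= 1e-12 * max(1, abs(minQ)), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    bi <- 0.5 * D[i, j] + (R[i] - R[j]) / (2 * (r - 2))
    bj <- D[i, j] - bi
    bi <- max(bi, 0); bj <- max(bj, 0)
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], bi, frag[j], bj)
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    dnew <- pmax(dnew, 0)
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    D <- D2
  }
  # final three nodes: three-point formulas
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  b <- pmax(c(b1, b2, b3), 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[1], b[1], frag[2], b[2], frag[3], b[3])
  tree <- ape::read.tree(text = nwk)
  if (midpoint) {
    if (!requireNamespace("phangorn", quietly = TRUE))
      stopf("nj_tree: midpoint rooting requires the phangorn package")
    tree <- phangorn::midpoint(tree)
  }
  tree
}
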