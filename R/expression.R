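#' Relative expression by the delta-delta-Ct method
#'
#' Per qPCR row, `dCt = Ct_target - Ct_reference`; per gene,
#' `ddCt = mean(dCt treated) - mean(dCt untreated)` and relative expression is
#' `2^-ddCt`. Per-replicate relative values (each treated replicate against
#' the mean untreated dCt) give the replicate mean and SD.
#'
#' @param ct `data.frame` with columns `gene`, `condition`
#'   (`"treated"`/`"untreated"`), `ct_target`, `ct_reference` (one row per
#'   replicate).
#' @return `data.frame`: `gene`, `ddct`, `rel_expr` (`2^-ddct`), `rel_mean`,
#'   `rel_sd` (over treated replicates).
#' @export
relative_expression <- function(ct) {
  need <- c("gene", "condition", "ct_target", "ct_reference")
  miss <- setdiff(need, names(ct))
  if (length(miss))
    stopf("relative_expression: missing column(s): %s",
          paste(miss, collapse = ", "))
  if (any(!is.finite(ct$ct_target)) || any(!is.finite(ct$ct_reference)))
    stopf("relative_expression: non-finite Ct value")
  bad <- setdiff(unique(ct$condition), c("treated", "untreated"))
  if (length(bad))
    stopf("relative_expression: unknown condition '%s'", bad[1])
  ct$dct <- ct$ct_target - ct$ct_reference
  out <- lapply(split(ct, ct$gene), function(g) {
    tr <- g$dct[g$condition == "treated"]
    un <- g$dct[g$condition == "untreated"]
    if (!length(tr) || !length(un))
      stopf("relative_expression: gene %s lacks a condition", g$gene[1])
    ddct <- mean(tr) - mean(un)
    rel_i <- 2^-(tr - mean(un))
    data.frame(gene = g$gene[1], ddct = ddct, rel_expr = 2^-ddct,
               rel_mean = mean(rel_i),
               rel_sd = if (length(rel_i) > 1) sd(rel_i) else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$gene), , drop = FALSE]
}

# vectorised exact two-sided Poisson rate test on two summed counts:
# conditional on x1 + x2, x1 ~ Binomial(x1 + x2, n1/(n1+n2)); two-sided
# p-value by the minimum-likelihood rule (as stats::poisson.test)
poisson_rate_test <- function(x1, x2, n1, n2) {
  pr <- n1 / (n1 + n2)
  vapply(seq_along(x1), function(i) {
    tot <- x1[i] + x2[i]
    if (tot == 0) return(1)
    dens <- dbinom(0:tot, tot, pr)
    dobs <- dens[x1[i] + 1]
    sum(dens[dens <= dobs * (1 + 1e-7)])
  }, 0)
}

#' Call up-regulated genes
#'
#' The published rule applied verbatim: a gene is called when its
#' Benjamini-Hochberg FDR is at most `fdr_max` AND `|log2 fold change|` is at
#' least `lfc_min` (defaults 0.05 and 2). Fold change is
#' `log2((mean treated + c) / (mean control + c))` with pseudocount
#' `c = pseudocount`. P-values come from a two-sided exact Poisson rate test
#' on the group-summed (rounded) counts, exposed for substitution via `test`.
#'
#' @param mat Nonnegative genes x samples matrix (counts or RPKM).
#' @param groups Vector over columns with exactly two values; the first value
#'   encountered (or `treated`) is the numerator group.
#' @param treated Which group value is "treated" (numerator).
#' @param fdr_max,lfc_min,pseudocount Thresholds and pseudocount.
#' @param test Function `(x_treated, x_control, n_treated, n_control) ->
#'   p-values` on summed counts.
#' @return `data.frame`: `gene`, `log2fc`, `p_value`, `fdr`, `up_regulated`.
#' @export
call_upregulated <- function(mat, groups, treated = NULL,
                             fdr_max = 0.05, lfc_min = 2, pseudocount = 1,
                             test = poisson_rate_test) {
  mat <- as.matrix(mat)
  if (length(groups) != ncol(mat))
    stopf("call_upregulated: groups length != number of samples")
  lv <- unique(groups)
  if (length(lv) != 2) stopf("call_upregulated: exactly two groups required")
  if (is.null(treated)) treated <- lv[1]
  control <- setdiff(lv, treated)
  a <- mat[, groups == treated, drop = FALSE]
  b <- mat[, groups == control, drop = FALSE]
  if (!ncol(a) || !ncol(b)) stopf("call_upregulated: empty group")
  lfc <- log2((rowMeans(a) + pseudocount) / (rowMeans(b) + pseudocount))
  p <- test(round(rowSums(a)), round(rowSums(b)), ncol(a), ncol(b))
  fdr <- p.adjust(p, method = "BH")
  data.frame(gene = rownames(mat), log2fc = lfc, p_value = p, fdr = fdr,
             up_regulated = fdr <= fdr_max & abs(lfc) >= lfc_min,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hierarchical clustering of expression profiles
#'
#' Complete-linkage agglomeration on Euclidean distances of the transformed
#' rows (default transform `log2(x + 1)`, matching log2 RPKM with a guard at
#' zero). Backed by [stats::hclust()], whose merge order is deterministic.
#'
#' @param mat Genes x samples matrix, at least 2 genes.
#' @param transform Row transform applied before distances.
#' @return List: `hclust` (the dendrogram), `order` (leaf gene ids),
#'   `heights`.
#' @export
hier_cluster <- function(mat, transform = function(x) log2(x + 1)) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stopf("hier_cluster: need at least 2 genes")
  hc <- hclust(dist(transform(mat), method = "euclidean"),
               method = "complete")
  list(hclust = hc, order = rownames(mat)[hc$order], heights = hc$height)
}

#' Pearson co-expression network with hub extraction
#'
#' Scores every unordered gene pair by Pearson correlation over samples and
#' draws an undirected edge when `r^2 >= r2_min` (inclusive, default 0.95).
#' Hubs are nodes of degree `>= hub_min` (inclusive, default 9), ranked by
#' degree then id. Zero-variance genes cannot be correlated and are excluded
#' with a warning.
#'
#' @param mat Genes x samples matrix with at least 3 samples.
#' @param r2_min Squared-correlation edge threshold.
#' @param hub_min Minimum degree of a hub.
#' @return List: `nodes`, `edges` (`gene_a`, `gene_b`, `r`, `r2`), `degree`
#'   (named, all nodes), `hubs`.
#' @export
coexpression_network <- function(mat, r2_min = 0.95, hub_min = 9) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 3) stopf("coexpression_network: need at least 3 samples")
  v <- apply(mat, 1, function(x) var(x) > 0)
  if (any(!v)) {
    warning(sprintf("coexpression_network: excluding %d zero-variance gene(s)",
                    sum(!v)))
    mat <- mat[v, , drop = FALSE]
  }
  nodes <- rownames(mat)
  n <- length(nodes)
  edges <- data.frame(gene_a = character(0), gene_b = character(0),
                      r = numeric(0), r2 = numeric(0))
  if (n >= 2) {
    cc <- cor(t(mat))
    ut <- which(upper.tri(cc) & cc^2 >= r2_min, arr.ind = TRUE)
    if (nrow(ut)) {
      edges <- data.frame(gene_a = nodes[ut[, 1]], gene_b = nodes[ut[, 2]],
                          r = cc[ut], r2 = cc[ut]^2,
                          stringsAsFactors = FALSE)
      edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  degree <- setNames(integer(n), nodes)
  if (nrow(edges)) {
    t1 <- table(factor(edges$gene_a, levels = nodes))
    t2 <- table(factor(edges$gene_b, levels = nodes))
    degree <- setNames(as.integer(t1 + t2), nodes)
  }
  hub <- degree[degree >= hub_min]
  hubs <- names(hub)[order(-hub, names(hub))]
  list(nodes = nodes, edges = edges, degree = degree, hubs = hubs)
}
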