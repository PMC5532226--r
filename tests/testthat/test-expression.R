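ct_fixture <- function(ct_treat, ct_untr, ref_shift = 0) {
  data.frame(gene = "g",
             condition = rep(c("treated", "untreated"),
                             c(length(ct_treat), length(ct_untr))),
             ct_target = c(ct_treat, ct_untr) + ref_shift,
             ct_reference = 20 + ref_shift)
}

test_that("relative_expression implements 2^-ddCt", {
  r <- relative_expression(ct_fixture(25, 27))
  expect_equal(r$ddct, -2)
  expect_equal(r$rel_expr, 4)

  # treated = untreated -> 1
  expect_equal(relative_expression(ct_fixture(25, 25))$rel_expr, 1)

  # a global Ct shift (reference drift) cancels
  expect_equal(relative_expression(ct_fixture(25, 27, ref_shift = 3))$rel_expr,
               4)

  # replicate summaries
  r2 <- relative_expression(ct_fixture(c(24, 26), c(27, 27)))
  expect_equal(r2$rel_mean, mean(2^-(c(24, 26) - 27)))
  expect_gt(r2$rel_sd, 0)

  expect_error(relative_expression(ct_fixture(25, numeric(0))),
               "lacks a condition")
})

test_that("relative expression is 1 when dCt distributions match", {
  ct <- rbind(ct_fixture(c(24, 25, 26), c(24, 25, 26)))
  expect_equal(relative_expression(ct)$rel_expr, 1)
})

test_that("poisson_rate_test agrees with stats::poisson.test", {
  set.seed(4)
  for (i in 1:25) {
    x1 <- rpois(1, sample(c(2, 20, 200), 1))
    x2 <- rpois(1, sample(c(2, 20, 200), 1))
    n1 <- sample(1:4, 1); n2 <- sample(1:4, 1)
    if (x1 + x2 == 0) next
    want <- stats::poisson.test(c(x1, x2), c(n1, n2))$p.value
    got <- wrkykit:::poisson_rate_test(x1, x2, n1, n2)
    expect_equal(got, want, tolerance = 1e-9, info = paste(x1, x2, n1, n2))
  }
})

test_that("call_upregulated applies both thresholds jointly", {
  ex <- make_expression(200, 3, n_de = 20, fc = 8, seed = 13)
  de <- call_upregulated(ex$mat, ex$meta$condition, treated = "treated")
  expect_true(all(abs(de$log2fc[de$up_regulated]) >= 2))
  expect_true(all(de$fdr[de$up_regulated] <= 0.05))
  # identical group means -> log2fc 0, never called
  flat <- matrix(100, 2, 6, dimnames = list(c("g1", "g2"), NULL))
  de0 <- call_upregulated(flat, rep(c("treated", "control"), each = 3))
  expect_equal(de0$log2fc, c(0, 0))
  expect_false(any(de0$up_regulated))
  expect_error(call_upregulated(flat, rep("a", 6)), "two groups")
})

test_that("planted 8-fold genes at deep counts are recovered", {
  ex <- make_expression(300, 3, n_de = 30, fc = 8, base_mean = 200,
                        seed = 21)
  de <- call_upregulated(ex$mat, ex$meta$condition, treated = "treated")
  recovered <- mean(de$up_regulated[ex$truth$de])
  expect_gte(recovered, 0.9)
  # and a no-effect generator plants nothing
  ex0 <- make_expression(50, 3, n_de = 10, fc = 1, seed = 22)
  expect_false(any(ex0$truth$de))
})

test_that("hier_cluster merges duplicates first and outliers last", {
  m <- rbind(g1 = c(1, 2, 3), g2 = c(1, 2, 3), g3 = c(50, 60, 70))
  hc <- hier_cluster(m, transform = identity)
  expect_equal(hc$heights[1], 0)                  # identical rows at height 0
  expect_identical(sort(hc$order), sort(rownames(m)))
  # outlier merges last: final merge height = distance(g3, {g1,g2})
  expect_equal(max(hc$heights),
               sqrt(sum((c(50, 60, 70) - c(1, 2, 3))^2)))
  expect_true(all(diff(hc$heights) >= 0))
  expect_error(hier_cluster(m[1, , drop = FALSE]), "at least 2")
})

test_that("constant matrices cluster degenerately but validly", {
  m <- matrix(5, 4, 3, dimnames = list(paste0("g", 1:4), NULL))
  hc <- hier_cluster(m)
  expect_true(all(hc$heights == 0))
  expect_setequal(hc$order, rownames(m))
})

test_that("coexpression_network edges, degrees and hubs are consistent", {
  set.seed(10)
  base <- matrix(rnorm(5 * 10), 5, 10,
                 dimnames = list(paste0("g", 1:5), NULL))
  base["g2", ] <- base["g1", ]            # exact duplicate -> r2 = 1 edge
  net <- coexpression_network(base, r2_min = 0.95, hub_min = 1)
  expect_true(any(net$edges$gene_a == "g1" & net$edges$gene_b == "g2" &
                    net$edges$r2 > 1 - 1e-9))
  expect_equal(sum(net$degree), 2 * nrow(net$edges))
  expect_true(all(net$edges$r2 >= 0.95))
  expect_error(coexpression_network(base[, 1:2]), "3 samples")
  withvar <- rbind(base, flat = rep(1, 10))
  expect_warning(coexpression_network(withvar), "zero-variance")
})

test_that("independent noise yields no edges; planted modules are cliques", {
  ex <- make_expression(40, 25, seed = 17)                 # pure noise
  net <- coexpression_network(log2(ex$mat + 1))
  expect_identical(nrow(net$edges), 0L)

  ex2 <- make_expression(30, 30, n_modules = 1, module_size = 10,
                         module_r = 0.995, seed = 18)
  net2 <- coexpression_network(log2(ex2$mat + 1), r2_min = 0.95, hub_min = 9)
  mod <- ex2$truth$gene[!is.na(ex2$truth$module)]
  in_mod <- net2$edges$gene_a %in% mod & net2$edges$gene_b %in% mod
  expect_identical(sum(in_mod), 45L)             # fully connected
  expect_true(all(mod %in% net2$hubs))
  expect_true(all(net2$degree[mod] >= 9))
})

test_that("module_r = 1 makes within-module profiles proportional", {
  ex <- make_expression(10, 5, n_modules = 1, module_size = 5, module_r = 1,
                        seed = 19)
  mod <- ex$truth$gene[!is.na(ex$truth$module)]
  m <- ex$mat[mod, ]
  ratios <- m[-1, , drop = FALSE] / rep(m[1, ], each = nrow(m) - 1)
  expect_equal(apply(ratios, 1, var), setNames(rep(0, 4), rownames(ratios)),
               tolerance = 1e-12)
})
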