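test_that("Simes aggregation matches the closed form and stays uniform under the null", {
  expect_equal(simes_aggregate(c(0.01, 0.04)), 0.02)
  expect_equal(simes_aggregate(0.37), 0.37)
  expect_error(simes_aggregate(numeric(0)), "empty")
  expect_error(simes_aggregate(c(0.1, 1.2)), "in \\[0, 1\\]")
  set.seed(20)
  K <- 5
  P <- matrix(runif(10000 * K), ncol = K)
  Ps <- t(apply(P, 1, sort))
  simes <- do.call(pmin, lapply(1:K, function(k) Ps[, k] * K / k))
  expect_gt(ks.test(simes, "punif")$p.value, 0.01)
  # the vectorized oracle agrees with the package function
  expect_equal(simes, apply(P, 1, simes_aggregate))
})

test_that("the hypothesis tree aggregates leaves by Simes at both levels", {
  leaves <- data.frame(gene = c("g1", "g1", "g1", "g2"),
                       context = c("c1", "c1", "c2", "c1"),
                       model = c("specific", "full", "specific", "specific"),
                       p = c(0.02, 0.9, 0.5, 0.001))
  tr <- hypothesis_tree(leaves)
  expect_equal(tr$contexts$p[tr$contexts$gene == "g1" & tr$contexts$context == "c1"],
               min(0.02 * 2, 0.9))
  expect_equal(tr$genes$p[tr$genes$gene == "g2"], 0.001)
  expect_error(hypothesis_tree(rbind(leaves, leaves[1, ])), "duplicate")
})

test_that("pooling methods extends the tree and rejects duplicate keys", {
  a <- data.frame(gene = "g1", context = "c1", model = c("m1", "m2"),
                  p = c(0.02, 0.9))
  b <- data.frame(gene = "g1", context = "c1", model = "other", p = 1)
  pooled <- pool_methods(a, b)
  # hand-recomputed Simes over the 3 leaves: min(.02*3, .9*3/2, 1)
  expect_equal(pooled$contexts$p, 0.06)
  expect_error(pool_methods(a, a), "duplicate")
  expect_equal(pool_methods(a)$contexts$p, min(0.02 * 2, 0.9))
})

test_that("hierarchical selection is tree-consistent and finds planted signal", {
  leaves <- expand.grid(gene = paste0("g", 1:40), context = paste0("c", 1:4),
                        model = c("specific", "full"), stringsAsFactors = FALSE)
  set.seed(21)
  leaves$p <- runif(nrow(leaves), 0.2, 1)
  sel0 <- hierarchical_fdr(hypothesis_tree(transform(leaves, p = 1)), q = 0.05)
  expect_equal(sum(sel0$leaves$selected), 0)
  leaves$p[leaves$gene == "g1" & leaves$context == "c2" &
             leaves$model == "full"] <- 1e-12
  sel <- hierarchical_fdr(hypothesis_tree(leaves), q = 0.05)
  expect_true(sel$genes$selected[sel$genes$gene == "g1"])
  expect_true(sel$contexts$selected[sel$contexts$gene == "g1" &
                                      sel$contexts$context == "c2"])
  expect_true(sel$leaves$selected[sel$leaves$gene == "g1" &
                                    sel$leaves$context == "c2" &
                                    sel$leaves$model == "full"])
  # every selected child has a selected parent
  for (i in which(sel$leaves$selected)) {
    expect_true(sel$contexts$selected[sel$contexts$gene == sel$leaves$gene[i] &
                                        sel$contexts$context == sel$leaves$context[i]])
  }
  for (i in which(sel$contexts$selected)) {
    expect_true(sel$genes$selected[sel$genes$gene == sel$contexts$gene[i]])
  }
})

test_that("lowering a leaf p-value never removes rejections", {
  set.seed(22)
  leaves <- expand.grid(gene = paste0("g", 1:20), context = paste0("c", 1:3),
                        model = c("m1", "m2"), stringsAsFactors = FALSE)
  leaves$p <- runif(nrow(leaves))^3
  before <- hierarchical_fdr(hypothesis_tree(leaves), q = 0.1)
  key <- function(d) paste(d$gene, d$context, d$model)[d$selected]
  for (j in sample(nrow(leaves), 5)) {
    mod <- leaves
    mod$p[j] <- mod$p[j] / 10
    after <- hierarchical_fdr(hypothesis_tree(mod), q = 0.1)
    expect_true(all(key(before$leaves) %in% key(after$leaves)))
  }
})
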