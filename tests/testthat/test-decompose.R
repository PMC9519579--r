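test_that("residualization gives OLS residuals orthogonal to covariates", {
  set.seed(2)
  inds <- paste0("i", 1:50)
  E <- expr_mat(rnorm(100), inds, c("c1", "c2"))
  z <- rnorm(50)
  # expression exactly linear in the covariate -> residuals all zero
  E[, "c1"] <- 2 + 3 * z
  st <- manual_study(list(g1 = E),
                     covariates = list(c1 = matrix(z, 50, 1, dimnames = list(inds, "z")),
                                       c2 = matrix(z, 50, 1, dimnames = list(inds, "z"))))
  rs <- residualize(st)
  expect_true(all(abs(rs$expr$g1[, "c1"]) < 1e-10))
  # residuals orthogonal to covariate and to the intercept
  r2 <- rs$expr$g1[, "c2"]
  expect_lt(abs(sum(r2 * z)), 1e-8 * 50)
  expect_lt(abs(sum(r2)), 1e-8 * 50)
  # constant covariate behaves as intercept-only: mean-centering
  stc <- manual_study(list(g1 = E),
                      covariates = list(c2 = matrix(1, 50, 1, dimnames = list(inds, "const"))))
  rc <- residualize(stc)
  expect_equal(rc$expr$g1[, "c2"], E[, "c2"] - mean(E[, "c2"]), tolerance = 1e-12)
})

test_that("center_scale standardizes to population variance 1 and flags degenerate vectors", {
  inds <- paste0("i", 1:3)
  E <- expr_mat(c(2, 4, 6, 5, 5, 5), inds, c("c1", "c2"))
  st <- center_scale(manual_study(list(g1 = E)))
  v <- st$expr$g1[, "c1"]
  expect_equal(mean(v), 0, tolerance = 1e-12)
  expect_equal(mean(v^2), 1, tolerance = 1e-12)
  # constant context excluded with a reason
  expect_true(all(is.na(st$expr$g1[, "c2"])))
  exc <- attr(st, "excluded")
  expect_true(any(exc$context == "c2" & exc$reason == "zero variance"))
  # already standardized input passes through unchanged
  st2 <- center_scale(st)
  expect_equal(st2$expr$g1[, "c1"], v, tolerance = 1e-12)
})

test_that("decomposition matches hand-worked examples", {
  inds <- c("a", "b")
  E <- expr_mat(c(2, 7, 4, NA), inds, c("c1", "c2"))  # a: (2,4); b: (7,NA)
  d <- decompose_expression(manual_study(list(g1 = E)))
  expect_equal(d$genes$g1$shared[["a"]], 3)
  expect_equal(unname(d$genes$g1$specific["a", ]), c(-1, 1))
  # single observed context: shared = value, specific = 0
  expect_equal(d$genes$g1$shared[["b"]], 7)
  expect_equal(d$genes$g1$specific["b", "c1"], 0)
  expect_true(is.na(d$genes$g1$specific["b", "c2"]))
})

test_that("decomposition identities hold exactly under random missingness", {
  set.seed(7)
  for (rep in 1:5) {
    inds <- paste0("i", 1:30)
    ctxs <- paste0("c", 1:5)
    E <- expr_mat(rnorm(150), inds, ctxs)
    E[sample(150, 40)] <- NA
    E[1, ] <- c(1.5, rep(NA, 4))          # guarantee a single-context individual
    st <- manual_study(list(g1 = E))
    d <- decompose_expression(st)$genes$g1
    rec <- d$shared + d$specific          # shared recycles down columns
    obs <- !is.na(E[rownames(d$specific), ])
    expect_true(all(abs(rec[obs] - E[rownames(d$specific), ][obs]) < 1e-10))
    expect_true(all(abs(rowSums(d$specific, na.rm = TRUE)) < 1e-10))
  }
  # complete data: global inner product of shared and specific is zero
  Ec <- expr_mat(rnorm(150), paste0("i", 1:30), paste0("c", 1:5))
  dc <- decompose_expression(manual_study(list(g1 = Ec)))$genes$g1
  expect_lt(abs(sum(dc$shared * dc$specific)), 1e-8)
})

test_that("group-level decomposition separates shared, group and specific terms", {
  inds <- "a"
  E <- expr_mat(c(1, 1, 3, 3), inds, c("c1", "c2", "c3", "c4"))
  grp <- c(c1 = "g1", c2 = "g1", c3 = "g2", c4 = "g2")
  d <- decompose_expression(manual_study(list(g = E)), groups = grp)$genes$g
  expect_equal(d$shared[["a"]], 2)
  expect_equal(unname(d$group_shared["a", c("g1", "g2")]), c(-1, 1))
  expect_true(all(abs(d$specific) < 1e-12))
  # one group containing every context reduces to the plain decomposition
  all_grp <- setNames(rep("g", 4), colnames(E))
  E2 <- expr_mat(rnorm(4 * 8), paste0("i", 1:8), colnames(E))
  d2 <- decompose_expression(manual_study(list(g = E2)), groups = all_grp)$genes$g
  expect_true(all(abs(d2$group_shared) < 1e-12))
  # reconstruction shared + group + specific is exact
  rec <- d2$shared + d2$group_shared[, "g"] + d2$specific
  expect_true(all(abs(rec - E2) < 1e-10))
  # singleton groups are collapsed with a warning
  expect_warning(
    decompose_expression(manual_study(list(g = E2)),
                         groups = setNames(c("a", "a", "a", "b"), colnames(E2))),
    "singleton")
})
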