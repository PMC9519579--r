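test_that("genotype panels are valid dosages, reproducible, and match the MAF law", {
  cfg <- tiny_config(n_genes = 2, n_snps = 30)
  p1 <- simulate_genotypes(cfg)
  p2 <- simulate_genotypes(cfg)
  expect_identical(p1, p2)
  for (g in names(p1$geno)) {
    expect_true(all(p1$geno[[g]] %in% 0:2))
    expect_true(all(p1$maf[[g]] >= 0.05 & p1$maf[[g]] <= 0.50))
  }
  # Monte-Carlo check of Bin(2, 0.5): column means about 1 within 3 SE
  cfgb <- tiny_config(n_genes = 1, n_snps = 5)
  pb <- simulate_genotypes(cfgb, n = 100000, maf = list(rep(0.5, 5)))
  se <- sqrt(2 * 0.5 * 0.5 / 1e5)
  expect_true(all(abs(colMeans(pb$geno[[1]]) - 1) < 3 * se))
})

test_that("effect draws honour sparsity, degenerate settings, and subset structure", {
  # zero-variance normal: pi = 1, h2 = 0 gives exactly zero shared effects
  cfg0 <- tiny_config(h2_shared = 0, causal_prob = 1, lambda = 0, n_genes = 2)
  tr0 <- simulate_effects(cfg0, simulate_genotypes(cfg0))
  expect_true(all(tr0$genes[[1]]$beta_shared == 0))
  # no specific contexts and no truly-specific additions: all deviations zero
  cfg1 <- tiny_config(frac_contexts_specific = 0, lambda = 0, n_genes = 2)
  tr1 <- simulate_effects(cfg1, simulate_genotypes(cfg1))
  expect_true(all(tr1$genes[[1]]$beta_specific == 0))
  # binomial mean: causal count per gene about M * pi
  cfg2 <- tiny_config(n_genes = 300, n_snps = 100, causal_prob = 0.05)
  tr2 <- simulate_effects(cfg2, simulate_genotypes(cfg2))
  counts <- vapply(tr2$genes, function(tg) length(tg$causal_shared), numeric(1))
  se <- sqrt(100 * 0.05 * 0.95 / 300)
  expect_lt(abs(mean(counts) - 5), 3 * se)
  # truly specific eQTLs avoid shared-causal SNPs
  for (tg in tr2$genes[1:20]) {
    extra <- unlist(tg$truly_specific)
    expect_length(intersect(extra, tg$causal_shared), 0)
  }
})

test_that("expression variance decomposes into heritability plus noise", {
  cfg <- sim_config(n_genes = 20, n_contexts = 6, n_snps = 200,
                    sample_size = c(2000, 2000), h2_shared = 0.5,
                    h2_specific = 0.2, causal_prob = 0.1, rho = 0, seed = 5)
  panel <- simulate_genotypes(cfg)
  truth <- simulate_effects(cfg, panel)
  study <- simulate_expression(cfg, panel, truth, complete = TRUE)
  vtot <- sapply(study$expr, function(E) mean(apply(E, 2, var)))
  expect_lt(abs(mean(vtot) - 1), 0.08)
  # heritability bookkeeping: var(G beta) / var(E) near h2_shared
  hsh <- mapply(function(cmp, E) var(cmp$shared) / mean(apply(E, 2, var)),
                study$components, study$expr)
  expect_lt(abs(mean(hsh) - 0.5), 0.1)
})

test_that("intra-individual noise correlation matches rho", {
  for (rho in c(0, 0.6)) {
    cfg <- sim_config(n_genes = 1, n_contexts = 4, n_snps = 10,
                      sample_size = c(20000, 20000), h2_shared = 0,
                      h2_specific = 0, causal_prob = 0.5, lambda = 0,
                      frac_contexts_specific = 0, rho = rho, seed = 31 + rho)
    panel <- simulate_genotypes(cfg)
    truth <- simulate_effects(cfg, panel)
    study <- simulate_expression(cfg, panel, truth, complete = TRUE)
    cc <- cor(study$expr[[1]])
    off <- cc[upper.tri(cc)]
    expect_true(all(abs(off - rho) < 3 / sqrt(20000) + 0.02))
    expect_lt(abs(mean(apply(study$expr[[1]], 2, var)) - 1), 0.05)
  }
})

test_that("missingness keeps every individual and respects the sample-size range", {
  cfg <- tiny_config(n_genes = 2, sample_size = c(30, 60))
  sim <- simulate_study(cfg, test = FALSE)
  E <- sim$train$expr[[1]]
  expect_true(all(rowSums(!is.na(E)) >= 1))
  sizes <- colSums(!is.na(E))
  expect_true(all(sizes >= 30 & sizes <= 60))
  # same pattern across genes
  expect_identical(is.na(sim$train$expr[[1]]), is.na(sim$train$expr[[2]]))
})

test_that("simulated studies are bit-identical under a fixed seed", {
  cfg <- tiny_config()
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$train$expr, s2$train$expr)
  expect_identical(s1$test$expr, s2$test$expr)
  expect_identical(s1$truth$genes, s2$truth$genes)
})

test_that("phenotypes have unit variance and vanish without genetic share", {
  cfg <- tiny_config(n_genes = 12, n_contexts = 5, n_snps = 40)
  panel <- simulate_genotypes(cfg, n = 8000, seed = 99)
  truth <- simulate_effects(cfg, panel)
  pcfg <- phenotype_config(n_causal_genes = 6, contexts_per_gene = 2,
                           var_explained = 0.2, n_external = 8000)
  ph <- simulate_phenotype(pcfg, panel, truth, seed = 4)
  expect_length(ph$y, 8000)
  expect_equal(nrow(ph$pairs), 12)
  # only 12 causal pairs: the realized genetic variance is itself variable
  expect_lt(abs(var(ph$y) - 1), 0.15)
  ph2 <- simulate_phenotype(pcfg, panel, truth, seed = 4)
  expect_identical(ph$y, ph2$y)
  # sigma_ge^2 = 0: pure noise, uncorrelated with every pair's genetic value
  pcfg0 <- phenotype_config(n_causal_genes = 6, contexts_per_gene = 2,
                            var_explained = 0, n_external = 8000)
  ph0 <- simulate_phenotype(pcfg0, panel, truth, seed = 5)
  comps <- true_components(panel, truth)
  r <- cor(ph0$y, comps[[ph0$pairs$gene[1]]]$total[, ph0$pairs$context[1]])
  expect_lt(abs(r), 4 / sqrt(8000))
  # requesting more causal genes than exist is an error
  expect_error(simulate_phenotype(phenotype_config(n_causal_genes = 50),
                                  panel, truth),
               "fewer heritable genes")
})
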