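#' Prediction-accuracy simulation study
#'
#' The train/test evaluation design: for each intra-individual noise
#' correlation setting, simulate a study, train the requested methods on
#' the training data, and score every gene-context pair on the independent
#' test panel by the adjusted R-squared between each method's predictor
#' and the *true* genetic component of expression. Also records the
#' cross-component leakage of the decomposition-based predictors: how much
#' of the true context-shared component the specific predictor captures in
#' held-out data, and vice versa.
#'
#' @param config a [sim_config()]; its `rho` is overridden per setting.
#' @param rhos intra-individual noise correlations to sweep (default
#'   `c(0, 0.3, 0.6)`).
#' @param methods subset of `c("content", "cbc", "grouplasso")`.
#' @param both_effects_only score only gene-contexts carrying both shared
#'   and specific effects (default `TRUE`).
#' @param cv,nfolds,nlambda,lambda.min.ratio training controls (see
#'   [fit_component()]).
#' @param seed integer seed.
#' @return data.frame with one row per rho/gene/context: test-set adjusted
#'   R-squared of each method against the true total genetic component
#'   (`r2_content_full`, `r2_cbc`, `r2_grouplasso`), and the leakage
#'   scores `r2_specific_vs_true_shared` / `r2_shared_vs_true_specific`.
#' @export
run_prediction_study <- function(config, rhos = c(0, 0.3, 0.6),
                                 methods = c("content", "cbc", "grouplasso"),
                                 both_effects_only = TRUE,
                                 cv = "preval", nfolds = 10, nlambda = 50,
                                 lambda.min.ratio = 0.05, seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  out <- list()
  for (rho in rhos) {
    cfg <- config
    cfg$rho <- rho
    cfg$seed <- derive_seed(seed, paste0("pred-rho-", rho))
    sim <- simulate_study(cfg, test = TRUE)
    test_geno <- sim$test$panel$geno
    comps_true <- sim$test$components
    pred_full <- pred_cbc <- pred_gl <- comp_pred <- NULL
    if ("content" %in% methods) {
      cm <- content_train(sim$train, cv = cv, nfolds = nfolds,
                          nlambda = nlambda,
                          lambda.min.ratio = lambda.min.ratio,
                          seed = derive_seed(cfg$seed, "content"))
      comp_pred <- predict_components(cm, test_geno)
      pred_full <- lapply(comp_pred, `[[`, "full")
    }
    if ("cbc" %in% methods) {
      bm <- cbc_train(sim$train, cv = cv, nfolds = nfolds, nlambda = nlambda,
                      lambda.min.ratio = lambda.min.ratio,
                      seed = derive_seed(cfg$seed, "cbc"))
      pred_cbc <- predict_contexts(bm, test_geno)
    }
    if ("grouplasso" %in% methods) {
      gm <- group_lasso_train(sim$train, seed = derive_seed(cfg$seed, "gl"))
      pred_gl <- predict_contexts(gm, test_geno)
    }
    for (g in names(sim$truth$genes)) {
      tg <- sim$truth$genes[[g]]
      tc <- comps_true[[g]]
      ctxs <- if (both_effects_only && config$h2_shared[1] > 0)
        tg$specific_contexts else colnames(tc$total)
      for (ctx in ctxs) {
        truth_tot <- tc$total[, ctx]
        row <- data.frame(rho = rho, gene = g, context = ctx,
                          r2_content_full = NA_real_, r2_cbc = NA_real_,
                          r2_grouplasso = NA_real_,
                          r2_specific_vs_true_shared = NA_real_,
                          r2_shared_vs_true_specific = NA_real_)
        if (!is.null(pred_full) && !all(is.na(pred_full[[g]][, ctx])))
          row$r2_content_full <- adjusted_r2(truth_tot, pred_full[[g]][, ctx])
        if (!is.null(pred_cbc) && ctx %in% colnames(pred_cbc[[g]]) &&
            !all(is.na(pred_cbc[[g]][, ctx])))
          row$r2_cbc <- adjusted_r2(truth_tot, pred_cbc[[g]][, ctx])
        if (!is.null(pred_gl) && ctx %in% colnames(pred_gl[[g]]) &&
            !all(is.na(pred_gl[[g]][, ctx])))
          row$r2_grouplasso <- adjusted_r2(truth_tot, pred_gl[[g]][, ctx])
        if (!is.null(comp_pred)) {
          sp <- comp_pred[[g]]$specific[, ctx]
          if (!all(is.na(sp)))
            row$r2_specific_vs_true_shared <-
              adjusted_r2(tc$shared, sp)
          row$r2_shared_vs_true_specific <-
            adjusted_r2(tc$specific[, ctx], comp_pred[[g]]$shared)
        }
        out[[length(out) + 1]] <- row
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
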