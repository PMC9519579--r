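#' Fit a penalized genetic predictor for one expression component
#'
#' Elastic-net regression of an expression component on cis genotype
#' dosages with honest out-of-fold predictions. Two cross-validation modes
#' are available:
#' \describe{
#'   \item{`"nested"`}{double cross-validation: an outer 10-fold split
#'     produces out-of-fold predictions, and within each outer training
#'     split an inner 10-fold CV selects the penalty. A final whole-data
#'     refit at the whole-data CV-selected penalty yields export weights.}
#'   \item{`"preval"`}{the prevalidation shortcut: a single 10-fold
#'     `cv.glmnet` with `keep = TRUE`; the out-of-fold predictions come
#'     from models never trained on the predicted fold, while the penalty
#'     is selected on the pooled CV curve. Much cheaper, used by the
#'     simulation sweeps.}
#' }
#' Genotypes are standardized internally during fitting (glmnet) and the
#' exported weights are on the dosage scale.
#'
#' @param y component expression vector (named by individual).
#' @param G dosage matrix, rows aligned with `y`.
#' @param alpha elastic-net mixing parameter (default 0.5, the TWAS
#'   convention).
#' @param nfolds folds for both CV levels (default 10).
#' @param cv `"preval"` or `"nested"`.
#' @param nlambda,lambda.min.ratio penalty path resolution.
#' @param seed integer seed controlling the fold assignment.
#' @param component label stored in the fit (e.g. `"shared"`,
#'   `"specific:context3"`).
#' @return `content_fit` with dosage-scale `weights`, `intercept`,
#'   out-of-fold `preval` predictions, `cv_r2`, `cv_adj_r2`, `lrt_stat`,
#'   `lrt_p`, selected `lambda` and a `null_model` flag (all selected
#'   weights zero).
#' @export
fit_component <- function(y, G, alpha = 0.5, nfolds = 10, cv = c("preval", "nested"),
                          nlambda = 50, lambda.min.ratio = 0.05,
                          seed = 1L, component = "component") {
  cv <- match.arg(cv)
  n <- length(y)
  stopifnot(nrow(G) == n)
  if (n < 20) stop("fit_component requires at least 20 individuals")
  if (any(!is.finite(G))) stop("genotype matrix contains non-finite values")
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(nfolds), n))

  if (cv == "preval") {
    cvfit <- glmnet::cv.glmnet(G, y, alpha = alpha, foldid = foldid,
                               keep = TRUE, nlambda = nlambda,
                               lambda.min.ratio = lambda.min.ratio,
                               standardize = TRUE)
    i <- which(cvfit$lambda == cvfit$lambda.min)[1]
    preval <- cvfit$fit.preval[, i]
    co <- coef(cvfit, s = "lambda.min")
    lambda <- cvfit$lambda.min
  } else {
    preval <- rep(NA_real_, n)
    for (k in seq_len(nfolds)) {
      tr <- foldid != k
      inner <- glmnet::cv.glmnet(G[tr, , drop = FALSE], y[tr], alpha = alpha,
                                 nfolds = nfolds, nlambda = nlambda,
                                 lambda.min.ratio = lambda.min.ratio,
                                 standardize = TRUE)
      preval[!tr] <- predict(inner, G[!tr, , drop = FALSE], s = "lambda.min")
    }
    cvfit <- glmnet::cv.glmnet(G, y, alpha = alpha, foldid = foldid,
                               nlambda = nlambda,
                               lambda.min.ratio = lambda.min.ratio,
                               standardize = TRUE)
    co <- coef(cvfit, s = "lambda.min")
    lambda <- cvfit$lambda.min
  }
  w <- as.numeric(co)[-1]
  names(w) <- colnames(G)
  names(preval) <- names(y) %||% rownames(G)
  lrt <- lrt_significance(y, preval)
  structure(list(
    component = component,
    weights = w, intercept = as.numeric(co)[1],
    lambda = lambda, alpha = alpha,
    preval = preval, y = y, n = n,
    cv_r2 = if (sd(preval) < 1e-12) 0 else cor(y, preval)^2,
    cv_adj_r2 = adjusted_r2(y, preval, p = 1L),
    lrt_stat = lrt$stat, lrt_p = lrt$p,
    null_model = all(w == 0)), class = "content_fit")
}

#' @export
predict.content_fit <- function(object, newdata, ...) {
  missing_snps <- setdiff(names(object$weights), colnames(newdata))
  if (length(missing_snps))
    stop("genotype matrix lacks SNPs: ", paste(head(missing_snps, 5), collapse = ", "))
  drop(object$intercept +
         newdata[, names(object$weights), drop = FALSE] %*% object$weights)
}

#' @export
print.content_fit <- function(x, ...) {
  cat("content_fit [", x$component, "]: n =", x$n,
      " nonzero =", sum(x$weights != 0),
      " cv adj R2 =", signif(x$cv_adj_r2, 3),
      " LRT p =", signif(x$lrt_p, 3), "\n")
  invisible(x)
}

# Plain elastic-net refit at a fixed penalty (exact path endpoint used for
# oracle-equivalence checks; lambda = 0 on n >> M data matches OLS).
enet_refit <- function(G, y, lambda, alpha = 0.5) {
  fit <- glmnet::glmnet(G, y, alpha = alpha,
                        lambda = c(lambda + 1, lambda), standardize = TRUE,
                        thresh = 1e-12)
  co <- coef(fit, s = lambda, exact = TRUE, x = G, y = y)
  setNames(as.numeric(co), c("(Intercept)", colnames(G)))
}

#' Recombine component predictors into a full per-context model
#'
#' Ordinary least squares of the observed context expression on the
#' context-shared and context-specific predictions (intercept included).
#' The regression weights re-scale and, for the specific component,
#' re-sign the deviations so the combination tracks observed expression.
#' A constant predictor is dropped (the model degenerates to a single
#' predictor and is flagged).
#'
#' @param y observed (centered/scaled) expression of the context.
#' @param shared_pred,specific_pred component predictions aligned to `y`
#'   (out-of-fold predictions for honest scoring).
#' @return `content_full` with `w_shared`, `w_specific`, `intercept`,
#'   `fitted`, `cv_r2`, `cv_adj_r2`, 2-df (or degenerate 1-df) `lrt_p`.
#' @export
fit_full <- function(y, shared_pred, specific_pred) {
  stopifnot(length(y) == length(shared_pred),
            length(y) == length(specific_pred))
  X <- cbind(shared = shared_pred, specific = specific_pred)
  keep <- apply(X, 2, sd) > 1e-12
  w <- c(shared = 0, specific = 0)
  if (!any(keep)) {
    fitted <- rep(mean(y), length(y))
    a0 <- mean(y)
  } else {
    fit <- lm.fit(cbind(1, X[, keep, drop = FALSE]), y)
    co <- fit$coefficients
    a0 <- co[1]
    w[names(which(keep))] <- co[-1]
    fitted <- drop(cbind(1, X[, keep, drop = FALSE]) %*% co)
  }
  p_used <- max(1L, sum(keep))
  lrt <- lrt_significance(y, X)
  structure(list(
    w_shared = unname(w["shared"]), w_specific = unname(w["specific"]),
    intercept = unname(a0), fitted = fitted, n = length(y),
    cv_r2 = if (sd(fitted) < 1e-12) 0 else cor(y, fitted)^2,
    cv_adj_r2 = adjusted_r2(y, fitted, p = p_used),
    lrt_stat = lrt$stat, lrt_p = lrt$p, df = lrt$df,
    degenerate = sum(keep) < 2), class = "content_full")
}

#' Combined SNP weights of a full model
#'
#' The full model's per-SNP weight vector is the weighted sum
#' `w_shared * beta_hat + w_specific * gamma_hat_c` of the component
#' weights, so each context exports a single weight vector.
#'
#' @param full a [fit_full()] result.
#' @param shared_fit,specific_fit the component `content_fit`s.
#' @return named numeric vector of dosage-scale weights.
#' @export
combine_weights <- function(full, shared_fit, specific_fit) {
  full$w_shared * shared_fit$weights + full$w_specific * specific_fit$weights
}
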