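#' @importFrom stats coef cor lm lm.fit pchisq pnorm rbinom rnorm rpois runif
#' @importFrom stats sd var predict setNames aggregate qr.resid
#' @importFrom utils head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adjusted coefficient of determination
#'
#' Squared-correlation R-squared between an outcome and a prediction,
#' penalized for the number of predictors:
#' \eqn{1 - (1 - R^2)(n - 1)/(n - p - 1)}.
#'
#' @param y numeric outcome vector.
#' @param yhat numeric prediction vector of the same length.
#' @param p number of predictors used to form `yhat` (default 1).
#' @return scalar adjusted R-squared. A constant `yhat` is treated as
#'   `R^2 = 0` (the prediction carries no signal).
#' @export
adjusted_r2 <- function(y, yhat, p = 1L) {
  stopifnot(length(y) == length(yhat))
  n <- length(y)
  if (n <= p + 1L) stop("adjusted_r2 requires n > p + 1")
  r2 <- if (sd(yhat) < 1e-12 || sd(y) < 1e-12) 0 else cor(y, yhat)^2
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Gaussian likelihood-ratio test against the intercept-only model
#'
#' Profile-likelihood LRT for a linear model: the statistic is
#' \eqn{n \log(RSS_0 / RSS_1)} with one degree of freedom per predictor.
#'
#' @param y outcome vector (need not be centered).
#' @param x predictor vector or matrix with 1 or 2 columns.
#' @return list with `stat`, `df`, `p`.
#' @export
lrt_significance <- function(y, x) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), ncol(x) %in% c(1L, 2L))
  n <- length(y)
  keep <- apply(x, 2, function(col) sd(col) > 1e-12)
  df <- sum(keep)
  rss0 <- sum((y - mean(y))^2)
  if (df == 0L) return(list(stat = 0, df = ncol(x), p = 1))
  fit <- lm.fit(cbind(1, x[, keep, drop = FALSE]), y)
  rss1 <- sum(fit$residuals^2)
  if (rss1 <= 0) return(list(stat = Inf, df = df, p = 0, separation = TRUE))
  stat <- n * log(rss0 / rss1)
  list(stat = stat, df = df, p = pchisq(stat, df = df, lower.tail = FALSE))
}

# Deterministic child seed from a base seed and a label (keeps below 2^31).
derive_seed <- function(seed, salt) {
  s <- sum(utf8ToInt(as.character(salt)) * seq_along(utf8ToInt(as.character(salt))))
  as.integer((as.numeric(seed) * 48271 + s) %% 2147483647)
}

# Population-variance scale (1/n denominator)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Standardize matrix columns with population sd; constant columns become 0.
standardize_cols <- function(G) {
  mu <- colMeans(G)
  s <- sqrt(colMeans(G^2) - mu^2)
  s[s < 1e-12] <- Inf
  Gs <- sweep(sweep(G, 2, mu, "-"), 2, s, "/")
  list(x = Gs, mean = mu, sd = s)
}
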