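#' Survey-weighted mean
#'
#' @param values Numeric vector.
#' @param weights Positive sampling weights, same length.
#' @return \eqn{\sum w_i x_i / \sum w_i}.
#' @export
weighted_mean <- function(values, weights) {
  if (length(values) != length(weights)) stop("values and weights differ in length")
  if (any(weights < 0)) stop("weights must be non-negative")
  sw <- sum(weights)
  if (sw <= 0) stop("weights sum to zero")
  sum(weights * values) / sw
}

#' Validate a survey design table
#'
#' @param design Data.frame with columns \code{stratum}, \code{psu},
#'   \code{weight} (one row per participant).
#' @return Invisibly, the design; errors if weights are non-positive or any
#'   stratum has a single PSU (a certainty PSU leaves no degrees of freedom
#'   for variance estimation; collapse such strata before analysis).
#' @export
validate_design <- function(design) {
  need <- c("stratum", "psu", "weight")
  missing <- setdiff(need, names(design))
  if (length(missing) > 0) {
    stop("design is missing columns: ", paste(missing, collapse = ", "))
  }
  if (any(design$weight <= 0)) stop("design weights must be positive")
  npsu <- tapply(design$psu, design$stratum, function(p) length(unique(p)))
  if (any(npsu < 2)) {
    stop("every stratum needs >= 2 PSUs for variance estimation; ",
         "singleton (certainty) strata should be collapsed with a neighbour")
  }
  invisible(design)
}

# Between-PSU covariance of influence totals: Sum_h n_h/(n_h-1) *
# Sum_c (t_hc - tbar_h)(t_hc - tbar_h)'. z is an n x p matrix of
# per-observation influence contributions.
psu_total_cov <- function(z, strata, psu) {
  z <- as.matrix(z)
  key <- paste(strata, psu, sep = "\r")
  totals <- rowsum(z, key, reorder = FALSE)
  tot_stratum <- strata[!duplicated(key)]
  G <- matrix(0, ncol(z), ncol(z))
  for (h in unique(tot_stratum)) {
    th <- totals[tot_stratum == h, , drop = FALSE]
    nh <- nrow(th)
    d <- sweep(th, 2, colMeans(th))
    G <- G + nh / (nh - 1) * crossprod(d)
  }
  G
}

#' Taylor-linearization SE of a survey-weighted mean
#'
#' Design-based standard error of the ratio-type weighted mean under a
#' stratified PSU design, by linearization: the influence of observation
#' \eqn{i} is \eqn{w_i (x_i - \hat\mu)/\sum w}, and variance is the
#' between-PSU variance of influence totals within strata.
#'
#' @param values Numeric vector.
#' @param design Survey design table (see [validate_design()]).
#' @return Standard error.
#' @export
taylor_se_mean <- function(values, design) {
  validate_design(design)
  mu <- weighted_mean(values, design$weight)
  z <- design$weight * (values - mu) / sum(design$weight)
  sqrt(psu_total_cov(z, design$stratum, design$psu)[1, 1])
}

#' Rao-Wu bootstrap replicate weights
#'
#' For each stratum with \eqn{n_h} PSUs, each replicate resamples
#' \eqn{n_h - 1} PSUs with replacement and rescales weights by
#' \eqn{(n_h/(n_h-1)) k_{hc}}, where \eqn{k_{hc}} counts selections of the
#' observation's PSU, giving design-consistent bootstrap variances.
#'
#' @param design Survey design table.
#' @param replicates Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return An \code{n x replicates} matrix of replicate weights.
#' @export
rao_wu_replicates <- function(design, replicates = 200, seed = 1) {
  validate_design(design)
  set.seed(seed)
  n <- nrow(design)
  key <- paste(design$stratum, design$psu, sep = "\r")
  psu_of_row <- match(key, unique(key))
  psu_stratum <- design$stratum[!duplicated(key)]
  W <- matrix(0, n, replicates)
  for (r in seq_len(replicates)) {
    mult <- numeric(length(psu_stratum))
    for (h in unique(psu_stratum)) {
      idx <- which(psu_stratum == h)
      nh <- length(idx)
      pick <- sample(idx, nh - 1, replace = TRUE)
      counts <- tabulate(match(pick, idx), nbins = nh)
      mult[idx] <- nh / (nh - 1) * counts
    }
    W[, r] <- design$weight * mult[psu_of_row]
  }
  W
}

#' Bootstrap standard error under a complex design
#'
#' Recomputes a statistic on each Rao-Wu replicate-weighted dataset and
#' reports the standard deviation across replicates, with a percentile
#' confidence interval. Any stage of the statistic that depends on weights
#' (including model re-fits) is re-run per replicate by the caller's
#' \code{statistic} function.
#'
#' @param statistic \code{function(data, weights)} returning a numeric vector.
#' @param data Object passed through to \code{statistic}.
#' @param design Survey design table aligned with \code{data} rows.
#' @param replicates Number of replicates (>= 50 for SE reporting).
#' @param seed Integer seed.
#' @param conf Confidence level for the percentile interval.
#' @return List with \code{estimate}, \code{se}, \code{ci} (matrix), and the
#'   replicate estimates.
#' @export
bootstrap_se <- function(statistic, data, design, replicates = 200, seed = 1,
                         conf = 0.95) {
  if (replicates < 50) {
    warning("fewer than 50 replicates gives unstable SEs")
  }
  W <- rao_wu_replicates(design, replicates, seed)
  est <- statistic(data, design$weight)
  reps <- matrix(NA_real_, replicates, length(est))
  for (r in seq_len(replicates)) {
    reps[r, ] <- statistic(data, W[, r])
  }
  alpha <- (1 - conf) / 2
  ci <- t(apply(reps, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE))
  list(estimate = est, se = apply(reps, 2, stats::sd, na.rm = TRUE),
       ci = ci, replicates = reps)
}

#' Survey-weighted linear regression
#'
#' Weighted least squares with design-based (Taylor linearization) variance:
#' point estimates solve \eqn{X'WX\beta = X'Wy}; the covariance of
#' \eqn{\hat\beta} is the sandwich \eqn{A^{-1} G A^{-1}} with \eqn{A = X'WX}
#' and \eqn{G} the stratified between-PSU covariance of the weighted score
#' totals. Degrees of freedom are PSUs minus strata.
#'
#' @param y Response vector.
#' @param X Design matrix (full rank after encoding).
#' @param design Survey design table aligned with rows of \code{X}.
#' @return Object of class \code{svy_lm}: coefficients, vcov, SEs, t and
#'   p-values, 95\% CIs, df, weighted R-squared, residuals.
#' @export
svy_lm <- function(y, X, design) {
  validate_design(design)
  X <- as.matrix(X)
  w <- design$weight
  qrX <- qr(sqrt(w) * X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  A <- crossprod(X, w * X)
  beta <- solve(A, crossprod(X, w * y))
  e <- as.numeric(y - X %*% beta)
  score <- (w * e) * X
  G <- psu_total_cov(score, design$stratum, design$psu)
  Ainv <- solve(A)
  V <- Ainv %*% G %*% Ainv
  dimnames(V) <- list(colnames(X), colnames(X))
  npsu <- length(unique(paste(design$stratum, design$psu)))
  df <- npsu - length(unique(design$stratum))
  se <- sqrt(diag(V))
  tval <- as.numeric(beta) / se
  p <- 2 * stats::pt(-abs(tval), df)
  crit <- stats::qt(0.975, df)
  ybar <- weighted_mean(y, w)
  r2 <- 1 - sum(w * e^2) / sum(w * (y - ybar)^2)
  out <- list(coefficients = stats::setNames(as.numeric(beta), colnames(X)),
              vcov = V, se = se, t = tval, p = p,
              ci = cbind(lower = as.numeric(beta) - crit * se,
                         upper = as.numeric(beta) + crit * se),
              df = df, r_squared = r2, residuals = e, n = length(y))
  class(out) <- "svy_lm"
  out
}

#' Joint Wald test for a block of coefficients
#'
#' Tests that a named set of coefficients is jointly zero using the
#' design-based covariance; referred to an F distribution with
#' (q, df) degrees of freedom, q the block size and df the design degrees
#' of freedom.
#'
#' @param fit A [svy_lm()] fit.
#' @param terms Coefficient names forming the block.
#' @return List with \code{F}, \code{df1}, \code{df2}, \code{p}.
#' @export
wald_test <- function(fit, terms) {
  idx <- match(terms, names(fit$coefficients))
  if (anyNA(idx)) stop("unknown terms: ", paste(terms[is.na(idx)], collapse = ", "))
  b <- fit$coefficients[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  W <- as.numeric(t(b) %*% solve(V, b))
  q <- length(idx)
  Fstat <- W / q
  p <- stats::pf(Fstat, q, fit$df, lower.tail = FALSE)
  list(F = Fstat, df1 = q, df2 = fit$df, p = p)
}
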