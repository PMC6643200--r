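#' Measurement-error model configuration
#'
#' @param method \code{"gibbs"} (blocked Gibbs sampler, the default) or
#'   \code{"moments"} (fast closed-form method-of-moments fit, also used to
#'   initialize the sampler).
#' @param iterations,burn,thin Sampler settings.
#' @param episodic_threshold A component is treated as episodically consumed
#'   when more than this share of recalls report zero intake.
#' @param quadrature_order Gauss-Hermite order for back-transformation bias
#'   correction.
#' @param converge_tol Relative difference between first- and second-half
#'   posterior means of the random-effect total variance below which the fit
#'   is flagged converged.
#' @param prior_weight Strength of the sampler's inverse-Wishart priors as a
#'   fraction of the sample, anchored at the method-of-moments estimates
#'   (empirical Bayes). A nearly flat prior (\code{prior_weight} close to 0)
#'   is not harmless here: with 13+ jointly modelled variables the
#'   inverse-Wishart determinant penalty measurably tilts the weakly
#'   identified between-/within-person variance split, shrinking the
#'   person-effect covariance. Anchoring at the unbiased moments estimate
#'   with modest weight removes that distortion.
#' @param seed Integer seed for the sampler.
#' @return Config list.
#' @export
me_config <- function(method = c("gibbs", "moments"), iterations = 2000,
                      burn = 500, thin = 1, episodic_threshold = 0.1,
                      quadrature_order = 9, converge_tol = 0.2,
                      prior_weight = 0.1, seed = 1) {
  if (prior_weight < 0 || prior_weight > 1) {
    stop("prior_weight must be in [0, 1]")
  }
  list(method = match.arg(method), iterations = iterations, burn = burn,
       thin = thin, episodic_threshold = episodic_threshold,
       quadrature_order = quadrature_order, converge_tol = converge_tol,
       prior_weight = prior_weight, seed = seed)
}

# Fixed-effect design shared by every part of the model: sex, age, heritage,
# field center, weekend (incl. Friday), self-reported usual-amount flag, and
# recall sequence. Factor levels are stored at fit time so reference-context
# matrices can be rebuilt identically; columns constant in the analysis
# sample (e.g. heritage within a single-heritage subgroup) are dropped and
# remembered via `keep`.
build_design <- function(covars, weekend, usual_amount, sequence,
                         info = NULL, keep = NULL) {
  if (is.null(info)) {
    info <- list(heritage = sort(unique(covars$heritage)),
                 field_center = sort(unique(covars$field_center)))
  }
  n <- nrow(covars)
  X <- cbind(
    `(Intercept)` = rep(1, n),
    age_c = (covars$age - 45) / 10,
    male = as.numeric(covars$sex == "male"),
    weekend = as.numeric(weekend),
    usual_more = as.numeric(usual_amount == "more"),
    usual_less = as.numeric(usual_amount == "less"),
    seq2 = as.numeric(sequence == 2)
  )
  for (lv in info$heritage[-1]) {
    X <- cbind(X, as.numeric(covars$heritage == lv))
    colnames(X)[ncol(X)] <- paste0("heritage_", gsub(" ", "_", lv))
  }
  for (lv in info$field_center[-1]) {
    X <- cbind(X, as.numeric(covars$field_center == lv))
    colnames(X)[ncol(X)] <- paste0("center_", gsub(" ", "_", lv))
  }
  if (is.null(keep)) {
    keep <- colnames(X)[c(TRUE, apply(X[, -1, drop = FALSE], 2,
                                      function(col) stats::var(col) > 0))]
  }
  list(X = X[, keep, drop = FALSE], info = info, keep = keep)
}

# Assemble matrices the fitter and conditional sampler share.
prepare_me_data <- function(recalls, covars, config) {
  vars <- intake_variables()
  recalls <- recalls[order(recalls$id, recalls$sequence), ]
  ids <- sort(unique(recalls$id))
  covars <- covars[match(ids, covars$id), , drop = FALSE]
  pid <- match(recalls$id, ids)
  n <- length(ids)
  J <- tabulate(pid, nbins = n)
  if (max(J) > 2) stop("at most 2 recalls per participant are supported")
  if (!any(J == 2)) {
    stop("identifiability requires participants with repeated recalls")
  }

  amounts <- matrix(NA_real_, nrow(recalls), length(vars),
                    dimnames = list(NULL, vars))
  for (v in setdiff(vars, c("fatty_acids", "empty_calories"))) {
    amounts[, v] <- recalls[[v]]
  }
  amounts[, "fatty_acids"] <- if ("fatty_acids" %in% names(recalls)) {
    recalls$fatty_acids
  } else {
    as.numeric(fatty_acid_ratio(recalls$pufa_g, recalls$mufa_g, recalls$sfa_g))
  }
  amounts[, "empty_calories"] <- if ("empty_calories_kcal" %in% names(recalls)) {
    recalls$empty_calories_kcal
  } else {
    recalls$energy * empty_calorie_share(
      recalls$solid_fat_kcal, recalls$added_sugar_kcal,
      recalls$alcohol_g, recalls$energy) / 100
  }

  zero_share <- colMeans(amounts == 0)
  episodic <- setdiff(names(zero_share)[zero_share > config$episodic_threshold],
                      "energy")
  transforms <- lapply(vars, function(v) {
    x <- amounts[, v]
    if (v %in% episodic) x <- x[x > 0]
    make_transform_spec(x, kind = if (v == "fatty_acids") "log" else "boxcox",
                        component = v)
  })
  names(transforms) <- vars

  Yt <- matrix(NA_real_, nrow(amounts), length(vars),
               dimnames = list(NULL, vars))
  for (v in vars) {
    obs <- if (v %in% episodic) amounts[, v] > 0 else rep(TRUE, nrow(amounts))
    Yt[obs, v] <- transform_amount(amounts[obs, v], transforms[[v]])
  }
  C <- matrix(1, nrow(amounts), length(episodic),
              dimnames = list(NULL, episodic))
  for (v in episodic) C[, v] <- as.numeric(amounts[, v] > 0)

  des <- build_design(covars[pid, , drop = FALSE], recalls$weekend,
                      recalls$usual_amount, recalls$sequence)
  list(vars = vars, episodic = episodic, transforms = transforms,
       Yt = Yt, C = C, X = des$X, design_info = des$info,
       design_keep = des$keep, pid = pid, J = J, ids = ids, covars = covars)
}

# Nearest positive-definite projection by eigenvalue clipping.
make_pd <- function(S, eps_frac = 1e-4) {
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE)
  floor_val <- eps_frac * mean(diag(S))
  ev$values <- pmax(ev$values, floor_val)
  out <- ev$vectors %*% diag(ev$values, length(ev$values)) %*% t(ev$vectors)
  dimnames(out) <- dimnames(S)
  out
}

# Probit random-intercept SD from within-person concordance of the two
# recall indicators, by matching E[C1 C2] under a shared normal intercept
# (Gauss-Hermite over the intercept; marginal slopes rescaled by
# sqrt(1 + sigma_v^2)).
probit_sigma_v <- function(eta_m1, eta_m2, concordance) {
  rule <- gh_rule(15)
  f <- function(sv) {
    scale <- sqrt(1 + sv^2)
    val <- 0
    for (q in seq_along(rule$nodes)) {
      v <- sv * rule$nodes[q]
      val <- val + rule$weights[q] *
        mean(stats::pnorm(eta_m1 * scale + v) * stats::pnorm(eta_m2 * scale + v))
    }
    val - concordance
  }
  if (f(0) >= 0) return(0)
  if (f(3) <= 0) return(3)
  stats::uniroot(f, c(0, 3), tol = 1e-4)$root
}

# Method-of-moments fit: per-component least squares for fixed effects,
# within-person covariance from recall differences, between-person
# covariance from person-mean residuals, marginal probit with a
# concordance-based random-intercept variance; cross-blocks by person-level
# covariance approximations. Fast, consistent under the model, and the
# Gibbs initializer.
fit_moments <- function(prep) {
  X <- prep$X
  nv <- length(prep$vars)
  ne <- length(prep$episodic)
  p <- ncol(X)
  beta <- matrix(0, p, nv, dimnames = list(colnames(X), prep$vars))
  Rsd <- matrix(NA_real_, nrow(X), nv, dimnames = list(NULL, prep$vars))
  for (k in seq_len(nv)) {
    obs <- !is.na(prep$Yt[, k])
    fit <- stats::lm.fit(X[obs, , drop = FALSE], prep$Yt[obs, k])
    beta[, k] <- fit$coefficients
    Rsd[obs, k] <- fit$residuals
  }

  two <- which(prep$J == 2)
  r1 <- Rsd[match(two, prep$pid), , drop = FALSE]
  r2 <- Rsd[nrow(Rsd) - match(two, rev(prep$pid)) + 1, , drop = FALSE]
  # rows are sorted by (id, sequence): first occurrence = recall 1, last =
  # recall 2 for two-recall persons.
  D <- r1 - r2
  Se <- stats::cov(D, use = "pairwise.complete.obs") / 2
  Se[is.na(Se)] <- 0
  rbar <- (ifelse(is.na(r1), 0, r1) + ifelse(is.na(r2), 0, r2)) /
    pmax(1, (!is.na(r1)) + (!is.na(r2)))
  rbar[is.na(r1) & is.na(r2)] <- NA
  Sb_a <- stats::cov(rbar, use = "pairwise.complete.obs") - Se / 2
  Sb_a[is.na(Sb_a)] <- 0

  alpha <- matrix(0, p, ne, dimnames = list(colnames(X), prep$episodic))
  sigma_v <- numeric(ne)
  svec <- matrix(NA_real_, length(two), ne)
  lambda <- numeric(ne)
  if (ne > 0) {
    for (j in seq_len(ne)) {
      gl <- suppressWarnings(stats::glm.fit(
        X, prep$C[, j], family = stats::binomial("probit")))
      am <- gl$coefficients
      eta_m <- as.numeric(X %*% am)
      c1 <- prep$C[match(two, prep$pid), j]
      c2 <- prep$C[nrow(prep$C) - match(two, rev(prep$pid)) + 1, j]
      conc <- mean(c1 * c2)
      e1 <- eta_m[match(two, prep$pid)]
      e2 <- eta_m[nrow(X) - match(two, rev(prep$pid)) + 1]
      sigma_v[j] <- probit_sigma_v(e1, e2, conc)
      alpha[, j] <- am * sqrt(1 + sigma_v[j]^2)
      svec[, j] <- (c1 + c2) / 2 - (stats::pnorm(e1) + stats::pnorm(e2)) / 2
      lambda[j] <- mean(stats::dnorm(eta_m))
    }
  }

  d <- nv + ne
  bnames <- c(prep$vars, prob_names(prep$episodic))
  Sb <- matrix(0, d, d, dimnames = list(bnames, bnames))
  Sb[1:nv, 1:nv] <- Sb_a
  if (ne > 0) {
    rb2 <- rbar
    for (j in seq_len(ne)) {
      for (k in seq_len(nv)) {
        cv <- stats::cov(svec[, j], rb2[, k], use = "complete.obs")
        Sb[nv + j, k] <- Sb[k, nv + j] <- cv / max(lambda[j], 1e-3)
      }
      for (j2 in seq_len(ne)) {
        if (j2 == j) {
          Sb[nv + j, nv + j] <- sigma_v[j]^2
        } else {
          cv <- stats::cov(svec[, j], svec[, j2], use = "complete.obs")
          Sb[nv + j, nv + j2] <- cv / max(lambda[j] * lambda[j2], 1e-4)
        }
      }
    }
  }
  Sb <- make_pd(Sb)
  Se <- make_pd(Se)
  list(beta = beta, alpha = alpha, Sigma_b = Sb, Sigma_e = Se,
       diagnostics = list(method = "moments", converged = TRUE))
}

riwish <- function(nu, S) {
  W <- stats::rWishart(1, nu, solve(S))[, , 1]
  V <- solve(W)
  (V + t(V)) / 2
}

# Blocked Gibbs sampler with data augmentation: latent probit scores for
# episodic consumption, conditional-normal imputation of transformed
# amounts on non-consumption days, vectorized conjugate updates of person
# effects (shared posterior precision within recall-count groups), matrix
# normal updates of the fixed effects, and inverse-Wishart updates of the
# covariances. Weakly informative priors center the covariances on the
# moment estimates with prior weight of about one observation.
fit_gibbs <- function(prep, init, config) {
  set.seed(config$seed)
  X <- prep$X
  R <- nrow(X)
  n <- length(prep$ids)
  nv <- length(prep$vars)
  ne <- length(prep$episodic)
  d <- nv + ne
  p <- ncol(X)
  pid <- prep$pid

  B <- init$beta
  A <- init$alpha
  Se <- init$Sigma_e
  Sb <- init$Sigma_b
  # Empirical-Bayes inverse-Wishart priors anchored at the moments
  # estimates. The prior carries `prior_weight` of the sample's worth of
  # pseudo-observations: a nearly flat inverse-Wishart (df ~ dimension)
  # would bias the between-/within split at this dimension (see
  # ?me_config).
  we <- max(1, ceiling(config$prior_weight * R))
  wb <- max(1, ceiling(config$prior_weight * n))
  nu0e <- nv + 1 + we
  S0e <- Se * we
  nu0b <- d + 1 + wb
  S0b <- Sb * wb

  cholXX <- chol(crossprod(X) + diag(1e-8, p))
  epi_col <- match(prep$episodic, prep$vars)
  miss <- is.na(prep$Yt)
  pattern <- apply(miss[, epi_col, drop = FALSE], 1, function(m)
    paste(as.integer(m), collapse = ""))
  pat_levels <- unique(pattern)
  Y <- prep$Yt
  # start imputation at the fixed-effect prediction
  mu0 <- X %*% B
  Y[miss] <- mu0[miss]
  Z <- matrix(0, R, ne)
  if (ne > 0) Z <- (prep$C - 0.5) * 2 * 0.5
  U <- matrix(0, n, d)

  n_keep <- 0
  sumB <- 0 * B; sumA <- 0 * A; sumSe <- 0 * Se; sumSb <- 0 * Sb
  sumU <- matrix(0, n, d)
  trace_tr <- numeric(0)

  Jgroups <- split(seq_len(n), prep$J)

  for (it in seq_len(config$iterations)) {
    mu <- X %*% B + U[pid, 1:nv, drop = FALSE]
    # 1. impute unobserved episodic amounts from their conditional normal
    for (pt in pat_levels) {
      m_idx <- epi_col[strsplit(pt, "")[[1]] == "1"]
      if (length(m_idx) == 0) next
      rows <- which(pattern == pt)
      o_idx <- setdiff(seq_len(nv), m_idx)
      K <- Se[m_idx, o_idx, drop = FALSE] %*%
        solve(Se[o_idx, o_idx, drop = FALSE] + diag(1e-10, length(o_idx)))
      Scond <- Se[m_idx, m_idx, drop = FALSE] -
        K %*% Se[o_idx, m_idx, drop = FALSE]
      Scond <- make_pd(Scond, 1e-10)
      cm <- mu[rows, m_idx, drop = FALSE] +
        (Y[rows, o_idx, drop = FALSE] - mu[rows, o_idx, drop = FALSE]) %*% t(K)
      Y[rows, m_idx] <- cm + matrix(stats::rnorm(length(rows) * length(m_idx)),
                                    length(rows)) %*% chol(Scond)
    }
    # 2. truncated-normal probit latents
    if (ne > 0) {
      etaZ <- X %*% A + U[pid, nv + seq_len(ne), drop = FALSE]
      plo <- stats::pnorm(-etaZ)
      uu <- matrix(stats::runif(R * ne), R, ne)
      pr <- ifelse(prep$C == 1, plo + uu * (1 - plo), uu * plo)
      pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
      Z <- etaZ + stats::qnorm(pr)
    }
    # 3. person effects: conjugate normal with shared precision per
    #    recall-count group
    resid <- cbind(Y - X %*% B, if (ne > 0) Z - X %*% A)
    S <- rowsum(resid, pid)
    Sbinv <- solve(Sb + diag(1e-10, d))
    Seinv <- solve(Se + diag(1e-10, nv))
    Dinv <- matrix(0, d, d)
    Dinv[1:nv, 1:nv] <- Seinv
    if (ne > 0) Dinv[nv + seq_len(ne), nv + seq_len(ne)] <- diag(1, ne)
    for (g in names(Jgroups)) {
      idx <- Jgroups[[g]]
      P <- Sbinv + as.numeric(g) * Dinv
      Pinv <- chol2inv(chol(P))
      means <- S[idx, , drop = FALSE] %*% Dinv %*% Pinv
      U[idx, ] <- means + matrix(stats::rnorm(length(idx) * d),
                                 length(idx)) %*% chol(Pinv)
    }
    # 4./5. fixed effects (matrix-normal conjugate draws)
    Ytil <- Y - U[pid, 1:nv, drop = FALSE]
    Bhat <- backsolve(cholXX,
                      forwardsolve(t(cholXX), crossprod(X, Ytil)))
    B <- Bhat + backsolve(cholXX, matrix(stats::rnorm(p * nv), p, nv)) %*%
      chol(Se + diag(1e-10, nv))
    dimnames(B) <- dimnames(init$beta)
    if (ne > 0) {
      Ztil <- Z - U[pid, nv + seq_len(ne), drop = FALSE]
      Ahat <- backsolve(cholXX,
                        forwardsolve(t(cholXX), crossprod(X, Ztil)))
      A <- Ahat + backsolve(cholXX, matrix(stats::rnorm(p * ne), p, ne))
      dimnames(A) <- dimnames(init$alpha)
    }
    # 6./7. covariances
    Res <- Ytil - X %*% B
    Se <- riwish(nu0e + R, S0e + crossprod(Res))
    Sb <- riwish(nu0b + n, S0b + crossprod(U))
    dimnames(Se) <- dimnames(init$Sigma_e)
    dimnames(Sb) <- dimnames(init$Sigma_b)

    if (it > config$burn && (it - config$burn) %% config$thin == 0) {
      n_keep <- n_keep + 1
      sumB <- sumB + B; sumA <- sumA + A
      sumSe <- sumSe + Se; sumSb <- sumSb + Sb
      sumU <- sumU + U
      trace_tr <- c(trace_tr, sum(diag(Sb)))
    }
  }
  half <- length(trace_tr) %/% 2
  conv <- if (half >= 2) {
    m1 <- mean(trace_tr[seq_len(half)])
    m2 <- mean(trace_tr[(half + 1):length(trace_tr)])
    abs(m2 - m1) / max(abs(m1), 1e-8) < config$converge_tol
  } else TRUE
  list(beta = sumB / n_keep, alpha = sumA / n_keep,
       Sigma_b = make_pd(sumSb / n_keep), Sigma_e = make_pd(sumSe / n_keep),
       u_mean = sumU / n_keep,
       diagnostics = list(method = "gibbs", iterations = config$iterations,
                          burn = config$burn, kept = n_keep,
                          converged = conv, trace = trace_tr))
}

#' Fit the multivariate usual-intake measurement-error model
#'
#' Fits the joint two-part nonlinear mixed model for 12 dietary components
#' plus energy from up to two 24-h recalls per participant: transformed-scale
#' amounts (Box-Cox 0.25, log for the fatty-acid ratio; centered and scaled
#' to variance 2) with correlated person effects and day-to-day residuals,
#' and a probit consumption submodel with its own correlated person effect
#' for each episodically consumed component. All parts adjust for sex, age,
#' heritage, field center, weekend (including Friday), self-reported
#' usual-amount flag, and recall sequence.
#'
#' @param recalls Recall table (see [generate_recalls()] for columns).
#' @param covars Participant covariate table.
#' @param config [me_config()] settings.
#' @return An object of class \code{me_model}: fixed effects \code{beta}
#'   (amounts) and \code{alpha} (consumption probits), random-effect
#'   covariance \code{Sigma_b}, residual covariance \code{Sigma_e},
#'   transforms, episodic classification, diagnostics, and the prepared
#'   data needed for conditional usual-intake draws.
#' @export
fit_me_model <- function(recalls, covars, config = me_config()) {
  prep <- prepare_me_data(recalls, covars, config)
  init <- fit_moments(prep)
  fit <- if (config$method == "gibbs") {
    fit_gibbs(prep, init, config)
  } else {
    init
  }
  out <- list(components = prep$vars, episodic = prep$episodic,
              transforms = prep$transforms,
              beta = fit$beta, alpha = fit$alpha,
              Sigma_b = fit$Sigma_b, Sigma_e = fit$Sigma_e,
              design_info = prep$design_info, design_keep = prep$design_keep,
              prep = prep, config = config, diagnostics = fit$diagnostics)
  class(out) <- "me_model"
  out
}

#' @export
print.me_model <- function(x, ...) {
  cat("Multivariate usual-intake measurement-error model\n")
  cat("  participants:", length(x$prep$ids),
      " recalls:", nrow(x$prep$X), "\n")
  cat("  episodic components:",
      if (length(x$episodic)) paste(x$episodic, collapse = ", ") else "none",
      "\n")
  cat("  method:", x$diagnostics$method,
      " converged:", isTRUE(x$diagnostics$converged), "\n")
  invisible(x)
}

#' Serialize a fitted model to JSON-compatible structure
#'
#' All matrices, transform parameters and diagnostics as plain lists, for
#' audit or archiving (the prepared data matrices are omitted).
#'
#' @param model An \code{me_model}.
#' @return A nested list of plain vectors/matrices.
#' @export
me_model_bundle <- function(model) {
  list(components = model$components, episodic = model$episodic,
       beta = model$beta, alpha = model$alpha,
       Sigma_b = model$Sigma_b, Sigma_e = model$Sigma_e,
       transforms = lapply(model$transforms, unclass),
       diagnostics = model$diagnostics[c("method", "converged")])
}
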