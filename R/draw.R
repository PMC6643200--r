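# Fixed-parameter conditional sampler for person effects: iterates the
# fitter's augmentation steps (impute unobserved episodic amounts, draw
# truncated probit latents, draw person effects from their conjugate
# conditional) with the fitted parameters held fixed, so collected person
# effects are draws from their posterior given each participant's recalls
# and covariates.
conditional_u_draws <- function(model, M, burn = 50, thin = 2, seed = 1) {
  set.seed(seed)
  prep <- model$prep
  X <- prep$X
  R <- nrow(X)
  n <- length(prep$ids)
  nv <- length(prep$vars)
  ne <- length(prep$episodic)
  d <- nv + ne
  pid <- prep$pid
  B <- model$beta
  A <- model$alpha
  Se <- model$Sigma_e
  Sb <- model$Sigma_b

  epi_col <- match(prep$episodic, prep$vars)
  miss <- is.na(prep$Yt)
  pattern <- apply(miss[, epi_col, drop = FALSE], 1, function(m)
    paste(as.integer(m), collapse = ""))
  pat_levels <- unique(pattern)
  # Precompute per-pattern conditional maps (parameters are fixed here).
  pat_maps <- lapply(pat_levels, function(pt) {
    m_idx <- epi_col[strsplit(pt, "")[[1]] == "1"]
    if (length(m_idx) == 0) return(NULL)
    o_idx <- setdiff(seq_len(nv), m_idx)
    K <- Se[m_idx, o_idx, drop = FALSE] %*%
      solve(Se[o_idx, o_idx, drop = FALSE] + diag(1e-10, length(o_idx)))
    list(m = m_idx, o = o_idx, K = K,
         cholS = chol(make_pd(Se[m_idx, m_idx, drop = FALSE] -
                                K %*% Se[o_idx, m_idx, drop = FALSE], 1e-10)))
  })
  names(pat_maps) <- pat_levels

  muB <- X %*% B
  etaA <- if (ne > 0) X %*% A else matrix(0, R, 0)
  Y <- prep$Yt
  Y[miss] <- muB[miss]
  U <- matrix(0, n, d)

  Sbinv <- solve(Sb + diag(1e-10, d))
  Seinv <- solve(Se + diag(1e-10, nv))
  Dinv <- matrix(0, d, d)
  Dinv[1:nv, 1:nv] <- Seinv
  if (ne > 0) Dinv[nv + seq_len(ne), nv + seq_len(ne)] <- diag(1, ne)
  Jgroups <- split(seq_len(n), prep$J)
  Pmaps <- lapply(names(Jgroups), function(g) {
    P <- Sbinv + as.numeric(g) * Dinv
    Pinv <- chol2inv(chol(P))
    list(Pinv = Pinv, cholPinv = chol(make_pd(Pinv, 1e-12)))
  })
  names(Pmaps) <- names(Jgroups)

  draws <- array(NA_real_, c(n, d, M))
  kept <- 0
  total_iters <- burn + M * thin
  for (it in seq_len(total_iters)) {
    mu <- muB + U[pid, 1:nv, drop = FALSE]
    for (pt in pat_levels) {
      mp <- pat_maps[[pt]]
      if (is.null(mp)) next
      rows <- which(pattern == pt)
      cm <- mu[rows, mp$m, drop = FALSE] +
        (Y[rows, mp$o, drop = FALSE] - mu[rows, mp$o, drop = FALSE]) %*% t(mp$K)
      Y[rows, mp$m] <- cm +
        matrix(stats::rnorm(length(rows) * length(mp$m)), length(rows)) %*%
        mp$cholS
    }
    if (ne > 0) {
      etaZ <- etaA + U[pid, nv + seq_len(ne), drop = FALSE]
      plo <- stats::pnorm(-etaZ)
      uu <- matrix(stats::runif(R * ne), R, ne)
      pr <- ifelse(prep$C == 1, plo + uu * (1 - plo), uu * plo)
      pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
      Z <- etaZ + stats::qnorm(pr)
    } else {
      Z <- matrix(0, R, 0)
    }
    S <- rowsum(cbind(Y - muB, Z - etaA), pid)
    for (g in names(Jgroups)) {
      idx <- Jgroups[[g]]
      mp <- Pmaps[[g]]
      means <- S[idx, , drop = FALSE] %*% Dinv %*% mp$Pinv
      U[idx, ] <- means + matrix(stats::rnorm(length(idx) * d),
                                 length(idx)) %*% mp$cholPinv
    }
    if (it > burn && (it - burn) %% thin == 0) {
      kept <- kept + 1
      draws[, , kept] <- U
    }
  }
  draws
}

# Reference-context design matrix for usual-intake prediction: each
# participant's own covariates with weekend = weekday, sequence = first,
# usual amount = "same"; optionally age fixed and sex overridden for
# age/sex standardization.
reference_design <- function(model, age = NULL, sex = NULL) {
  covars <- model$prep$covars
  if (!is.null(age)) covars$age <- age
  if (!is.null(sex)) covars$sex <- sex
  build_design(covars, weekend = rep(FALSE, nrow(covars)),
               usual_amount = rep("same", nrow(covars)),
               sequence = rep(1L, nrow(covars)),
               info = model$design_info, keep = model$design_keep)$X
}

#' Draw usual-intake vectors for each participant
#'
#' Draws person effects from their posterior given the participant's recalls
#' and covariates (a fixed-parameter run of the fitter's augmentation
#' sampler) and converts each draw to a natural-scale usual intake: the
#' within-person expectation of the back-transformed daily amount (Gauss-
#' Hermite over the component's residual), times the consumption probability
#' for episodic components. Recall context is set to its reference levels
#' (weekday, first recall, usual amount "same").
#'
#' @param model A fitted \code{me_model}.
#' @param M Draws per participant (100 by convention).
#' @param seed Integer seed.
#' @param standardize Optional list \code{list(age =, pct_male =)}: fixes
#'   age and marginalizes sex to the given percent male (sex resampled per
#'   draw), for age/sex-standardized summaries.
#' @param burn,thin Conditional-sampler settings.
#' @return Data.frame with \code{id}, \code{draw}, usual amounts for the 10
#'   components and energy, \code{fatty_acids} ratio and
#'   \code{empty_calories_kcal} (an intake-profile table scoreable by
#'   [score_profile()]).
#' @export
draw_usual <- function(model, M = 100, seed = 1, standardize = NULL,
                       burn = 50, thin = 2) {
  if (M < 1) stop("M must be >= 1")
  prep <- model$prep
  n <- length(prep$ids)
  nv <- length(prep$vars)
  ne <- length(model$episodic)
  udraws <- conditional_u_draws(model, M, burn = burn, thin = thin,
                                seed = seed)

  if (is.null(standardize)) {
    Xr <- reference_design(model)
    lp_base <- Xr %*% model$beta                       # n x nv
    eta_base <- if (ne > 0) Xr %*% model$alpha else matrix(0, n, 0)
    male_extra <- NULL
  } else {
    Xr <- reference_design(model, age = standardize$age,
                           sex = rep("female", n))
    lp_base <- Xr %*% model$beta
    eta_base <- if (ne > 0) Xr %*% model$alpha else matrix(0, n, 0)
    set.seed(seed + 7)
    male_extra <- matrix(stats::runif(n * M) < standardize$pct_male / 100,
                         n, M)
  }

  rule <- gh_rule(model$config$quadrature_order)
  has_male <- "male" %in% rownames(model$beta)
  bmale <- if (has_male) model$beta["male", ] else rep(0, nv)
  amale <- if (has_male && ne > 0) model$alpha["male", ] else rep(0, max(ne, 1))
  usual <- array(NA_real_, c(n, M, nv))
  for (k in seq_len(nv)) {
    v <- prep$vars[k]
    m_mat <- matrix(lp_base[, k], n, M) + udraws[, k, ]
    if (!is.null(male_extra)) {
      m_mat <- m_mat + bmale[k] * male_extra
    }
    sd_e <- sqrt(model$Sigma_e[k, k])
    spec <- model$transforms[[v]]
    inv <- function(t) inverse_transform(t, spec)
    usual[, , k] <- gh_expect(m_mat, sd_e, inv, rule)
    if (v %in% model$episodic) {
      j <- match(v, model$episodic)
      eta <- matrix(eta_base[, j], n, M) + udraws[, nv + j, ]
      if (!is.null(male_extra)) {
        eta <- eta + amale[j] * male_extra
      }
      usual[, , k] <- usual[, , k] * stats::pnorm(eta)
    }
  }

  out <- data.frame(id = rep(prep$ids, M),
                    draw = rep(seq_len(M), each = n))
  for (k in seq_len(nv)) {
    v <- prep$vars[k]
    col <- as.numeric(usual[, , k])
    if (v == "empty_calories") {
      out$empty_calories_kcal <- col
    } else {
      out[[v]] <- col
    }
  }
  out$energy <- pmax(out$energy, 1)
  out
}
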