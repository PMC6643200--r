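#' Modelled intake variables
#'
#' The measurement-error model treats 13 variables jointly: the 10 directly
#' measured HEI component amounts, the fatty-acid ratio, empty-calorie
#' energy, and total energy.
#'
#' @return Character vector of the 13 modelled variable names.
#' @export
intake_variables <- function() {
  c("total_fruit", "whole_fruit", "total_veg", "greens_beans",
    "whole_grains", "dairy", "total_protein", "seafood_plant_prot",
    "fatty_acids", "refined_grains", "sodium", "empty_calories", "energy")
}

#' Synthetic-cohort configuration
#'
#' Defines the data-generating process the analysis assumes: person-level
#' usual intakes drawn on the transformed scale (Box-Cox 0.25 for amounts
#' and energy, log for the fatty-acid ratio) from a multivariate normal with
#' covariate effects, a probit consumption submodel for episodically
#' consumed components, large within-person day-to-day noise, and a
#' stratified two-stage weighted survey design. Defaults emulate an urban
#' Hispanic/Latino adult cohort: median intakes around 1 cup fruit, 1.8 cup
#' vegetables, 2 cup dairy, 6 oz protein foods, 5.5 oz refined grains, 3 g
#' sodium and 2000 kcal/day, episodic greens/beans, whole grains and
#' seafood/plant proteins consumed on roughly 45-70% of days, and day-to-day
#' variances about three times the between-person variances.
#'
#' @param n Number of participants.
#' @param n_strata,psus_per_stratum Survey design dimensions (every stratum
#'   gets at least 2 PSUs).
#' @param weight_log_sd SD of log sampling weights (weight variation).
#' @param heritage_probs Named probabilities over the six heritage groups.
#' @param episodic Components with a consumption-probability part.
#' @param p_second_recall Probability a participant completes the second
#'   recall.
#' @param mu Named transformed-scale medians for the 13 intake variables.
#' @param sigma_b,sigma_e Named between- and within-person SDs
#'   (transformed scale) for the 13 variables.
#' @param cor_b,cor_e Exchangeable between-/within-person correlations.
#' @param cor_b_cross Correlation between an episodic component's
#'   consumption-propensity effect and its own amount effect.
#' @param probit_mu Named probit intercepts (conditional scale) for the
#'   episodic components.
#' @param sigma_v Between-person SD of the probit random effects.
#' @param beta_age Named effects per decade of age (centered at 45 y).
#' @param beta_male Named male-vs-female effects.
#' @param weekend_effect,sequence_effect Named recall-level effects
#'   (weekend including Friday; second vs first recall).
#' @param usual_amount_effect Shift for self-reported "more"/"less" than
#'   usual intake (+/-, applied to all amount variables).
#' @param usual_amount_probs Probabilities of reporting more/same/less.
#' @param heritage_effects Optional 6 x 13 matrix of heritage shifts.
#' @param misspecified If TRUE, within-person noise is drawn from a shifted
#'   chi-square (skewed) instead of a normal, for robustness experiments.
#' @return A config list (class \code{cohort_config}).
#' @export
cohort_config <- function(
    n = 2000,
    n_strata = 8,
    psus_per_stratum = 4,
    weight_log_sd = 0.5,
    heritage_probs = c("Mexican" = 0.4106, "Central American" = 0.1092,
                       "Cuban" = 0.1483, "Dominican" = 0.0929,
                       "Puerto Rican" = 0.1709, "South American" = 0.0681),
    episodic = c("greens_beans", "whole_grains", "seafood_plant_prot"),
    p_second_recall = 1.0,
    mu = c(total_fruit = 0.00, whole_fruit = -0.72, total_veg = 0.63,
           greens_beans = -0.64, whole_grains = 0.50, dairy = 0.76,
           total_protein = 2.26, seafood_plant_prot = 0.43,
           fatty_acids = 0.64, refined_grains = 2.13, sodium = 1.26,
           empty_calories = 14.7, energy = 22.75),
    sigma_b = c(total_fruit = 0.45, whole_fruit = 0.45, total_veg = 0.40,
                greens_beans = 0.45, whole_grains = 0.50, dairy = 0.45,
                total_protein = 0.35, seafood_plant_prot = 0.45,
                fatty_acids = 0.25, refined_grains = 0.35, sodium = 0.25,
                empty_calories = 1.50, energy = 1.00),
    sigma_e = c(total_fruit = 0.80, whole_fruit = 0.80, total_veg = 0.70,
                greens_beans = 0.80, whole_grains = 0.85, dairy = 0.80,
                total_protein = 0.60, seafood_plant_prot = 0.80,
                fatty_acids = 0.45, refined_grains = 0.65, sodium = 0.50,
                empty_calories = 2.50, energy = 1.70),
    cor_b = 0.20, cor_e = 0.15, cor_b_cross = 0.35,
    probit_mu = c(greens_beans = -0.16, whole_grains = 0.67,
                  seafood_plant_prot = 0.16),
    sigma_v = 0.80,
    beta_age = c(total_fruit = 0.06, whole_fruit = 0.06, total_veg = 0.06,
                 greens_beans = 0.04, whole_grains = 0.04, dairy = 0.00,
                 total_protein = 0.00, seafood_plant_prot = 0.04,
                 fatty_acids = 0.02, refined_grains = -0.04, sodium = 0.00,
                 empty_calories = -0.10, energy = -0.20),
    beta_male = c(total_fruit = -0.10, whole_fruit = -0.10, total_veg = 0.00,
                  greens_beans = 0.00, whole_grains = 0.00, dairy = 0.00,
                  total_protein = 0.20, seafood_plant_prot = 0.00,
                  fatty_acids = 0.00, refined_grains = 0.20, sodium = 0.15,
                  empty_calories = 0.30, energy = 1.20),
    weekend_effect = c(total_fruit = 0.00, whole_fruit = 0.00,
                       total_veg = 0.00, greens_beans = 0.00,
                       whole_grains = 0.00, dairy = 0.00,
                       total_protein = 0.00, seafood_plant_prot = 0.00,
                       fatty_acids = 0.00, refined_grains = 0.00,
                       sodium = 0.00, empty_calories = 0.30, energy = 0.30),
    sequence_effect = c(total_fruit = 0.00, whole_fruit = 0.00,
                        total_veg = 0.00, greens_beans = 0.00,
                        whole_grains = 0.00, dairy = 0.00,
                        total_protein = 0.00, seafood_plant_prot = 0.00,
                        fatty_acids = 0.00, refined_grains = 0.00,
                        sodium = 0.00, empty_calories = 0.00, energy = -0.15),
    usual_amount_effect = 0.25,
    usual_amount_probs = c(more = 0.2, same = 0.6, less = 0.2),
    heritage_effects = NULL,
    misspecified = FALSE) {
  vars <- intake_variables()
  stopifnot(n >= 1, psus_per_stratum >= 2, n_strata >= 1,
            p_second_recall >= 0, p_second_recall <= 1)
  heritage_probs <- heritage_probs / sum(heritage_probs)
  if (is.null(heritage_effects)) {
    heritage_effects <- matrix(0, length(heritage_probs), length(vars),
                               dimnames = list(names(heritage_probs), vars))
    heritage_effects["Mexican", "whole_grains"] <- 0.50
    heritage_effects["Dominican", "total_fruit"] <- 0.30
    heritage_effects["Puerto Rican", "empty_calories"] <- 0.30
  }
  for (nmvec in list(mu, sigma_b, sigma_e, beta_age, beta_male,
                     weekend_effect, sequence_effect)) {
    stopifnot(all(vars %in% names(nmvec)))
  }
  stopifnot(all(sigma_b[vars] > 0), all(sigma_e[vars] > 0), sigma_v > 0)
  stopifnot(all(episodic %in% names(probit_mu)))
  cfg <- list(n = n, n_strata = n_strata, psus_per_stratum = psus_per_stratum,
              weight_log_sd = weight_log_sd, heritage_probs = heritage_probs,
              episodic = episodic, p_second_recall = p_second_recall,
              mu = mu[vars], sigma_b = sigma_b[vars], sigma_e = sigma_e[vars],
              cor_b = cor_b, cor_e = cor_e, cor_b_cross = cor_b_cross,
              probit_mu = probit_mu[episodic], sigma_v = sigma_v,
              beta_age = beta_age[vars], beta_male = beta_male[vars],
              weekend_effect = weekend_effect[vars],
              sequence_effect = sequence_effect[vars],
              usual_amount_effect = usual_amount_effect,
              usual_amount_probs = usual_amount_probs,
              heritage_effects = heritage_effects,
              misspecified = misspecified)
  class(cfg) <- "cohort_config"
  cfg
}

prob_names <- function(episodic) {
  if (length(episodic)) paste0("prob_", episodic) else character(0)
}

# Exchangeable correlation matrix with unit diagonal.
exch_cor <- function(d, rho) {
  m <- matrix(rho, d, d)
  diag(m) <- 1
  m
}

# Full random-effect covariance: 13 amount effects + one propensity effect
# per episodic component, exchangeable within blocks, with a stronger link
# between an episodic component's propensity and its own amount.
build_sigma_b <- function(cfg) {
  vars <- intake_variables()
  ne <- length(cfg$episodic)
  d <- length(vars) + ne
  sds <- c(cfg$sigma_b, rep(cfg$sigma_v, ne))
  R <- exch_cor(d, cfg$cor_b * 0.5)
  R[seq_along(vars), seq_along(vars)] <- exch_cor(length(vars), cfg$cor_b)
  for (j in seq_len(ne)) {
    k <- match(cfg$episodic[j], vars)
    R[length(vars) + j, k] <- R[k, length(vars) + j] <- cfg$cor_b_cross
  }
  S <- diag(sds) %*% R %*% diag(sds)
  nm <- c(vars, prob_names(cfg$episodic))
  dimnames(S) <- list(nm, nm)
  S
}

build_sigma_e <- function(cfg) {
  vars <- intake_variables()
  S <- diag(cfg$sigma_e) %*% exch_cor(length(vars), cfg$cor_e) %*%
    diag(cfg$sigma_e)
  dimnames(S) <- list(vars, vars)
  S
}

# Inverse Box-Cox with lambda = 0.25 and no shift (generator scale).
bc_inv <- function(t) pmax(0, 1 + 0.25 * t)^4
bc_fwd <- function(x) (x^0.25 - 1) / 0.25

#' Generate a synthetic cohort with known usual-intake truth
#'
#' Draws participant covariates, a stratified two-stage survey design with
#' variable weights, and person-level true usual intakes: transformed-scale
#' person means for the 13 intake variables (including covariate effects and
#' correlated person effects) and per-day consumption propensities for the
#' episodic components.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return List with \code{covariates}, \code{design}, and \code{truth}
#'   (transformed-scale person means \code{mean_t}, probit linear predictors
#'   \code{probit_eta}, consumption probabilities \code{prob}, and the
#'   config).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  cfg <- config
  set.seed(seed)
  n <- cfg$n
  vars <- intake_variables()

  age <- pmin(74, pmax(18, round(stats::rnorm(n, 41.3, 14.5))))
  sex <- sample(c("male", "female"), n, replace = TRUE,
                prob = c(0.4776, 0.5224))
  heritage <- sample(names(cfg$heritage_probs), n, replace = TRUE,
                     prob = cfg$heritage_probs)
  field_center <- sample(c("Bronx", "Chicago", "Miami", "San Diego"), n,
                         replace = TRUE)
  covars <- data.frame(
    id = seq_len(n), age = age, sex = sex, heritage = heritage,
    field_center = field_center,
    education = sample(c("lt_hs", "hs", "gt_hs"), n, TRUE, c(0.35, 0.27, 0.38)),
    income = sample(c("lt10k", "10_20k", "20_40k", "40_75k", "gt75k"), n, TRUE,
                    c(0.18, 0.32, 0.34, 0.12, 0.04)),
    employment = sample(c("employed", "unemployed", "retired"), n, TRUE,
                        c(0.52, 0.35, 0.13)),
    marital = sample(c("single", "married", "sep_div_wid"), n, TRUE,
                     c(0.30, 0.50, 0.20)),
    bmi_group = sample(c("underweight", "normal", "overweight", "obese"), n,
                       TRUE, c(0.02, 0.22, 0.37, 0.39)),
    smoking = sample(c("never", "former", "current"), n, TRUE,
                     c(0.61, 0.19, 0.20)),
    activity = sample(c("inactive", "low", "medium", "high"), n, TRUE,
                      c(0.38, 0.20, 0.20, 0.22)),
    language_preference = sample(c("Spanish", "English"), n, TRUE,
                                 c(0.81, 0.19)),
    sash_language = pmin(5, pmax(1, round(stats::rnorm(n, 2.3, 1.1), 1))),
    sash_social = pmin(5, pmax(1, round(stats::rnorm(n, 2.6, 0.8), 1))),
    us_born = stats::runif(n) < 0.16,
    years_us = round(pmax(0, pmin(age - 15, stats::rexp(n, 1 / 15)))),
    diabetes = stats::runif(n) < 0.148,
    hypertension = stats::runif(n) < 0.221,
    high_cholesterol = stats::runif(n) < 0.424,
    stringsAsFactors = FALSE
  )

  stratum <- sample(seq_len(cfg$n_strata), n, replace = TRUE)
  psu <- sample(seq_len(cfg$psus_per_stratum), n, replace = TRUE)
  design <- data.frame(
    id = covars$id, stratum = stratum,
    psu = paste(stratum, psu, sep = "-"),
    weight = stats::rlnorm(n, 0, cfg$weight_log_sd)
  )
  # Guarantee >= 2 populated PSUs per stratum (relevant at tiny n).
  for (h in unique(design$stratum)) {
    idx <- which(design$stratum == h)
    if (length(unique(design$psu[idx])) < 2 && length(idx) >= 2) {
      design$psu[idx[1:2]] <- paste(h, 1:2, sep = "-")
    }
  }

  # Person-level effects: fixed covariate part + correlated random effects.
  ne <- length(cfg$episodic)
  Sb <- build_sigma_b(cfg)
  b <- MASS::mvrnorm(n, rep(0, ncol(Sb)), Sb)

  age_c <- (covars$age - 45) / 10
  male <- as.numeric(covars$sex == "male")
  fixed <- outer(age_c, cfg$beta_age) + outer(male, cfg$beta_male) +
    cfg$heritage_effects[covars$heritage, , drop = FALSE]
  mean_t <- sweep(fixed, 2, cfg$mu, "+") + b[, seq_along(vars), drop = FALSE]
  colnames(mean_t) <- vars

  probit_eta <- matrix(0, n, ne, dimnames = list(NULL, cfg$episodic))
  if (ne > 0) {
    probit_eta <- sweep(b[, length(vars) + seq_len(ne), drop = FALSE], 2,
                        cfg$probit_mu, "+")
    colnames(probit_eta) <- cfg$episodic
  }

  list(covariates = covars, design = design,
       truth = list(mean_t = mean_t, probit_eta = probit_eta,
                    prob = stats::pnorm(probit_eta), config = cfg))
}

#' Generate 24-h recall records for a cohort
#'
#' Simulates up to two recalls per participant: recall-level context
#' (weekend including Friday, recall sequence, self-reported usual-amount
#' flag) shifts the transformed-scale mean; day-to-day noise is multivariate
#' normal (or skewed under the misspecification toggle); episodic components
#' are zero on non-consumption days drawn from the probit submodel. Both
#' recalls of a participant are correlated only through the person effects.
#'
#' @param cohort Output of [generate_cohort()].
#' @param seed Integer seed.
#' @return A recall data.frame: id, sequence, weekend, usual_amount, energy,
#'   the 10 component amounts, fatty-acid constituents (pufa/mufa/sfa g),
#'   and empty-calorie constituents (solid fat and added sugar kcal,
#'   alcohol g).
#' @export
generate_recalls <- function(cohort, seed = 1) {
  cfg <- cohort$truth$config
  set.seed(seed + 1e6)
  n <- nrow(cohort$covariates)
  vars <- intake_variables()
  second <- stats::runif(n) < cfg$p_second_recall
  id <- c(seq_len(n), which(second))
  sequence <- c(rep(1L, n), rep(2L, sum(second)))
  R <- length(id)

  weekend <- stats::runif(R) < 3 / 7
  usual_amount <- sample(names(cfg$usual_amount_probs), R, TRUE,
                         cfg$usual_amount_probs)
  ua_shift <- ifelse(usual_amount == "more", cfg$usual_amount_effect,
                     ifelse(usual_amount == "less", -cfg$usual_amount_effect, 0))

  Se <- build_sigma_e(cfg)
  e <- MASS::mvrnorm(R, rep(0, length(vars)), Se)
  if (cfg$misspecified) {
    # Skewed day-to-day noise with the same covariance scale: standardized
    # chi-square(4) margins applied through the same correlation.
    z <- (stats::rchisq(R * length(vars), 4) - 4) / sqrt(8)
    e <- matrix(z, R, length(vars)) %*% chol(Se)
  }

  Yt <- cohort$truth$mean_t[id, , drop = FALSE] +
    outer(weekend, cfg$weekend_effect) +
    outer(as.numeric(sequence == 2L), cfg$sequence_effect) +
    outer(ua_shift, rep(1, length(vars))) + e
  colnames(Yt) <- vars

  consumed <- matrix(TRUE, R, length(cfg$episodic),
                     dimnames = list(NULL, cfg$episodic))
  if (length(cfg$episodic) > 0) {
    eta <- cohort$truth$probit_eta[id, , drop = FALSE]
    consumed[] <- stats::runif(R * ncol(eta)) < stats::pnorm(eta)
  }

  amounts <- matrix(NA_real_, R, length(vars), dimnames = list(NULL, vars))
  for (k in seq_along(vars)) {
    v <- vars[k]
    amounts[, k] <- if (v == "fatty_acids") exp(Yt[, k]) else bc_inv(Yt[, k])
  }
  for (v in cfg$episodic) amounts[!consumed[, v], v] <- 0

  energy <- pmax(300, amounts[, "energy"])
  empty_kcal <- pmin(amounts[, "empty_calories"], 0.95 * energy)
  ratio <- amounts[, "fatty_acids"]
  # Decompose the modelled ratio and empty-calorie totals into constituents
  # the HEI scorer accepts: SFA at ~11% of energy, alcohol kept below the
  # 13 g/1000 kcal threshold so solid fat + added sugar carry the total.
  sfa_g <- 0.11 * energy / 9
  unsat <- ratio * sfa_g
  alcohol_g <- ifelse(stats::runif(R) < 0.3,
                      stats::runif(R) * 13 * energy / 1000, 0)

  out <- data.frame(
    id = id, sequence = sequence, weekend = weekend,
    usual_amount = usual_amount, energy = energy,
    stringsAsFactors = FALSE
  )
  for (v in setdiff(vars, c("fatty_acids", "empty_calories", "energy"))) {
    out[[v]] <- amounts[, v]
  }
  out$pufa_g <- 0.4 * unsat
  out$mufa_g <- 0.6 * unsat
  out$sfa_g <- sfa_g
  out$solid_fat_kcal <- 0.6 * empty_kcal
  out$added_sugar_kcal <- 0.4 * empty_kcal
  out$alcohol_g <- alcohol_g
  out[order(out$id, out$sequence), ]
}

# Nodes/weights for Gauss-Hermite expectation over N(0, sd^2).
gh_rule <- function(order = 9) {
  # Golub-Welsch via the symmetric tridiagonal Jacobi matrix.
  i <- seq_len(order - 1)
  J <- matrix(0, order, order)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  ev <- eigen(J, symmetric = TRUE)
  list(nodes = ev$values * sqrt(2),        # for N(0,1): x = sqrt(2) t
       weights = ev$vectors[1, ]^2)        # normalized to sum 1
}

# E[inv(m + sd*Z)] for Z ~ N(0,1), columnwise over a matrix of means.
gh_expect <- function(m, sd, inv, rule = gh_rule(9)) {
  out <- 0
  for (q in seq_along(rule$nodes)) {
    out <- out + rule$weights[q] * inv(m + sd * rule$nodes[q])
  }
  out
}

#' True usual intakes of a synthetic cohort
#'
#' Computes each participant's true usual daily intake on the natural scale:
#' the within-person expectation of the back-transformed daily intake
#' (9-point Gauss-Hermite over the day-to-day noise), times the consumption
#' probability for episodic components, at reference recall context
#' (weekday, first recall, usual amount "same").
#'
#' @param cohort Output of [generate_cohort()].
#' @return Data.frame of usual amounts: id, energy, the 10 components,
#'   \code{fatty_acids} ratio and \code{empty_calories_kcal}.
#' @export
true_usual_intake <- function(cohort) {
  cfg <- cohort$truth$config
  vars <- intake_variables()
  rule <- gh_rule(9)
  n <- nrow(cohort$truth$mean_t)
  usual <- matrix(NA_real_, n, length(vars), dimnames = list(NULL, vars))
  for (k in seq_along(vars)) {
    v <- vars[k]
    inv <- if (v == "fatty_acids") exp else bc_inv
    usual[, k] <- gh_expect(cohort$truth$mean_t[, k], cfg$sigma_e[v], inv, rule)
    if (v %in% cfg$episodic) {
      usual[, k] <- usual[, k] * cohort$truth$prob[, v]
    }
  }
  out <- data.frame(id = cohort$covariates$id)
  for (v in setdiff(vars, c("fatty_acids", "empty_calories"))) {
    out[[v]] <- usual[, v]
  }
  out$energy <- pmax(300, usual[, "energy"])
  out$fatty_acids <- usual[, "fatty_acids"]
  out$empty_calories_kcal <- usual[, "empty_calories"]
  out
}

#' Survey-weighted summaries of the true usual-intake distribution
#'
#' The gold standard the usual-intake pipeline must recover: survey-weighted
#' per-component mean HEI scores, percent with the maximum component score,
#' and the mean total, computed from the true usual intakes.
#'
#' @param cohort Output of [generate_cohort()].
#' @param standards HEI standards table.
#' @return List with \code{component} (data.frame: component, mean_score,
#'   pct_at_max) and \code{total_mean}.
#' @export
true_summaries <- function(cohort, standards = hei_standards()) {
  usual <- true_usual_intake(cohort)
  scores <- score_profile(usual, standards)
  w <- cohort$design$weight[match(usual$id, cohort$design$id)]
  comps <- hei_components()
  maxp <- standards$max_points[match(comps, standards$component)]
  comp <- data.frame(
    component = comps,
    mean_score = vapply(comps, function(v) weighted_mean(scores[[v]], w),
                        numeric(1)),
    pct_at_max = vapply(seq_along(comps), function(i) {
      100 * weighted_mean(as.numeric(scores[[comps[i]]] >= maxp[i] - 1e-9), w)
    }, numeric(1)),
    row.names = NULL
  )
  list(component = comp, total_mean = weighted_mean(scores$total, w))
}
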