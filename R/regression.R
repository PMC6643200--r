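#' Person-level HEI from averaged recalls
#'
#' Averages component amounts and energy across a participant's available
#' recalls first, then scores once (average-then-score): densities are
#' computed from averaged intake, not averaged per-recall densities.
#'
#' @param recalls Recall table (1 or 2 rows per participant).
#' @param standards HEI standards table.
#' @return Data.frame: id, the 12 component scores, total.
#' @export
person_hei <- function(recalls, standards = hei_standards()) {
  if (nrow(recalls) == 0) stop("at least one recall is required")
  num_cols <- setdiff(names(recalls)[vapply(recalls, is.numeric, logical(1))],
                      c("id", "sequence"))
  agg <- stats::aggregate(recalls[num_cols], by = list(id = recalls$id), mean)
  scores <- score_profile(agg, standards)
  cbind(id = agg$id, scores)
}

# Reference levels matching the conventional reporting of the regression
# model (Mexican heritage, Bronx, no high school, lowest income, obese,
# current smoker, inactive, male, English preference).
.reg_refs <- list(
  heritage = "Mexican", field_center = "Bronx", education = "lt_hs",
  income = "lt10k", bmi_group = "obese", smoking = "current",
  activity = "inactive", sex = "male", language_preference = "English"
)

# Encode one variable into design columns; returns a matrix whose column
# names are prefixed by the variable name so blocks can be tracked.
encode_term <- function(data, var) {
  x <- data[[var]]
  if (is.null(x)) stop("unknown covariate: ", var)
  if (is.numeric(x)) {
    m <- matrix(x, ncol = 1, dimnames = list(NULL, var))
  } else if (is.logical(x)) {
    m <- matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, var))
  } else {
    lev <- sort(unique(as.character(x)))
    ref <- .reg_refs[[var]]
    if (!is.null(ref) && ref %in% lev) lev <- c(ref, setdiff(lev, ref))
    if (length(lev) < 2) stop("covariate ", var, " is constant")
    m <- vapply(lev[-1], function(l) as.numeric(x == l),
                numeric(length(x)))
    colnames(m) <- paste0(var, ":", lev[-1])
  }
  m
}

#' Specification for the correlates regression
#'
#' @param candidates Covariates considered by backward selection.
#' @param forced Covariates kept in the model regardless of significance.
#' @param alpha_stay Retention threshold for the joint Wald p-value.
#' @return A \code{regression_spec} list.
#' @export
regression_spec <- function(
    candidates = c("age", "sex", "bmi_group", "smoking", "activity",
                   "education", "income", "employment", "marital",
                   "heritage", "us_born", "years_us", "language_preference",
                   "sash_language", "sash_social", "field_center",
                   "high_cholesterol", "diabetes", "hypertension"),
    forced = c("field_center", "heritage"),
    alpha_stay = 0.1) {
  if (!all(forced %in% candidates)) stop("forced terms must be candidates")
  if (alpha_stay <= 0 || alpha_stay >= 1) stop("alpha_stay must be in (0,1)")
  structure(list(candidates = candidates, forced = forced,
                 alpha_stay = alpha_stay), class = "regression_spec")
}

build_reg_design <- function(data, terms) {
  blocks <- lapply(terms, function(v) encode_term(data, v))
  X <- cbind(`(Intercept)` = rep(1, nrow(data)), do.call(cbind, blocks))
  block_cols <- lapply(blocks, colnames)
  names(block_cols) <- terms
  list(X = X, block_cols = block_cols)
}

#' Survey-weighted regression with forced-variable backward selection
#'
#' Fits a survey-weighted linear model of the outcome on all candidate
#' covariates, then repeatedly drops the least significant non-forced
#' variable (categorical variables tested and dropped as whole blocks via
#' joint Wald tests) while its p-value exceeds \code{alpha_stay}. Ties in
#' least-significance go to the larger p, then alphabetical name. The
#' audit trail records each drop with its p-value.
#'
#' @param y Outcome vector (person-level HEI total).
#' @param data Covariate data.frame aligned with \code{y}.
#' @param design Survey design table aligned with rows.
#' @param spec A [regression_spec()].
#' @return List: \code{fit} (final [svy_lm()]), \code{table} (term,
#'   estimate, 95\% CI, p), \code{kept} terms, \code{audit} (variable,
#'   p_at_drop, step), \code{r_squared}.
#' @export
backward_select <- function(y, data, design, spec = regression_spec()) {
  current <- spec$candidates
  audit <- data.frame(variable = character(0), p_at_drop = numeric(0),
                      step = integer(0))
  step <- 0L
  repeat {
    des <- build_reg_design(data, current)
    fit <- svy_lm(y, des$X, design)
    droppable <- setdiff(current, spec$forced)
    if (length(droppable) == 0) break
    pvals <- vapply(droppable, function(v)
      wald_test(fit, des$block_cols[[v]])$p, numeric(1))
    ord <- order(-pvals, droppable)
    worst <- droppable[ord[1]]
    if (pvals[ord[1]] <= spec$alpha_stay) break
    step <- step + 1L
    audit <- rbind(audit, data.frame(variable = worst,
                                     p_at_drop = pvals[ord[1]],
                                     step = step))
    current <- setdiff(current, worst)
  }
  des <- build_reg_design(data, current)
  fit <- svy_lm(y, des$X, design)
  tab <- data.frame(term = names(fit$coefficients),
                    estimate = unname(fit$coefficients),
                    lcl = fit$ci[, "lower"], ucl = fit$ci[, "upper"],
                    p = fit$p, row.names = NULL)
  list(fit = fit, table = tab, kept = current, audit = audit,
       r_squared = fit$r_squared, block_cols = des$block_cols)
}
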