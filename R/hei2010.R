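#' Energy-density of an intake amount
#'
#' HEI-2010 standards are density based: amounts are expressed per 1000 kcal
#' of energy before scoring, so that the index measures dietary quality
#' independently of quantity.
#'
#' @param amount Daily amount in the component's natural units (vectorized).
#' @param energy Daily energy intake in kcal (vectorized, recycled).
#' @return \code{amount * 1000 / energy}.
#' @export
compute_density <- function(amount, energy) {
  if (any(!is.finite(energy)) || any(energy <= 0)) {
    stop("invalid profile: energy must be positive and finite")
  }
  if (any(amount < 0, na.rm = TRUE)) {
    stop("invalid profile: amounts must be non-negative")
  }
  amount * 1000 / energy
}

#' Fatty-acid ratio (PUFA + MUFA) / SFA
#'
#' The HEI-2010 fatty-acid component scores the ratio of unsaturated to
#' saturated fat. A zero-SFA intake with nonzero unsaturated fat yields an
#' unbounded ratio: it is capped at the largest representable value and
#' flagged (attribute \code{capped}), since any cap above the maximum-score
#' anchor scores identically. Zero fat of both kinds leaves the ratio
#' undefined and is an error.
#'
#' @param pufa_g,mufa_g,sfa_g Grams per day of poly-/mono-unsaturated and
#'   saturated fatty acids (vectorized).
#' @return Numeric ratio vector, with a logical \code{capped} attribute when
#'   any element was capped.
#' @export
fatty_acid_ratio <- function(pufa_g, mufa_g, sfa_g) {
  unsat <- pufa_g + mufa_g
  if (any(sfa_g < 0 | unsat < 0, na.rm = TRUE)) {
    stop("fatty-acid intakes must be non-negative")
  }
  undefined <- sfa_g == 0 & unsat == 0
  if (any(undefined, na.rm = TRUE)) {
    stop("missing ratio: zero saturated and zero unsaturated fat")
  }
  capped <- sfa_g == 0 & unsat > 0
  ratio <- ifelse(capped, .Machine$double.xmax, unsat / sfa_g)
  if (any(capped, na.rm = TRUE)) {
    attr(ratio, "capped") <- capped
  }
  ratio
}

#' Empty-calorie share of energy
#'
#' Empty calories are energy from solid fats, added sugars, and alcohol
#' beyond a threshold of 13 g per 1000 kcal of energy; only grams above the
#' threshold contribute, at 7 kcal/g.
#'
#' @param solid_fat_kcal,added_sugar_kcal Daily kcal from solid fats and
#'   added sugars.
#' @param alcohol_g Daily grams of alcohol.
#' @param energy Daily energy, kcal (> 0).
#' @return Percent of energy from empty calories (vectorized).
#' @export
empty_calorie_share <- function(solid_fat_kcal, added_sugar_kcal, alcohol_g,
                                energy) {
  if (any(energy <= 0)) stop("invalid profile: energy must be positive")
  excess_alcohol_kcal <- 7 * pmax(0, alcohol_g - 13 * energy / 1000)
  (solid_fat_kcal + added_sugar_kcal + excess_alcohol_kcal) / energy * 100
}

#' Score a single HEI-2010 component from its density
#'
#' Adequacy components score linearly from 0 points at zero density to the
#' full points at the maximum-score density, then plateau. Moderation
#' components and the fatty-acid ratio interpolate linearly between the
#' zero-score anchor (0 points) and the maximum-score anchor (full points),
#' clamped to the component's range.
#'
#' @param density Density value(s) on the component's scale (per 1000 kcal,
#'   percent of energy, or ratio).
#' @param std A single-row slice of the standards table for this component.
#' @return Points in \code{[0, std$max_points]} (vectorized over density).
#' @export
score_component <- function(density, std) {
  if (nrow(std) != 1) stop("std must be a single standards row")
  if (any(density < 0, na.rm = TRUE)) {
    stop("density must be non-negative for component ", std$component)
  }
  frac <- (density - std$density_at_zero) /
    (std$density_at_max - std$density_at_zero)
  std$max_points * pmin(1, pmax(0, frac))
}

# Columns an IntakeProfile may carry for the two derived components; either
# the raw constituents or the precomputed value must be present.
.fat_cols <- c("pufa_g", "mufa_g", "sfa_g")
.empty_cols <- c("solid_fat_kcal", "added_sugar_kcal", "alcohol_g")

#' Validate an intake-profile table
#'
#' An intake profile holds one row per diet (a recall, a recall average, or a
#' usual-intake draw): \code{energy} in kcal plus daily amounts for the ten
#' directly-measured components, and either raw fatty-acid grams
#' (\code{pufa_g}, \code{mufa_g}, \code{sfa_g}) or a precomputed
#' \code{fatty_acids} ratio, and either empty-calorie constituents
#' (\code{solid_fat_kcal}, \code{added_sugar_kcal}, \code{alcohol_g}) or a
#' precomputed \code{empty_calories_kcal} total.
#'
#' @param profile A data.frame of intake profiles.
#' @return Invisibly, \code{profile}; errors on violations.
#' @export
validate_profile <- function(profile) {
  amount_cols <- setdiff(hei_components(), c("fatty_acids", "empty_calories"))
  missing <- setdiff(c("energy", amount_cols), names(profile))
  if (length(missing) > 0) {
    stop("profile is missing columns: ", paste(missing, collapse = ", "))
  }
  if (any(profile$energy <= 0)) stop("invalid profile: energy must be positive")
  for (col in amount_cols) {
    if (any(profile[[col]] < 0)) {
      stop("invalid profile: negative amount in ", col)
    }
  }
  has_fat <- all(.fat_cols %in% names(profile)) || "fatty_acids" %in% names(profile)
  has_empty <- all(.empty_cols %in% names(profile)) ||
    "empty_calories_kcal" %in% names(profile)
  if (!has_fat) stop("profile needs pufa_g/mufa_g/sfa_g or fatty_acids")
  if (!has_empty) {
    stop("profile needs solid_fat_kcal/added_sugar_kcal/alcohol_g or empty_calories_kcal")
  }
  invisible(profile)
}

#' Densities of all 12 components of an intake profile
#'
#' @param profile Intake profile table (see [validate_profile()]).
#' @return A numeric matrix (rows = profiles, columns = the 12 components):
#'   per-1000-kcal densities, the fatty-acid ratio, and the empty-calorie
#'   percent of energy.
#' @export
profile_densities <- function(profile) {
  validate_profile(profile)
  comps <- hei_components()
  dens <- matrix(NA_real_, nrow(profile), length(comps),
                 dimnames = list(NULL, comps))
  for (comp in setdiff(comps, c("fatty_acids", "empty_calories"))) {
    dens[, comp] <- compute_density(profile[[comp]], profile$energy)
  }
  dens[, "fatty_acids"] <- if ("fatty_acids" %in% names(profile)) {
    profile$fatty_acids
  } else {
    as.numeric(fatty_acid_ratio(profile$pufa_g, profile$mufa_g, profile$sfa_g))
  }
  dens[, "empty_calories"] <- if ("empty_calories_kcal" %in% names(profile)) {
    profile$empty_calories_kcal / profile$energy * 100
  } else {
    empty_calorie_share(profile$solid_fat_kcal, profile$added_sugar_kcal,
                        profile$alcohol_g, profile$energy)
  }
  dens
}

#' Score intake profiles on HEI-2010
#'
#' Computes the 12 component scores and the total (0-100) for each profile
#' row. Scoring is density based, so scaling amounts and energy together
#' leaves scores unchanged.
#'
#' @param profile Intake profile table (see [validate_profile()]).
#' @param standards Standards table from [hei_standards()].
#' @return A data.frame with the 12 per-component score columns and
#'   \code{total}, one row per profile.
#' @export
score_profile <- function(profile, standards = hei_standards()) {
  standards <- validate_standards(standards)
  dens <- profile_densities(profile)
  scores <- matrix(NA_real_, nrow(dens), ncol(dens),
                   dimnames = dimnames(dens))
  for (i in seq_along(hei_components())) {
    comp <- hei_components()[i]
    scores[, comp] <- score_component(dens[, comp],
                                      standards[standards$component == comp, ])
  }
  out <- as.data.frame(scores)
  out$total <- rowSums(scores)
  out
}
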