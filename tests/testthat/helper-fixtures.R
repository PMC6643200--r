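# Shared fixtures for the test suite.

# Intake profile at every maximum-score standard: each adequacy component's
# density equals its full-score standard, the fatty-acid ratio exceeds 2.5,
# and every moderation component is at or below its full-score standard.
perfect_profile <- function(energy = 2000) {
  k <- energy / 1000
  data.frame(
    energy = energy,
    total_fruit = 0.8 * k,
    whole_fruit = 0.4 * k,
    total_veg = 1.1 * k,
    greens_beans = 0.2 * k,
    whole_grains = 1.5 * k,
    dairy = 1.3 * k,
    total_protein = 2.5 * k,
    seafood_plant_prot = 0.8 * k,
    pufa_g = 12, mufa_g = 18, sfa_g = 10,      # ratio 3.0 > 2.5
    refined_grains = 1.8 * k,
    sodium = 1.1 * k,
    solid_fat_kcal = 0.19 * energy * 0.6,
    added_sugar_kcal = 0.19 * energy * 0.4,
    alcohol_g = 0
  )
}

# Profile at or beyond every zero-score anchor.
worst_profile <- function(energy = 2000) {
  k <- energy / 1000
  data.frame(
    energy = energy,
    total_fruit = 0, whole_fruit = 0, total_veg = 0, greens_beans = 0,
    whole_grains = 0, dairy = 0, total_protein = 0, seafood_plant_prot = 0,
    pufa_g = 6, mufa_g = 6, sfa_g = 10,        # ratio 1.2 -> 0 points
    refined_grains = 4.3 * k,
    sodium = 2.0 * k,
    solid_fat_kcal = 0.50 * energy * 0.6,
    added_sugar_kcal = 0.50 * energy * 0.4,
    alcohol_g = 0
  )
}

# Small shared cohort for model-level tests (cached across tests).
.fixture_env <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    cfg <- cohort_config(n = 300)
    .fixture_env$cohort <- generate_cohort(cfg, seed = 42)
    .fixture_env$recalls <- generate_recalls(.fixture_env$cohort, seed = 42)
  }
  list(cohort = .fixture_env$cohort, recalls = .fixture_env$recalls)
}

# An iid single-stratum design: every observation its own PSU, equal weights.
iid_design <- function(n, weight = 1) {
  data.frame(stratum = 1L, psu = seq_len(n), weight = weight)
}
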