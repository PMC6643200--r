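# Shared settings for the numbered analysis scripts. Each script can be run
# on its own (later scripts read the CSVs written by earlier ones), e.g.
#   Rscript analysis/01_simulate.R
# Outputs land under results/.

library(heiusual)

cfg <- list(
  seed = 2024,
  n = 1500,            # participants in the simulated cohort
  M = 50,              # usual-intake draws per participant
  boot_reps = 100,     # bootstrap replicates for summary SEs
  data_dir = file.path("results", "data"),
  table_dir = file.path("results", "tables")
)
for (d in c(cfg$data_dir, cfg$table_dir)) {
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
}
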