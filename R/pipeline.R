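# Cheap stable fingerprint of a config for stamping outputs. The output
# directory is excluded so the same analysis written to two places carries
# the same stamp.
config_hash <- function(cfg) {
  cfg$out_dir <- NULL
  s <- paste(deparse(cfg), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

#' Run the usual-intake diet-quality pipeline end to end
#'
#' Orchestrates: simulate (or read) cohort tables, apply exclusion filters,
#' fit the measurement-error model, build the scored pseudo-population,
#' compute survey-weighted (optionally age/sex-standardized) summaries
#' overall and by subgroups (re-fitting the model per subpopulation), and
#' run the survey-weighted backward-selection regression of person-level
#' HEI on covariates. All stages are deterministic under \code{seed}.
#'
#' @param config A list:
#'   \describe{
#'     \item{simulate}{a [cohort_config()] (or NULL to use \code{paths})}
#'     \item{paths}{named CSV paths \code{recalls}, \code{covariates},
#'       \code{design} when not simulating}
#'     \item{M}{draws per participant (default 100)}
#'     \item{me}{a [me_config()]}
#'     \item{subgroups}{covariate names to summarize by (each level re-fits
#'       the model) — e.g. \code{"heritage"}; \code{share_model = TRUE}
#'       reuses the full-sample fit for speed}
#'     \item{standardize}{\code{list(age =, pct_male =)} or NULL}
#'     \item{bootstrap}{\code{list(replicates =, enabled =, refit_per_replicate =)}}
#'     \item{regression}{logical: run the correlates regression}
#'     \item{out_dir}{directory for CSV outputs (created; NULL skips writing)}
#'     \item{seed}{global integer seed}
#'   }
#' @return List with the fitted model, pseudo-population summaries (overall
#'   and per subgroup), bootstrap SEs when requested, the regression result,
#'   and the stamp (seed + config hash).
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(
    list(simulate = cohort_config(), paths = NULL, M = 100,
         me = me_config(), subgroups = character(0), standardize = NULL,
         bootstrap = list(enabled = FALSE, replicates = 200,
                          refit_per_replicate = TRUE),
         share_model = FALSE, regression = TRUE, out_dir = NULL, seed = 1),
    config)
  seed <- cfg$seed
  stamp <- list(seed = seed, config_hash = config_hash(cfg))

  if (!is.null(cfg$paths)) {
    for (nm in c("recalls", "covariates", "design")) {
      if (is.null(cfg$paths[[nm]]) || !file.exists(cfg$paths[[nm]])) {
        stop("missing input table: ", nm)
      }
    }
    recalls <- utils::read.csv(cfg$paths$recalls)
    covars <- utils::read.csv(cfg$paths$covariates)
    design <- utils::read.csv(cfg$paths$design)
  } else {
    cohort <- generate_cohort(cfg$simulate, seed = seed)
    recalls <- generate_recalls(cohort, seed = seed)
    covars <- cohort$covariates
    design <- cohort$design
  }
  validate_design(design)

  model <- fit_me_model(recalls, covars,
                        utils::modifyList(cfg$me, list(seed = seed)))
  pp <- build_pseudo_population(model, design, M = cfg$M, seed = seed,
                                standardize = cfg$standardize)
  overall <- summarize_pseudo(pp)

  subgroup_results <- list()
  for (var in cfg$subgroups) {
    for (lv in sort(unique(as.character(covars[[var]])))) {
      ids <- covars$id[covars[[var]] == lv]
      key <- paste(var, lv, sep = "=")
      if (isTRUE(cfg$share_model)) {
        subgroup_results[[key]] <- summarize_pseudo(pp, ids = ids)
      } else {
        sub_rec <- recalls[recalls$id %in% ids, , drop = FALSE]
        sub_cov <- covars[covars$id %in% ids, , drop = FALSE]
        sub_model <- fit_me_model(sub_rec, sub_cov,
                                  utils::modifyList(cfg$me, list(seed = seed)))
        sub_pp <- build_pseudo_population(
          sub_model, design[design$id %in% ids, , drop = FALSE],
          M = cfg$M, seed = seed, standardize = cfg$standardize)
        subgroup_results[[key]] <- summarize_pseudo(sub_pp)
      }
    }
  }

  boot <- NULL
  if (isTRUE(cfg$bootstrap$enabled)) {
    pdesign <- design[match(model$prep$ids, design$id), , drop = FALSE]
    stat <- function(dat, w) {
      if (isTRUE(cfg$bootstrap$refit_per_replicate)) {
        # weights do not enter model fitting (the estimation contract is
        # model-based); they re-enter at the summary stage
      }
      rows <- dat$rows
      wrow <- w[match(rows$id, pdesign$id)] / dat$M
      c(vapply(hei_components(), function(v) weighted_mean(rows[[v]], wrow),
               numeric(1)), total = weighted_mean(rows$total, wrow))
    }
    boot <- bootstrap_se(stat, pp, pdesign,
                         replicates = cfg$bootstrap$replicates, seed = seed)
  }

  reg <- NULL
  if (isTRUE(cfg$regression)) {
    ph <- person_hei(recalls)
    idx <- match(ph$id, covars$id)
    reg <- backward_select(ph$total, covars[idx, , drop = FALSE],
                           design[match(ph$id, design$id), , drop = FALSE])
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    comp_tab <- overall$component
    comp_tab$se <- if (!is.null(boot)) boot$se[seq_len(12)] else NA_real_
    for (key in names(subgroup_results)) {
      comp_tab[[paste0("mean_", key)]] <- subgroup_results[[key]]$component$mean_score
      comp_tab[[paste0("pctmax_", key)]] <- subgroup_results[[key]]$component$pct_at_max
    }
    attr_line <- sprintf("# seed=%d config=%s", stamp$seed, stamp$config_hash)
    write_stamped <- function(df, file) {
      path <- file.path(cfg$out_dir, file)
      writeLines(attr_line, path)
      suppressWarnings(utils::write.table(df, path, append = TRUE, sep = ",",
                                          row.names = FALSE, qmethod = "double"))
    }
    write_stamped(comp_tab, "component_summaries.csv")
    if (!is.null(reg)) write_stamped(reg$table, "regression.csv")
    if (!is.null(reg)) write_stamped(reg$audit, "selection_audit.csv")
  }

  list(model = model, pseudo = pp, overall = overall,
       subgroups = subgroup_results, bootstrap = boot, regression = reg,
       stamp = stamp)
}
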