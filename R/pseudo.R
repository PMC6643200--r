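#' Build a scored pseudo-population of usual-intake draws
#'
#' Draws M usual-intake vectors per participant from the fitted model,
#' scores every draw on HEI-2010, and attaches the survey design: each
#' pseudo-row carries its participant's stratum and PSU and weight/M, so
#' survey-weighted statistics over pseudo-rows estimate population
#' statistics of the usual-intake distribution.
#'
#' @param model Fitted \code{me_model}.
#' @param design Survey design table (id, stratum, psu, weight).
#' @param M Draws per participant.
#' @param seed Integer seed.
#' @param standardize Optional \code{list(age =, pct_male =)} passed to
#'   [draw_usual()] for age/sex standardization.
#' @param standards HEI standards table.
#' @return Object of class \code{pseudo_population}: \code{rows} (id, draw,
#'   component scores, total, stratum, psu, weight), \code{usual} (the
#'   draws), \code{M}, \code{standardize}.
#' @export
build_pseudo_population <- function(model, design, M = 100, seed = 1,
                                    standardize = NULL,
                                    standards = hei_standards()) {
  usual <- draw_usual(model, M = M, seed = seed, standardize = standardize)
  scores <- score_profile(usual, standards)
  idx <- match(usual$id, design$id)
  if (anyNA(idx)) stop("design table is missing participants present in the model")
  rows <- cbind(usual[, c("id", "draw")], scores,
                design[idx, c("stratum", "psu")],
                weight = design$weight[idx] / M)
  out <- list(rows = rows, usual = usual, M = M, standardize = standardize,
              standards = standards)
  class(out) <- "pseudo_population"
  out
}

#' Survey-weighted summaries of a pseudo-population
#'
#' Per-component mean scores, mean total, and the percent of the population
#' achieving each component's maximum score (meeting the recommendation;
#' equality judged with an absolute tolerance of 1e-9 points).
#'
#' @param pp A \code{pseudo_population}.
#' @param ids Optional participant ids restricting the summary to a
#'   subpopulation (note the estimation contract: subgroup statistics in the
#'   full pipeline refit the model per subpopulation).
#' @return List with \code{component} (component, mean_score, pct_at_max)
#'   and \code{total_mean}.
#' @export
summarize_pseudo <- function(pp, ids = NULL) {
  rows <- pp$rows
  if (!is.null(ids)) {
    rows <- rows[rows$id %in% ids, , drop = FALSE]
    if (nrow(rows) == 0) stop("empty subgroup")
  }
  comps <- hei_components()
  maxp <- pp$standards$max_points[match(comps, pp$standards$component)]
  comp <- data.frame(
    component = comps,
    mean_score = vapply(comps, function(v) weighted_mean(rows[[v]], rows$weight),
                        numeric(1)),
    pct_at_max = vapply(seq_along(comps), function(i) {
      100 * weighted_mean(as.numeric(rows[[comps[i]]] >= maxp[i] - 1e-9),
                          rows$weight)
    }, numeric(1)),
    row.names = NULL
  )
  list(component = comp, total_mean = weighted_mean(rows$total, rows$weight))
}
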