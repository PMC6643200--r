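#' HEI-2010 component identifiers
#'
#' The 12 components of the Healthy Eating Index 2010 in canonical order:
#' nine adequacy components (scored upward with consumption), the fatty-acid
#' ratio, and three moderation components (scored downward).
#'
#' @return Character vector of the 12 component ids.
#' @export
hei_components <- function() {
  c("total_fruit", "whole_fruit", "total_veg", "greens_beans",
    "whole_grains", "dairy", "total_protein", "seafood_plant_prot",
    "fatty_acids", "refined_grains", "sodium", "empty_calories")
}

#' Load HEI-2010 scoring standards
#'
#' Reads the per-component scoring constants (maximum points, scoring
#' direction, and the density anchors earning zero and maximum points) from a
#' versioned YAML configuration. The shipped configuration encodes the
#' HEI-2010 standards: e.g. total fruit earns its full 5 points at
#' \eqn{\ge 0.8} cup-equivalents per 1000 kcal, sodium earns its full 10
#' points at \eqn{\le 1.1} g per 1000 kcal and 0 points at \eqn{\ge 2.0}
#' g/1000 kcal, and empty calories (solid fats, added sugars, and alcohol
#' beyond 13 g/1000 kcal) earn 20 points at \eqn{\le 19\%} of energy.
#'
#' @param path Optional path to an alternative standards YAML; defaults to the
#'   configuration shipped with the package.
#' @return A data.frame with one row per component and columns
#'   \code{component}, \code{max_points}, \code{direction},
#'   \code{density_at_zero}, \code{density_at_max}, \code{units}.
#' @export
hei_standards <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hei2010_standards.yaml", package = "heiusual")
  }
  cfg <- yaml::read_yaml(path)
  comp <- cfg$components
  std <- data.frame(
    component = names(comp),
    max_points = vapply(comp, function(x) as.numeric(x$max_points), numeric(1)),
    direction = vapply(comp, function(x) x$direction, character(1)),
    density_at_zero = vapply(comp, function(x) as.numeric(x$density_at_zero), numeric(1)),
    density_at_max = vapply(comp, function(x) as.numeric(x$density_at_max), numeric(1)),
    units = vapply(comp, function(x) x$units, character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  validate_standards(std)
  std[match(hei_components(), std$component), , drop = FALSE]
}

#' Validate a standards table
#'
#' Checks the structural invariants of an HEI-2010 standards table: all 12
#' components present, maximum points in \{5, 10, 20\} summing to 100,
#' adequacy anchors at 0 below their maximum-score density, moderation anchors
#' above, and the ratio component's lower anchor below its upper anchor.
#'
#' @param std A standards data.frame as returned by [hei_standards()].
#' @return Invisibly, \code{std}; errors if an invariant is violated.
#' @export
validate_standards <- function(std) {
  need <- hei_components()
  missing <- setdiff(need, std$component)
  if (length(missing) > 0) {
    stop("standards configuration is missing components: ",
         paste(missing, collapse = ", "))
  }
  std <- std[match(need, std$component), , drop = FALSE]
  if (!all(std$max_points %in% c(5, 10, 20))) {
    stop("max_points must be 5, 10 or 20 for every component")
  }
  if (sum(std$max_points) != 100) {
    stop("component maximum points must sum to 100, got ", sum(std$max_points))
  }
  if (!all(std$direction %in% c("adequacy", "moderation", "ratio"))) {
    stop("direction must be adequacy, moderation or ratio")
  }
  adeq <- std$direction == "adequacy"
  if (!all(std$density_at_zero[adeq] == 0 &
           std$density_at_max[adeq] > 0)) {
    stop("adequacy components need density_at_zero = 0 < density_at_max")
  }
  mods <- std$direction == "moderation"
  if (!all(std$density_at_max[mods] < std$density_at_zero[mods])) {
    stop("moderation components need density_at_max < density_at_zero")
  }
  rat <- std$direction == "ratio"
  if (!all(std$density_at_zero[rat] < std$density_at_max[rat])) {
    stop("ratio component needs density_at_zero < density_at_max")
  }
  invisible(std)
}
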