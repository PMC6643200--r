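#' Cohort-assembly exclusion filters
#'
#' Applies the analysis-sample filters to a participant roster, in order:
#' age at or above 74 years; missing heritage; other or mixed heritage; no
#' dietary recalls; unreliable recalls; and energy intake below the 1st or
#' above the 99th sex-specific percentile. Each participant is counted
#' against the first criterion they fail, so the per-criterion counts plus
#' the retained count partition the roster.
#'
#' The roster needs columns \code{id}, \code{age}, \code{heritage} (with
#' \code{"other"}, \code{"mixed"} or \code{NA} marking non-analysable
#' heritage), \code{n_recalls} (0, 1 or 2), \code{reliable} (logical), and
#' either an \code{energy_percentile_flag} column
#' (\code{"below-p1"}, \code{"above-p99"}, \code{"in-range"}) or
#' \code{energy} + \code{sex} columns from which sex-specific percentiles
#' are computed empirically among participants with recalls.
#'
#' @param roster Roster data.frame.
#' @return A list with \code{retained} (ids kept), \code{roster} (the
#'   retained rows), and \code{audit}: a data.frame of per-criterion
#'   exclusion counts in application order.
#' @export
apply_exclusions <- function(roster) {
  need <- c("id", "age", "heritage", "n_recalls", "reliable")
  missing <- setdiff(need, names(roster))
  if (length(missing) > 0) {
    stop("roster is missing columns: ", paste(missing, collapse = ", "))
  }
  n <- nrow(roster)
  if (n == 0) {
    audit <- data.frame(
      criterion = c("age_ge_74", "missing_heritage", "other_mixed_heritage",
                    "no_recalls", "unreliable_recalls", "energy_percentile"),
      excluded = 0L)
    return(list(retained = roster$id, roster = roster, audit = audit))
  }

  if (!"energy_percentile_flag" %in% names(roster)) {
    if (!all(c("energy", "sex") %in% names(roster))) {
      stop("roster needs energy_percentile_flag or energy + sex columns")
    }
    flag <- rep(NA_character_, n)
    has_recall <- roster$n_recalls > 0 & !is.na(roster$energy)
    for (s in unique(roster$sex[has_recall])) {
      idx <- which(has_recall & roster$sex == s)
      q <- stats::quantile(roster$energy[idx], c(0.01, 0.99), type = 2)
      flag[idx] <- ifelse(roster$energy[idx] < q[1], "below-p1",
                          ifelse(roster$energy[idx] > q[2], "above-p99",
                                 "in-range"))
    }
    roster$energy_percentile_flag <- flag
  }

  fails <- cbind(
    age_ge_74 = !is.na(roster$age) & roster$age >= 74,
    missing_heritage = is.na(roster$heritage) | roster$heritage == "missing",
    other_mixed_heritage = !is.na(roster$heritage) &
      roster$heritage %in% c("other", "mixed"),
    no_recalls = roster$n_recalls == 0,
    unreliable_recalls = !roster$reliable,
    energy_percentile = !is.na(roster$energy_percentile_flag) &
      roster$energy_percentile_flag %in% c("below-p1", "above-p99")
  )
  first_fail <- apply(fails, 1, function(f) {
    w <- which(f)
    if (length(w) == 0) 0L else w[1]
  })
  counts <- tabulate(first_fail[first_fail > 0], nbins = ncol(fails))
  keep <- first_fail == 0L
  list(retained = roster$id[keep],
       roster = roster[keep, , drop = FALSE],
       audit = data.frame(criterion = colnames(fails), excluded = counts))
}
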