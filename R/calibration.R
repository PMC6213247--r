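# Monte-Carlo calibration utilities for the comparison engine and the
# synthetic generator. These run the exact production route (assumption
# checks -> omnibus -> post-hoc) on simulated cohorts.

#' Null calibration of the routed comparison engine
#'
#' Draws `n_reps` null cohorts (all groups from one normal distribution,
#' `n` per group), runs the full route on each and records, per group pair,
#' whether the unadjusted pairwise p-value fell below `alpha`. The per-pair
#' rejection frequency estimates the route's per-comparison type-I error.
#'
#' @param n_reps number of null replicates.
#' @param n group size (default 9).
#' @param alpha nominal level (default 0.05).
#' @return named numeric vector of per-pair rejection frequencies.
#' @export
lsd_null_calibration <- function(n_reps = 5000, n = 9, alpha = 0.05) {
  groups <- rep(diet_groups(), each = n)
  rej <- NULL
  for (i in seq_len(n_reps)) {
    d <- data.frame(value = stats::rnorm(3 * n), diet_group = groups)
    cmp <- suppressWarnings(group_compare(value ~ diet_group, d))
    hit <- stats::setNames(as.numeric(cmp$pairwise$p < alpha),
                           paste(cmp$pairwise$group_b, "vs", cmp$pairwise$group_a))
    rej <- if (is.null(rej)) hit else rej + hit
  }
  rej / n_reps
}

#' Detection power across synthetic spot cohorts
#'
#' Simulates `n_reps` densitometry cohorts from `config`, computes the
#' carbonylation-index table, runs the comparison engine on every spot and
#' tallies (i) how often each spot's pair of interest is flagged significant
#' and (ii) whether every emitted arrow agreed with the sign of the group
#' mean difference.
#'
#' @param config a [cohort_config()] (spot targets define the effect sizes).
#' @param n_reps number of simulated cohorts.
#' @param pair character vector `c(group_a, group_b)` tallied for
#'   significance (default HFHS vs STD).
#' @param alpha significance level (default 0.05, strict).
#' @return list `flag_rate` (named per-spot frequencies), `effect_size`
#'   (named per-spot standardized mean differences of the configured
#'   targets), `arrows_consistent` (logical).
#' @export
spot_detection_power <- function(config, n_reps = 200,
                                 pair = c("STD", "HFHS"), alpha = 0.05) {
  spots <- unique(config$spots$spot_id)
  hits <- stats::setNames(numeric(length(spots)), spots)
  arrows_ok <- TRUE
  for (r in seq_len(n_reps)) {
    dens <- generate_densitometry(config, seed = NULL)
    tab <- carbonylation_table(dens, detection_limit = config$detection_limit)
    tab <- tab[tab$defined, ]
    for (s in spots) {
      d <- tab[tab$spot_id == s, ]
      cmp <- suppressWarnings(
        group_compare(index ~ diet_group,
                      data.frame(index = d$index, diet_group = d$diet_group)))
      pw <- annotate_comparison(cmp, alpha = alpha)
      arrows_ok <- arrows_ok &&
        all(pw$arrow == "" | (pw$arrow == "+" & pw$diff > 0) |
              (pw$arrow == "-" & pw$diff < 0))
      row <- pw[(pw$group_a == pair[1] & pw$group_b == pair[2]) |
                (pw$group_a == pair[2] & pw$group_b == pair[1]), ]
      if (nrow(row) && !is.na(row$p[1]) && row$p[1] < alpha) {
        hits[s] <- hits[s] + 1
      }
    }
  }
  es <- vapply(spots, function(s) {
    d <- config$spots[config$spots$spot_id == s, ]
    m <- stats::setNames(d$mean, d$diet_group)
    sdv <- stats::setNames(d$sd, d$diet_group)
    abs(m[[pair[2]]] - m[[pair[1]]]) /
      sqrt((sdv[[pair[1]]]^2 + sdv[[pair[2]]]^2) / 2)
  }, numeric(1))
  list(flag_rate = hits / n_reps, effect_size = es, arrows_consistent = arrows_ok)
}
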