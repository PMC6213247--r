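#' Moment-matched truncated-normal draws
#'
#' Draws from a normal distribution truncated below at zero whose parameters
#' are solved so that the *truncated* distribution has exactly the requested
#' mean and standard deviation (naive truncation of `N(mean, sd)` would bias
#' the mean upward whenever `mean/sd` is small). Sampling is by inverse CDF,
#' so draws are reproducible across platforms given the RNG state.
#'
#' @param n number of draws.
#' @param mean,sd target moments of the truncated distribution; `sd = 0`
#'   returns `rep(mean, n)`. Requires `mean > sd` (the truncated-at-zero
#'   normal family cannot reach a coefficient of variation of 1 or more).
#' @return numeric vector of `n` non-negative draws.
#' @export
rtnorm_match <- function(n, mean, sd) {
  stop_if_not_scalar_number(mean, "mean")
  stop_if_not_scalar_number(sd, "sd")
  if (mean < 0 || sd < 0) stop("`mean` and `sd` must be >= 0", call. = FALSE)
  if (sd == 0) return(rep(mean, n))
  par <- tnorm_solve(mean, sd)
  plo <- stats::pnorm(-par$mu / par$sigma)
  u <- stats::runif(n)
  par$mu + par$sigma * stats::qnorm(plo + u * (1 - plo))
}

# hazard-type ratio phi(a)/Phi(a), computed on the log scale for stability
tnorm_lambda <- function(a) exp(stats::dnorm(a, log = TRUE) - stats::pnorm(a, log.p = TRUE))

# solve for (mu, sigma) of the underlying normal such that truncation at 0
# yields moments (m, s); parameterized by a = mu/sigma:
#   E  = sigma * (a + lambda(a))
#   SD = sigma * sqrt(1 - a*lambda(a) - lambda(a)^2)
tnorm_solve <- function(m, s) {
  k <- m / s
  if (k <= 1) {
    stop(sprintf("mean/sd = %.3f <= 1: not reachable by a zero-truncated normal", k),
         call. = FALSE)
  }
  f <- function(a) {
    h <- tnorm_lambda(a)
    (a + h) / sqrt(pmax(1 - a * h - h^2, .Machine$double.eps)) - k
  }
  lo <- -1
  while (f(lo) > 0 && lo > -40) lo <- lo - 1
  root <- stats::uniroot(f, c(lo, k + 1), tol = 1e-12)$root
  h <- tnorm_lambda(root)
  sigma <- s / sqrt(1 - root * h - h^2)
  list(mu = root * sigma, sigma = sigma)
}

#' Cohort configuration
#'
#' Bundles everything the generator needs: per-variable per-group (mean, sd)
#' for scalar variables, the fatty-acid composition table, the per-spot
#' carbonylation-index table, group size, and the densitometry settings
#' (Coomassie log-normal scale, detection limit, low-abundance spot
#' analogues).
#'
#' @param variables data.frame `variable, diet_group, mean, sd` for scalar
#'   measurements (biometrics, enzymes, peroxidation).
#' @param fatty_acids data.frame `fa_name, diet_group, mean, sd` (percent of
#'   total fatty acids; renormalized to 100 per animal after drawing).
#' @param spots data.frame `spot_id, diet_group, mean, sd` of target
#'   carbonylation indexes.
#' @param n_per_group animals per group (default 9).
#' @param groups diet-group labels.
#' @param coomassie_meanlog,coomassie_sdlog log-normal parameters of the raw
#'   Coomassie spot intensity (arbitrary densitometry units).
#' @param detection_limit raw Coomassie intensity below which a spot is
#'   unquantifiable.
#' @param low_abundance_spots character vector of spot ids generated below
#'   the Coomassie detection limit but with strong FTSC signal (undefined
#'   index downstream; analogues of the study's spots A-E).
#' @param low_abundance_ftsc FTSC intensity scale of those spots.
#' @return object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(variables, fatty_acids, spots,
                          n_per_group = 9, groups = diet_groups(),
                          coomassie_meanlog = log(5e4), coomassie_sdlog = 0.3,
                          detection_limit = 1e3,
                          low_abundance_spots = c("A", "B", "C", "D", "E"),
                          low_abundance_ftsc = 5e5) {
  cfg <- list(variables = variables, fatty_acids = fatty_acids, spots = spots,
              n_per_group = as.integer(n_per_group), groups = groups,
              coomassie_meanlog = coomassie_meanlog,
              coomassie_sdlog = coomassie_sdlog,
              detection_limit = detection_limit,
              low_abundance_spots = as.character(low_abundance_spots),
              low_abundance_ftsc = low_abundance_ftsc)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  check_tab <- function(tab, key, what) {
    if (!all(c(key, "diet_group", "mean", "sd") %in% names(tab))) {
      stop(sprintf("config %s table needs columns %s, diet_group, mean, sd",
                   what, key), call. = FALSE)
    }
    if (any(!is.finite(tab$mean)) || any(!is.finite(tab$sd))) {
      stop(sprintf("config %s table has non-finite mean/sd", what), call. = FALSE)
    }
    if (any(tab$sd < 0)) stop(sprintf("config %s table has sd < 0", what), call. = FALSE)
    if (any(tab$mean < 0)) stop(sprintf("config %s table has mean < 0", what), call. = FALSE)
    bad <- setdiff(unique(tab$diet_group), cfg$groups)
    if (length(bad)) stop("config table has unknown diet group(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  check_tab(cfg$variables, "variable", "variables")
  check_tab(cfg$fatty_acids, "fa_name", "fatty_acids")
  check_tab(cfg$spots, "spot_id", "spots")
  if (is.na(cfg$n_per_group) || cfg$n_per_group < 2L) {
    stop("`n_per_group` must be >= 2", call. = FALSE)
  }
  if (cfg$detection_limit <= 0) stop("`detection_limit` must be > 0", call. = FALSE)
  invisible(cfg)
}

#' Default cohort configuration from the packaged study tables
#'
#' Builds the [cohort_config()] whose group means and standard deviations are
#' the published ones: biometric/plasma measurements and antioxidant enzymes,
#' conjugated dienes, the 22-acid liver composition, and the 36 spot
#' carbonylation indexes, at `n = 9` animals per group. This configuration
#' *is* the emulated study condition; its values are not tuning knobs.
#'
#' @param n_per_group animals per group (default 9, the study's group size).
#' @return a `cohort_config`.
#' @export
default_cohort_config <- function(n_per_group = 9) {
  tabs <- study_tables()
  scalars <- rbind(
    tabs$biometrics[, c("variable", "diet_group", "mean", "sd")],
    tabs$antioxidants[tabs$antioxidants$variable != "gssg_gsh",
                      c("variable", "diet_group", "mean", "sd")],
    tabs$peroxidation[, c("variable", "diet_group", "mean", "sd")])
  cohort_config(variables = scalars,
                fatty_acids = tabs$fatty_acids,
                spots = tabs$spots[, c("spot_id", "diet_group", "mean", "sd")],
                n_per_group = n_per_group)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration:\n")
  cat(sprintf("  %d groups (%s) x n = %d\n", length(x$groups),
              paste(x$groups, collapse = ", "), x$n_per_group))
  cat(sprintf("  %d scalar variables, %d fatty acids, %d spots (+%d low-abundance)\n",
              length(unique(x$variables$variable)),
              length(unique(x$fatty_acids$fa_name)),
              length(unique(x$spots$spot_id)), length(x$low_abundance_spots)))
  invisible(x)
}

#' Write / read a cohort configuration as JSON
#'
#' Serializes the full configuration (tables included) so a cohort's
#' provenance — config plus seed — can be stored alongside its outputs.
#'
#' @param config a [cohort_config()].
#' @param path file path.
#' @return `write_cohort_config` returns `path` invisibly;
#'   `read_cohort_config` returns a `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, digits = I(17), auto_unbox = TRUE,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_num_cols <- function(df, cols) {
    df <- as.data.frame(df)
    for (cl in cols) df[[cl]] <- as.numeric(df[[cl]])
    df
  }
  cohort_config(variables = as_num_cols(x$variables, c("mean", "sd")),
                fatty_acids = as_num_cols(x$fatty_acids, c("mean", "sd")),
                spots = as_num_cols(x$spots, c("mean", "sd")),
                n_per_group = x$n_per_group, groups = x$groups,
                coomassie_meanlog = as.numeric(x$coomassie_meanlog),
                coomassie_sdlog = as.numeric(x$coomassie_sdlog),
                detection_limit = as.numeric(x$detection_limit),
                low_abundance_spots = as.character(x$low_abundance_spots),
                low_abundance_ftsc = as.numeric(x$low_abundance_ftsc))
}

draw_scalar <- function(n, mean, sd) {
  if (sd == 0) rep(mean, n) else rtnorm_match(n, mean, sd)
}

#' Generate a synthetic per-animal cohort
#'
#' Draws a full cohort from a [cohort_config()]: every scalar variable from a
#' zero-truncated normal moment-matched to its configured (mean, sd); the
#' fatty-acid profile per acid, then renormalized to sum to 100 per animal
#' (the only between-acid dependence; no covariance structure is published);
#' and the 2-D densitometry via [generate_densitometry()]. Animal ids are
#' `<group>_<i>`, each animal is its own gel. Fixing `seed` makes the cohort
#' bit-identical across runs.
#'
#' @param config a `cohort_config`.
#' @param seed integer seed (set once at entry; pass `NULL` to use the
#'   current RNG state).
#' @return object of class `synthetic_cohort`: list of data.frames
#'   `animals` (`animal_id, diet_group`), `biometrics` (wide, one row per
#'   animal), `fatty_acids` (long), `densitometry` (long), plus `config` and
#'   `seed`.
#' @export
generate_cohort <- function(config, seed = NULL) {
  validate_cohort_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_per_group
  animals <- data.frame(
    animal_id = unlist(lapply(config$groups, function(g) {
      sprintf("%s_%d", gsub("[^A-Za-z0-9]+", "", g), seq_len(n))
    })),
    diet_group = rep(config$groups, each = n), stringsAsFactors = FALSE)

  # scalar variables, drawn variable-major then group-major (fixed order)
  biom <- animals
  for (v in unique(config$variables$variable)) {
    col <- rep(NA_real_, nrow(animals))
    for (g in config$groups) {
      row <- config$variables[config$variables$variable == v &
                              config$variables$diet_group == g, ]
      if (nrow(row) == 1L) {
        col[animals$diet_group == g] <- draw_scalar(n, row$mean, row$sd)
      }
    }
    biom[[v]] <- col
  }

  # fatty acids: independent per-acid draws, renormalized to 100 per animal
  fa_rows <- lapply(config$groups, function(g) {
    tab <- config$fatty_acids[config$fatty_acids$diet_group == g, ]
    draws <- vapply(seq_len(nrow(tab)),
                    function(i) draw_scalar(n, tab$mean[i], tab$sd[i]),
                    numeric(n))  # n x n_fa
    draws <- draws * 100 / rowSums(draws)
    ids <- animals$animal_id[animals$diet_group == g]
    data.frame(animal_id = rep(ids, times = nrow(tab)),
               diet_group = g,
               fa_name = rep(tab$fa_name, each = n),
               percent = as.vector(draws), stringsAsFactors = FALSE)
  })
  fatty_acids <- do.call(rbind, fa_rows)

  densitometry <- generate_densitometry(config, seed = NULL, animals = animals)

  structure(list(animals = animals, biometrics = biom,
                 fatty_acids = fatty_acids, densitometry = densitometry,
                 config = config, seed = seed),
            class = "synthetic_cohort")
}

#' Generate synthetic 2-D gel densitometry
#'
#' Per animal (= one gel pair) and spot: the raw Coomassie intensity is drawn
#' log-normal; the target carbonylation index is drawn from a zero-truncated
#' normal moment-matched to that spot/group's configured (mean, sd); the FTSC
#' intensity is `index * Coomassie`, so the raw-ratio index recovers the
#' configured targets. Low-abundance analogue spots are drawn with Coomassie
#' uniformly below the detection limit and a strong fixed-scale FTSC signal,
#' so their index is undefined downstream.
#'
#' @param config a `cohort_config`.
#' @param seed integer seed, or `NULL` to continue the current RNG stream.
#' @param animals optional animal table (`animal_id, diet_group`); built from
#'   the config when omitted.
#' @return long data.frame `gel_id, animal_id, diet_group, channel, spot_id,
#'   intensity`.
#' @export
generate_densitometry <- function(config, seed = NULL, animals = NULL) {
  validate_cohort_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_per_group
  if (is.null(animals)) {
    animals <- data.frame(
      animal_id = unlist(lapply(config$groups, function(g) {
        sprintf("%s_%d", gsub("[^A-Za-z0-9]+", "", g), seq_len(n))
      })),
      diet_group = rep(config$groups, each = n), stringsAsFactors = FALSE)
  }
  spot_ids <- unique(config$spots$spot_id)
  rows <- lapply(seq_len(nrow(animals)), function(i) {
    g <- animals$diet_group[i]
    tab <- config$spots[config$spots$diet_group == g, ]
    tab <- tab[match(spot_ids, tab$spot_id), ]
    coomassie <- stats::rlnorm(nrow(tab), config$coomassie_meanlog,
                               config$coomassie_sdlog)
    target <- vapply(seq_len(nrow(tab)),
                     function(j) draw_scalar(1, tab$mean[j], tab$sd[j]),
                     numeric(1))
    ftsc <- target * coomassie
    lo <- config$low_abundance_spots
    lo_coomassie <- config$detection_limit * stats::runif(length(lo), 0.05, 0.8)
    lo_ftsc <- config$low_abundance_ftsc * stats::rlnorm(length(lo), 0, 0.2)
    data.frame(gel_id = animals$animal_id[i], animal_id = animals$animal_id[i],
               diet_group = g,
               channel = rep(c("FTSC", "Coomassie"),
                             each = nrow(tab) + length(lo)),
               spot_id = rep(c(tab$spot_id, lo), times = 2),
               intensity = c(ftsc, lo_ftsc, coomassie, lo_coomassie),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d animals (%s), seed %s\n",
              nrow(x$animals),
              paste(sprintf("%s n=%d", x$config$groups,
                            as.integer(table(x$animals$diet_group)[x$config$groups])),
                    collapse = ", "),
              x$seed %||% "<none>"))
  cat(sprintf("  %d biometric columns, %d fatty-acid rows, %d densitometry rows\n",
              ncol(x$biometrics) - 2L, nrow(x$fatty_acids), nrow(x$densitometry)))
  invisible(x)
}

#' Configured-mean recovery check for a generated cohort
#'
#' For every configured (variable, diet group) pair — scalar variables,
#' fatty acids and spot carbonylation indexes — compares the cohort's sample
#' mean with the configured mean. A pair is `recovered` when the sample mean
#' lies within 3 standard errors (`3 * sd / sqrt(n)`) of the target. For
#' variables configured with `sd = 0` the draw is constant, so the standard
#' error is degenerate; these count as recovered when the deviation stays
#' below half of the printed table resolution (`max(0.005, 0.001 * mean)`),
#' the slack needed because compositional renormalization of the fatty-acid
#' profiles rescales constants by a factor of order 1e-4.
#'
#' @param cohort a [generate_cohort()] result.
#' @return data.frame `kind, variable, diet_group, target_mean, sample_mean,
#'   se, recovered`.
#' @export
mean_recovery <- function(cohort) {
  cfg <- cohort$config
  spot_tab <- carbonylation_table(cohort$densitometry,
                                  detection_limit = cfg$detection_limit)
  if (!"diet_group" %in% names(spot_tab)) {
    spot_tab$diet_group <-
      cohort$animals$diet_group[match(spot_tab$animal_id, cohort$animals$animal_id)]
  }
  rows <- list()
  add <- function(kind, variable, g, target, sd0, x) {
    x <- x[!is.na(x)]
    se <- sd0 / sqrt(length(x))
    recovered <- if (sd0 == 0) {
      abs(mean(x) - target) <= max(0.005, 0.001 * target)
    } else {
      abs(mean(x) - target) <= 3 * se
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, variable = variable, diet_group = g, target_mean = target,
      sample_mean = mean(x), se = se, recovered = recovered,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(cfg$variables))) {
    v <- cfg$variables[i, ]
    add("scalar", v$variable, v$diet_group, v$mean, v$sd,
        cohort$biometrics[cohort$biometrics$diet_group == v$diet_group, v$variable])
  }
  for (i in seq_len(nrow(cfg$fatty_acids))) {
    v <- cfg$fatty_acids[i, ]
    add("fatty_acid", v$fa_name, v$diet_group, v$mean, v$sd,
        cohort$fatty_acids$percent[cohort$fatty_acids$diet_group == v$diet_group &
                                   cohort$fatty_acids$fa_name == v$fa_name])
  }
  for (i in seq_len(nrow(cfg$spots))) {
    v <- cfg$spots[i, ]
    add("spot", v$spot_id, v$diet_group, v$mean, v$sd,
        spot_tab$index[spot_tab$diet_group == v$diet_group &
                       spot_tab$spot_id == v$spot_id])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
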