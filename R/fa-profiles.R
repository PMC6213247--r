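#' Construct a fatty-acid profile
#'
#' A profile is the GC-FID composition of one sample, expressed as percentages
#' of total fatty acids. Values are stored under canonical names
#' (see [canonical_fa_name()]).
#'
#' @param values named numeric vector: fatty-acid shorthand -> percent of
#'   total fatty acids.
#' @param tol numeric, allowed deviation of the total from 100 (percentage
#'   points). The default 0.5 absorbs the rounding of published tables.
#' @param check logical; set `FALSE` to skip the closure/negativity checks
#'   (useful for partial profiles).
#' @return an object of class `fa_profile` (named numeric vector).
#' @examples
#' p <- fa_profile(c("16:0" = 30, "18:1ω9" = 25, "18:2ω6" = 40, "22:6ω3" = 5))
#' class_sums(p)
#' @export
fa_profile <- function(values, tol = 0.5, check = TRUE) {
  if (!is.numeric(values) || is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("`values` must be a named numeric vector of percentages", call. = FALSE)
  }
  names(values) <- canonical_fa_name(names(values))
  if (anyDuplicated(names(values))) {
    stop("duplicate fatty-acid names after canonicalization", call. = FALSE)
  }
  if (check) {
    if (any(values < 0)) stop("fatty-acid percentages must be >= 0", call. = FALSE)
    total <- sum(values)
    if (abs(total - 100) > tol) {
      stop(sprintf("profile percentages sum to %.3f, outside 100 +/- %.3g", total, tol),
           call. = FALSE)
    }
  }
  structure(values, class = "fa_profile")
}

#' @export
print.fa_profile <- function(x, ...) {
  cat("Fatty-acid profile (% of total fatty acids), ", length(x), " acids, total ",
      format(sum(x), digits = 5), "%\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

as_fa_profile <- function(x, ...) {
  if (inherits(x, "fa_profile")) x else fa_profile(x, ...)
}

#' Fatty-acid class sums
#'
#' Sums the profile into the classes reported in composition tables:
#' saturated (SAT), monounsaturated (MUFA), polyunsaturated (PUFA, two or more
#' double bonds) and the omega-3 / omega-6 PUFA subtotals. Monounsaturated
#' omega-3/6 acids (none occur in practice) would count toward MUFA only:
#' the omega subtotals are PUFA subtotals, which is what reproduces published
#' class rows.
#'
#' @param profile an [fa_profile()] (or named numeric vector of percentages).
#' @return named numeric vector with elements `SAT`, `MUFA`, `PUFA`,
#'   `omega3`, `omega6` (percent of total fatty acids).
#' @export
class_sums <- function(profile) {
  profile <- as_fa_profile(profile, check = FALSE)
  desc <- parse_fa_name(names(profile))
  v <- as.numeric(profile)
  pufa <- desc$double_bonds >= 2L
  c(SAT    = sum(v[desc$family == "saturated"]),
    MUFA   = sum(v[desc$double_bonds == 1L]),
    PUFA   = sum(v[pufa]),
    omega3 = sum(v[pufa & desc$family == "n-3"]),
    omega6 = sum(v[pufa & desc$family == "n-6"]))
}

# product/substrate pairs defining the desaturase-index panel, plus the
# EPA/DHA ratio reported alongside composition tables
fad_index_pairs <- function() {
  list(
    scd16    = c("16:1n-7", "16:0"),   # delta-9 stearoyl-CoA desaturase, C16
    scd18    = c("18:1n-9", "18:0"),   # delta-9 stearoyl-CoA desaturase, C18
    d4d      = c("22:6n-3", "22:5n-3"),
    d5d      = c("20:4n-6", "20:3n-6"),
    d6d_dgla = c("20:3n-6", "18:2n-6"),
    d6d_gla  = c("18:3n-6", "18:2n-6"),
    d5d6d    = c("20:5n-3", "18:3n-3"),
    epa_dha  = c("20:5n-3", "22:6n-3")
  )
}

#' Desaturase (FAD) index panel
#'
#' Desaturase activity is estimated as the percentage ratio of the enzyme's
#' product to its substrate: SCD-16 = 16:1n-7/16:0, SCD-18 = 18:1n-9/18:0,
#' delta-4 = 22:6n-3/22:5n-3, delta-5 = 20:4n-6/20:3n-6, delta-6 =
#' 20:3n-6/18:2n-6 (DGLA route) and 18:3n-6/18:2n-6 (GLA route), and the
#' combined delta-5/6 = 20:5n-3/18:3n-3. The EPA/DHA ratio
#' (20:5n-3 / 22:6n-3) is included in the panel.
#'
#' A ratio whose substrate percentage is zero (or whose acids are absent from
#' the profile) is returned as `NA` — undefined, not an error — so panels stay
#' computable sample by sample.
#'
#' @param profile an [fa_profile()].
#' @return named numeric vector `scd16, scd18, d4d, d5d, d6d_dgla, d6d_gla,
#'   d5d6d, epa_dha`; `NA` where undefined.
#' @export
desaturase_indexes <- function(profile) {
  profile <- as_fa_profile(profile, check = FALSE)
  pairs <- fad_index_pairs()
  vapply(pairs, function(pr) {
    num <- unname(profile[pr[1]])
    den <- unname(profile[pr[2]])
    if (is.na(den) || is.na(num) || den == 0) NA_real_ else num / den
  }, numeric(1))
}

#' Omega-6 / omega-3 inflammation index
#'
#' The ratio of the omega-6 to the omega-3 PUFA class sums; lower values
#' indicate a more anti-inflammatory tissue fatty-acid phenotype.
#'
#' @param profile an [fa_profile()].
#' @return a single number, or `NA` when the omega-3 sum is zero.
#' @export
inflammation_index <- function(profile) {
  cs <- class_sums(profile)
  if (cs[["omega3"]] == 0) return(NA_real_)
  unname(cs[["omega6"]] / cs[["omega3"]])
}

#' Between-diet shift of selected fatty acids
#'
#' Difference, in percentage points of total fatty acids, of the summed
#' percentage of `fas` between two profiles (`profile_b - profile_a`), e.g.
#' the DHA gain of the fish-oil arm over the unsupplemented high-caloric arm.
#'
#' @param profile_a,profile_b [fa_profile()] objects (reference first).
#' @param fas character vector of fatty-acid names (any accepted dialect).
#' @return a single number (percentage points).
#' @export
diet_shift <- function(profile_a, profile_b, fas) {
  profile_a <- as_fa_profile(profile_a, check = FALSE)
  profile_b <- as_fa_profile(profile_b, check = FALSE)
  if (length(fas) == 0L) stop("`fas` must name at least one fatty acid", call. = FALSE)
  fas <- canonical_fa_name(fas)
  missing_a <- setdiff(fas, names(profile_a))
  missing_b <- setdiff(fas, names(profile_b))
  if (length(missing_a) || length(missing_b)) {
    stop(sprintf("unknown fatty acid(s): %s",
                 paste(unique(c(missing_a, missing_b)), collapse = ", ")),
         call. = FALSE)
  }
  sum(profile_b[fas]) - sum(profile_a[fas])
}

#' Per-sample derived fatty-acid quantities from a long table
#'
#' Takes a long-format table (`animal_id, diet_group, fa_name, percent`) and
#' returns one row per animal with the class sums, the desaturase-index panel
#' and the inflammation index, computed per animal ("mean of ratios" when the
#' result is later averaged by group — the convention behind published
#' desaturase tables).
#'
#' @param fa_long data.frame with columns `animal_id`, `diet_group`,
#'   `fa_name`, `percent`.
#' @param tol closure tolerance passed to [fa_profile()].
#' @return data.frame, one row per animal: `animal_id`, `diet_group`, class
#'   sums, desaturase panel, `omega6_omega3`.
#' @export
fa_derived_table <- function(fa_long, tol = 0.5) {
  needed <- c("animal_id", "diet_group", "fa_name", "percent")
  if (!all(needed %in% names(fa_long))) {
    stop("`fa_long` needs columns: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  split_by <- split(fa_long, fa_long$animal_id)
  rows <- lapply(split_by, function(d) {
    prof <- fa_profile(stats::setNames(d$percent, d$fa_name), tol = tol)
    cbind(data.frame(animal_id = d$animal_id[1], diet_group = d$diet_group[1],
                     stringsAsFactors = FALSE),
          as.data.frame(t(class_sums(prof))),
          as.data.frame(t(desaturase_indexes(prof))),
          data.frame(omega6_omega3 = inflammation_index(prof)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$diet_group, out$animal_id), , drop = FALSE]
}
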