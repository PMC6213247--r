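#' Parts-per-million normalization of gel densitometry
#'
#' Expresses each spot's integrated optical density as parts per million of
#' the total integrated optical density of that gel/channel, removing
#' gel-to-gel loading and exposure differences. The output always sums to
#' 1e6 (up to floating rounding) and is invariant to rescaling the input.
#'
#' @param intensities named (or unnamed) non-negative numeric vector, one
#'   element per spot/band of a single gel and channel.
#' @return numeric vector of the same length and names, in ppm.
#' @export
ppm_normalize <- function(intensities) {
  if (!is.numeric(intensities) || length(intensities) == 0L) {
    stop("`intensities` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stop("intensities must be finite and >= 0", call. = FALSE)
  }
  total <- sum(intensities)
  if (total <= 0) stop("all intensities are zero: no normalizable signal", call. = FALSE)
  1e6 * intensities / total
}

#' Protein carbonylation index of one spot
#'
#' The carbonylation index is the FTSC (carbonyl-specific fluorescence)
#' intensity divided by the Coomassie (total protein) intensity of the same
#' spot, i.e. carbonylation normalized for protein amount. When the spot's
#' raw Coomassie signal is below the stain's detection limit the index is
#' undefined (`NA`) — such spots carry carbonyl fluorescence but no
#' quantifiable protein amount and must propagate as missing, never as zero.
#'
#' @param ftsc FTSC intensity of the spot (raw or ppm, but the same scale as
#'   `coomassie`).
#' @param coomassie Coomassie intensity of the spot on the same scale.
#' @param coomassie_raw raw Coomassie intensity used for the detection-limit
#'   check; defaults to `coomassie`.
#' @param detection_limit minimum quantifiable raw Coomassie intensity
#'   (default 0: no limit).
#' @return index value, or `NA` when below the detection limit.
#' @export
carbonylation_index <- function(ftsc, coomassie, coomassie_raw = coomassie,
                                detection_limit = 0) {
  if (any(c(ftsc, coomassie, coomassie_raw) < 0, na.rm = TRUE)) {
    stop("intensities must be >= 0", call. = FALSE)
  }
  ifelse(is.na(coomassie_raw) | coomassie_raw < detection_limit | coomassie <= 0,
         NA_real_, ftsc / coomassie)
}

#' Total-lane carbonylation index for 1-D gels
#'
#' Eq.-style index at lane granularity: summed FTSC lane intensity over summed
#' Coomassie lane intensity. Used for the global (total) protein carbonylation
#' readout of 1-D gels.
#'
#' @param band_ftsc numeric vector of FTSC band intensities of one lane.
#' @param band_coomassie numeric vector of Coomassie band intensities of the
#'   same lane (need not be band-matched; only totals enter).
#' @return a single index value.
#' @export
lane_index <- function(band_ftsc, band_coomassie) {
  if (length(band_ftsc) == 0L || length(band_coomassie) == 0L) {
    stop("both lanes must be non-empty", call. = FALSE)
  }
  if (any(band_ftsc < 0) || any(band_coomassie < 0)) {
    stop("intensities must be >= 0", call. = FALSE)
  }
  total_coomassie <- sum(band_coomassie)
  if (total_coomassie <= 0) stop("zero Coomassie lane total", call. = FALSE)
  sum(band_ftsc) / total_coomassie
}

#' Per-animal spot carbonylation index table from long densitometry
#'
#' Pairs the FTSC and Coomassie channels of each gel by `spot_id` and computes
#' the per-spot carbonylation index. With `normalization = "raw"` (default)
#' the index is the raw intensity ratio; with `"ppm"` each channel is first
#' ppm-normalized within its gel, which rescales every index of a gel by that
#' gel's total-Coomassie/total-FTSC factor and therefore yields an index
#' relative to the gel's overall carbonylation load (see the methods
#' vignette for why raw is the default).
#'
#' @param densitometry data.frame with columns `gel_id`, `animal_id`,
#'   `channel` (`"FTSC"` or `"Coomassie"`), `spot_id`, `intensity`, and
#'   optionally `diet_group` (carried through).
#' @param detection_limit raw Coomassie intensity below which a spot's index
#'   is undefined.
#' @param normalization `"raw"` or `"ppm"`.
#' @return data.frame `animal_id[, diet_group], spot_id, index, defined`.
#' @export
carbonylation_table <- function(densitometry, detection_limit = 0,
                                normalization = c("raw", "ppm")) {
  normalization <- match.arg(normalization)
  needed <- c("gel_id", "animal_id", "channel", "spot_id", "intensity")
  if (!all(needed %in% names(densitometry))) {
    stop("`densitometry` needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(densitometry$channel), c("FTSC", "Coomassie"))
  if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "), call. = FALSE)

  per_gel <- split(densitometry, densitometry$gel_id)
  rows <- lapply(per_gel, function(g) {
    f <- g[g$channel == "FTSC", ]
    c_ <- g[g$channel == "Coomassie", ]
    if (anyDuplicated(f$spot_id) || anyDuplicated(c_$spot_id)) {
      stop(sprintf("gel '%s': duplicate (channel, spot) records", g$gel_id[1]),
           call. = FALSE)
    }
    spots <- intersect(f$spot_id, c_$spot_id)
    fi <- stats::setNames(f$intensity, f$spot_id)[spots]
    ci <- stats::setNames(c_$intensity, c_$spot_id)[spots]
    if (normalization == "ppm") {
      fv <- ppm_normalize(fi)
      cv <- ppm_normalize(ci)
    } else {
      fv <- fi
      cv <- ci
    }
    idx <- carbonylation_index(fv, cv, coomassie_raw = ci,
                               detection_limit = detection_limit)
    out <- data.frame(animal_id = g$animal_id[1], spot_id = spots,
                      index = unname(idx), defined = !is.na(idx),
                      stringsAsFactors = FALSE)
    if ("diet_group" %in% names(g)) out$diet_group <- g$diet_group[1]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  cols <- c("animal_id", intersect("diet_group", names(out)), "spot_id", "index", "defined")
  out[, cols, drop = FALSE]
}
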