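#' Adiposity index
#'
#' Total abdominal (perigonadal) fat mass as a percentage of body weight:
#' `fat * 100 / body_weight`.
#'
#' @param abdominal_fat fat depot mass (g).
#' @param body_weight body weight (g), must be positive.
#' @return percentage.
#' @export
adiposity_index <- function(abdominal_fat, body_weight) {
  if (any(body_weight <= 0)) stop("`body_weight` must be > 0", call. = FALSE)
  if (any(abdominal_fat < 0)) stop("`abdominal_fat` must be >= 0", call. = FALSE)
  abdominal_fat * 100 / body_weight
}

#' Hepatosomatic index
#'
#' Liver weight as a percentage of body weight: `liver * 100 / body_weight`.
#'
#' @param liver_weight liver mass (g).
#' @param body_weight body weight (g), must be positive.
#' @return percentage.
#' @export
hepatosomatic_index <- function(liver_weight, body_weight) {
  if (any(body_weight <= 0)) stop("`body_weight` must be > 0", call. = FALSE)
  if (any(liver_weight < 0)) stop("`liver_weight` must be >= 0", call. = FALSE)
  liver_weight * 100 / body_weight
}

#' Redox and transaminase ratio panel
#'
#' Per-animal ratios reported alongside the raw measurements: GSSG/GSH
#' (oxidized over reduced glutathione, higher = more redox imbalance) and the
#' AST/ALT and ALT/AST transaminase ratios. Ratios are computed animal by
#' animal; averaging them per group gives a mean of ratios, which differs from
#' the ratio of the group means (Jensen's inequality) — published ratio rows
#' follow the per-animal convention.
#'
#' @param gssg,gsh oxidized and reduced glutathione (same units).
#' @param ast,alt transaminase activities (U/L).
#' @return data.frame with columns `gssg_gsh`, `ast_alt`, `alt_ast`; `NA`
#'   where a denominator is zero.
#' @export
ratio_panel <- function(gssg, gsh, ast, alt) {
  safe_ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  data.frame(gssg_gsh = safe_ratio(gssg, gsh),
             ast_alt  = safe_ratio(ast, alt),
             alt_ast  = safe_ratio(alt, ast))
}

#' Augment a per-animal biometrics table with derived indexes
#'
#' Adds `adiposity_index`, `hepatosomatic_index` and the [ratio_panel()]
#' columns to a wide per-animal table. Columns that are absent are skipped.
#'
#' @param biometrics data.frame with (some of) the columns `body_weight`,
#'   `perigonadal_fat`, `liver_weight`, `gssg`, `gsh`, `ast`, `alt`.
#' @return the input with derived columns appended.
#' @export
add_biometric_indexes <- function(biometrics) {
  b <- biometrics
  if (all(c("perigonadal_fat", "body_weight") %in% names(b))) {
    b$adiposity_index <- adiposity_index(b$perigonadal_fat, b$body_weight)
  }
  if (all(c("liver_weight", "body_weight") %in% names(b))) {
    b$hepatosomatic_index <- hepatosomatic_index(b$liver_weight, b$body_weight)
  }
  if (all(c("gssg", "gsh") %in% names(b))) {
    rp <- ratio_panel(b$gssg, b$gsh,
                      if ("ast" %in% names(b)) b$ast else NA_real_,
                      if ("alt" %in% names(b)) b$alt else NA_real_)
    b <- cbind(b, rp)
  }
  b
}
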