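# Published group summary statistics of the three-arm rat diet study
# (standard chow STD, high-fat high-sucrose HFHS, HFHS + EPA/DHA 1:1 fish
# oil), packaged as reference inputs: they parameterize the synthetic-cohort
# generator and drive the printed-cell reproduction checks. Per-animal raw
# data were not deposited; only these group means and standard deviations are
# available. Stars/arrows are the published significance annotations and are
# carried as metadata, never asserted.

study_long_row <- function(variable, unit, std, hfhs, w3) {
  data.frame(variable = variable, unit = unit,
             diet_group = diet_groups(),
             mean = c(std[1], hfhs[1], w3[1]),
             sd = c(std[2], hfhs[2], w3[2]),
             stringsAsFactors = FALSE)
}

study_biometrics_df <- function() {
  r <- study_long_row
  out <- rbind(
    r("body_weight",     "g",       c(539.6, 49.4), c(568.3, 24.3), c(579.9, 35.7)),
    r("length",          "cm",      c(25.7, 0.4),   c(26.5, 0.6),   c(26.4, 0.4)),
    r("perigonadal_fat", "g",       c(9.0, 3.2),    c(13.1, 3.9),   c(13.3, 4.4)),
    r("liver_weight",    "g",       c(2.7, 0),      c(2.5, 0),      c(2.5, 0)),
    r("liver_fat",       "%",       c(7.01, 0.61),  c(6.64, 0.79),  c(6.55, 0.70)),
    r("triglycerides",   "mmol/L",  c(0.69, 0.20),  c(0.52, 0.26),  c(0.59, 0.23)),
    r("cholesterol",     "mmol/L",  c(3.61, 0.38),  c(2.90, 0.50),  c(2.55, 0.42)),
    r("hdl",             "mmol/L",  c(1.15, 0.12),  c(0.94, 0.16),  c(0.85, 0.12)),
    r("ldl",             "mmol/L",  c(0.43, 0.11),  c(0.39, 0.09),  c(0.32, 0.07)),
    r("insulin",         "ng/mL",   c(0.95, 0.60),  c(2.0, 0.25),   c(2.1, 0.40)),
    r("glucose",         "mg/mL",   c(65, 2),       c(66, 1.5),     c(64, 2)),
    r("ast",             "U/L",     c(70.19, 21.91), c(57.12, 10.74), c(53.58, 10.15)),
    r("alt",             "U/L",     c(27.09, 8.24), c(19.03, 3.88), c(22.84, 4.18)))
  out
}

# printed derived biometric cells (no s.d. printed): reproduced, never drawn
study_biometric_indexes_df <- function() {
  rbind(
    data.frame(variable = "adiposity_index", diet_group = diet_groups(),
               printed = c(1.7, 2.3, 2.3), digits = 1, stringsAsFactors = FALSE),
    data.frame(variable = "hepatosomatic_index", diet_group = diet_groups(),
               printed = c(0.50, 0.44, 0.43), digits = 2, stringsAsFactors = FALSE),
    data.frame(variable = "ast_alt", diet_group = diet_groups(),
               printed = c(2.64, 3.14, 2.37), digits = 2, stringsAsFactors = FALSE),
    data.frame(variable = "alt_ast", diet_group = diet_groups(),
               printed = c(0.39, 0.35, 0.43), digits = 2, stringsAsFactors = FALSE))
}

study_antioxidants_df <- function() {
  r <- study_long_row
  rbind(
    r("sod",  "U/g tissue",    c(813.11, 154.56), c(579.17, 58.90), c(742.72, 61.18)),
    r("cat",  "mmol/g tissue", c(16.83, 2.61),    c(15.46, 0.47),   c(16.22, 0.86)),
    r("gr",   "U/g tissue",    c(157.23, 27.43),  c(109.25, 7.90),  c(134.47, 11.32)),
    r("gpx",  "U/g tissue",    c(848.56, 207.92), c(680.24, 34.88), c(766.28, 53.36)),
    r("gsh",  "umol/g tissue", c(1.38, 0.72),     c(0.73, 0.16),    c(1.00, 0.22)),
    r("gssg", "umol/g tissue", c(2.72, 0.42),     c(2.36, 0.15),    c(1.95, 0.15)),
    r("gssg_gsh", "ratio",     c(2.45, 1.27),     c(4.51, 0.94),    c(2.87, 0.76)))
}

study_fatty_acids_df <- function() {
  fa <- function(name, std, hfhs, w3) {
    data.frame(fa_name = canonical_fa_name(name), diet_group = diet_groups(),
               mean = c(std[1], hfhs[1], w3[1]), sd = c(std[2], hfhs[2], w3[2]),
               stringsAsFactors = FALSE)
  }
  rbind(
    fa("14:0",   c(0.39, 0.05), c(1.12, 0.15), c(1.06, 0.12)),
    fa("15:0",   c(0.20, 0.01), c(0.47, 0.02), c(0.44, 0.03)),
    fa("16:0",   c(20.31, 0.38), c(22.07, 0.45), c(21.88, 0.43)),
    fa("16:1w7", c(1.36, 0.20), c(2.26, 0.45), c(1.92, 0.29)),
    fa("17:0",   c(0.50, 0.04), c(0.58, 0.01), c(0.57, 0.01)),
    fa("18:0",   c(9.81, 0.53), c(11.21, 0.79), c(11.70, 0.79)),
    fa("18:1w9", c(8.24, 0.76), c(19.56, 1.21), c(17.66, 1.10)),
    fa("18:1w7", c(3.71, 0.12), c(3.60, 0.31), c(2.76, 0.14)),
    fa("18:2w6", c(25.93, 0.83), c(10.68, 0.39), c(10.82, 0.28)),
    fa("18:3w6", c(0.54, 0.03), c(0.24, 0.02), c(0.18, 0.00)),
    fa("20:0",   c(0.00, 0.00), c(0.00, 0.00), c(0.00, 0.00)),
    fa("18:3w3", c(0.67, 0.05), c(0.35, 0.04), c(0.34, 0.04)),
    fa("20:1w9", c(0.15, 0.01), c(0.50, 0.06), c(0.48, 0.06)),
    fa("18:4w3", c(0.00, 0.00), c(0.00, 0.00), c(0.00, 0.00)),
    fa("20:2w6", c(0.33, 0.03), c(0.10, 0.01), c(0.11, 0.01)),
    fa("20:3w6", c(0.34, 0.01), c(0.68, 0.08), c(0.86, 0.05)),
    fa("20:4w6", c(20.01, 1.10), c(17.01, 1.18), c(15.22, 0.96)),
    fa("20:5w3", c(0.32, 0.03), c(0.37, 0.04), c(1.11, 0.13)),
    fa("22:4w6", c(0.71, 0.06), c(0.29, 0.03), c(0.21, 0.01)),
    fa("22:5w6", c(0.44, 0.02), c(0.28, 0.04), c(0.16, 0.01)),
    fa("22:5w3", c(1.34, 0.06), c(1.00, 0.10), c(1.41, 0.09)),
    fa("22:6w3", c(4.69, 0.27), c(7.64, 0.65), c(11.10, 0.63)))
}

# printed class-sum and ratio rows of the composition table; `digits` is the
# printed precision used in reproduction checks
study_fa_classes_df <- function() {
  row <- function(variable, vals, digits) {
    data.frame(variable = variable, diet_group = diet_groups(), printed = vals,
               digits = digits, stringsAsFactors = FALSE)
  }
  rbind(
    row("SAT",     c(31.22, 35.44, 35.65), 2),
    row("MUFA",    c(13.46, 25.93, 22.83), 2),
    row("PUFA",    c(55.32, 38.63, 41.52), 2),
    row("omega3",  c(7.02, 9.35, 13.96), 2),
    row("omega6",  c(48.30, 29.28, 27.56), 2),
    row("epa_dha", c(0.068, 0.048, 0.100), 3))
}

# printed desaturase-index panel (computed per animal, then averaged)
study_desaturases_df <- function() {
  r <- function(variable, std, hfhs, w3) {
    data.frame(variable = variable, diet_group = diet_groups(),
               mean = c(std[1], hfhs[1], w3[1]), sd = c(std[2], hfhs[2], w3[2]),
               stringsAsFactors = FALSE)
  }
  rbind(
    r("scd16",    c(0.07, 0.01), c(0.10, 0.02), c(0.09, 0.01)),
    r("scd18",    c(0.87, 0.12), c(1.82, 0.28), c(1.57, 0.21)),
    r("d4d",      c(3.53, 0.21), c(7.94, 1.02), c(8.07, 0.82)),
    r("d5d",      c(60.22, 4.02), c(26.90, 4.24), c(18.00, 1.45)),
    r("d6d_dgla", c(0.01, 0.00), c(0.06, 0.01), c(0.07, 0.00)),
    r("d6d_gla",  c(0.02, 0.00), c(0.02, 0.00), c(0.02, 0.00)),
    r("d5d6d",    c(0.47, 0.04), c(1.06, 0.06), c(3.37, 0.48)))
}

study_peroxidation_df <- function() {
  study_long_row("conjugated_dienes", "mmol hydroperoxides/kg lipid",
                 c(15.82, 0.49), c(23.32, 2.15), c(21.85, 2.48))
}

# 2-D spot carbonylation indexes: 36 identified spots, per-group mean (s.d.),
# published arrows (direction of significant change) and stars. Arrow columns:
# hfhs_vs_std and w3_vs_hfhs; "+" increase, "-" decrease, "" not significant.
study_spots_df <- function() {
  s <- function(spot, gene, std, hfhs, w3, star1, arrow1, star2, arrow2) {
    data.frame(spot_id = as.character(spot), gene = gene,
               diet_group = diet_groups(),
               mean = c(std[1], hfhs[1], w3[1]), sd = c(std[2], hfhs[2], w3[2]),
               star_hfhs_vs_std = star1, arrow_hfhs_vs_std = arrow1,
               star_w3_vs_hfhs = star2, arrow_w3_vs_hfhs = arrow2,
               stringsAsFactors = FALSE)
  }
  rbind(
    s(1,  "Cps1",     c(0.39, 0.20), c(0.76, 0.10), c(0.44, 0.06), "**", "+", "**", "-"),
    s(2,  "Pc",       c(1.01, 0.27), c(0.99, 0.14), c(0.61, 0.02), "",   "",  "**", "-"),
    s(3,  "Dmgdh",    c(0.44, 0.14), c(0.67, 0.10), c(0.60, 0.08), "*",  "+", "",   ""),
    s(4,  "Alb",      c(0.88, 0.18), c(1.49, 0.04), c(0.91, 0.07), "**", "+", "**", "-"),
    s(5,  "Tkt",      c(0.80, 0.21), c(0.85, 0.12), c(0.53, 0.08), "",   "",  "**", "-"),
    s(6,  "Cat",      c(0.64, 0.16), c(0.91, 0.01), c(0.52, 0.00), "**", "+", "**", "-"),
    s(7,  "Pdia3",    c(1.28, 0.19), c(0.77, 0.20), c(1.28, 0.03), "**", "-", "**", "+"),
    s(8,  "Hspd1",    c(0.59, 0.15), c(0.36, 0.03), c(0.24, 0.06), "*",  "-", "*",  "-"),
    s(9,  "Gk",       c(0.62, 0.06), c(0.53, 0.13), c(0.32, 0.06), "",   "",  "*",  "-"),
    s(10, "Ftcd",     c(0.54, 0.05), c(0.43, 0.13), c(0.29, 0.07), "*",  "-", "",   ""),
    s(11, "Aldh2",    c(0.59, 0.03), c(0.85, 0.05), c(0.65, 0.03), "**", "+", "**", "-"),
    s(12, "Pah",      c(1.23, 0.22), c(1.19, 0.14), c(0.82, 0.05), "",   "",  "**", "-"),
    s(13, "Aldh6a1",  c(1.14, 0.58), c(1.00, 0.45), c(1.03, 0.08), "",   "",  "",   ""),
    s(14, "Aldh7a1",  c(1.00, 0.08), c(1.08, 0.21), c(0.74, 0.02), "",   "",  "*",  "-"),
    s(15, "Abat",     c(1.26, 0.46), c(0.93, 0.28), c(0.95, 0.38), "",   "",  "",   ""),
    s(16, "Hmgcs2",   c(0.95, 0.37), c(1.01, 0.41), c(1.02, 0.12), "",   "",  "",   ""),
    s(17, "Pgd",      c(0.71, 0.11), c(0.63, 0.13), c(0.59, 0.17), "",   "",  "",   ""),
    s(18, "Actb",     c(1.15, 0.31), c(1.19, 0.19), c(0.67, 0.32), "",   "",  "*",  "-"),
    s(19, "Idh1",     c(0.31, 0.16), c(0.40, 0.16), c(0.24, 0.04), "",   "",  "",   ""),
    s(20, "Fah",      c(0.48, 0.03), c(0.75, 0.10), c(0.50, 0.08), "**", "+", "*",  "-"),
    s(21, "Ass1",     c(1.00, 0.16), c(1.87, 0.03), c(0.90, 0.11), "**", "+", "**", "-"),
    s(22, "Pgk1",     c(0.52, 0.11), c(0.89, 0.04), c(0.59, 0.14), "**", "+", "**", "-"),
    s(23, "Adh1",     c(1.09, 0.13), c(1.16, 0.26), c(0.59, 0.14), "",   "",  "*",  "-"),
    s(24, "Aldob",    c(0.91, 0.06), c(0.97, 0.04), c(0.62, 0.08), "*",  "+", "**", "-"),
    s(25, "Akr1d1",   c(0.38, 0.05), c(0.32, 0.03), c(0.19, 0.05), "*",  "-", "**", "-"),
    s(26, "Rgn",      c(0.53, 0.11), c(0.72, 0.19), c(1.06, 0.27), "*",  "+", "**", "+"),
    s(27, "Gapdh",    c(0.59, 0.21), c(0.55, 0.14), c(0.75, 0.29), "**", "-", "",   ""),
    s(28, "Tst",      c(0.50, 0.04), c(0.57, 0.10), c(0.63, 0.06), "",   "",  "",   ""),
    s(29, "Mdh1",     c(0.41, 0.15), c(0.77, 0.09), c(0.41, 0.12), "**", "+", "**", "-"),
    s(30, "Haao",     c(0.72, 0.42), c(0.81, 0.03), c(0.51, 0.14), "",   "",  "**", "-"),
    s(31, "Nit2",     c(1.89, 0.39), c(1.95, 0.30), c(1.31, 0.47), "",   "",  "*",  "-"),
    s(32, "Ca3",      c(0.56, 0.12), c(0.83, 0.17), c(0.43, 0.09), "*",  "+", "*",  "-"),
    s(33, "Gstm2",    c(1.35, 0.37), c(1.98, 0.12), c(1.17, 0.31), "**", "+", "**", "-"),
    s(34, "Gstm2",    c(0.95, 0.03), c(1.35, 0.08), c(0.93, 0.01), "**", "+", "**", "-"),
    s(35, "Gstm2",    c(0.72, 0.19), c(2.25, 0.16), c(1.14, 0.07), "**", "+", "**", "-"),
    s(36, "Hsd17b10", c(0.56, 0.46), c(0.98, 0.12), c(0.62, 0.26), "*",  "+", "*",  "-"))
}

#' Published group summary tables of the diet study
#'
#' The study's printed per-group means and standard deviations, packaged as
#' reference inputs: biometric and plasma measurements, liver antioxidant
#' system, liver fatty-acid composition (22 acids), printed class sums and
#' EPA/DHA ratios, the desaturase-index panel, lipid peroxidation, and the 36
#' identified 2-D spot carbonylation indexes with their published star/arrow
#' annotations. `n = 9` animals per group. These tables parameterize
#' [default_cohort_config()] and the printed-cell checks of
#' [reproduce_printed()].
#'
#' @return named list of data.frames: `biometrics`, `biometric_indexes`,
#'   `antioxidants`, `fatty_acids`, `fa_classes`, `desaturases`,
#'   `peroxidation`, `spots`.
#' @export
study_tables <- function() {
  list(biometrics = study_biometrics_df(),
       biometric_indexes = study_biometric_indexes_df(),
       antioxidants = study_antioxidants_df(),
       fatty_acids = study_fatty_acids_df(),
       fa_classes = study_fa_classes_df(),
       desaturases = study_desaturases_df(),
       peroxidation = study_peroxidation_df(),
       spots = study_spots_df())
}

#' Printed group-mean fatty-acid profile of one diet group
#'
#' Convenience accessor: the published mean composition column as an
#' [fa_profile()] (the columns sum to 99.99-100.01 due to printed rounding).
#'
#' @param diet_group `"STD"`, `"HFHS"` or `"HFHS+w3"`.
#' @return an `fa_profile`.
#' @export
study_mean_profile <- function(diet_group = diet_groups()) {
  diet_group <- match.arg(diet_group)
  fa <- study_fatty_acids_df()
  fa <- fa[fa$diet_group == diet_group, ]
  fa_profile(stats::setNames(fa$mean, fa$fa_name), tol = 0.5)
}
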