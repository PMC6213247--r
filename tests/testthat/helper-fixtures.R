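# Shared fixture builders and independent oracles.

# Hand-built family/class lookup for the 22 acids of the liver composition
# table — deliberately independent of parse_fa_name(), used as the oracle for
# class sums.
fa_class_lookup <- function() {
  data.frame(
    fa_name = c("14:0", "15:0", "16:0", "16:1n-7", "17:0", "18:0", "18:1n-9",
                "18:1n-7", "18:2n-6", "18:3n-6", "20:0", "18:3n-3", "20:1n-9",
                "18:4n-3", "20:2n-6", "20:3n-6", "20:4n-6", "20:5n-3",
                "22:4n-6", "22:5n-6", "22:5n-3", "22:6n-3"),
    class = c("SAT", "SAT", "SAT", "MUFA", "SAT", "SAT", "MUFA", "MUFA",
              "PUFA", "PUFA", "SAT", "PUFA", "MUFA", "PUFA", "PUFA", "PUFA",
              "PUFA", "PUFA", "PUFA", "PUFA", "PUFA", "PUFA"),
    omega = c(NA, NA, NA, "n-7", NA, NA, "n-9", "n-7", "n-6", "n-6", NA,
              "n-3", "n-9", "n-3", "n-6", "n-6", "n-6", "n-3", "n-6", "n-6",
              "n-3", "n-3"),
    stringsAsFactors = FALSE)
}

# brute-force class sums over the lookup table
oracle_class_sums <- function(profile) {
  lk <- fa_class_lookup()
  v <- stats::setNames(as.numeric(profile), names(profile))
  stopifnot(all(names(v) %in% lk$fa_name))
  cls <- lk$class[match(names(v), lk$fa_name)]
  om <- lk$omega[match(names(v), lk$fa_name)]
  c(SAT = sum(v[cls == "SAT"]), MUFA = sum(v[cls == "MUFA"]),
    PUFA = sum(v[cls == "PUFA"]),
    omega3 = sum(v[cls == "PUFA" & !is.na(om) & om == "n-3"]),
    omega6 = sum(v[cls == "PUFA" & !is.na(om) & om == "n-6"]))
}

# random valid profile over the study's 22 acids, summing to 100
random_profile <- function() {
  lk <- fa_class_lookup()
  w <- stats::rexp(nrow(lk)) + 0.01
  fa_profile(stats::setNames(100 * w / sum(w), lk$fa_name))
}

# minimal cohort configuration for fast generator tests
tiny_config <- function(sd_scale = 1, n_per_group = 3) {
  g <- c("STD", "HFHS", "HFHS+w3")
  vars <- expand.grid(variable = c("body_weight", "gsh"), diet_group = g,
                      stringsAsFactors = FALSE)
  vars$mean <- rep(c(500, 1.4), times = 3)
  vars$sd <- rep(c(40, 0.3), times = 3) * sd_scale
  fas <- expand.grid(fa_name = c("16:0", "18:1n-9", "18:2n-6", "22:6n-3"),
                     diet_group = g, stringsAsFactors = FALSE)
  fas$mean <- rep(c(30, 25, 35, 10), times = 3)
  fas$sd <- rep(c(1, 1, 1, 0.5), times = 3) * sd_scale
  spots <- expand.grid(spot_id = c("1", "2"), diet_group = g,
                       stringsAsFactors = FALSE)
  spots$mean <- rep(c(0.8, 1.5), times = 3)
  spots$sd <- rep(c(0.1, 0.2), times = 3) * sd_scale
  cohort_config(variables = vars, fatty_acids = fas, spots = spots,
                n_per_group = n_per_group)
}

# long densitometry table for one gel from named intensity vectors
gel_table <- function(ftsc, coomassie, gel = "g1", animal = "a1") {
  rbind(
    data.frame(gel_id = gel, animal_id = animal, channel = "FTSC",
               spot_id = names(ftsc), intensity = unname(ftsc),
               stringsAsFactors = FALSE),
    data.frame(gel_id = gel, animal_id = animal, channel = "Coomassie",
               spot_id = names(coomassie), intensity = unname(coomassie),
               stringsAsFactors = FALSE))
}
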