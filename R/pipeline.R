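#' Recompute every printed derived cell from the published group means
#'
#' Pure arithmetic on the packaged printed tables: class sums and EPA/DHA
#' ratios of the composition table (from the 22 printed acid means),
#' desaturase indexes in ratio-of-group-means mode, the EPA/DHA/EPA+DHA
#' between-diet shifts, and the adiposity and hepatosomatic indexes from the
#' printed mean masses. Each computed value is rounded half-up to the printed
#' precision and compared with the printed cell; mismatching cells (the
#' published desaturase panel was computed per animal, so several
#' ratio-of-means cells differ) are reported, not errors.
#'
#' @param out_dir optional directory; when given, the report is also written
#'   to `reproduce_printed.csv` there.
#' @return data.frame `table, quantity, diet_group, computed, printed, match`.
#' @export
reproduce_printed <- function(out_dir = NULL) {
  tabs <- study_tables()
  rows <- list()
  add <- function(table, quantity, diet_group, computed, printed, digits) {
    comp <- round_half_up(computed, digits)
    rows[[length(rows) + 1L]] <<- data.frame(
      table = table, quantity = quantity, diet_group = diet_group,
      computed = comp, printed = printed,
      match = isTRUE(abs(comp - printed) < 1e-9), stringsAsFactors = FALSE)
  }

  profiles <- lapply(stats::setNames(nm = diet_groups()), study_mean_profile)

  # composition-table class rows and EPA/DHA ratio
  cls <- tabs$fa_classes
  for (i in seq_len(nrow(cls))) {
    g <- cls$diet_group[i]
    v <- cls$variable[i]
    computed <- if (v == "epa_dha") {
      desaturase_indexes(profiles[[g]])[["epa_dha"]]
    } else {
      class_sums(profiles[[g]])[[v]]
    }
    add("fa_classes", v, g, computed, cls$printed[i], cls$digits[i])
  }

  # desaturase panel, ratio-of-group-means mode (printed cells are per-animal
  # averages; exactly which cells agree is part of the report)
  des <- tabs$desaturases
  for (i in seq_len(nrow(des))) {
    g <- des$diet_group[i]
    v <- des$variable[i]
    add("desaturases", v, g, desaturase_indexes(profiles[[g]])[[v]],
        des$mean[i], 2)
  }

  # between-diet incorporation shifts (percentage points, HFHS -> HFHS+w3)
  shifts <- list(dha = "22:6w3", epa = "20:5w3", epa_dha = c("20:5w3", "22:6w3"))
  printed_shifts <- c(dha = 3.46, epa = 0.74, epa_dha = 4.20)
  for (nm in names(shifts)) {
    add("diet_shift", paste0(nm, "_shift"), "HFHS+w3 vs HFHS",
        diet_shift(profiles[["HFHS"]], profiles[["HFHS+w3"]], shifts[[nm]]),
        printed_shifts[[nm]], 2)
  }

  # biometric indexes from printed group means
  biom <- tabs$biometrics
  bm <- function(variable, g) {
    biom$mean[biom$variable == variable & biom$diet_group == g]
  }
  idx <- tabs$biometric_indexes
  for (i in seq_len(nrow(idx))) {
    g <- idx$diet_group[i]
    v <- idx$variable[i]
    computed <- switch(v,
      adiposity_index = adiposity_index(bm("perigonadal_fat", g), bm("body_weight", g)),
      hepatosomatic_index = hepatosomatic_index(bm("liver_weight", g), bm("body_weight", g)),
      ast_alt = bm("ast", g) / bm("alt", g),
      alt_ast = bm("alt", g) / bm("ast", g))
    add("biometric_indexes", v, g, computed, idx$printed[i], idx$digits[i])
  }

  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report, file.path(out_dir, "reproduce_printed.csv"),
                     row.names = FALSE)
  }
  report
}

#' Run the whole pipeline on a synthetic (or supplied) cohort
#'
#' Generates a cohort from `config` (unless one is supplied), computes every
#' derived quantity — biometric indexes, per-animal fatty-acid class sums and
#' desaturase panel, per-spot carbonylation indexes — runs the three-group
#' comparison engine on all of them, and writes the result tables plus a run
#' manifest (config echo, seed, file inventory with MD5 hashes) to
#' `out_dir`. Re-running with the same config and seed reproduces every file
#' bit for bit.
#'
#' @param config a [cohort_config()]; default [default_cohort_config()].
#' @param seed integer seed for the cohort draw.
#' @param out_dir output directory (created if needed); `NULL` returns
#'   results without writing.
#' @param reference reference group for significance stars.
#' @return (invisibly) list with `cohort`, `tables` (named list of result
#'   data.frames) and `manifest`.
#' @export
run_all <- function(config = default_cohort_config(), seed = 1L,
                    out_dir = NULL, reference = "STD") {
  cohort <- generate_cohort(config, seed = seed)
  message(sprintf("stage cohort: %d animals drawn", nrow(cohort$animals)))

  biom <- add_biometric_indexes(cohort$biometrics)
  message(sprintf("stage biometrics: %d rows x %d columns", nrow(biom), ncol(biom)))

  fa_derived <- fa_derived_table(cohort$fatty_acids, tol = 1e-6)
  message(sprintf("stage fatty_acids: %d animals x %d derived columns",
                  nrow(fa_derived), ncol(fa_derived) - 2L))

  spots <- carbonylation_table(cohort$densitometry,
                               detection_limit = config$detection_limit)
  message(sprintf("stage carbonylation: %d spot indexes (%d undefined)",
                  nrow(spots), sum(!spots$defined)))

  tidy <- rbind(
    tidy_from_wide(biom, exclude = c("animal_id", "diet_group")),
    tidy_from_wide(fa_derived, exclude = c("animal_id", "diet_group")),
    data.frame(variable = paste0("spot_", spots$spot_id),
               animal_id = spots$animal_id, diet_group = spots$diet_group,
               value = spots$index, stringsAsFactors = FALSE))
  # variables without two groups of two observations (e.g. spots undefined in
  # every animal) cannot be compared; they are dropped from the stage, logged
  usable <- vapply(split(tidy, tidy$variable), function(d) {
    ns <- table(d$diet_group[!is.na(d$value)])
    sum(ns >= 2) >= 2
  }, logical(1))
  skipped <- names(usable)[!usable]
  if (length(skipped)) {
    message(sprintf("stage group_stats: skipping %d variable(s) with too few defined values (%s)",
                    length(skipped), paste(skipped, collapse = ", ")))
  }
  comparisons <- compare_variables(tidy[tidy$variable %in% names(usable)[usable], ],
                                   reference = reference)
  message(sprintf("stage group_stats: %d variables compared (%d nonparametric)",
                  nrow(comparisons), sum(comparisons$route == "nonparametric")))

  tables <- list(biometrics = biom, fa_derived = fa_derived,
                 carbonylation = spots, comparisons = comparisons,
                 reproduce_printed = reproduce_printed())

  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    for (nm in names(tables)) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(tables[[nm]], f, row.names = FALSE)
      files <- c(files, f)
    }
    cfg_path <- file.path(out_dir, "config.json")
    write_cohort_config(config, cfg_path)
    files <- c(files, cfg_path)
    manifest <- list(seed = seed,
                     package_version = as.character(utils::packageVersion("dietredox")),
                     files = data.frame(file = basename(files),
                                        md5 = unname(tools::md5sum(files)),
                                        stringsAsFactors = FALSE))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    message(sprintf("stage manifest: %d files written to %s",
                    length(files) + 1L, out_dir))
  }
  invisible(list(cohort = cohort, tables = tables, manifest = manifest))
}

tidy_from_wide <- function(wide, exclude) {
  vars <- setdiff(names(wide), exclude)
  vars <- vars[vapply(wide[vars], is.numeric, logical(1))]
  do.call(rbind, lapply(vars, function(v) {
    data.frame(variable = v, animal_id = wide$animal_id,
               diet_group = wide$diet_group, value = wide[[v]],
               stringsAsFactors = FALSE)
  }))
}
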