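#' Assumption checks routing between ANOVA and Kruskal-Wallis
#'
#' Per-group normality (Shapiro-Wilk) and homogeneity of variances
#' (median-centered Levene / Brown-Forsythe) at level `alpha`. The variable is
#' routed to the nonparametric branch when any normality test or the
#' homogeneity test rejects. Groups too small (< 3 non-missing values) or
#' constant make normality untestable: the route falls back to nonparametric
#' with a warning.
#'
#' @param values numeric vector of observations (may contain `NA`).
#' @param groups factor or character vector of group labels, same length.
#' @param alpha routing level (default 0.05).
#' @return list with `route` (`"parametric"` or `"nonparametric"`),
#'   `normality_p` (named per-group vector, `NA` where untestable),
#'   `levene_p`, and `testable` (logical).
#' @export
check_assumptions <- function(values, groups, alpha = 0.05) {
  d <- drop_missing(values, groups)
  split_v <- split(d$values, d$groups)
  normality_p <- vapply(split_v, function(v) {
    if (length(v) < 3L || stats::sd(v) == 0) return(NA_real_)
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  untestable <- anyNA(normality_p)
  levene_p <- if (all(vapply(split_v, stats::sd, numeric(1)) == 0)) {
    NA_real_  # constant within every group: no variances to compare
  } else {
    lt <- car::leveneTest(d$values, d$groups, center = stats::median)
    lt[["Pr(>F)"]][1]
  }
  if (untestable || is.na(levene_p)) {
    warning("normality untestable (constant or tiny group); routing nonparametric",
            call. = FALSE)
    route <- "nonparametric"
  } else if (any(normality_p < alpha) || levene_p < alpha) {
    route <- "nonparametric"
  } else {
    route <- "parametric"
  }
  list(route = route, normality_p = normality_p, levene_p = levene_p,
       testable = !untestable)
}

#' Omnibus three-group test
#'
#' One-way ANOVA F-test on the parametric route, Kruskal-Wallis rank test on
#' the nonparametric route. Missing values are dropped.
#'
#' @param values,groups observations and group labels.
#' @param route `"parametric"` or `"nonparametric"`.
#' @return list `method`, `statistic`, `df`, `p.value`.
#' @export
omnibus_test <- function(values, groups, route = c("parametric", "nonparametric")) {
  route <- match.arg(route)
  d <- drop_missing(values, groups)
  if (route == "parametric") {
    fit <- stats::aov(values ~ groups, data = d)
    tab <- summary(fit)[[1]]
    list(method = "one-way ANOVA", statistic = tab[["F value"]][1],
         df = c(tab[["Df"]][1], tab[["Df"]][2]), p.value = tab[["Pr(>F)"]][1])
  } else {
    kw <- suppressWarnings(stats::kruskal.test(d$values, d$groups))
    p <- kw$p.value
    if (is.nan(p)) p <- 1  # all observations tied across groups
    list(method = "Kruskal-Wallis", statistic = unname(kw$statistic),
         df = unname(kw$parameter), p.value = p)
  }
}

#' Fisher least-significant-difference pairwise comparisons
#'
#' Pairwise t statistics using the mean-square error and residual degrees of
#' freedom of the full one-way model:
#' `t = (mean_a - mean_b) / sqrt(MSE * (1/n_a + 1/n_b))`, two-sided p, no
#' multiplicity adjustment (LSD is unadjusted by definition). With two groups
#' this reduces exactly to the pooled-variance two-sample t-test.
#'
#' @param values,groups observations and group labels (`NA` dropped).
#' @param pairs list of length-2 character vectors of group labels; default
#'   all pairs in group-level order.
#' @return data.frame `group_a, group_b, diff` (mean_b - mean_a), `t`, `df`,
#'   `p`, `direction` (`"up"`/`"down"`/`"none"`, the sign of mean_b - mean_a).
#'   `p` is `NA` when the pooled MSE is zero.
#' @export
fisher_lsd <- function(values, groups, pairs = NULL) {
  d <- drop_missing(values, groups)
  lv <- levels(d$groups)
  if (is.null(pairs)) pairs <- utils::combn(lv, 2, simplify = FALSE)
  ns <- tapply(d$values, d$groups, length)
  ms <- tapply(d$values, d$groups, mean)
  sse <- sum(tapply(d$values, d$groups, function(v) sum((v - mean(v))^2)))
  df <- length(d$values) - nlevels(d$groups)
  mse <- sse / df
  rows <- lapply(pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    if (!all(pr %in% lv)) stop("unknown group in `pairs`: ", paste(pr, collapse = "/"),
                               call. = FALSE)
    diff <- unname(ms[b] - ms[a])
    if (mse == 0) {
      tt <- NA_real_; p <- NA_real_
    } else {
      tt <- -diff / sqrt(mse * (1 / ns[[a]] + 1 / ns[[b]]))  # t of a - b
      p <- 2 * stats::pt(-abs(tt), df)
    }
    data.frame(group_a = a, group_b = b, diff = diff, t = unname(tt), df = df,
               p = unname(p),
               direction = if (is.na(diff) || diff == 0) "none" else
                 if (diff > 0) "up" else "down",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# rank-based pairwise fallback for the nonparametric route: unadjusted
# Mann-Whitney (midranks, normal approximation with continuity correction)
pairwise_rank_tests <- function(values, groups, pairs = NULL) {
  d <- drop_missing(values, groups)
  lv <- levels(d$groups)
  if (is.null(pairs)) pairs <- utils::combn(lv, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    va <- d$values[d$groups == pr[1]]
    vb <- d$values[d$groups == pr[2]]
    diff <- mean(vb) - mean(va)
    p <- if (stats::sd(c(va, vb)) == 0) 1 else
      suppressWarnings(stats::wilcox.test(va, vb, exact = FALSE, correct = TRUE)$p.value)
    data.frame(group_a = pr[1], group_b = pr[2], diff = diff, t = NA_real_,
               df = NA_real_, p = p,
               direction = if (diff == 0) "none" else if (diff > 0) "up" else "down",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare one variable across diet groups
#'
#' The full comparison route used throughout the pipeline: assumption checks
#' (see [check_assumptions()]) decide between one-way ANOVA with Fisher LSD
#' post-hoc tests and Kruskal-Wallis with unadjusted pairwise rank tests.
#' Pairwise p-values are reported unconditionally (LSD is unadjusted by
#' definition; the omnibus p is reported alongside, not used as a gate).
#'
#' @param formula a two-sided formula `value ~ group`.
#' @param data data.frame holding the formula variables.
#' @param reference reference group for star flags (default `"STD"`).
#' @param alpha_route level of the assumption tests (default 0.05).
#' @param route `"auto"` (default) or a forced route.
#' @return object of class `group_comparison`: list with `variable`, `groups`
#'   (per-group n/mean/sd data.frame), `route`, `assumptions`, `omnibus`,
#'   `pairwise`, `reference`, `flags` (per non-reference group: `""`, `"*"`
#'   p < 0.05, `"**"` p < 0.01 against the reference).
#' @examples
#' set.seed(1)
#' d <- data.frame(value = rnorm(27, rep(c(0, 1, 0), each = 9)),
#'                 group = rep(c("STD", "HFHS", "HFHS+w3"), each = 9))
#' group_compare(value ~ group, d)
#' @export
group_compare <- function(formula, data, reference = "STD", alpha_route = 0.05,
                          route = c("auto", "parametric", "nonparametric")) {
  route <- match.arg(route)
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  values <- mf[[1]]
  groups <- mf[[2]]
  d <- drop_missing(values, groups)

  assumptions <- NULL
  if (route == "auto") {
    assumptions <- withCallingHandlers(
      check_assumptions(d$values, d$groups, alpha = alpha_route),
      warning = function(w) invokeRestart("muffleWarning"))
    if (!assumptions$testable) {
      warning(sprintf("'%s': normality untestable; routed nonparametric",
                      deparse(formula[[2]])), call. = FALSE)
    }
    route <- assumptions$route
  }
  omnibus <- omnibus_test(d$values, d$groups, route)
  pairwise <- if (route == "parametric") fisher_lsd(d$values, d$groups)
              else pairwise_rank_tests(d$values, d$groups)

  per_group <- data.frame(
    group = levels(d$groups),
    n = as.integer(tapply(d$values, d$groups, length)),
    mean = as.numeric(tapply(d$values, d$groups, mean)),
    sd = as.numeric(tapply(d$values, d$groups, stats::sd)),
    stringsAsFactors = FALSE)

  flags <- character(0)
  if (reference %in% per_group$group) {
    others <- setdiff(per_group$group, reference)
    flags <- vapply(others, function(g) {
      row <- pairwise[(pairwise$group_a == reference & pairwise$group_b == g) |
                      (pairwise$group_b == reference & pairwise$group_a == g), ]
      significance_flag(row$p[1])
    }, character(1))
  }

  structure(list(variable = deparse(formula[[2]]), groups = per_group,
                 route = route, assumptions = assumptions, omnibus = omnibus,
                 pairwise = pairwise, reference = reference, flags = flags),
            class = "group_comparison")
}

# star convention: * p < 0.05, ** p < 0.01, strict inequalities
significance_flag <- function(p) {
  if (is.na(p)) "" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Star and arrow annotation of a comparison
#'
#' Arrows mark significant pairwise changes only: `"+"` when the second group
#' of the pair has the larger mean, `"-"` when smaller; non-significant pairs
#' get `""`. Stars use the strict thresholds `* p < 0.05`, `** p < 0.01`.
#'
#' @param comparison a [group_compare()] result.
#' @param alpha significance level for the arrows (default 0.05, strict).
#' @return the `pairwise` data.frame augmented with `star` and `arrow`.
#' @export
annotate_comparison <- function(comparison, alpha = 0.05) {
  pw <- comparison$pairwise
  pw$star <- vapply(pw$p, significance_flag, character(1))
  pw$arrow <- ifelse(!is.na(pw$p) & pw$p < alpha & pw$direction != "none",
                     ifelse(pw$diff > 0, "+", "-"), "")
  pw
}

#' @export
print.group_comparison <- function(x, digits = 4, ...) {
  cat("Three-group comparison of", x$variable, "\n")
  cat("Route:", x$route, sprintf("(omnibus %s p = %s)\n", x$omnibus$method,
                                 format.pval(x$omnibus$p.value, digits = digits)))
  g <- x$groups
  g$mean <- signif(g$mean, digits); g$sd <- signif(g$sd, digits)
  print(g, row.names = FALSE)
  cat("Pairwise (unadjusted):\n")
  pw <- annotate_comparison(x)
  pw$diff <- signif(pw$diff, digits); pw$p <- signif(pw$p, digits)
  print(pw[, c("group_a", "group_b", "diff", "p", "direction", "star", "arrow")],
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.group_comparison <- function(object, ...) {
  print(object, ...)
  if (!is.null(object$assumptions)) {
    cat("Assumption checks: Shapiro p =",
        paste(format.pval(object$assumptions$normality_p, digits = 3), collapse = ", "),
        "; Levene p =", format.pval(object$assumptions$levene_p, digits = 3), "\n")
  }
  invisible(object)
}

#' Compare many variables from a tidy table
#'
#' Runs [group_compare()] for every variable of a tidy long table
#' (`variable, animal_id, diet_group, value`) and returns a flat results
#' table in the style of published comparison tables: per-group `mean (s.d.)`,
#' per-pair p-values, stars and arrows.
#'
#' @param tidy data.frame with columns `variable`, `diet_group`, `value`
#'   (an `animal_id` column is allowed and ignored).
#' @param reference reference group for the star column (default `"STD"`).
#' @param alpha_route routing level, see [group_compare()].
#' @return data.frame, one row per variable: group means/sds, omnibus route
#'   and p, one `p`, `star` and `arrow` column per group pair.
#' @export
compare_variables <- function(tidy, reference = "STD", alpha_route = 0.05) {
  needed <- c("variable", "diet_group", "value")
  if (!all(needed %in% names(tidy))) {
    stop("`tidy` needs columns: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  # one canonical group order for every variable so the flattened rows share
  # identical pairwise columns regardless of per-variable row order
  tidy$diet_group <- factor(tidy$diet_group, levels = unique(tidy$diet_group))
  vars <- unique(tidy$variable)
  rows <- lapply(vars, function(v) {
    d <- tidy[tidy$variable == v, ]
    cmp <- suppressWarnings(
      group_compare(value ~ diet_group, d, reference = reference,
                    alpha_route = alpha_route))
    pw <- annotate_comparison(cmp)
    row <- data.frame(variable = v, route = cmp$route,
                      omnibus_p = cmp$omnibus$p.value, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(cmp$groups))) {
      g <- cmp$groups$group[i]
      tag <- gsub("[^A-Za-z0-9]+", "_", g)
      row[[paste0("mean_", tag)]] <- cmp$groups$mean[i]
      row[[paste0("sd_", tag)]] <- cmp$groups$sd[i]
      row[[paste0("n_", tag)]] <- cmp$groups$n[i]
    }
    for (i in seq_len(nrow(pw))) {
      tag <- gsub("[^A-Za-z0-9]+", "_",
                  paste(pw$group_b[i], "vs", pw$group_a[i]))
      row[[paste0("p_", tag)]] <- pw$p[i]
      row[[paste0("star_", tag)]] <- pw$star[i]
      row[[paste0("arrow_", tag)]] <- pw$arrow[i]
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# shared NA handling: drop missing observations, keep group factor in the
# order of first appearance, require >= 2 groups with >= 2 observations
drop_missing <- function(values, groups) {
  if (length(values) != length(groups)) {
    stop("`values` and `groups` must have equal length", call. = FALSE)
  }
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(groups[keep])
  ns <- table(groups)
  if (sum(ns >= 2) < 2) {
    stop("need at least 2 groups with at least 2 non-missing observations",
         call. = FALSE)
  }
  groups <- droplevels(factor(groups, levels = names(ns)[ns >= 2]))
  keep2 <- !is.na(groups)
  data.frame(values = values[keep2], groups = groups[keep2])
}
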