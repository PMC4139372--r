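#' Grid-based herbivory index of one leaf
#'
#' Leaves are scored on a transparent millimetre grid; the index is the
#' proportion of grid points falling within damaged leaf area.
#'
#' @param damaged_points,total_points Non-negative integer point counts,
#'   `damaged_points <= total_points`, `total_points > 0`.
#' @return Proportion of leaf area lost, in \[0, 1\]. Vectorized.
#' @export
herbivory_index <- function(damaged_points, total_points) {
  if (any(total_points <= 0)) stop("total_points must be positive", call. = FALSE)
  if (any(damaged_points < 0) || any(damaged_points > total_points)) {
    stop("damaged_points must lie in [0, total_points]", call. = FALSE)
  }
  damaged_points / total_points
}

#' Stem-level herbivory rate: mean over the tagged leaves
#'
#' The analysis unit of the exclusion experiment is the stem-year mean of
#' the (nominally nine) tagged leaves. Incomplete stems are averaged over
#' the available leaves and their leaf count reported.
#'
#' @param leaves A data frame of leaf records with columns
#'   `species`, `individual`, `stem`, `year`, `herbivory_pct` (and
#'   optionally `leaf`, `position`).
#' @return A tibble with one row per species x individual x stem x year:
#'   `herbivory_pct` (the stem mean) and `n_leaves`.
#' @export
stem_mean_herbivory <- function(leaves) {
  stopifnot(all(c("species", "individual", "stem", "year", "herbivory_pct")
                %in% names(leaves)))
  leaves |>
    dplyr::group_by(.data$species, .data$individual, .data$stem, .data$year) |>
    dplyr::summarise(herbivory_pct = mean(.data$herbivory_pct),
                     n_leaves = dplyr::n(), .groups = "drop")
}

#' Three-factor fixed-effects ANOVA of herbivory
#'
#' Full factorial model `herbivory ~ species * stem * year` on stem-level
#' herbivory percentages. Balanced designs reproduce the textbook Type-I
#' decomposition exactly; unbalanced data are handled with sum-to-zero
#' contrasts and partial (Type-III) sums of squares.
#'
#' @param stem_means A data frame with columns `species`, `stem`, `year` and
#'   the response (default `herbivory_pct`), e.g. from
#'   [stem_mean_herbivory()].
#' @param response Name of the response column.
#' @param arcsine Apply the arcsine-square-root variance-stabilizing
#'   transform to the response (given as a percentage) before fitting.
#'   Off by default: grid-based leaf-loss percentages are typically close
#'   enough to normal.
#' @return A `factorial_anova` object: list with `table` (tibble: term, df,
#'   sumsq, meansq, statistic, p.value), `fit` (the `lm`), `type`
#'   (`"III"`), `response`. `tidy()` returns the table.
#' @export
factorial_anova <- function(stem_means, response = "herbivory_pct",
                            arcsine = FALSE) {
  need <- c("species", "stem", "year", response)
  stopifnot(all(need %in% names(stem_means)))
  d <- stem_means
  d$species <- factor(d$species)
  d$stem <- factor(d$stem)
  d$year <- factor(d$year)
  for (f in c("species", "stem", "year")) {
    if (nlevels(d[[f]]) < 2L) {
      stop("factor '", f, "' needs at least 2 levels", call. = FALSE)
    }
  }
  if (any(table(d$species, d$stem, d$year) == 0L)) {
    stop("empty species x stem x year cell: the full interaction model ",
         "cannot be fitted", call. = FALSE)
  }
  y <- d[[response]]
  if (arcsine) y <- asin(sqrt(pmin(pmax(y / 100, 0), 1)))
  d$.response <- y
  fit <- stats::lm(.response ~ species * stem * year, data = d,
                   contrasts = list(species = "contr.sum", stem = "contr.sum",
                                    year = "contr.sum"))
  if (stats::var(y) < .Machine$double.eps) {
    # degenerate constant response: zero SS everywhere, F undefined
    terms_lm <- attr(stats::terms(fit), "term.labels")
    dfs <- vapply(strsplit(terms_lm, ":"), function(parts) {
      prod(vapply(parts, function(p) nlevels(d[[p]]) - 1L, integer(1)))
    }, numeric(1))
    tab <- tibble::tibble(
      term = c(terms_lm, "Residuals"),
      df = c(dfs, nrow(d) - 1L - sum(dfs)),
      sumsq = 0, meansq = 0, statistic = NA_real_, p.value = NA_real_)
    return(structure(list(table = tab, fit = fit, type = "III",
                          response = response, arcsine = arcsine),
                     class = "factorial_anova"))
  }
  a3 <- car::Anova(fit, type = 3)
  tab <- tibble::tibble(
    term = rownames(a3),
    df = a3$Df,
    sumsq = a3$`Sum Sq`,
    statistic = a3$`F value`,
    p.value = a3$`Pr(>F)`
  ) |>
    dplyr::filter(.data$term != "(Intercept)") |>
    dplyr::mutate(meansq = .data$sumsq / .data$df, .after = "sumsq")
  structure(list(table = tab, fit = fit, type = "III", response = response,
                 arcsine = arcsine),
            class = "factorial_anova")
}

#' @export
print.factorial_anova <- function(x, ...) {
  cat(sprintf("<factorial_anova> %s ~ species * stem * year (Type %s SS)\n",
              x$response, x$type))
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidy a factorial ANOVA
#'
#' @param x A `factorial_anova`.
#' @param ... Unused.
#' @return `tidy()`: the term table (term, df, sumsq, meansq, statistic,
#'   p.value). `glance()`: one-row model summary.
#' @method tidy factorial_anova
#' @export
tidy.factorial_anova <- function(x, ...) x$table

#' @rdname tidy.factorial_anova
#' @method glance factorial_anova
#' @export
glance.factorial_anova <- function(x, ...) {
  s <- summary(x$fit)
  err <- x$table[x$table$term == "Residuals", ]
  tibble::tibble(
    r.squared = s$r.squared,
    df.residual = err$df,
    ms.error = err$meansq,
    nobs = stats::nobs(x$fit)
  )
}

#' Tukey HSD pairwise comparisons from cell summaries
#'
#' Studentized-range test on a set of group means against a common error
#' mean square, using the Tukey-Kramer allowance for unequal group sizes:
#' `q = |mi - mj| / sqrt((MSE / 2) * (1/ni + 1/nj))`, with the adjusted
#' p-value from `ptukey(q, k, df_error)`.
#'
#' @param cell_means Named numeric vector of group means.
#' @param ms_error Error mean square from the fitted ANOVA.
#' @param df_error Error degrees of freedom (> 0).
#' @param group_sizes Group sizes, a single number or one per group.
#' @param conf.level Confidence level for the honest significant
#'   difference intervals.
#' @return A tibble with one row per unordered pair: `group_1`, `group_2`,
#'   `estimate` (mean difference, group_2 - group_1), `conf.low`,
#'   `conf.high`, `q`, `adj.p.value`, `significant` (at 0.05).
#' @export
tukey_hsd <- function(cell_means, ms_error, df_error, group_sizes,
                      conf.level = 0.95) {
  if (df_error <= 0) stop("df_error must be positive", call. = FALSE)
  k <- length(cell_means)
  stopifnot(k >= 2, length(group_sizes) %in% c(1L, k))
  if (length(group_sizes) == 1L) group_sizes <- rep(group_sizes, k)
  groups <- names(cell_means) %||% as.character(seq_len(k))
  pairs <- utils::combn(k, 2)
  i <- pairs[1, ]; j <- pairs[2, ]
  est <- as.numeric(cell_means[j] - cell_means[i])
  se <- sqrt(ms_error / 2 * (1 / group_sizes[i] + 1 / group_sizes[j]))
  q <- abs(est) / se
  crit <- stats::qtukey(conf.level, k, df_error)
  adj_p <- stats::ptukey(q, k, df_error, lower.tail = FALSE)
  tibble::tibble(
    group_1 = groups[i], group_2 = groups[j],
    estimate = est,
    conf.low = est - crit * se,
    conf.high = est + crit * se,
    q = q,
    adj.p.value = adj_p,
    significant = adj_p < 0.05
  )
}

#' Tukey HSD for one factor of a fitted factorial ANOVA
#'
#' Convenience wrapper computing the factor's cell means and sizes from the
#' model frame and delegating to [tukey_hsd()].
#'
#' @param anova_fit A `factorial_anova`.
#' @param factor_name One of `"species"`, `"stem"`, `"year"`.
#' @inheritParams tukey_hsd
#' @export
tukey_posthoc <- function(anova_fit, factor_name = "species",
                          conf.level = 0.95) {
  stopifnot(inherits(anova_fit, "factorial_anova"))
  mf <- stats::model.frame(anova_fit$fit)
  f <- mf[[factor_name]]
  y <- mf[[".response"]]
  g <- glance.factorial_anova(anova_fit)
  tukey_hsd(tapply(y, f, mean), g$ms.error, g$df.residual,
            as.integer(table(f)), conf.level)
}

#' Per-species control vs exclusion t-tests with Bonferroni correction
#'
#' Within each year, compares herbivory between the two stem treatments for
#' every plant species with a Student's t-test (pooled variance by default),
#' then multiplies each raw p-value by the number of species tested in that
#' year (capped at 1). The family is the set of species within one year,
#' matching per-year reporting of such experiments.
#'
#' @param stem_means Stem-level herbivory data (columns `species`, `stem`,
#'   `year`, `herbivory_pct`); `stem` must have exactly two levels.
#' @param welch Use the Welch (unequal-variance) t-test instead of the
#'   pooled-variance Student's t-test.
#' @param paired Pair stems within individuals (requires `individual`
#'   column); off by default.
#' @return A tibble with one row per species x year: `t`, `df`, `p.value`,
#'   `adj.p.value` (Bonferroni), `estimate` (mean treatment minus control
#'   difference), `flag` (`"zero_variance"` when the test is undefined).
#' @export
per_species_treatment_tests <- function(stem_means, welch = FALSE,
                                        paired = FALSE) {
  stopifnot(all(c("species", "stem", "year", "herbivory_pct")
                %in% names(stem_means)))
  stems <- sort(unique(as.character(stem_means$stem)))
  if (length(stems) != 2L) stop("need exactly two stem treatments", call. = FALSE)
  out <- stem_means |>
    dplyr::group_by(.data$year, .data$species) |>
    dplyr::group_modify(function(d, key) {
      x <- d$herbivory_pct[d$stem == stems[2]]  # treatment-style level
      y <- d$herbivory_pct[d$stem == stems[1]]
      if (length(x) == 0 || length(y) == 0) {
        stop("both stem groups must be non-empty for species ", key$species,
             call. = FALSE)
      }
      if (paired && length(x) != length(y)) {
        stop("paired test needs matched group sizes", call. = FALSE)
      }
      if (stats::sd(c(x, y)) == 0) {
        return(tibble::tibble(t = NA_real_, df = NA_real_, p.value = NA_real_,
                              estimate = mean(x) - mean(y),
                              flag = "zero_variance"))
      }
      tt <- stats::t.test(x, y, var.equal = !welch, paired = paired)
      tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                     p.value = tt$p.value, estimate = mean(x) - mean(y),
                     flag = NA_character_)
    }) |>
    dplyr::ungroup()
  out |>
    dplyr::group_by(.data$year) |>
    dplyr::mutate(adj.p.value = pmin(1, .data$p.value * dplyr::n()),
                  .after = "p.value") |>
    dplyr::ungroup()
}

#' Paired year-to-year test of log-transformed ant abundance
#'
#' Ant counts are log(x + 1) transformed and compared between two periods
#' with a paired t-test, pairing records by plant individual (within
#' species). Sign convention: the statistic is computed on period A minus
#' period B, so more ants in period B gives a negative t.
#'
#' @param records_a,records_b Data frames with columns `species`,
#'   `individual`, `ant_count` for the two periods.
#' @return A one-row tibble: `t`, `df`, `p.value`, `n_pairs`,
#'   `mean_log_diff`.
#' @export
paired_abundance_test <- function(records_a, records_b) {
  need <- c("species", "individual", "ant_count")
  stopifnot(all(need %in% names(records_a)), all(need %in% names(records_b)))
  key_a <- paste(records_a$species, records_a$individual, sep = "\r")
  key_b <- paste(records_b$species, records_b$individual, sep = "\r")
  shared <- intersect(key_a, key_b)
  if (length(shared) < length(key_a) || length(shared) < length(key_b)) {
    warning("dropping ", length(key_a) + length(key_b) - 2 * length(shared),
            " unpaired records")
  }
  if (length(shared) < 2) stop("need at least 2 complete pairs", call. = FALSE)
  a <- log1p(records_a$ant_count[match(shared, key_a)])
  b <- log1p(records_b$ant_count[match(shared, key_b)])
  d <- a - b
  if (stats::sd(d) < 1e-8 * max(1, abs(mean(d)))) {
    # zero-variance differences: t is 0 (no shift) or unbounded (pure shift)
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(tibble::tibble(t = t_stat, df = length(shared) - 1,
                          p.value = if (mean(d) == 0) 1 else 0,
                          n_pairs = length(shared), mean_log_diff = mean(d)))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p.value = tt$p.value, n_pairs = length(shared),
                 mean_log_diff = mean(a - b))
}
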