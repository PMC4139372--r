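# derive independent per-stage seeds from one study seed so stages can be
# re-run alone; kept below 2^31
stage_seeds <- function(seed, n = 6L) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Full metric report for one network
#'
#' Computes in one pass every descriptor of a network summary table:
#' species counts, links and associations, average degrees with standard
#' errors, connectance, web asymmetry (signed and magnitude), H2'
#' specialization, and NODF with its Monte-Carlo significance under the Ce
#' null. Deterministic given `seed`.
#'
#' @param x A quantitative `incidence_matrix`.
#' @param n_randomizations Null-model draws for the NODF test.
#' @param seed Integer seed for the null ensemble.
#' @param precision Reporting precision rule (see [report_value()]) applied
#'   to connectance, web asymmetry and H2'; counts, degrees, NODF and p are
#'   reported in full.
#' @return A one-row tibble mirroring a published network-metrics table:
#'   `period`, `n_ants`, `n_plants`, `n_links`, `n_associations`,
#'   `mean_degree_plants`, `se_degree_plants`, `mean_degree_ants`,
#'   `se_degree_ants`, `connectance_pct`, `web_asymmetry`,
#'   `web_asymmetry_abs`, `h2_prime`, `nodf`, `nodf_z`, `nodf_p`.
#' @export
metric_report <- function(x, n_randomizations = 1000, seed = 1,
                          precision = c("full", "truncate2", "round3")) {
  precision <- match.arg(precision)
  stopifnot(inherits(x, "incidence_matrix"))
  deg_p <- average_degree(x, "plants")
  deg_a <- average_degree(x, "ants")
  W <- web_asymmetry(ncol(x), nrow(x))
  h2 <- h2_prime(x)
  nest <- nestedness_significance(x, n_randomizations, seed)
  prec <- function(v) report_value(v, precision)
  tibble::tibble(
    period = attr(x, "period") %||% NA_character_,
    n_ants = nrow(x), n_plants = ncol(x),
    n_links = n_links(x), n_associations = sum(x),
    mean_degree_plants = deg_p$mean_degree, se_degree_plants = deg_p$se_degree,
    mean_degree_ants = deg_a$mean_degree, se_degree_ants = deg_a$se_degree,
    connectance_pct = prec(connectance(x)),
    web_asymmetry = prec(W),
    web_asymmetry_abs = prec(abs(W)),
    h2_prime = prec(h2$h2_prime),
    nodf = nest$observed, nodf_z = nest$z, nodf_p = nest$p
  )
}

#' Run the full two-period study pipeline
#'
#' Orchestrates the complete analysis: a metric report per period network,
#' the two-period alignment/turnover/KS comparison, and — when experiment
#' data are supplied — the herbivory statistics (stem means, factorial
#' ANOVA, Tukey post hoc on species, per-species Bonferroni t-tests, paired
#' abundance test). One global seed fans out to fixed per-stage seeds, so
#' the whole bundle is reproducible and stages can be re-run independently.
#'
#' @param net_a,net_b `incidence_matrix` objects for the two periods
#'   (`net_b` optional: a single-network run).
#' @param leaves Leaf-record data frame (see [stem_mean_herbivory()]), or
#'   `NULL` to skip the experiment stage (a message is emitted).
#' @param abundance Optional abundance records (`species`, `individual`,
#'   `year`, `ant_count`) with two year levels.
#' @param n_randomizations Null draws per NODF test.
#' @param seed Global seed.
#' @param precision Reporting precision rule for metric reports.
#' @param out_dir Optional directory: writes `metrics.tsv`,
#'   `comparison.json`, `anova.tsv`, `species_tests.tsv`, `summary.json`
#'   and a small run log.
#' @return A list with `metrics` (tibble, one row per period),
#'   `comparison` (`network_comparison` or `NULL`), `anova`, `tukey_species`,
#'   `species_tests`, `abundance_test` (each `NULL` when skipped), and
#'   `seed`.
#' @export
run_study <- function(net_a, net_b = NULL, leaves = NULL, abundance = NULL,
                      n_randomizations = 1000, seed = 1,
                      precision = "full", out_dir = NULL) {
  seeds <- stage_seeds(seed)
  metrics <- metric_report(net_a, n_randomizations, seeds[1], precision)
  comparison <- NULL
  if (!is.null(net_b)) {
    metrics <- dplyr::bind_rows(
      metrics, metric_report(net_b, n_randomizations, seeds[2], precision))
    comparison <- align_networks(net_a, net_b)
  }
  anova <- tukey_species <- species_tests <- abundance_test <- NULL
  if (!is.null(leaves)) {
    sm <- stem_mean_herbivory(leaves)
    anova <- factorial_anova(sm)
    tukey_species <- tukey_posthoc(anova, "species")
    species_tests <- per_species_treatment_tests(sm)
  } else {
    message("no leaf records supplied; experiment stage skipped")
  }
  if (!is.null(abundance)) {
    yrs <- sort(unique(as.character(abundance$year)))
    stopifnot(length(yrs) == 2L)
    abundance_test <- paired_abundance_test(
      abundance[abundance$year == yrs[1], ],
      abundance[abundance$year == yrs[2], ])
  }
  out <- list(metrics = metrics, comparison = comparison, anova = anova,
              tukey_species = tukey_species, species_tests = species_tests,
              abundance_test = abundance_test, seed = seed)
  if (!is.null(out_dir)) write_study_bundle(out, out_dir)
  out
}

write_study_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(res$metrics, file.path(out_dir, "metrics.tsv"))
  if (!is.null(res$comparison)) {
    jsonlite::write_json(
      list(glance = glance.network_comparison(res$comparison),
           degree_changes = tidy.network_comparison(res$comparison)),
      file.path(out_dir, "comparison.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$anova)) {
    readr::write_tsv(res$anova$table, file.path(out_dir, "anova.tsv"))
    readr::write_tsv(res$species_tests,
                     file.path(out_dir, "species_tests.tsv"))
  }
  summary <- list(
    seed = res$seed,
    metrics = res$metrics,
    abundance_test = res$abundance_test,
    versions = list(antnet = as.character(utils::packageVersion("antnet")),
                    r = paste(R.version$major, R.version$minor, sep = "."))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  writeLines(sprintf("antnet run: seed %s, %s", res$seed, format(Sys.time())),
             file.path(out_dir, "run.log"))
  invisible(out_dir)
}
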