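#' Two-sample Kolmogorov-Smirnov test on degree samples
#'
#' D is the maximum absolute difference between the two empirical CDFs,
#' evaluated exactly on the pooled support; the p-value comes from the
#' asymptotic two-sample distribution. Degree samples are discrete with
#' heavy ties, so no continuity correction is applied and the p-value is
#' flagged approximate for samples smaller than 10.
#'
#' @param x,y Non-empty numeric samples (e.g. degree sequences).
#' @return A one-row tibble: `statistic` (D), `p.value`, `n_x`, `n_y`,
#'   `approx` (`TRUE` when either sample has fewer than 10 values).
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  tibble::tibble(
    statistic = unname(kt$statistic),
    p.value = kt$p.value,
    n_x = length(x), n_y = length(y),
    approx = length(x) < 10 || length(y) < 10
  )
}

#' Align two temporal snapshots of a network
#'
#' Matches species by exact label, lists the turnover (species present in
#' only one period), tabulates per-species degree change (a species absent
#' from one period counts as degree 0 there), and compares the ant and
#' plant degree distributions of the two periods with a two-sample KS test.
#'
#' @param a,b `incidence_matrix` snapshots sharing the plant label set
#'   (a warning is raised for a partial overlap, an error for none).
#' @return A `network_comparison` object: list with `shared_ants`,
#'   `only_in_a`, `only_in_b`, `degree_changes` (tibble: species, degree_a,
#'   degree_b, delta, unchanged), `ks_ants`, `ks_plants`, `period_a`,
#'   `period_b`.
#' @export
align_networks <- function(a, b) {
  stopifnot(inherits(a, "incidence_matrix"), inherits(b, "incidence_matrix"))
  plants_a <- colnames(a); plants_b <- colnames(b)
  if (length(intersect(plants_a, plants_b)) == 0) {
    stop("the two networks share no plant labels", call. = FALSE)
  }
  if (!setequal(plants_a, plants_b)) {
    warning("plant label sets differ between periods; comparing on labels as given")
  }
  ants_a <- rownames(a); ants_b <- rownames(b)
  shared <- intersect(ants_a, ants_b)
  union_ants <- union(ants_a, ants_b)
  deg_a <- stats::setNames(species_degree(a, "ants")$degree, ants_a)
  deg_b <- stats::setNames(species_degree(b, "ants")$degree, ants_b)
  da <- ifelse(union_ants %in% ants_a, deg_a[union_ants], 0L)
  db <- ifelse(union_ants %in% ants_b, deg_b[union_ants], 0L)
  changes <- tibble::tibble(
    species = union_ants,
    degree_a = as.integer(da),
    degree_b = as.integer(db),
    delta = as.integer(db - da),
    unchanged = da == db
  )
  structure(list(
    shared_ants = shared,
    only_in_a = setdiff(ants_a, ants_b),
    only_in_b = setdiff(ants_b, ants_a),
    degree_changes = changes,
    ks_ants = ks_two_sample(deg_a, deg_b),
    ks_plants = ks_two_sample(species_degree(a, "plants")$degree,
                              species_degree(b, "plants")$degree),
    period_a = attr(a, "period"), period_b = attr(b, "period")
  ), class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("<network_comparison> '%s' vs '%s'\n", x$period_a, x$period_b))
  cat(sprintf("  shared ants %d; only in '%s' %d; only in '%s' %d\n",
              length(x$shared_ants), x$period_a, length(x$only_in_a),
              x$period_b, length(x$only_in_b)))
  cat(sprintf("  KS ants D = %.3f (P = %.3f); KS plants D = %.3f (P = %.3f)\n",
              x$ks_ants$statistic, x$ks_ants$p.value,
              x$ks_plants$statistic, x$ks_plants$p.value))
  invisible(x)
}

#' Tidy a two-period network comparison
#'
#' @param x A `network_comparison`.
#' @param ... Unused.
#' @return `tidy()`: the per-species degree-change tibble with a `turnover`
#'   column (`"shared"`, `"only_in_a"`, `"only_in_b"`). `glance()`: one-row
#'   summary with turnover counts and both KS results.
#' @method tidy network_comparison
#' @export
tidy.network_comparison <- function(x, ...) {
  dplyr::mutate(x$degree_changes, turnover = dplyr::case_when(
    .data$species %in% x$shared_ants ~ "shared",
    .data$species %in% x$only_in_a ~ "only_in_a",
    TRUE ~ "only_in_b"
  ))
}

#' @rdname tidy.network_comparison
#' @method glance network_comparison
#' @export
glance.network_comparison <- function(x, ...) {
  tibble::tibble(
    n_shared = length(x$shared_ants),
    n_only_in_a = length(x$only_in_a),
    n_only_in_b = length(x$only_in_b),
    n_unchanged_degree = sum(x$degree_changes$unchanged),
    ks_ants_d = x$ks_ants$statistic, ks_ants_p = x$ks_ants$p.value,
    ks_plants_d = x$ks_plants$statistic, ks_plants_p = x$ks_plants$p.value
  )
}
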