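#' The packaged Cerrado ant-plant incidence table
#'
#' Loads the bundled two-year field census of ants visiting extrafloral
#' nectaries on nine Cerrado tree species: a 31 ant x 9 plant count matrix
#' whose cells give the number of tagged individuals (30 per plant species,
#' 270 in total) on which each ant species was recorded. The file carries a
#' printed row-total column that is checked against the cell sums at load
#' time.
#'
#' @return An `incidence_matrix` (31 x 9, grand total 693) with
#'   `n_individuals_per_plant = 30` and period `"combined"`.
#' @export
fixture_table1 <- function() {
  path <- system.file("extdata", "table1_interactions.csv", package = "antnet",
                      mustWork = TRUE)
  m <- read_incidence(path, dialect = "matrix",
                      n_individuals_per_plant = 30, period = "combined")
  if (nrow(m) != 31L || ncol(m) != 9L || sum(m) != 693L) {
    stop("packaged incidence table failed its checksum", call. = FALSE)
  }
  m
}

# ants recorded in a single study year (derived from the census notes
# shipped with the fixture); used to carve per-year networks out of the
# combined table
ants_only_2009 <- c("Crematogaster bruchi", "Linepithema aztecoides")
ants_only_2010 <- c("Camponotus lespesii", "Camponotus vittatus",
                    "Cephalotes atratus", "Forelius brasiliensis",
                    "Ectatomma planidens")

#' Per-year ant subsets of the packaged table
#'
#' The combined census distinguishes species seen in only one of the two
#' study years. Dropping the other year's exclusive species from the
#' combined table yields the species composition of each yearly network
#' (26 ants in the first year, 29 in the second). Note the within-year
#' interaction counts themselves were not published, so the retained cells
#' still hold combined-period counts; these subsets reproduce species
#' composition and turnover, not per-year weights.
#'
#' @param year `"2009"` or `"2010"`.
#' @return An `incidence_matrix` restricted to the ants recorded that year.
#' @export
fixture_year_network <- function(year = c("2009", "2010")) {
  year <- match.arg(year)
  m <- fixture_table1()
  drop <- if (year == "2009") ants_only_2010 else ants_only_2009
  keep <- setdiff(rownames(m), drop)
  incidence_matrix(unclass_incidence(m)[keep, , drop = FALSE],
                   attr(m, "n_individuals_per_plant"), period = year)
}

#' Simulate a bipartite ant-plant count network
#'
#' Draws a count matrix with the statistical structure the analyses assume:
#' skewed species totals, a target binary fill, and a nestedness dial.
#' Species weights follow a power-law-like rank distribution
#' (`rank^-marginal_skew`). Cell presence probabilities interpolate between
#' a uniform-given-fill form (`nested_strength = 0`) and the Ce form built
#' from the skewed target degrees (`nested_strength = 1`), so nestedness is
#' induced through marginal heterogeneity exactly as the Ce null family
#' models it. Counts on realized links are binomial out of
#' `n_individuals_per_plant` trials (truncated below at 1), respecting the
#' tagged-individuals semantics of the field census.
#'
#' @param n_ants,n_plants Network dimensions (defaults: the study's nine
#'   plant species and a 29-ant assemblage).
#' @param target_fill Target proportion of realized links, in (0, 1\].
#' @param marginal_skew Exponent of the rank-weight distribution (0 =
#'   homogeneous totals).
#' @param nested_strength In \[0, 1\]: 0 = random given fill, 1 = maximally
#'   nested layout for the drawn marginals.
#' @param n_individuals_per_plant Cap for any cell count.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @return An `incidence_matrix` with labels `ant_1..n` / `plant_1..n`.
#' @export
generate_network <- function(n_ants = 29, n_plants = 9, target_fill = 0.5,
                             marginal_skew = 1, nested_strength = 1,
                             n_individuals_per_plant = 30, seed = 1) {
  stopifnot(n_ants >= 2, n_plants >= 2, target_fill > 0, target_fill <= 1,
            marginal_skew >= 0, nested_strength >= 0, nested_strength <= 1)
  L <- target_fill * n_ants * n_plants
  rank_weights <- function(n) {
    w <- seq_len(n)^(-marginal_skew)
    w / sum(w)
  }
  # target degrees proportional to rank weights, capped at the axis length,
  # with the excess redistributed so the degree sum stays at L
  cap_degrees <- function(w, cap) {
    k <- L * w
    repeat {
      over <- k >= cap
      if (all(over)) return(rep(cap, length(k)))
      spare <- L - cap * sum(over)
      k_new <- k
      k_new[over] <- cap
      k_new[!over] <- k[!over] * spare / sum(k[!over])
      if (max(k_new) <= cap + 1e-9) return(k_new)
      k <- k_new
    }
  }
  u <- rank_weights(n_ants)
  v <- rank_weights(n_plants)
  k_row <- cap_degrees(u, n_plants) # target ant degrees
  k_col <- cap_degrees(v, n_ants)   # target plant degrees
  p_ce <- outer(k_row / n_plants, k_col / n_ants, `+`) / 2
  p <- (1 - nested_strength) * target_fill + nested_strength * p_ce
  p <- pmin(pmax(p, 0), 1)
  withr::with_seed(seed, {
    pres <- matrix(stats::rbinom(length(p), 1L, p), n_ants)
    mean_count <- max(1, round(0.35 * n_individuals_per_plant))
    counts <- matrix(
      stats::rbinom(length(p), n_individuals_per_plant,
                    mean_count / n_individuals_per_plant),
      n_ants)
    counts <- pmax(counts, 1L) * pres
    dimnames(counts) <- list(paste0("ant_", seq_len(n_ants)),
                             paste0("plant_", seq_len(n_plants)))
    incidence_matrix(counts, n_individuals_per_plant,
                     period = sprintf("sim_seed%d", seed))
  })
}

default_species_effects <- function() {
  e <- seq(-1, 1, length.out = 9)
  e <- e / stats::sd(e) * 5          # species SD of 5 percentage points
  stats::setNames(e, paste0("species_", seq_len(9)))
}

#' Simulate an ant-exclusion herbivory experiment
#'
#' Generates a balanced species x stem-treatment x year factorial with
#' `n_individuals` plants per species, two stems per plant (ants present /
#' ants excluded), two years, and nine tagged leaves per stem. Leaf
#' herbivory (%) is additive: baseline + species effect + treatment effect
#' (added on excluded stems) + year effect (added in the second year) +
#' optional interactions + Gaussian stem noise, plus Gaussian within-stem
#' leaf noise; values are clamped to \[0, 100\]. Ant abundance on control
#' stems is lognormal with a year multiplier.
#'
#' @param species_effects Named vector of 9 species deviations (% points).
#' @param treatment_effect Herbivory added when ants are excluded (% points).
#' @param year_effect Herbivory added in year B (% points).
#' @param interaction_effects Optional list with matrices/vectors
#'   `species_stem`, `species_year` (length 9) and scalar `stem_year`.
#' @param noise_sd SD of the stem-level Gaussian noise (% points).
#' @param leaf_noise_sd SD of the within-stem leaf noise.
#' @param n_individuals Plants per species (study design: 30).
#' @param baseline Intercept herbivory (%).
#' @param abundance_meanlog,abundance_sdlog Lognormal parameters of
#'   control-stem ant counts.
#' @param abundance_year_multiplier Multiplier on year-B abundance.
#' @param seed Integer seed.
#' @return A list with `leaves` (tibble: species, individual, stem, year,
#'   leaf, position, herbivory_pct) and `abundance` (tibble: species,
#'   individual, year, ant_count).
#' @export
generate_herbivory <- function(species_effects = default_species_effects(),
                               treatment_effect = 3, year_effect = 4,
                               interaction_effects = NULL,
                               noise_sd = 2, leaf_noise_sd = 1,
                               n_individuals = 30, baseline = 15,
                               abundance_meanlog = log(20),
                               abundance_sdlog = 0.8,
                               abundance_year_multiplier = 1.5,
                               seed = 1) {
  stopifnot(length(species_effects) == 9, noise_sd >= 0, leaf_noise_sd >= 0,
            n_individuals >= 1)
  sp <- names(species_effects) %||% paste0("species_", seq_len(9))
  stems <- c("control_with_ants", "treatment_ants_excluded")
  years <- c("A", "B")
  positions <- c("apex", "middle", "base")
  design <- tidyr::expand_grid(
    species = sp,
    individual = sprintf("ind_%02d", seq_len(n_individuals)),
    stem = stems,
    year = years
  )
  ie <- interaction_effects %||% list()
  sp_stem <- stats::setNames(rep(0, 9), sp)
  if (!is.null(ie$species_stem)) sp_stem[] <- ie$species_stem
  sp_year <- stats::setNames(rep(0, 9), sp)
  if (!is.null(ie$species_year)) sp_year[] <- ie$species_year
  stem_year <- ie$stem_year %||% 0

  withr::with_seed(seed, {
    excl <- design$stem == stems[2]
    yrB <- design$year == "B"
    mu <- baseline +
      unname(species_effects[design$species]) +
      treatment_effect * excl +
      year_effect * yrB +
      sp_stem[design$species] * excl +
      sp_year[design$species] * yrB +
      stem_year * (excl & yrB)
    stem_mu <- mu + stats::rnorm(nrow(design), 0, noise_sd)
    leaves <- design |>
      dplyr::mutate(.stem_mu = stem_mu) |>
      tidyr::expand_grid(leaf = seq_len(9)) |>
      dplyr::mutate(
        position = positions[(leaf - 1) %/% 3 + 1],
        herbivory_pct = pmin(100, pmax(0,
          .data$.stem_mu + stats::rnorm(dplyr::n(), 0, leaf_noise_sd)))
      ) |>
      dplyr::select(-".stem_mu")
    abundance <- design |>
      dplyr::filter(.data$stem == stems[1]) |>
      dplyr::mutate(ant_count = round(
        exp(stats::rnorm(dplyr::n(), abundance_meanlog, abundance_sdlog)) *
          ifelse(.data$year == "B", abundance_year_multiplier, 1))) |>
      dplyr::select("species", "individual", "year", "ant_count")
    list(leaves = leaves, abundance = abundance)
  })
}
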