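test_that("the grid index is the damaged-point proportion", {
  expect_equal(herbivory_index(13, 52), 0.25)
  expect_equal(herbivory_index(0, 100), 0)
  expect_equal(herbivory_index(100, 100), 1)
  expect_error(herbivory_index(1, 0), "positive")
  expect_error(herbivory_index(5, 4), "0, total_points")
})

test_that("stem means average the available leaves and log the count", {
  leaves <- tidyr::expand_grid(species = "s1", individual = "i1",
                               stem = "control", year = "A", leaf = 1:9)
  leaves$herbivory_pct <- 4
  sm <- stem_mean_herbivory(leaves)
  expect_equal(sm$herbivory_pct, 4)
  expect_equal(sm$n_leaves, 9L)
  three <- leaves[1:3, ]
  three$herbivory_pct <- c(0, 50, 100)
  sm3 <- stem_mean_herbivory(three)
  expect_equal(sm3$herbivory_pct, 50)
  expect_equal(sm3$n_leaves, 3L)
})

test_that("the balanced factorial has the textbook df structure and SS partition", {
  sim <- generate_herbivory(seed = 5)
  sm <- stem_mean_herbivory(sim$leaves)
  fit <- factorial_anova(sm)
  tab <- tidy(fit)
  expect_equal(tab$df[match(c("species", "stem", "year", "species:stem",
                              "species:year", "stem:year",
                              "species:stem:year"), tab$term)],
               c(8L, 1L, 1L, 8L, 8L, 1L, 8L))
  expect_equal(tab$df[tab$term == "Residuals"],
               9 * 2 * 2 * 30 - (1 + 8 + 1 + 1 + 8 + 8 + 1 + 8))
  # exact partition of the total sum of squares on balanced data
  ss_total <- sum((sm$herbivory_pct - mean(sm$herbivory_pct))^2)
  expect_equal(sum(tab$sumsq), ss_total, tolerance = 1e-8)
})

test_that("balanced Type-III equals the classical Type-I decomposition", {
  sim <- generate_herbivory(seed = 23, n_individuals = 6)
  sm <- stem_mean_herbivory(sim$leaves)
  tab <- tidy(factorial_anova(sm))
  ref <- as.data.frame(anova(stats::aov(
    herbivory_pct ~ species * stem * year,
    data = transform(sm, species = factor(species), stem = factor(stem),
                     year = factor(year)))))
  ref_terms <- trimws(rownames(ref))
  for (term in setdiff(tab$term, "Residuals")) {
    expect_equal(tab$sumsq[tab$term == term],
                 ref$`Sum Sq`[ref_terms == term], tolerance = 1e-8,
                 label = paste("SS of", term))
  }
})

test_that("anova contracts: constant response, empty cell, grand-mean shift", {
  sim <- generate_herbivory(seed = 2, n_individuals = 4)
  sm <- stem_mean_herbivory(sim$leaves)
  flat <- sm
  flat$herbivory_pct <- 7
  tab <- tidy(factorial_anova(flat))
  expect_equal(sum(tab$sumsq), 0, tolerance = 1e-16)

  holed <- sm[!(sm$species == "species_1" & sm$stem == "control_with_ants" &
                  sm$year == "A"), ]
  expect_error(factorial_anova(holed), "empty")

  shifted <- sm
  shifted$herbivory_pct <- shifted$herbivory_pct + 100
  f1 <- tidy(factorial_anova(sm))
  f2 <- tidy(factorial_anova(shifted))
  expect_equal(f2$statistic, f1$statistic, tolerance = 1e-8)
})

test_that("factorial anova recovers injected main effects", {
  hits <- vapply(1:25, function(s) {
    sim <- generate_herbivory(seed = 1000 + s)
    tab <- tidy(factorial_anova(stem_mean_herbivory(sim$leaves)))
    all(tab$p.value[match(c("species", "stem", "year"), tab$term)] < 0.01)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("tukey_hsd follows the studentized range and TukeyHSD", {
  eq <- tukey_hsd(c(a = 5, b = 5), ms_error = 2, df_error = 20,
                  group_sizes = 10)
  expect_equal(eq$adj.p.value, 1, tolerance = 1e-9)
  far <- tukey_hsd(c(a = 0, b = 50), ms_error = 1, df_error = 20,
                   group_sizes = 10)
  expect_lt(far$adj.p.value, 0.05)
  expect_equal(nrow(tukey_hsd(setNames(1:5, letters[1:5]), 1, 20, 3)),
               5 * 4 / 2)
  expect_error(tukey_hsd(c(a = 1, b = 2), 1, 0, 3), "df_error")

  # cross-check adjusted p and intervals against stats::TukeyHSD
  withr::local_seed(77)
  d <- data.frame(g = rep(letters[1:4], each = 12),
                  y = rnorm(48) + rep(c(0, 1, 2, 4), each = 12))
  av <- stats::aov(y ~ g, d)
  ref <- as.data.frame(stats::TukeyHSD(av)$g)
  ms <- summary(av)[[1]]["Residuals", "Mean Sq"]
  got <- tukey_hsd(tapply(d$y, d$g, mean), ms, df.residual(av), 12)
  expect_equal(got$adj.p.value, ref$`p adj`, tolerance = 1e-6)
  expect_equal(got$estimate, ref$diff, tolerance = 1e-10)
  expect_equal(got$conf.low, ref$lwr, tolerance = 1e-6)
})

test_that("tukey_posthoc on species gives k(k-1)/2 comparisons", {
  sim <- generate_herbivory(seed = 3, n_individuals = 5)
  fit <- factorial_anova(stem_mean_herbivory(sim$leaves))
  tk <- tukey_posthoc(fit, "species")
  expect_equal(nrow(tk), 9 * 8 / 2)
  expect_true(all(tk$adj.p.value >= 0 & tk$adj.p.value <= 1))
})

test_that("per-species tests Bonferroni-adjust within year", {
  sim <- generate_herbivory(seed = 6, n_individuals = 8)
  sm <- stem_mean_herbivory(sim$leaves)
  res <- per_species_treatment_tests(sm)
  expect_equal(nrow(res), 18)
  expect_equal(res$adj.p.value, pmin(1, res$p.value * 9))
  expect_true(all(res$adj.p.value >= res$p.value))

  # identical (but varying) groups give t = 0, p = 1
  flat <- sm
  flat$herbivory_pct <- as.numeric(factor(flat$individual))
  r <- per_species_treatment_tests(flat)
  expect_true(all(abs(r$t) < 1e-12))
  expect_true(all(r$p.value > 0.999))
  const <- sm
  const$herbivory_pct <- 5
  rc <- per_species_treatment_tests(const)
  expect_true(all(rc$flag == "zero_variance"))
})

test_that("only species with a real treatment effect pass at adjusted 0.05", {
  # delta = 3 * noise SD on species 1-3 only, n = 30 stems per group
  hits <- vapply(1:20, function(s) {
    sim <- generate_herbivory(
      species_effects = setNames(rep(0, 9), paste0("species_", 1:9)),
      treatment_effect = 0, year_effect = 0, noise_sd = 2, leaf_noise_sd = 0,
      interaction_effects = list(species_stem = c(rep(6, 3), rep(0, 6))),
      seed = 400 + s)
    res <- per_species_treatment_tests(stem_mean_herbivory(sim$leaves))
    sig <- res$species[res$adj.p.value < 0.05]
    all(paste0("species_", 1:3) %in% sig) &&
      !any(paste0("species_", 4:9) %in% sig)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("paired abundance test is signed A minus B on log(x+1)", {
  a <- data.frame(species = "s", individual = 1:10, ant_count = c(1:10))
  expect_equal(paired_abundance_test(a, a)$t, 0)
  expect_equal(paired_abundance_test(a, a)$p.value, 1)
  b <- a
  b$ant_count <- round((a$ant_count + 1) * 2 - 1)  # +log 2 in log1p space
  res <- paired_abundance_test(a, b)
  expect_lt(res$t, 0)
  expect_lt(res$p.value, 0.05)
  expect_warning(paired_abundance_test(a, b[1:8, ]), "unpaired")
  expect_error(paired_abundance_test(a[1, , drop = FALSE], b[1, , drop = FALSE]),
               "2 complete pairs")
})

test_that("a year multiplier of 1.5 is detected in 270 lognormal pairs", {
  hits <- vapply(1:20, function(s) {
    sim <- generate_herbivory(seed = 600 + s)
    ab <- sim$abundance
    paired_abundance_test(ab[ab$year == "A", ], ab[ab$year == "B", ])$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("null simulation keeps the main-effect type-I error near 0.05", {
  # no effects at all; 1,000 refits of the balanced design at reduced n
  p_vals <- vapply(1:1000, function(s) {
    sim <- generate_herbivory(
      species_effects = setNames(rep(0, 9), paste0("species_", 1:9)),
      treatment_effect = 0, year_effect = 0, noise_sd = 2, leaf_noise_sd = 0,
      n_individuals = 3, seed = 300000 + s)
    tab <- tidy(factorial_anova(stem_mean_herbivory(sim$leaves)))
    tab$p.value[match(c("species", "stem", "year"), tab$term)]
  }, numeric(3))
  rates <- rowMeans(p_vals < 0.05)
  # three simultaneous binomial checks: family-wise 95% band (Bonferroni)
  half_width <- qnorm(1 - 0.05 / (2 * 3)) * sqrt(0.05 * 0.95 / 1000)
  for (r in rates) {
    expect_gte(r, 0.05 - half_width)
    expect_lte(r, 0.05 + half_width)
  }
  # sharper calibration check: null p-values are uniform
  expect_gt(ks.test(as.vector(p_vals), "punif")$p.value, 0.01)
})
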