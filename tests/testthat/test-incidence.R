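test_that("construction validates labels, signs and the per-plant cap", {
  m <- toy_matrix(c(0, 2, 5, 0), 2, 2)
  expect_s3_class(m, "incidence_matrix")
  expect_error(incidence_matrix(matrix(1, 1, 1)), "row names")
  dup <- matrix(1, 2, 2, dimnames = list(c("a", "a"), c("p1", "p2")))
  expect_error(incidence_matrix(dup), "duplicate ant")
  neg <- matrix(c(-1, 0, 0, 0), 2, 2,
                dimnames = list(c("a1", "a2"), c("p1", "p2")))
  expect_error(incidence_matrix(neg), "non-negative")
  big <- matrix(c(31, 0, 0, 0), 2, 2,
                dimnames = list(c("a1", "a2"), c("p1", "p2")))
  expect_error(incidence_matrix(big, n_individuals_per_plant = 30), "exceeds")
})

test_that("edge-list reading sums duplicate pairs and zero-fills gaps", {
  el <- data.frame(ant = c("a1", "a1", "a2"), plant = c("p1", "p1", "p2"),
                   count = c(2, 3, 4))
  m <- as_incidence_matrix(el)
  expect_equal(m["a1", "p1"], 5L, ignore_attr = TRUE)
  expect_equal(m["a1", "p2"], 0L, ignore_attr = TRUE)

  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ant\tplant\tcount", "a1\tp1\t2", "a1\tp1\t3"), tf)
  m2 <- read_incidence(tf)
  expect_equal(m2["a1", "p1"], 5L, ignore_attr = TRUE)
})

test_that("matrix dialect errors name the offending cell or label", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ant,p1,p2", "a1,1,x", "a2,0,1"), tf)
  expect_error(read_incidence(tf, "matrix"), "ant 'a1', plant 'p2'")
  writeLines(c("ant,p1,p1", "a1,1,2"), tf)
  expect_error(read_incidence(tf, "matrix"), "duplicate plant")
})

test_that("write/read round-trips both dialects exactly", {
  withr::local_seed(42)
  m <- generate_network(n_ants = 12, n_plants = 5, seed = 99)
  for (dialect in c("matrix", "edgelist")) {
    tf <- withr::local_tempfile(fileext = if (dialect == "matrix") ".csv" else ".tsv")
    write_incidence(m, tf, dialect)
    m2 <- read_incidence(tf, period = attr(m, "period"))
    expect_equal(unclass_mat(m2), unclass_mat(m), ignore_attr = TRUE)
  }
})

test_that("degrees, connectance and asymmetry follow their definitions", {
  m <- toy_matrix(c(1, 1, 0, 1, 0, 0), 2, 3)
  expect_equal(species_degree(m, "ants")$degree, c(2L, 1L))
  expect_equal(species_degree(m, "plants")$degree, c(2L, 1L, 0L))
  zero <- toy_matrix(rep(0, 6), 2, 3)
  expect_equal(species_degree(zero, "ants")$degree, c(0L, 0L))

  expect_equal(connectance(m), 100 * 3 / 6)
  full <- toy_matrix(rep(1, 6), 2, 3)
  expect_equal(connectance(full), 100)

  expect_equal(web_asymmetry(5, 5), 0)
  expect_equal(web_asymmetry(9, 26), -17 / 35)
  expect_error(web_asymmetry(0, 0), "positive")
  # printed-table parity: truncation toward zero, not rounding
  expect_equal(report_value(abs(web_asymmetry(9, 26)), "truncate2"), 0.48)
  expect_equal(report_value(abs(web_asymmetry(9, 29)), "truncate2"), 0.52)
})

test_that("average degree uses the sample-SD standard error", {
  m <- toy_matrix(c(1, 1, 0, 1, 0, 0), 2, 3)
  ad <- average_degree(m, "ants")
  expect_equal(ad$mean_degree, 1.5)
  expect_equal(ad$se_degree, sd(c(2, 1)) / sqrt(2))
  same <- toy_matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(average_degree(same, "ants")$se_degree, 0)
  single <- incidence_matrix(matrix(c(1, 1), 1, 2,
                                    dimnames = list("a1", c("p1", "p2"))))
  expect_true(is.na(average_degree(single, "ants")$se_degree))
})

test_that("binarize is idempotent and preserves zero rows", {
  m <- toy_matrix(c(0, 2, 5, 0, 0, 0), 3, 2)
  b <- binarize(m)
  expect_equal(unclass_mat(b), matrix(c(0L, 1L, 1L, 0L, 0L, 0L), 3, 2,
                                      byrow = TRUE), ignore_attr = TRUE)
  expect_equal(unclass_mat(binarize(b)), unclass_mat(b))
})

test_that("occupancy needs the per-plant census size and a known label", {
  m <- incidence_matrix(matrix(c(3, 0, 0, 0), 2, 2,
                               dimnames = list(c("a1", "a2"), c("p1", "p2"))),
                        n_individuals_per_plant = 30)
  expect_equal(occupancy(m, "a1"), 100 * 3 / 60)
  expect_equal(occupancy(m, "a2"), 0)
  expect_error(occupancy(m, "zz"), "unknown ant")
  no_npp <- toy_matrix(c(1, 0, 0, 1), 2, 2)
  expect_error(occupancy(no_npp, "a1"), "not set")
})

test_that("full-degree species are those linked to every plant", {
  m <- toy_matrix(c(1, 1, 1, 0, 0, 0), 2, 3)
  expect_equal(full_degree_species(m), "a1")
  expect_equal(full_degree_species(toy_matrix(rep(0, 4), 2, 2)), character(0))
  col1 <- incidence_matrix(matrix(c(2, 0, 1), 3, 1,
                                  dimnames = list(paste0("a", 1:3), "p1")))
  expect_equal(full_degree_species(col1), c("a1", "a3"))
})

test_that("degree sums, connectance and |W| are permutation invariant", {
  withr::local_seed(7)
  for (rep in 1:20) {
    m <- random_binary_matrix(6, 5)
    im <- incidence_matrix(m)
    L <- n_links(im)
    expect_equal(sum(species_degree(im, "ants")$degree), L)
    expect_equal(sum(species_degree(im, "plants")$degree), L)
    perm <- incidence_matrix(m[sample(6), sample(5)])
    expect_equal(connectance(perm), connectance(im))
    expect_equal(sort(species_degree(perm, "ants")$degree),
                 sort(species_degree(im, "ants")$degree))
  }
})

test_that("tidy/glance present the matrix as tibbles", {
  m <- toy_matrix(c(0, 2, 5, 0), 2, 2)
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  expect_equal(nrow(tidy(m, keep_zeros = TRUE)), 4)
  g <- glance(m)
  expect_equal(g$n_links, 2L)
  expect_equal(g$n_associations, 7L)
})
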