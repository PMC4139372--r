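#' NODF nestedness of a binary matrix
#'
#' Nestedness metric based on Overlap and Decreasing Fill, on a 0-100 scale.
#' For every unordered pair of rows (and of columns), the paired term is
#' `100 * shared presences / fill of the less-filled member` when the two
#' fills strictly differ, and 0 when they are equal (the decreasing-fill
#' requirement); an empty less-filled line contributes 0. NODF is the mean
#' over all row pairs and column pairs.
#'
#' @param x A binary `incidence_matrix` (or 0/1 matrix) with at least two
#'   rows and two columns. Quantitative matrices must be passed through
#'   [binarize()] first.
#' @return NODF in \[0, 100\].
#' @export
nodf <- function(x) {
  b <- if (inherits(x, "incidence_matrix")) unclass_incidence(x) else as.matrix(x)
  if (!is_binary(b)) {
    stop("nodf() needs a binary matrix; call binarize() first", call. = FALSE)
  }
  if (nrow(b) < 2L || ncol(b) < 2L) {
    stop("nodf() needs at least 2 rows and 2 columns", call. = FALSE)
  }
  storage.mode(b) <- "double"
  terms <- c(nodf_axis_terms(b), nodf_axis_terms(t(b)))
  mean(terms)
}

# pairwise overlap terms along rows of b (vectorized over all row pairs)
nodf_axis_terms <- function(b) {
  fills <- rowSums(b)
  shared <- tcrossprod(b)            # shared presences for every row pair
  n <- nrow(b)
  pairs <- which(upper.tri(shared), arr.ind = TRUE)
  fi <- fills[pairs[, 1]]
  fj <- fills[pairs[, 2]]
  lo <- pmin(fi, fj)
  out <- numeric(nrow(pairs))
  ok <- fi != fj & lo > 0
  out[ok] <- 100 * shared[pairs][ok] / lo[ok]
  out
}

#' Cell probabilities of the Ce (type II) null model
#'
#' Under the Ce null the probability that ant i interacts with plant j is the
#' mean of the row's and the column's fill proportions:
#' `p_ij = (k_i / C + k_j / R) / 2`, with `k_i` the degree of row i, `k_j`
#' the degree of column j, and R, C the matrix dimensions. The probabilities
#' sum exactly to the observed number of links L, so the null conserves the
#' expected fill.
#'
#' @inheritParams nodf
#' @return A numeric matrix of probabilities in \[0, 1\], same dimnames.
#' @export
null_ce_probabilities <- function(x) {
  b <- if (inherits(x, "incidence_matrix")) unclass_incidence(x) else as.matrix(x)
  if (!is_binary(b)) {
    stop("Ce probabilities are defined on a binary matrix; call binarize()",
         call. = FALSE)
  }
  storage.mode(b) <- "double"
  (outer(rowSums(b) / ncol(b), colSums(b) / nrow(b), `+`)) / 2
}

#' Draw one binary matrix from a cell-probability matrix
#'
#' Independent Bernoulli draw per cell; reproducible given `seed`.
#'
#' @param probabilities Numeric matrix of probabilities in \[0, 1\].
#' @param seed Optional integer seed (Mersenne-Twister).
#' @return A 0/1 integer matrix with the same dimnames.
#' @export
sample_null <- function(probabilities, seed = NULL) {
  stopifnot(all(probabilities >= 0), all(probabilities <= 1))
  draw <- function() {
    m <- matrix(stats::rbinom(length(probabilities), 1L, probabilities),
                nrow(probabilities), dimnames = dimnames(probabilities))
    storage.mode(m) <- "integer"
    m
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Monte-Carlo significance of NODF under the Ce null
#'
#' Draws `n_randomizations` matrices from the Ce null model of the observed
#' matrix and scores each with [nodf()]. Null matrices with empty rows or
#' columns are kept and scored (their empty lines contribute zero overlap);
#' only the count of fully degenerate (all-zero) draws is reported. The
#' one-tailed p-value uses the add-one rule `(1 + #(null >= obs)) / (1 + n)`
#' so that p is never exactly zero.
#'
#' @inheritParams nodf
#' @param n_randomizations Number of null draws (the classical choice is
#'   1000).
#' @param seed Integer seed for the whole ensemble.
#' @return A `null_ensemble` object: list with `observed`, `null_values`,
#'   `null_mean`, `null_sd`, `z`, `p`, `seed`, `n_randomizations`,
#'   `n_degenerate_discarded`, `statistic`. See [tidy.null_ensemble()].
#' @export
nestedness_significance <- function(x, n_randomizations = 1000, seed = NULL) {
  if (n_randomizations < 1L) stop("n_randomizations must be >= 1", call. = FALSE)
  b <- if (inherits(x, "incidence_matrix")) unclass_incidence(binarize(x)) else {
    m <- as.matrix(x)
    m[m > 0] <- 1L
    storage.mode(m) <- "integer"
    m
  }
  observed <- nodf(b)
  probs <- null_ce_probabilities(b)
  run <- function() {
    vapply(seq_len(n_randomizations), function(i) {
      m <- sample_null(probs)
      if (all(m == 0L)) return(c(NA_real_, 1))
      c(nodf(m), 0)
    }, numeric(2))
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  nulls <- res[1, ]
  n_degenerate <- sum(res[2, ])
  nulls[is.na(nulls)] <- 0  # an all-empty draw has no overlap at all
  null_mean <- mean(nulls)
  null_sd <- stats::sd(nulls)
  structure(list(
    statistic = "NODF",
    observed = observed,
    null_values = nulls,
    null_mean = null_mean,
    null_sd = null_sd,
    z = if (null_sd > 0) (observed - null_mean) / null_sd else NA_real_,
    p = (1 + sum(nulls >= observed)) / (1 + n_randomizations),
    seed = seed,
    n_randomizations = as.integer(n_randomizations),
    n_degenerate_discarded = as.integer(n_degenerate)
  ), class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %s = %.3f; null %.3f +/- %.3f (n = %d); z = %.2f; P = %.4g\n",
              x$statistic, x$observed, x$null_mean, x$null_sd,
              x$n_randomizations, x$z, x$p))
  invisible(x)
}

#' Tidy a Monte-Carlo null ensemble
#'
#' @param x A `null_ensemble`.
#' @param ... Unused.
#' @return `tidy()`: one row per null draw (`draw`, `value`). `glance()`: a
#'   one-row summary with the observed statistic, null mean/SD, z and p.
#' @method tidy null_ensemble
#' @export
tidy.null_ensemble <- function(x, ...) {
  tibble::tibble(draw = seq_along(x$null_values), value = x$null_values)
}

#' @rdname tidy.null_ensemble
#' @method glance null_ensemble
#' @export
glance.null_ensemble <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, observed = x$observed,
    null_mean = x$null_mean, null_sd = x$null_sd, z = x$z, p = x$p,
    n_randomizations = x$n_randomizations,
    n_degenerate_discarded = x$n_degenerate_discarded
  )
}
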