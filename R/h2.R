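#' Two-dimensional Shannon entropy of interaction proportions
#'
#' `H2 = -sum p_ij ln p_ij` over the positive cells of a quantitative
#' interaction matrix, with `p_ij = a_ij / m` and m the grand total of
#' interactions. Natural logarithm throughout.
#'
#' @param x A quantitative `incidence_matrix` (or count matrix) with grand
#'   total > 0.
#' @return H2 in nats.
#' @export
shannon_h2 <- function(x) {
  a <- if (inherits(x, "incidence_matrix")) unclass_incidence(x) else as.matrix(x)
  m <- sum(a)
  if (m <= 0) stop("grand total must be positive", call. = FALSE)
  p <- a[a > 0] / m
  -sum(p * log(p))
}

#' Entropy bounds of H2 given fixed marginal totals
#'
#' The maximum is the entropy of the continuous independence table with
#' cells `r_i * c_j / m` (equivalently the sum of the two marginal
#' entropies): the most generalized arrangement compatible with the
#' marginals. The minimum comes from the greedy concentration heuristic:
#' repeatedly allocate `min(largest remaining row total, largest remaining
#' column total)` to that cell and decrement, until all mass is placed —
#' packing interactions into as few cells as the marginals allow. Ties are
#' broken by lowest index.
#'
#' @param row_totals,col_totals Non-negative marginal totals with equal sums.
#' @return A list with `h2_min` and `h2_max` (nats).
#' @export
h2_bounds <- function(row_totals, col_totals) {
  m <- sum(row_totals)
  if (!isTRUE(all.equal(m, sum(col_totals)))) {
    stop("row and column totals must have the same sum", call. = FALSE)
  }
  if (m <= 0) stop("grand total must be positive", call. = FALSE)
  marg_entropy <- function(t) {
    p <- t[t > 0] / m
    -sum(p * log(p))
  }
  h2_max <- marg_entropy(row_totals) + marg_entropy(col_totals)

  r <- as.numeric(row_totals)
  c_ <- as.numeric(col_totals)
  cells <- numeric(0)
  while (sum(r) > 1e-12) {
    i <- which.max(r)   # which.max takes the lowest index on ties
    j <- which.max(c_)
    q <- min(r[i], c_[j])
    cells <- c(cells, q)
    r[i] <- r[i] - q
    c_[j] <- c_[j] - q
  }
  p <- cells[cells > 0] / m
  list(h2_min = -sum(p * log(p)), h2_max = h2_max)
}

#' Network-level specialization index H2'
#'
#' Standardizes the two-dimensional Shannon entropy of a quantitative
#' interaction matrix between its constrained extremes given the observed
#' marginal totals: `H2' = (H2max - H2) / (H2max - H2min)`, clamped to
#' \[0, 1\]. 0 means extreme generalization (interactions distributed as
#' expected from the marginals alone), 1 extreme specialization
#' (interactions maximally concentrated). When the bounds are degenerate
#' (`H2max - H2min` below `tol`) the index is defined as 0.
#'
#' @inheritParams shannon_h2
#' @param tol Degeneracy tolerance for the bound difference.
#' @return An `h2_result` object: list with `h2`, `h2_min`, `h2_max`,
#'   `h2_prime`. Use [tidy.h2_result()] for a tibble.
#' @export
h2_prime <- function(x, tol = 1e-9) {
  a <- if (inherits(x, "incidence_matrix")) unclass_incidence(x) else as.matrix(x)
  h2 <- shannon_h2(a)
  bounds <- h2_bounds(rowSums(a), colSums(a))
  denom <- bounds$h2_max - bounds$h2_min
  h2p <- if (denom < tol) 0 else
    min(1, max(0, (bounds$h2_max - h2) / denom))
  structure(list(h2 = h2, h2_min = bounds$h2_min, h2_max = bounds$h2_max,
                 h2_prime = h2p),
            class = "h2_result")
}

#' @export
print.h2_result <- function(x, ...) {
  cat(sprintf("<h2_result> H2 = %.4f in [%.4f, %.4f]; H2' = %.4f\n",
              x$h2, x$h2_min, x$h2_max, x$h2_prime))
  invisible(x)
}

#' Tidy an H2' result
#'
#' @param x An `h2_result`.
#' @param ... Unused.
#' @return A one-row tibble with `h2`, `h2_min`, `h2_max`, `h2_prime`.
#' @method tidy h2_result
#' @export
tidy.h2_result <- function(x, ...) {
  tibble::tibble(h2 = x$h2, h2_min = x$h2_min, h2_max = x$h2_max,
                 h2_prime = x$h2_prime)
}
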