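# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementations.

# NODF by direct pairwise enumeration, O(R^2 C + C^2 R)
naive_nodf <- function(b) {
  b <- as.matrix(b)
  pair_terms <- function(m) {
    n <- nrow(m)
    out <- c()
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        fi <- sum(m[i, ]); fj <- sum(m[j, ])
        if (fi == fj || min(fi, fj) == 0) {
          out <- c(out, 0)
        } else {
          shared <- sum(m[i, ] == 1 & m[j, ] == 1)
          out <- c(out, 100 * shared / min(fi, fj))
        }
      }
    }
    out
  }
  mean(c(pair_terms(b), pair_terms(t(b))))
}

# all non-negative integer tables with the given marginals (small cases only)
enumerate_tables <- function(row_totals, col_totals) {
  R <- length(row_totals); C <- length(col_totals)
  out <- list()
  recurse <- function(cells, idx, r_rem, c_rem) {
    if (idx > R * C) {
      if (all(r_rem == 0) && all(c_rem == 0)) {
        out[[length(out) + 1]] <<- matrix(cells, R, C, byrow = TRUE)
      }
      return(invisible())
    }
    i <- (idx - 1) %/% C + 1
    j <- (idx - 1) %% C + 1
    for (v in 0:min(r_rem[i], c_rem[j])) {
      r2 <- r_rem; r2[i] <- r2[i] - v
      c2 <- c_rem; c2[j] <- c2[j] - v
      # prune: a row must be exhausted by its last column
      if (j == C && r2[i] != 0) next
      recurse(c(cells, v), idx + 1, r2, c2)
    }
  }
  recurse(integer(0), 1, row_totals, col_totals)
  out
}

shannon_of_table <- function(m) {
  p <- m[m > 0] / sum(m)
  -sum(p * log(p))
}

# minimum two-dimensional entropy over all integer tables with the marginals
exhaustive_min_entropy <- function(row_totals, col_totals) {
  tabs <- enumerate_tables(row_totals, col_totals)
  min(vapply(tabs, shannon_of_table, numeric(1)))
}

random_binary_matrix <- function(nr, nc, fill = 0.5) {
  matrix(rbinom(nr * nc, 1, fill), nr, nc,
         dimnames = list(paste0("r", seq_len(nr)), paste0("c", seq_len(nc))))
}

toy_matrix <- function(cells, nr, nc, prefix = c("a", "p")) {
  incidence_matrix(matrix(cells, nr, nc, byrow = TRUE,
                          dimnames = list(paste0(prefix[1], seq_len(nr)),
                                          paste0(prefix[2], seq_len(nc)))))
}

# plain integer matrix view for exact comparisons
unclass_mat <- function(m) {
  matrix(as.integer(m), nrow(m), ncol(m), dimnames = dimnames(m))
}
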