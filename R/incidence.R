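#' Construct a labelled ant x plant incidence matrix
#'
#' The central data structure of the package: a non-negative integer count
#' matrix with ant species as rows and plant species as columns. Counts are
#' typically the number of tagged plant individuals on which an ant species
#' was recorded, so a cell can never exceed the number of tagged individuals
#' per plant species when that number is known.
#'
#' @param counts A numeric matrix of non-negative integers with unique row
#'   (ant) and column (plant) names, or an object coercible to one.
#' @param n_individuals_per_plant Positive integer; number of tagged
#'   individuals per plant species (upper bound for any cell), or `NULL` if
#'   unknown.
#' @param period Free-text label for the sampling period (e.g. `"2009"`,
#'   `"combined"`).
#' @return An object of class `incidence_matrix`: the validated integer
#'   matrix with attributes `n_individuals_per_plant` and `period`.
#' @examples
#' m <- incidence_matrix(matrix(c(0, 2, 5, 0), 2, 2,
#'   dimnames = list(c("a1", "a2"), c("p1", "p2"))))
#' connectance(m)
#' @export
incidence_matrix <- function(counts, n_individuals_per_plant = NULL,
                             period = "combined") {
  counts <- as.matrix(counts)
  if (nrow(counts) < 1L || ncol(counts) < 1L) {
    stop("incidence matrix needs at least one ant row and one plant column",
         call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry ant row names and plant column names", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate ant labels: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate plant labels: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyNA(counts) || !is.numeric(counts)) {
    stop("all cells must be non-missing numbers", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("all cells must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (!is.null(n_individuals_per_plant)) {
    n_individuals_per_plant <- as.integer(n_individuals_per_plant)
    stopifnot(length(n_individuals_per_plant) == 1L, n_individuals_per_plant > 0L)
    if (any(counts > n_individuals_per_plant)) {
      stop("a cell count exceeds n_individuals_per_plant (",
           n_individuals_per_plant, ")", call. = FALSE)
    }
  }
  structure(counts,
            n_individuals_per_plant = n_individuals_per_plant,
            period = period,
            class = c("incidence_matrix", "matrix", "array"))
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("<incidence_matrix> %d ants x %d plants, period '%s'\n",
              nrow(x), ncol(x), attr(x, "period") %||% "?"))
  cat(sprintf("  links %d, associations %d", n_links(x), sum(x)))
  npp <- attr(x, "n_individuals_per_plant")
  if (!is.null(npp)) cat(sprintf(", %d tagged individuals per plant", npp))
  cat("\n")
  print(unclass_incidence(x), ...)
  invisible(x)
}

# strip class/attributes for base-matrix operations
unclass_incidence <- function(x) {
  y <- as.matrix(x)
  attr(y, "n_individuals_per_plant") <- NULL
  attr(y, "period") <- NULL
  class(y) <- NULL
  dim(y) <- dim(x)
  dimnames(y) <- dimnames(x)
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Turn an incidence matrix into a tidy edge list
#'
#' @param x An `incidence_matrix`.
#' @param keep_zeros Keep unrealized (zero-count) ant-plant pairs?
#' @param ... Unused.
#' @return A tibble with columns `ant`, `plant`, `count`.
#' @method tidy incidence_matrix
#' @export
tidy.incidence_matrix <- function(x, keep_zeros = FALSE, ...) {
  out <- tibble::tibble(
    ant = rep(rownames(x), times = ncol(x)),
    plant = rep(colnames(x), each = nrow(x)),
    count = as.integer(x)
  )
  if (!keep_zeros) out <- dplyr::filter(out, .data$count > 0L)
  dplyr::arrange(out, match(.data$ant, rownames(x)), match(.data$plant, colnames(x)))
}

#' One-row summary of an incidence matrix
#'
#' @inheritParams tidy.incidence_matrix
#' @return A tibble with species counts, link count, grand total, fill and
#'   connectance.
#' @method glance incidence_matrix
#' @export
glance.incidence_matrix <- function(x, ...) {
  tibble::tibble(
    n_ants = nrow(x), n_plants = ncol(x),
    n_links = n_links(x), n_associations = sum(x),
    fill = n_links(x) / length(x),
    connectance_pct = connectance(x)
  )
}

#' Read an incidence matrix from disk
#'
#' Two dialects are supported. `"matrix"`: a CSV with plant labels in the
#' header, ant labels in the first column and integer counts in the cells (an
#' optional `total` column of row sums is checked and dropped). `"edgelist"`:
#' a TSV with columns `ant`, `plant`, `count` (and optionally `period`);
#' duplicate (ant, plant) pairs are summed and unlisted pairs are zero.
#'
#' @param path File to read.
#' @param dialect `"auto"` (by extension/columns), `"matrix"` or `"edgelist"`.
#' @param n_individuals_per_plant,period Passed to [incidence_matrix()].
#' @return An `incidence_matrix`.
#' @export
read_incidence <- function(path, dialect = c("auto", "matrix", "edgelist"),
                           n_individuals_per_plant = NULL, period = "combined") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "auto") {
    header <- strsplit(readLines(path, n = 1L), "[,\t]")[[1]]
    dialect <- if (all(c("ant", "plant", "count") %in% header)) "edgelist" else "matrix"
  }
  if (dialect == "matrix") {
    d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    ants <- as.character(d[[1]])
    # keep the raw header: data-frame subsetting silently repairs duplicates
    plants <- names(d)[-1]
    d <- d[, -1, drop = FALSE]
    total_col <- plants == "total"
    totals <- if (any(total_col)) d[[which(total_col)]] else NULL
    plants <- plants[!total_col]
    d <- d[, !total_col, drop = FALSE]
    cells <- suppressWarnings(
      vapply(d, function(col) as.numeric(col), numeric(nrow(d)))
    )
    cells <- matrix(cells, nrow = nrow(d), dimnames = list(ants, plants))
    if (anyNA(cells)) {
      bad <- which(is.na(cells), arr.ind = TRUE)[1, ]
      stop(sprintf("malformed numeric cell at ant '%s', plant '%s'",
                   ants[bad[1]], names(d)[bad[2]]), call. = FALSE)
    }
    m <- incidence_matrix(cells, n_individuals_per_plant, period)
    if (!is.null(totals) && !all(rowSums(m) == totals)) {
      stop("row totals column disagrees with cell sums", call. = FALSE)
    }
    m
  } else {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("ant", "plant", "count") %in% names(d))) {
      stop("edge list needs columns ant, plant, count", call. = FALSE)
    }
    if (anyNA(suppressWarnings(as.numeric(d$count)))) {
      bad <- which(is.na(suppressWarnings(as.numeric(d$count))))[1]
      stop(sprintf("malformed numeric cell at ant '%s', plant '%s'",
                   d$ant[bad], d$plant[bad]), call. = FALSE)
    }
    as_incidence_matrix(d, n_individuals_per_plant = n_individuals_per_plant,
                        period = period)
  }
}

#' Build an incidence matrix from a tidy edge list
#'
#' @param x A data frame with columns `ant`, `plant`, `count`. Duplicate
#'   (ant, plant) rows are summed; pairs absent from the data are zero.
#' @inheritParams read_incidence
#' @export
as_incidence_matrix <- function(x, n_individuals_per_plant = NULL,
                                period = "combined") {
  stopifnot(is.data.frame(x), all(c("ant", "plant", "count") %in% names(x)))
  agg <- x |>
    dplyr::group_by(.data$ant, .data$plant) |>
    dplyr::summarise(count = sum(as.numeric(.data$count)), .groups = "drop")
  ants <- unique(as.character(x$ant))
  plants <- unique(as.character(x$plant))
  m <- matrix(0, length(ants), length(plants), dimnames = list(ants, plants))
  m[cbind(match(agg$ant, ants), match(agg$plant, plants))] <- agg$count
  incidence_matrix(m, n_individuals_per_plant, period)
}

#' Write an incidence matrix to disk
#'
#' @param x An `incidence_matrix`.
#' @param path Output file.
#' @param dialect `"matrix"` (CSV) or `"edgelist"` (TSV). The edge list is
#'   written densely — zero cells included — so species without links and the
#'   axis ordering survive a round trip; hand-written sparse edge lists read
#'   just as well.
#' @return `path`, invisibly.
#' @export
write_incidence <- function(x, path, dialect = c("matrix", "edgelist")) {
  dialect <- match.arg(dialect)
  if (dialect == "matrix") {
    d <- tibble::as_tibble(unclass_incidence(x), .name_repair = "minimal")
    d <- dplyr::bind_cols(tibble::tibble(ant = rownames(x)), d)
    readr::write_csv(d, path)
  } else {
    readr::write_tsv(tidy.incidence_matrix(x, keep_zeros = TRUE), path)
  }
  invisible(path)
}

#' Reduce a quantitative matrix to presence/absence
#'
#' @param x An `incidence_matrix`.
#' @return The qualitative (0/1) `incidence_matrix`; labels and attributes
#'   preserved. Idempotent.
#' @export
binarize <- function(x) {
  stopifnot(inherits(x, "incidence_matrix"))
  b <- unclass_incidence(x)
  b[b > 0] <- 1L
  incidence_matrix(b, attr(x, "n_individuals_per_plant"), attr(x, "period"))
}

is_binary <- function(x) all(x %in% c(0L, 1L))

#' Number of realized links (L)
#' @param x An `incidence_matrix`.
#' @export
n_links <- function(x) sum(unclass_incidence(x) > 0)

#' Species degree
#'
#' Degree k of a species is its number of partner species with a positive
#' count.
#'
#' @param x An `incidence_matrix`.
#' @param axis `"ants"` (rows) or `"plants"` (columns).
#' @return A tibble with columns `species` and `degree`, in axis label order.
#' @export
species_degree <- function(x, axis = c("ants", "plants")) {
  axis <- match.arg(axis)
  b <- unclass_incidence(x) > 0
  k <- if (axis == "ants") rowSums(b) else colSums(b)
  tibble::tibble(species = names(k), degree = as.integer(k))
}

#' Average species degree with its standard error
#'
#' @inheritParams species_degree
#' @return A tibble with `axis`, `n_species`, `mean_degree`, `se_degree`
#'   (sample SD / sqrt(n); `NA` for a single species).
#' @export
average_degree <- function(x, axis = c("ants", "plants")) {
  axis <- match.arg(axis)
  k <- species_degree(x, axis)$degree
  se <- if (length(k) > 1L) stats::sd(k) / sqrt(length(k)) else NA_real_
  tibble::tibble(axis = axis, n_species = length(k),
                 mean_degree = mean(k), se_degree = se)
}

#' Network connectance (percentage of possible links realized)
#'
#' @param x An `incidence_matrix`.
#' @return `100 * L / (I * J)` where L is the number of realized links and I,
#'   J the numbers of plant and ant species.
#' @export
connectance <- function(x) {
  connectance_value(n_links(x), nrow(x), ncol(x))
}

#' @rdname connectance
#' @param n_links,n_ants,n_plants Closed-form inputs when no matrix is at
#'   hand (e.g. a link count read from a published table).
#' @export
connectance_value <- function(n_links, n_ants, n_plants) {
  stopifnot(n_ants > 0, n_plants > 0, n_links >= 0,
            n_links <= n_ants * n_plants)
  100 * n_links / (n_ants * n_plants)
}

#' Web asymmetry
#'
#' W = (I - J) / (I + J) for I plant and J ant species: 0 for balanced webs,
#' positive when plants outnumber ants, negative otherwise, in \[-1, 1\].
#' Published tables often report the magnitude |W|; use [report_value()] with
#' the `truncate2` rule for table parity.
#'
#' @param n_plants,n_ants Species counts I and J.
#' @return Signed W.
#' @export
web_asymmetry <- function(n_plants, n_ants) {
  if (n_plants + n_ants == 0) stop("I + J must be positive", call. = FALSE)
  (n_plants - n_ants) / (n_plants + n_ants)
}

#' Apply a reporting precision rule
#'
#' `"truncate2"` truncates toward zero at 2 decimals (the convention behind
#' printed values like 0.48 for 17/35); `"round3"` rounds to 3 decimals;
#' `"full"` returns the value unchanged.
#'
#' @param x Numeric vector.
#' @param rule Precision rule.
#' @export
report_value <- function(x, rule = c("full", "truncate2", "round3")) {
  rule <- match.arg(rule)
  switch(rule,
         full = x,
         truncate2 = trunc(x * 100) / 100,
         round3 = round(x, 3))
}

#' Occupancy of an ant species across tagged plant individuals
#'
#' @param x An `incidence_matrix` with `n_individuals_per_plant` set.
#' @param ant Ant row label.
#' @return Percentage of all tagged plant individuals
#'   (`n_plants * n_individuals_per_plant`) on which the ant was recorded.
#' @export
occupancy <- function(x, ant) {
  npp <- attr(x, "n_individuals_per_plant")
  if (is.null(npp)) stop("n_individuals_per_plant is not set", call. = FALSE)
  if (!ant %in% rownames(x)) stop("unknown ant label: ", ant, call. = FALSE)
  100 * sum(x[ant, ]) / (ncol(x) * npp)
}

#' Ant species interacting with every plant species
#'
#' @param x An `incidence_matrix`.
#' @return Character vector of ant labels whose degree equals the number of
#'   plant columns, in row order.
#' @export
full_degree_species <- function(x) {
  deg <- species_degree(x, "ants")
  deg$species[deg$degree == ncol(x)]
}
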