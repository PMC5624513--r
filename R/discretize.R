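#' Equal-width bin edges
#'
#' Partition the range of a continuous expression vector into `n_bins` bins of
#' equal width. When `n_bins` is not given it defaults to the square root of
#' the number of observations, rounded half-away-from-zero to the nearest
#' integer (minimum 1) -- the usual heuristic for moderate sample sizes.
#'
#' @param values Numeric vector of observations (finite, non-empty).
#' @param n_bins Optional positive integer number of bins.
#' @return An object of class `bin_edges`: a list with `edges` (strictly
#'   increasing numeric vector of length B + 1) and `method`.
#' @seealso [bayesian_blocks_edges()], [discretize()]
#' @examples
#' uniform_width_edges(c(0, 1, 2, 3), n_bins = 2)
#' @export
uniform_width_edges <- function(values, n_bins = NULL) {
  check_finite_values(values)
  if (is.null(n_bins)) {
    n_bins <- max(1L, round_half_away(sqrt(length(values))))
  }
  n_bins <- as.integer(n_bins)
  if (length(n_bins) != 1L || is.na(n_bins) || n_bins < 1L) {
    stop("'n_bins' must be a single positive integer", call. = FALSE)
  }
  lo <- min(values)
  hi <- max(values)
  if (lo == hi) {
    # degenerate range: one bin straddling the common value
    return(new_bin_edges(c(lo - 0.5, hi + 0.5), "uniform_width"))
  }
  new_bin_edges(seq(lo, hi, length.out = n_bins + 1L), "uniform_width")
}

#' Bayesian-blocks bin edges
#'
#' Adaptive variable-width partition of a continuous vector obtained by
#' maximizing the Bayesian-blocks fitness function for point data (dynamic
#' programming over all admissible change points). Bins are not constrained to
#' equal width, so sharp features such as bimodal expression or zero inflation
#' get their own blocks while smooth regions are merged.
#'
#' The number of blocks is governed by a per-block penalty derived from the
#' false-alarm probability `p0`; the default `p0 = 0.05` is the standard
#' choice for the point-measure fitness and is an assumption of this
#' implementation (not a fitted quantity).
#'
#' @param values Numeric vector, at least 2 finite observations.
#' @param p0 False-alarm probability controlling the prior on the number of
#'   blocks.
#' @return An object of class `bin_edges`.
#' @export
bayesian_blocks_edges <- function(values, p0 = 0.05) {
  check_finite_values(values)
  if (length(values) < 2L) {
    stop("Bayesian blocks requires at least 2 observations", call. = FALSE)
  }
  n <- length(values)
  tab <- sort_unique_counts(values)
  v <- tab$values
  w <- tab$counts
  m <- length(v)
  if (m == 1L) {
    return(new_bin_edges(c(v - 0.5, v + 0.5), "bayesian_blocks"))
  }
  # cell boundaries: data extremes plus midpoints between distinct values
  cell_edges <- c(v[1L], (v[-m] + v[-1L]) / 2, v[m])
  # per-block penalty (prior on number of change points)
  ncp_prior <- 4 - log(73.53 * p0 * n^(-0.478))
  cw <- c(0, cumsum(w))

  best <- numeric(m)
  last <- integer(m)
  for (r in seq_len(m)) {
    starts <- seq_len(r)
    nk <- cw[r + 1L] - cw[starts]
    tk <- cell_edges[r + 1L] - cell_edges[starts]
    fit <- nk * (log(nk) - log(tk)) - ncp_prior
    fit <- fit + c(0, best[seq_len(r - 1L)])
    i <- which.max(fit)
    best[r] <- fit[i]
    last[r] <- i
  }
  # backtrack change points
  cps <- integer(0)
  r <- m
  while (r > 0L) {
    cps <- c(last[r], cps)
    r <- last[r] - 1L
  }
  edges <- cell_edges[c(cps, m + 1L)]
  new_bin_edges(edges, "bayesian_blocks")
}

#' Assign observations to bins
#'
#' Maps each value to the bin index `i` such that
#' `edges[i] <= v < edges[i + 1]`; the last bin is closed on the right and
#' out-of-range values clamp to the nearest end bin, so every observation gets
#' exactly one label.
#'
#' @param values Numeric vector.
#' @param edges A `bin_edges` object (or a strictly increasing numeric vector
#'   of boundaries).
#' @param gene Optional gene identifier carried along with the labels.
#' @return An object of class `discretized`: list with integer `labels` in
#'   `1..n_bins`, `n_bins`, and `gene`.
#' @export
discretize <- function(values, edges, gene = NA_character_) {
  check_finite_values(values)
  e <- if (inherits(edges, "bin_edges")) edges$edges else edges
  labels <- findInterval(values, e, rightmost.closed = TRUE, all.inside = TRUE)
  structure(
    list(labels = as.integer(labels), n_bins = length(e) - 1L,
         gene = as.character(gene)),
    class = "discretized"
  )
}

#' Discretize one gene vector with a named scheme
#'
#' Convenience wrapper fitting edges on the full marginal of `values` and
#' labelling the same vector. Each gene is discretized once from its complete
#' marginal; joint tables downstream reuse these per-gene labels (a product
#' partition), keeping the pairwise MI matrix and the triplet decompositions
#' mutually consistent.
#'
#' @inheritParams uniform_width_edges
#' @param method `"bayesian_blocks"` (default) or `"uniform_width"`.
#' @param gene Optional gene identifier.
#' @return A `discretized` object.
#' @export
discretize_gene <- function(values,
                            method = c("bayesian_blocks", "uniform_width"),
                            n_bins = NULL, gene = NA_character_) {
  method <- match.arg(method)
  edges <- if (method == "bayesian_blocks") {
    bayesian_blocks_edges(values)
  } else {
    uniform_width_edges(values, n_bins = n_bins)
  }
  discretize(values, edges, gene = gene)
}

#' Discretize every gene of an expression matrix
#'
#' @param data Numeric matrix, genes in rows (rownames are gene ids).
#' @inheritParams discretize_gene
#' @return Named list of `discretized` objects, one per gene.
#' @export
discretize_matrix <- function(data,
                              method = c("bayesian_blocks", "uniform_width"),
                              n_bins = NULL) {
  method <- match.arg(method)
  data <- as_expression_matrix(data)
  out <- lapply(rownames(data), function(g) {
    discretize_gene(data[g, ], method = method, n_bins = n_bins, gene = g)
  })
  names(out) <- rownames(data)
  out
}

new_bin_edges <- function(edges, method) {
  edges <- as.numeric(edges)
  if (any(diff(edges) <= 0)) {
    stop("bin edges must be strictly increasing", call. = FALSE)
  }
  structure(list(edges = edges, method = method), class = "bin_edges")
}

#' @export
print.bin_edges <- function(x, ...) {
  cat(sprintf("Bin edges (%s): %d bin(s)\n", x$method, length(x$edges) - 1L))
  print(x$edges)
  invisible(x)
}

#' @export
print.discretized <- function(x, ...) {
  cat(sprintf("Discretized variable%s: %d observations in %d bin(s)\n",
              if (is.na(x$gene)) "" else paste0(" '", x$gene, "'"),
              length(x$labels), x$n_bins))
  invisible(x)
}

check_finite_values <- function(values) {
  if (length(values) == 0L) stop("'values' must be non-empty", call. = FALSE)
  bad <- which(!is.finite(values))
  if (length(bad)) {
    stop(sprintf("non-finite values at indices: %s",
                 paste(utils::head(bad, 10L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

round_half_away <- function(x) {
  # round() in R rounds half to even; the binning heuristic rounds half away
  # from zero
  trunc(x + sign(x) * 0.5)
}

sort_unique_counts <- function(values) {
  s <- sort(values)
  keep <- c(TRUE, diff(s) > 0)
  idx <- cumsum(keep)
  list(values = s[keep], counts = as.numeric(tabulate(idx, max(idx))))
}
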