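#' Infer a gene regulatory network from single-cell expression data
#'
#' The main fitting function of the package. Takes a genes-by-cells
#' expression matrix, discretizes each gene, and ranks all undirected gene
#' pairs by the chosen algorithm:
#' \describe{
#'   \item{`pidc`}{partial-information-decomposition scores with per-gene
#'     network context (the recommended default): the proportional unique
#'     contribution (PUC) of each pair, passed through the two genes'
#'     empirical score distributions.}
#'   \item{`puc`}{the raw PUC score without the context step.}
#'   \item{`clr`}{mutual information z-scored against each gene's own MI
#'     background.}
#'   \item{`mi`}{the relevance network (raw mutual information).}
#'   \item{`aracne`}{mutual information with data-processing-inequality
#'     pruning of the weakest edge in each triangle.}
#' }
#'
#' @param data Numeric matrix (genes in rows, cells in columns) with unique
#'   rownames, or anything [as_expression_matrix()] accepts.
#' @param method Inference algorithm, see above.
#' @param discretizer `"bayesian_blocks"` (default, recommended) or
#'   `"uniform_width"`.
#' @param estimator Probability/entropy estimator: `"ml"` (default),
#'   `"miller_madow"` (MI-based methods only), `"dirichlet"`, `"shrinkage"`.
#' @param family Per-gene score distribution for PIDC: `"gamma"` or
#'   `"gaussian"`.
#' @param tau ARACNE DPI tolerance.
#' @param n_bins Bin-count override for uniform-width discretization.
#' @param prior_weight Dirichlet prior weight.
#' @return An object of class `grn`: list with `edges` (a `ranked_edges`
#'   data frame), `method`, `genes`, `n_cells`, `mi` (the MI matrix for the
#'   MI-based methods), `puc` (for puc/pidc), and the matched `call`.
#'   Methods: [print.grn()], [summary.grn()], [coef.grn()], [plot.grn()].
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(5 * 60), 5, dimnames = list(paste0("G", 1:5), NULL))
#' x[2, ] <- x[1, ] + rnorm(60, sd = 0.2)  # G2 tracks G1
#' fit <- infer_network(x, method = "mi", discretizer = "uniform_width")
#' head(coef(fit))
#' @export
infer_network <- function(data,
                          method = c("pidc", "puc", "clr", "mi", "aracne"),
                          discretizer = c("bayesian_blocks", "uniform_width"),
                          estimator = "ml",
                          family = c("gamma", "gaussian"),
                          tau = 0.1, n_bins = NULL, prior_weight = 1) {
  method <- match.arg(method)
  discretizer <- match.arg(discretizer)
  estimator <- match.arg(estimator, ESTIMATOR_CHOICES)
  family <- match.arg(family)
  data <- as_expression_matrix(data)

  mi <- NULL
  puc <- NULL
  if (method %in% c("mi", "clr", "aracne")) {
    mi <- mi_matrix(data, discretizer = discretizer, estimator = estimator,
                    n_bins = n_bins, prior_weight = prior_weight)
    edges <- switch(method,
                    mi = relevance_network(mi),
                    clr = clr_network(mi),
                    aracne = aracne_network(mi, tau = tau))
  } else if (method == "puc") {
    puc <- puc_matrix(data, discretizer = discretizer, estimator = estimator,
                      n_bins = n_bins, prior_weight = prior_weight)
    mi <- attr(puc, "mi")
    edges <- ranked_edges_from_scores(puc)
  } else {
    edges <- pidc_network(data, discretizer = discretizer,
                          estimator = estimator, family = family,
                          n_bins = n_bins, prior_weight = prior_weight)
    puc <- attr(edges, "puc")
    mi <- attr(puc, "mi")
  }

  structure(
    list(edges = edges, method = method, discretizer = discretizer,
         estimator = estimator, family = family, tau = tau,
         genes = rownames(data), n_cells = ncol(data), mi = mi, puc = puc,
         call = match.call()),
    class = "grn"
  )
}

#' @export
print.grn <- function(x, ...) {
  cat(sprintf("Inferred gene network (%s): %d genes, %d cells, %d ranked edges\n",
              x$method, length(x$genes), x$n_cells, nrow(x$edges)))
  cat(sprintf("  discretizer: %s; estimator: %s\n", x$discretizer,
              x$estimator))
  print(utils::head(as.data.frame(x$edges), 5))
  invisible(x)
}

#' Summary of an inferred network
#'
#' @param object A `grn` fit.
#' @param top Number of leading edges to display.
#' @param ... Unused.
#' @export
summary.grn <- function(object, top = 10L, ...) {
  s <- object$edges$score
  out <- list(method = object$method, n_genes = length(object$genes),
              n_cells = object$n_cells, n_edges = nrow(object$edges),
              score_summary = summary(s),
              top_edges = utils::head(as.data.frame(object$edges), top))
  class(out) <- "summary.grn"
  out
}

#' @export
print.summary.grn <- function(x, ...) {
  cat(sprintf("Network inference (%s): %d genes, %d cells\n", x$method,
              x$n_genes, x$n_cells))
  cat("Edge score distribution:\n")
  print(x$score_summary)
  cat("Top edges:\n")
  print(x$top_edges)
  invisible(x)
}

#' Edge scores of a fitted network
#'
#' @param object A `grn` fit.
#' @param ... Unused.
#' @return Named numeric vector of edge scores, names `"geneA|geneB"`, in
#'   rank order.
#' @export
coef.grn <- function(object, ...) {
  stats::setNames(object$edges$score,
                  paste(object$edges$gene_a, object$edges$gene_b, sep = "|"))
}

#' Plot the top edges of an inferred network
#'
#' Draws the thresholded network with igraph when available, otherwise a
#' simple circular layout in base graphics.
#'
#' @param x A `grn` fit.
#' @param percent Percentage of possible edges to draw.
#' @param ... Passed to the underlying plot call.
#' @export
plot.grn <- function(x, percent = 5, ...) {
  top <- threshold_top_percent(x$edges, percent)
  if (requireNamespace("igraph", quietly = TRUE)) {
    g <- igraph::graph_from_data_frame(top[, c("gene_a", "gene_b")],
                                       directed = FALSE,
                                       vertices = x$genes)
    igraph::plot.igraph(g, edge.width = 1 + 3 * rank(top$score) /
                          max(1, nrow(top)), ...)
  } else {
    n <- length(x$genes)
    theta <- seq(0, 2 * pi, length.out = n + 1L)[-1L]
    xs <- cos(theta); ys <- sin(theta)
    plot(xs, ys, type = "n", axes = FALSE, xlab = "", ylab = "", ...)
    ai <- match(top$gene_a, x$genes)
    bi <- match(top$gene_b, x$genes)
    segments(xs[ai], ys[ai], xs[bi], ys[bi], col = "grey50")
    text(xs * 1.08, ys * 1.08, x$genes, cex = 0.7)
  }
  invisible(x)
}
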