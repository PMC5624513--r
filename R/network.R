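#' Pairwise mutual information matrix
#'
#' Discretizes every gene of an expression matrix once (from its full
#' marginal) and computes the mutual information for every gene pair. All the
#' inference algorithms in this package start from this matrix.
#'
#' @param data Numeric expression matrix, genes in rows (rownames are gene
#'   ids), cells in columns.
#' @param discretizer `"bayesian_blocks"` (default) or `"uniform_width"`.
#' @param estimator One of `"ml"`, `"miller_madow"`, `"dirichlet"`,
#'   `"shrinkage"`.
#' @param n_bins Optional bin-count override for the uniform-width
#'   discretizer.
#' @param prior_weight Dirichlet prior weight per cell.
#' @return Symmetric non-negative matrix of MI values in bits, zero diagonal.
#' @export
mi_matrix <- function(data, discretizer = c("bayesian_blocks",
                                            "uniform_width"),
                      estimator = "ml", n_bins = NULL, prior_weight = 1) {
  discretizer <- match.arg(discretizer)
  estimator <- match.arg(estimator, ESTIMATOR_CHOICES)
  data <- as_expression_matrix(data)
  if (nrow(data) < 2L) stop("need at least 2 genes", call. = FALSE)
  reject_constant_genes(data)
  disc <- discretize_matrix(data, method = discretizer, n_bins = n_bins)
  genes <- rownames(data)
  n <- length(genes)
  m <- matrix(0, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      mi <- mutual_information(disc[[i]], disc[[j]], estimator = estimator,
                               prior_weight = prior_weight)
      m[i, j] <- m[j, i] <- max(0, mi)
    }
  }
  m
}

#' Relevance network: rank edges by raw mutual information
#'
#' @param mi Symmetric MI matrix with gene dimnames (see [mi_matrix()]).
#' @return A `ranked_edges` data frame (gene_a, gene_b, score, rank), sorted
#'   by score descending with lexicographic gene-pair tie-break.
#' @export
relevance_network <- function(mi) {
  ranked_edges_from_scores(mi)
}

#' CLR network: mutual information against each gene's own background
#'
#' Each MI value is converted to a z-score against the mean and standard
#' deviation of the MI values involving each of its two genes (self excluded,
#' negative z clipped to zero); the edge score is the Euclidean combination
#' `sqrt(z_x^2 + z_y^2)`. Genes whose MI background has zero spread contribute
#' zero.
#'
#' @inheritParams relevance_network
#' @export
clr_network <- function(mi) {
  n <- nrow(mi)
  if (n < 3L) stop("CLR requires at least 3 genes", call. = FALSE)
  z <- matrix(0, n, n, dimnames = dimnames(mi))
  for (i in seq_len(n)) {
    row <- mi[i, -i]
    mu <- mean(row)
    sdev <- stats::sd(row)
    if (is.finite(sdev) && sdev > 0) {
      z[i, -i] <- pmax(0, (row - mu) / sdev)
    }
  }
  score <- sqrt(z^2 + t(z)^2)
  ranked_edges_from_scores(score)
}

#' ARACNE network: prune indirect edges via the data processing inequality
#'
#' In every gene triangle the minimum-MI edge is marked for removal when it is
#' smaller than `(1 - tau)` times the second-smallest MI of the triangle.
#' Surviving edges are ranked by MI; removed edges are appended with score 0.
#'
#' @inheritParams relevance_network
#' @param tau DPI tolerance in `[0, 1)`; default 0.1.
#' @export
aracne_network <- function(mi, tau = 0.1) {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0 || tau >= 1) {
    stop("'tau' must be in [0, 1)", call. = FALSE)
  }
  n <- nrow(mi)
  removed <- matrix(FALSE, n, n)
  if (n >= 3L) {
    for (i in seq_len(n - 2L)) {
      for (j in (i + 1L):(n - 1L)) {
        for (k in (j + 1L):n) {
          vals <- c(mi[i, j], mi[i, k], mi[j, k])
          ord <- order(vals)
          if (vals[ord[1L]] < (1 - tau) * vals[ord[2L]]) {
            pair <- switch(ord[1L], c(i, j), c(i, k), c(j, k))
            removed[pair[1L], pair[2L]] <- TRUE
            removed[pair[2L], pair[1L]] <- TRUE
          }
        }
      }
    }
  }
  score <- mi
  score[removed] <- 0
  ranked_edges_from_scores(score)
}

#' Proportional unique contribution (PUC) matrix
#'
#' For every unordered gene pair (X, Y), sums over every third gene Z the
#' ratio of unique information to mutual information, with each of X and Y
#' treated as the target in turn:
#' `u_XY = sum_Z Unique_Z(X;Y)/I(X;Y) + sum_Z Unique_Z(Y;X)/I(X;Y)`.
#' The unique information is the pairwise MI minus the triplet redundancy, so
#' each ratio lies in `[0, 1]` and `u_XY` aggregates `2(n - 2)` terms. Pairs
#' whose MI is numerically zero contribute zero (0/0 convention).
#'
#' @inheritParams mi_matrix
#' @return Symmetric matrix of PUC scores (attribute `mi` carries the MI
#'   matrix used).
#' @export
puc_matrix <- function(data, discretizer = c("bayesian_blocks",
                                             "uniform_width"),
                       estimator = "ml", n_bins = NULL, prior_weight = 1) {
  discretizer <- match.arg(discretizer)
  estimator <- match.arg(estimator, ESTIMATOR_CHOICES)
  if (estimator == "miller_madow") {
    stop("the Miller-Madow estimator cannot be used for PUC/PIDC (no ",
         "probability table; see ?pid)", call. = FALSE)
  }
  data <- as_expression_matrix(data)
  n <- nrow(data)
  if (n < 3L) {
    stop("PUC needs at least 3 genes (there are n - 2 triplets per pair)",
         call. = FALSE)
  }
  reject_constant_genes(data)
  disc <- discretize_matrix(data, method = discretizer, n_bins = n_bins)
  genes <- rownames(data)

  if (estimator == "ml") {
    res <- puc_ml(disc, genes)
  } else {
    res <- puc_general(disc, genes, estimator, prior_weight)
  }
  res
}

# fast path: with maximum likelihood the pairwise tables equal the marginals
# of the triplet table, so redundancies only need per-pair specific
# informations
puc_ml <- function(disc, genes) {
  n <- length(genes)
  mi <- matrix(0, n, n, dimnames = list(genes, genes))
  spec <- vector("list", n)            # spec[[a]][[t]]: I_spec of target-t
  for (a in seq_len(n)) spec[[a]] <- vector("list", n)
  pz <- vector("list", n)
  u <- matrix(0, n, n, dimnames = list(genes, genes))

  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      p <- unclass(ml_probabilities(freq_table(disc[[a]], disc[[b]])))
      mi[a, b] <- mi[b, a] <- max(0, mi_from_joint(p))
      spec[[a]][[b]] <- specific_information_states(p)      # source a, target b
      spec[[b]][[a]] <- specific_information_states(t(p))   # source b, target a
    }
  }
  for (g in seq_len(n)) {
    tab <- tabulate(disc[[g]]$labels, disc[[g]]$n_bins)
    pz[[g]] <- tab / sum(tab)
  }

  for (i in seq_len(n - 2L)) {
    for (j in (i + 1L):(n - 1L)) {
      for (k in (j + 1L):n) {
        trip <- c(i, j, k)
        for (t_idx in 1:3) {
          t <- trip[t_idx]
          src <- trip[-t_idx]
          a <- src[1L]; b <- src[2L]
          keep <- pz[[t]] > 0
          red <- sum(pz[[t]][keep] *
                       pmin(spec[[a]][[t]][keep], spec[[b]][[t]][keep]))
          for (s in src) {
            m <- mi[t, s]
            if (m > 1e-12) {
              u[t, s] <- u[t, s] + max(0, m - red) / m
              u[s, t] <- u[t, s]
            }
          }
        }
      }
    }
  }
  # accumulate symmetrically: u[t, s] and u[s, t] were kept in sync above
  attr(u, "mi") <- mi
  u
}

# general path: estimate the full 3-way joint per triplet and marginalize, so
# the Eq-8 identity holds for shrinkage/Dirichlet tables too
puc_general <- function(disc, genes, estimator, prior_weight) {
  n <- length(genes)
  u <- matrix(0, n, n, dimnames = list(genes, genes))
  mi <- matrix(0, n, n, dimnames = list(genes, genes))
  cnt <- matrix(0L, n, n)
  for (i in seq_len(n - 2L)) {
    for (j in (i + 1L):(n - 1L)) {
      for (k in (j + 1L):n) {
        trip <- c(i, j, k)
        for (t_idx in 1:3) {
          t <- trip[t_idx]
          src <- trip[-t_idx]
          p3 <- unclass(estimate_probabilities(
            freq_table(disc[[src[1L]]], disc[[src[2L]]], disc[[t]]),
            estimator, prior_weight))
          res <- pid_from_joint(p3)
          add_ratio <- function(s, uni, m) {
            if (m > 1e-12) u[t, s] <<- u[t, s] + uni / m
            mi[t, s] <<- mi[s, t] <<- m
            u[s, t] <<- u[t, s]
          }
          add_ratio(src[1L], res$unique_x, res$mi_x)
          add_ratio(src[2L], res$unique_y, res$mi_y)
        }
      }
    }
  }
  attr(u, "mi") <- mi
  u
}

#' Fit a per-gene distribution to PUC scores
#'
#' Fits either a Gamma (method of moments: shape = mean^2/var, scale =
#' var/mean) or Gaussian (sample mean and sd) distribution to the PUC scores
#' involving one gene. When the Gamma moments are invalid (non-positive mean
#' or variance) the fit falls back to a Gaussian with a warning; a Gaussian
#' with zero spread degenerates to a step CDF at the common value.
#'
#' @param scores Numeric vector of at least 2 scores.
#' @param family `"gamma"` (default) or `"gaussian"`.
#' @param gene Optional gene identifier.
#' @return Object of class `gene_score_dist` with a [score_cdf()] evaluator.
#' @export
fit_gene_distribution <- function(scores, family = c("gamma", "gaussian"),
                                  gene = NA_character_) {
  family <- match.arg(family)
  if (length(scores) < 2L) {
    stop("need at least 2 scores to fit a distribution", call. = FALSE)
  }
  m <- mean(scores)
  v <- stats::var(scores)
  if (family == "gamma" && (v <= 0 || m <= 0)) {
    warning("invalid Gamma moments (mean <= 0 or var <= 0); ",
            "falling back to Gaussian", call. = FALSE)
    family <- "gaussian"
  }
  params <- if (family == "gamma") {
    c(shape = m^2 / v, scale = v / m)
  } else {
    c(mean = m, sd = sqrt(max(0, v)))
  }
  structure(list(gene = as.character(gene), family = family, params = params,
                 support = scores),
            class = "gene_score_dist")
}

#' Evaluate the fitted cumulative distribution function
#'
#' @param dist A `gene_score_dist` from [fit_gene_distribution()].
#' @param q Numeric vector of scores.
#' @return `F(q)` in `[0, 1]`.
#' @export
score_cdf <- function(dist, q) {
  p <- dist$params
  if (dist$family == "gamma") {
    stats::pgamma(q, shape = p[["shape"]], scale = p[["scale"]])
  } else if (p[["sd"]] > 0) {
    stats::pnorm(q, mean = p[["mean"]], sd = p[["sd"]])
  } else {
    as.numeric(q >= p[["mean"]])    # degenerate spread: step CDF
  }
}

#' @export
print.gene_score_dist <- function(x, ...) {
  cat(sprintf("Per-gene score distribution%s: %s(%s)\n",
              if (is.na(x$gene)) "" else paste0(" '", x$gene, "'"),
              x$family,
              paste(sprintf("%s = %.4g", names(x$params), x$params),
                    collapse = ", ")))
  invisible(x)
}

#' PIDC network: PUC plus per-gene network context
#'
#' Computes the PUC matrix, fits an empirical distribution to each gene's
#' PUC scores against all other genes, and scores each edge by the sum of the
#' two genes' cumulative distribution functions evaluated at the pair's PUC
#' score: `c = F_X(u_XY) + F_Y(u_XY)`, in `[0, 2]`. Ranking by this
#' confidence highlights the most important interactions per gene rather than
#' the globally largest raw scores.
#'
#' @inheritParams puc_matrix
#' @param family Distribution family for the per-gene CDFs: `"gamma"`
#'   (default) or `"gaussian"`.
#' @return A `ranked_edges` data frame; the PUC matrix is attached as
#'   attribute `puc`.
#' @export
pidc_network <- function(data, discretizer = c("bayesian_blocks",
                                               "uniform_width"),
                         estimator = "ml", family = c("gamma", "gaussian"),
                         n_bins = NULL, prior_weight = 1) {
  family <- match.arg(family)
  data <- as_expression_matrix(data)
  if (ncol(data) < 20L) {
    warning("fewer than 20 cells: triplet probability estimates will be poor",
            call. = FALSE)
  }
  u <- puc_matrix(data, discretizer = discretizer, estimator = estimator,
                  n_bins = n_bins, prior_weight = prior_weight)
  genes <- rownames(u)
  n <- length(genes)
  dists <- lapply(seq_len(n), function(i) {
    fit_gene_distribution(u[i, -i], family = family, gene = genes[i])
  })
  conf <- matrix(0, n, n, dimnames = dimnames(u))
  for (i in seq_len(n - 1L)) {
    fi <- score_cdf(dists[[i]], u[i, ])
    for (j in (i + 1L):n) {
      conf[i, j] <- conf[j, i] <- fi[j] + score_cdf(dists[[j]], u[i, j])
    }
  }
  out <- ranked_edges_from_scores(conf)
  attr(out, "puc") <- u
  out
}

#' Keep the top percentage of possible edges
#'
#' Retains the `ceiling(percent/100 * n(n-1)/2)` highest-ranked edges, where
#' `n` is the size of the gene universe the ranking was built over (so the
#' count refers to all possible pairs, not just the listed ones).
#'
#' @param ranked A `ranked_edges` data frame.
#' @param percent Percentage in `(0, 100]`.
#' @export
threshold_top_percent <- function(ranked, percent) {
  if (!is.numeric(percent) || length(percent) != 1L || percent <= 0 ||
      percent > 100) {
    stop("'percent' must be in (0, 100]", call. = FALSE)
  }
  genes <- attr(ranked, "genes")
  n <- length(genes)
  total <- n * (n - 1) / 2
  keep <- min(nrow(ranked), ceiling(percent / 100 * total))
  out <- ranked[seq_len(keep), , drop = FALSE]
  attr(out, "genes") <- genes
  class(out) <- class(ranked)
  out
}

# build a deterministic ranked edge list from a symmetric score matrix
ranked_edges_from_scores <- function(score) {
  genes <- rownames(score)
  if (is.null(genes)) genes <- paste0("G", seq_len(nrow(score)))
  n <- length(genes)
  idx <- which(upper.tri(score), arr.ind = TRUE)
  ga <- genes[idx[, 1L]]
  gb <- genes[idx[, 2L]]
  swap <- ga > gb
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  s <- score[idx]
  ord <- order(-s, ga, gb, method = "radix")
  out <- data.frame(gene_a = ga[ord], gene_b = gb[ord], score = s[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  structure(out, genes = sort(genes, method = "radix"),
            class = c("ranked_edges", "data.frame"))
}

#' @export
print.ranked_edges <- function(x, n = 10L, ...) {
  cat(sprintf("Ranked edge list: %d edges over %d genes\n", nrow(x),
              length(attr(x, "genes"))))
  print(utils::head(as.data.frame(x), n))
  if (nrow(x) > n) cat(sprintf("... and %d more edges\n", nrow(x) - n))
  invisible(x)
}
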