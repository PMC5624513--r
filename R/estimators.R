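#' Joint frequency table from discretized variables
#'
#' Builds a 1-3 dimensional array of joint counts over the bin labels of up to
#' three discretized variables (a product partition: each axis uses the bins
#' fitted on that gene's full marginal).
#'
#' @param ... One to three `discretized` objects (or plain integer label
#'   vectors, in which case `n_bins` must be supplied).
#' @param n_bins Optional integer vector of bin counts, one per variable, used
#'   when raw label vectors are passed.
#' @return Object of class `freq_table`: integer array with attribute
#'   `axis_genes`.
#' @export
freq_table <- function(..., n_bins = NULL) {
  vars <- list(...)
  if (length(vars) < 1L || length(vars) > 3L) {
    stop("freq_table takes between 1 and 3 variables", call. = FALSE)
  }
  labs <- vector("list", length(vars))
  bins <- integer(length(vars))
  genes <- character(length(vars))
  for (i in seq_along(vars)) {
    v <- vars[[i]]
    if (inherits(v, "discretized")) {
      labs[[i]] <- v$labels
      bins[i] <- v$n_bins
      genes[i] <- v$gene
    } else {
      labs[[i]] <- as.integer(v)
      bins[i] <- if (!is.null(n_bins)) as.integer(n_bins[i]) else max(labs[[i]])
      genes[i] <- NA_character_
    }
    if (any(labs[[i]] < 1L) || any(labs[[i]] > bins[i])) {
      stop(sprintf("labels of variable %d outside 1..%d", i, bins[i]),
           call. = FALSE)
    }
  }
  n <- unique(lengths(labs))
  if (length(n) != 1L) {
    stop("all variables must have the same number of observations",
         call. = FALSE)
  }
  if (n == 0L) stop("empty variables", call. = FALSE)
  # flatten multi-way index and tabulate
  idx <- labs[[1L]]
  mult <- bins[1L]
  if (length(labs) > 1L) {
    for (i in 2L:length(labs)) {
      idx <- idx + (labs[[i]] - 1L) * mult
      mult <- mult * bins[i]
    }
  }
  counts <- tabulate(idx, nbins = prod(bins))
  a <- array(as.integer(counts), dim = bins)
  structure(a, class = "freq_table", axis_genes = genes)
}

#' Maximum likelihood probabilities
#'
#' The empirical frequencies taken as the probability estimate:
#' `p = counts / n`.
#'
#' @param f A `freq_table` (or non-negative count array).
#' @return Numeric array of the same shape summing to 1, with attribute
#'   `estimator = "maximum_likelihood"`.
#' @export
ml_probabilities <- function(f) {
  counts <- unclass_counts(f)
  n <- sum(counts)
  if (n < 1) stop("frequency table must contain at least one observation",
                  call. = FALSE)
  prob_table(counts / n, "maximum_likelihood")
}

#' Dirichlet (pseudocount) probabilities
#'
#' Posterior mean under a symmetric Dirichlet prior with weight `prior_weight`
#' in every cell: `p_k = (counts_k + a) / (n + a * K)`.
#'
#' @inheritParams ml_probabilities
#' @param prior_weight Positive prior weight `a` per cell (default 1).
#' @export
dirichlet_probabilities <- function(f, prior_weight = 1) {
  counts <- unclass_counts(f)
  if (!is.numeric(prior_weight) || length(prior_weight) != 1L ||
      prior_weight <= 0) {
    stop("'prior_weight' must be a single positive number", call. = FALSE)
  }
  n <- sum(counts)
  if (n < 1) stop("frequency table must contain at least one observation",
                  call. = FALSE)
  k <- length(counts)
  prob_table((counts + prior_weight) / (n + prior_weight * k), "dirichlet")
}

#' James-Stein shrinkage probabilities
#'
#' Convex combination of the maximum likelihood estimate and the uniform
#' target distribution, `p = lambda / K + (1 - lambda) * theta_hat`, with the
#' closed-form optimal shrinkage intensity
#' `lambda* = (1 - sum(theta^2)) / ((n - 1) * sum((1/K - theta)^2))`
#' clipped to `[0, 1]`. For `n = 1` the intensity is undefined and is set to 1
#' (fully uniform).
#'
#' @inheritParams ml_probabilities
#' @export
shrinkage_probabilities <- function(f) {
  counts <- unclass_counts(f)
  n <- sum(counts)
  if (n < 1) stop("frequency table must contain at least one observation",
                  call. = FALSE)
  k <- length(counts)
  theta <- counts / n
  if (n == 1) {
    lambda <- 1
  } else {
    denom <- (n - 1) * sum((1 / k - theta)^2)
    lambda <- if (denom == 0) 1 else (1 - sum(theta^2)) / denom
    lambda <- min(1, max(0, lambda))
  }
  prob_table(lambda / k + (1 - lambda) * theta, "shrinkage")
}

#' Shannon entropy of a probability table (bits)
#'
#' `H = -sum(p * log2(p))` over non-zero entries. All information measures in
#' this package use base-2 logarithms (bits); the ratio-based network scores
#' are invariant to the base.
#'
#' @param p Probability array (any shape; must be non-negative and sum to 1
#'   within tolerance).
#' @return Entropy in bits.
#' @export
entropy <- function(p) {
  p <- as.numeric(p)
  if (any(p < -1e-12)) stop("probabilities must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8) {
    stop("probabilities must sum to 1", call. = FALSE)
  }
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Miller-Madow entropy estimate (bits)
#'
#' Bias-corrected plug-in entropy: the maximum likelihood entropy plus
#' `(B - 1) / (2n)` nats, where `B` is the number of occupied bins. This
#' estimator corrects the entropy directly and never produces a probability
#' table, so it can enter entropy-combination measures (MI, CMI) but not the
#' partial information decomposition.
#'
#' @inheritParams ml_probabilities
#' @export
miller_madow_entropy <- function(f) {
  counts <- unclass_counts(f)
  n <- sum(counts)
  if (n < 1) stop("frequency table must contain at least one observation",
                  call. = FALSE)
  b_hat <- sum(counts > 0)
  entropy(counts / n) + (b_hat - 1) / (2 * n) / log(2)
}

#' Estimate a probability table with a named estimator
#'
#' @inheritParams ml_probabilities
#' @param estimator One of `"ml"`, `"dirichlet"`, `"shrinkage"`.
#' @param prior_weight Dirichlet prior weight (ignored by the others).
#' @export
estimate_probabilities <- function(f, estimator = c("ml", "dirichlet",
                                                    "shrinkage"),
                                   prior_weight = 1) {
  estimator <- match.arg(estimator)
  switch(estimator,
         ml = ml_probabilities(f),
         dirichlet = dirichlet_probabilities(f, prior_weight = prior_weight),
         shrinkage = shrinkage_probabilities(f))
}

prob_table <- function(p, estimator) {
  structure(p, class = "prob_table", estimator = estimator)
}

unclass_counts <- function(f) {
  counts <- unclass(f)
  attr(counts, "axis_genes") <- NULL
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  counts
}

# entropy of an axis subset of a joint probability array (bits)
marginal_entropy <- function(p, margin = NULL) {
  p <- as.array(unclass(p))
  if (!is.null(margin) && length(dim(p)) > 1L) {
    p <- apply(p, margin, sum)
  }
  entropy(p)
}

ESTIMATOR_CHOICES <- c("ml", "miller_madow", "dirichlet", "shrinkage")
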