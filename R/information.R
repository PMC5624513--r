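#' Mutual information between two discretized variables (bits)
#'
#' `I(X;Y) = H(X) + H(Y) - H(X,Y)`: the reduction in joint entropy relative to
#' independence. Non-negative and symmetric; zero iff the estimated joint
#' factorizes. With the `"miller_madow"` estimator the three entropies are
#' bias-corrected directly from counts; with the table estimators the
#' marginals are obtained by summing the estimated joint so the measure is
#' internally consistent.
#'
#' @param x,y `discretized` objects (see [discretize()]), or integer label
#'   vectors.
#' @param estimator One of `"ml"`, `"miller_madow"`, `"dirichlet"`,
#'   `"shrinkage"`.
#' @param prior_weight Dirichlet prior weight per cell.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y, estimator = "ml", prior_weight = 1) {
  estimator <- match.arg(estimator, ESTIMATOR_CHOICES)
  x <- as_discretized(x)
  y <- as_discretized(y)
  f <- freq_table(x, y)
  if (estimator == "miller_madow") {
    counts <- unclass_counts(f)
    mi <- miller_madow_entropy(rowSums(counts)) +
      miller_madow_entropy(colSums(counts)) -
      miller_madow_entropy(counts)
    return(mi)
  }
  p <- estimate_probabilities(f, estimator, prior_weight)
  mi_from_joint(unclass(p))
}

#' Conditional mutual information I(X;Y|Z) (bits)
#'
#' `I(X;Y|Z) = H(X,Z) + H(Y,Z) - H(X,Y,Z) - H(Z)`: the information between X
#' and Y that remains once Z is known.
#'
#' @inheritParams mutual_information
#' @param z Conditioning `discretized` variable.
#' @export
conditional_mutual_information <- function(x, y, z, estimator = "ml",
                                           prior_weight = 1) {
  estimator <- match.arg(estimator, ESTIMATOR_CHOICES)
  x <- as_discretized(x); y <- as_discretized(y); z <- as_discretized(z)
  f <- freq_table(x, y, z)
  h <- entropy_fn(estimator, prior_weight)
  counts <- unclass_counts(f)
  h(apply(counts, c(1, 3), sum)) + h(apply(counts, c(2, 3), sum)) -
    h(counts) - h(apply(counts, 3, sum))
}

#' Interaction information II(X;Y;Z) (bits)
#'
#' `II = I(X;Y|Z) - I(X;Y)`, computed from a single three-way table via the
#' symmetric entropy expansion so the value is identical under any rotation of
#' the three variables. Positive values indicate synergy dominates, negative
#' values redundancy; it equals synergy minus redundancy of the partial
#' information decomposition.
#'
#' @inheritParams conditional_mutual_information
#' @export
interaction_information <- function(x, y, z, estimator = "ml",
                                    prior_weight = 1) {
  estimator <- match.arg(estimator, ESTIMATOR_CHOICES)
  x <- as_discretized(x); y <- as_discretized(y); z <- as_discretized(z)
  counts <- unclass_counts(freq_table(x, y, z))
  h <- entropy_fn(estimator, prior_weight)
  # - [H(X)+H(Y)+H(Z)] + [H(XY)+H(XZ)+H(YZ)] - H(XYZ), symmetric in X,Y,Z
  -(h(apply(counts, 1, sum)) + h(apply(counts, 2, sum)) +
      h(apply(counts, 3, sum))) +
    (h(apply(counts, c(1, 2), sum)) + h(apply(counts, c(1, 3), sum)) +
       h(apply(counts, c(2, 3), sum))) -
    h(counts)
}

#' Specific information of a source about one target state (bits)
#'
#' `I_spec(z; X) = sum_x p(x|z) * (log2(1/p(z)) - log2(1/p(z|x)))`, the
#' information the source variable X provides about the particular state `z`
#' of the target. Equals the Kullback-Leibler divergence of `p(x|z)` from
#' `p(x)`, hence non-negative; its target-weighted expectation over states is
#' the mutual information.
#'
#' @param z_state Integer bin index (state of the target).
#' @param z Target `discretized` variable.
#' @param x Source `discretized` variable.
#' @inheritParams mutual_information
#' @export
specific_information <- function(z_state, z, x, estimator = "ml",
                                 prior_weight = 1) {
  estimator <- match.arg(estimator, ESTIMATOR_CHOICES)
  if (estimator == "miller_madow") {
    stop("the Miller-Madow estimator corrects entropies only and yields no ",
         "probability table, so specific information is not defined for it",
         call. = FALSE)
  }
  z <- as_discretized(z); x <- as_discretized(x)
  p <- unclass(estimate_probabilities(freq_table(x, z), estimator,
                                      prior_weight))
  p_z <- colSums(p)
  z_state <- as.integer(z_state)
  if (z_state < 1L || z_state > length(p_z) || p_z[z_state] <= 0) {
    stop("target state has zero probability", call. = FALSE)
  }
  specific_information_states(p)[z_state]
}

# vector of I_spec(z; X) over all target states, from a joint p(x, z);
# states with p(z) = 0 get NA
specific_information_states <- function(p_xz) {
  p_z <- colSums(p_xz)
  p_x <- rowSums(p_xz)
  out <- rep(NA_real_, length(p_z))
  for (zi in which(p_z > 0)) {
    px_given_z <- p_xz[, zi] / p_z[zi]
    nz <- px_given_z > 0
    # p(z|x)/p(z) = p(x|z)/p(x)
    out[zi] <- sum(px_given_z[nz] * log2(px_given_z[nz] / p_x[nz]))
  }
  out
}

#' Partial information decomposition for a gene triplet
#'
#' Decomposes the information that two source genes `x` and `y` jointly carry
#' about a `target` gene into four non-negative parts (all in bits):
#' redundancy (available from either source alone), two unique contributions
#' (available from only one source), and synergy (available only from both
#' together). Redundancy is the target-probability-weighted minimum over
#' sources of the specific information; each unique term is the corresponding
#' pairwise MI minus the redundancy; synergy is interaction information plus
#' redundancy. The four terms sum to the joint mutual information
#' `I({X,Y}; target)`.
#'
#' "Source" and "target" carry no mechanistic meaning: they only say which
#' gene's states are being informed about, not which gene regulates which.
#'
#' All tables are derived from a single estimated three-way joint
#' distribution, so the defining identities hold to numerical precision for
#' every estimator. The Miller-Madow estimator is rejected because it
#' produces no probability table and its meaning for decompositions is
#' unclear.
#'
#' @param target Target `discretized` variable.
#' @param x,y Source `discretized` variables.
#' @inheritParams mutual_information
#' @return Object of class `pid_result` with fields `target`, `sources`,
#'   `redundancy`, `unique_x`, `unique_y`, `synergy`, and the pairwise
#'   informations `mi_x`, `mi_y`.
#' @export
pid <- function(target, x, y, estimator = "ml", prior_weight = 1) {
  estimator <- match.arg(estimator, ESTIMATOR_CHOICES)
  if (estimator == "miller_madow") {
    stop("the Miller-Madow estimator cannot be used for the partial ",
         "information decomposition: it corrects entropies without ",
         "estimating a probability distribution, and its meaning for ",
         "higher-order measures is unclear", call. = FALSE)
  }
  target <- as_discretized(target)
  x <- as_discretized(x)
  y <- as_discretized(y)
  p3 <- unclass(estimate_probabilities(freq_table(x, y, target), estimator,
                                       prior_weight))
  res <- pid_from_joint(p3)
  structure(
    c(list(target = target$gene, sources = c(x$gene, y$gene)), res),
    class = "pid_result"
  )
}

# PID terms from a joint probability array p(x, y, z) with z the target
pid_from_joint <- function(p3) {
  p_xz <- apply(p3, c(1, 3), sum)
  p_yz <- apply(p3, c(2, 3), sum)
  p_xy <- apply(p3, c(1, 2), sum)
  p_z <- apply(p3, 3, sum)

  i_xz <- mi_from_joint(p_xz)
  i_yz <- mi_from_joint(p_yz)
  i_xy <- mi_from_joint(p_xy)

  spec_x <- specific_information_states(p_xz)
  spec_y <- specific_information_states(p_yz)
  keep <- p_z > 0
  red <- sum(p_z[keep] * pmin(spec_x[keep], spec_y[keep]))

  # I(X;Y|Z) from the same joint
  cmi <- marginal_entropy(p3, c(1, 3)) + marginal_entropy(p3, c(2, 3)) -
    entropy(p3) - entropy(p_z)
  ii <- cmi - i_xy

  terms <- c(redundancy = red,
             unique_x = i_xz - red,
             unique_y = i_yz - red,
             synergy = ii + red)
  terms <- clip_pid_terms(terms)
  c(as.list(terms), list(mi_x = i_xz, mi_y = i_yz))
}

clip_pid_terms <- function(terms, tol = 1e-9) {
  bad <- terms <= -tol
  if (any(bad)) {
    stop(sprintf(
      "internal consistency error: PID term(s) %s negative beyond tolerance",
      paste(names(terms)[bad], collapse = ", ")), call. = FALSE)
  }
  pmax(terms, 0)
}

mi_from_joint <- function(p) {
  entropy(rowSums(p)) + entropy(colSums(p)) - entropy(p)
}

# entropy estimator dispatch used by the entropy-combination measures; takes
# a count array, returns bits
entropy_fn <- function(estimator, prior_weight = 1) {
  if (estimator == "miller_madow") {
    return(miller_madow_entropy)
  }
  function(counts) {
    entropy(estimate_probabilities(
      structure(as.array(counts), class = "freq_table"),
      estimator, prior_weight))
  }
}

as_discretized <- function(v) {
  if (inherits(v, "discretized")) return(v)
  v <- as.integer(v)
  structure(list(labels = v, n_bins = max(v), gene = NA_character_),
            class = "discretized")
}

#' @export
print.pid_result <- function(x, digits = 5, ...) {
  cat(sprintf("Partial information decomposition (target %s; sources %s, %s)\n",
              x$target, x$sources[1], x$sources[2]))
  vals <- c(redundancy = x$redundancy, unique_x = x$unique_x,
            unique_y = x$unique_y, synergy = x$synergy)
  print(round(vals, digits))
  invisible(x)
}
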