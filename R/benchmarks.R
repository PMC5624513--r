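#' All recorded states of an ensemble as an expression matrix
#'
#' Flattens a trajectory ensemble into a genes-by-cells matrix in which every
#' recorded (repeat, time) state is one cell, keeping mRNA species only.
#' This is the convention for the small-circuit decomposition profiles, where
#' every record of every repeat enters the estimate (e.g. 25 repeats x 41
#' times = 1025 cells).
#'
#' @param ensemble A `trajectory_ensemble`.
#' @return Expression matrix with attribute `cell_times`.
#' @export
ensemble_expression <- function(ensemble) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  mrna <- grep("^x", ensemble$species)
  reps <- dim(ensemble$states)[1]
  nt <- dim(ensemble$states)[2]
  cells <- matrix(0, length(mrna), reps * nt)
  cell_times <- numeric(reps * nt)
  col <- 0L
  for (r in seq_len(reps)) {
    for (k in seq_len(nt)) {
      col <- col + 1L
      cells[, col] <- ensemble$states[r, k, mrna]
      cell_times[col] <- ensemble$times[k]
    }
  }
  dimnames(cells) <- list(paste0("G", seq_along(mrna)),
                          paste0("cell", seq_len(ncol(cells))))
  attr(cells, "cell_times") <- cell_times
  cells
}

#' Triplet decomposition profile of a stimulated one-edge circuit
#'
#' Simulates the thermodynamic three-gene circuit with a single activating
#' edge G1 -> G2 and the stimulating ligand targeting G1, then decomposes the
#' information for each gene treated as the target in turn (12 values:
#' redundancy, two unique terms and synergy per target). Returns the summary
#' used to inspect the connected-pair signature: the mean unique information
#' between the connected pair, between unconnected pairs, and the mean
#' redundancy and synergy.
#'
#' @param seed RNG seed.
#' @param repeats Trajectories per stimulus configuration.
#' @param discretizer,estimator Passed to the information measures.
#' @param stimulus If `FALSE`, the stimulus is disabled (the circuit relaxes
#'   to steady state and the signature should fade).
#' @param burn_in Time added before recording starts when the stimulus is
#'   disabled (steady-state control).
#' @return Named numeric vector with `unique_connected`,
#'   `unique_unconnected`, `redundancy`, `synergy`.
#' @export
one_edge_pid_profile <- function(seed = NULL, repeats = 25L,
                                 discretizer = "bayesian_blocks",
                                 estimator = "ml", stimulus = TRUE,
                                 burn_in = 0) {
  top <- circuit_topology(3, data.frame(regulator = 1, target = 2, sign = 1),
                          stimulus_target = if (stimulus) 1L else NA)
  pars <- thermo_params(t_end = 1000 + burn_in,
                        n_records = 41L + as.integer(round(burn_in / 25)),
                        stimulus_time = 500 + burn_in)
  ens <- simulate_thermo(top, pars, repeats = repeats, seed = seed)
  if (burn_in > 0) {
    keep <- ens$times >= burn_in
    ens$states <- ens$states[, keep, , drop = FALSE]
    ens$times <- ens$times[keep]
  }
  cells <- ensemble_expression(ens)
  disc <- discretize_matrix(cells, method = discretizer)
  res <- list()
  for (t in 1:3) {
    src <- setdiff(1:3, t)
    res[[t]] <- pid(disc[[t]], disc[[src[1]]], disc[[src[2]]],
                    estimator = estimator)
  }
  # unique terms between the connected pair (G1, G2): target G1's unique from
  # G2 and target G2's unique from G1; the rest involve the unconnected G3
  uniq <- function(target, source) {
    r <- res[[target]]
    src <- setdiff(1:3, target)
    if (src[1] == source) r$unique_x else r$unique_y
  }
  c(unique_connected = mean(c(uniq(1, 2), uniq(2, 1))),
    unique_unconnected = mean(c(uniq(1, 3), uniq(2, 3), uniq(3, 1),
                                uniq(3, 2))),
    redundancy = mean(vapply(res, `[[`, numeric(1), "redundancy")),
    synergy = mean(vapply(res, `[[`, numeric(1), "synergy")))
}

#' Inference benchmark on a random in-silico circuit
#'
#' One end-to-end benchmark replicate: draw a random signed DAG, simulate
#' single-cell data from the mass-action model over a 21-point grid on
#' `[0, 1000]` (stimulus on gene 1 from time 500), sample cells with the
#' requested scheme, optionally inject dropouts, infer networks with the
#' requested algorithms and score each against the true circuit by AUPR.
#'
#' @param seed RNG seed (drives topology, simulation and sampling).
#' @param n_genes,mean_degree,sign_prob Passed to [random_dag()].
#' @param repeats Trajectories simulated (must cover the scheme).
#' @param scheme Cell sampling scheme for [sample_cells()].
#' @param methods Algorithms to score.
#' @param dropout_quantile If non-`NULL`, also score data after
#'   [add_dropouts()] at this quantile (probability 0.5).
#' @param discretizer,estimator Passed to [infer_network()].
#' @return List with `aupr` (named vector), `aupr_dropout` (or `NULL`),
#'   `n_edges` and `n_cells`.
#' @export
dag_benchmark <- function(seed, n_genes = 10L, mean_degree = 2,
                          sign_prob = 0.5, repeats = 100L, scheme = "medium",
                          methods = c("pidc", "puc", "mi"),
                          dropout_quantile = NULL,
                          discretizer = "bayesian_blocks",
                          estimator = "ml") {
  set.seed(seed)
  topo <- random_dag(n_genes, mean_degree = mean_degree,
                     sign_prob = sign_prob)
  if (nrow(topo$edges) == 0L) {   # a usable benchmark needs positives
    topo <- circuit_topology(
      n_genes, data.frame(regulator = 1, target = 2, sign = 1))
  }
  topo$stimulus_target <- 1L
  pars <- mass_action_params(t_end = 1000, stimulus_time = 500,
                             n_records = 21L)
  ens <- simulate_mass_action(topo, pars, repeats = repeats)
  cells <- sample_cells(ens, scheme)
  gold <- as_gold_standard(topo)
  score <- function(dat) {
    vapply(methods, function(m) {
      fit <- infer_network(dat, method = m, discretizer = discretizer,
                           estimator = estimator)
      pr_and_roc(fit$edges, gold)$aupr
    }, numeric(1))
  }
  out <- list(aupr = score(cells), aupr_dropout = NULL,
              n_edges = nrow(topo$edges), n_cells = ncol(cells))
  if (!is.null(dropout_quantile)) {
    out$aupr_dropout <- score(add_dropouts(cells, quantile = dropout_quantile,
                                           drop_prob = 0.5))
  }
  out
}
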