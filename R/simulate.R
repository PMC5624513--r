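#' Define a small signed gene circuit
#'
#' A directed, signed regulatory topology used by the stochastic simulators
#' and as a gold standard for evaluation. Self-regulation and duplicate
#' ordered pairs are rejected.
#'
#' @param n_genes Number of genes (at least 2).
#' @param edges Data frame or matrix with columns regulator, target, sign
#'   (+1 activating, -1 inhibiting); may have zero rows.
#' @param stimulus_target Index of the gene targeted by the stimulating
#'   ligand, or `NA` for none.
#' @return Object of class `circuit_topology`.
#' @export
circuit_topology <- function(n_genes, edges = NULL, stimulus_target = NA) {
  n_genes <- as.integer(n_genes)
  if (n_genes < 2L) stop("need at least 2 genes", call. = FALSE)
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- data.frame(regulator = integer(0), target = integer(0),
                        sign = integer(0))
  } else {
    edges <- as.data.frame(edges)
    colnames(edges) <- c("regulator", "target", "sign")
    edges$regulator <- as.integer(edges$regulator)
    edges$target <- as.integer(edges$target)
    edges$sign <- as.integer(edges$sign)
    if (any(edges$regulator < 1L | edges$regulator > n_genes) ||
        any(edges$target < 1L | edges$target > n_genes)) {
      stop("edge endpoints outside 1..n_genes", call. = FALSE)
    }
    if (any(edges$regulator == edges$target)) {
      stop("self-regulation is not allowed", call. = FALSE)
    }
    if (anyDuplicated(edges[, c("regulator", "target")])) {
      stop("at most one edge per ordered gene pair", call. = FALSE)
    }
    if (!all(edges$sign %in% c(-1L, 1L))) {
      stop("edge sign must be +1 (activate) or -1 (inhibit)", call. = FALSE)
    }
  }
  if (!is.na(stimulus_target)) {
    stimulus_target <- as.integer(stimulus_target)
    if (stimulus_target < 1L || stimulus_target > n_genes) {
      stop("'stimulus_target' outside 1..n_genes", call. = FALSE)
    }
  }
  structure(list(n_genes = n_genes, edges = edges,
                 stimulus_target = stimulus_target),
            class = "circuit_topology")
}

#' @export
print.circuit_topology <- function(x, ...) {
  cat(sprintf("Circuit: %d genes, %d signed edges, stimulus target: %s\n",
              x$n_genes, nrow(x$edges),
              if (is.na(x$stimulus_target)) "none" else x$stimulus_target))
  if (nrow(x$edges)) print(x$edges)
  invisible(x)
}

#' Parameters of the thermodynamic gene-circuit model
#'
#' Defaults are the standard operating point of the model: decay
#' `lambda = 0.02` per unit time for both mRNA and protein, maximal
#' transcription scale `alpha_transcription = 2` and translation scale
#' `alpha_translation = 2` molecules per unit time, dissociation constant
#' `k_half = 50` molecules for every regulator, relative transcription rates
#' 0.1 (unbound), 0.001 (any inhibitor bound; inhibition dominates) and 5
#' (only activators bound), with the stimulating ligand clamped at 20
#' molecules from time 500 of a 1000-time-unit course recorded at 41 equally
#' spaced points.
#'
#' @param lambda Decay rate (1/time) shared by mRNA and protein.
#' @param alpha_transcription Transcription rate scale (molecules/time).
#' @param alpha_translation Maximal translation rate (molecules/time).
#' @param k_half Dissociation constant (molecules), recycled per gene.
#' @param alpha_unbound,alpha_inhibited,alpha_activated Relative rates by
#'   bound-state class.
#' @param stimulus_level Clamped stimulus copy number after onset.
#' @param stimulus_time Stimulus onset time.
#' @param t_end Simulation end time.
#' @param n_records Number of equally spaced recording times in `[0, t_end]`.
#' @export
thermo_params <- function(lambda = 0.02, alpha_transcription = 2,
                          alpha_translation = 2, k_half = 50,
                          alpha_unbound = 0.1, alpha_inhibited = 0.001,
                          alpha_activated = 5, stimulus_level = 20,
                          stimulus_time = 500, t_end = 1000,
                          n_records = 41L) {
  p <- list(lambda = lambda, alpha_transcription = alpha_transcription,
            alpha_translation = alpha_translation, k_half = k_half,
            alpha_unbound = alpha_unbound,
            alpha_inhibited = alpha_inhibited,
            alpha_activated = alpha_activated,
            stimulus_level = stimulus_level, stimulus_time = stimulus_time,
            t_end = t_end, n_records = as.integer(n_records))
  rates <- c(p$lambda, p$alpha_transcription, p$alpha_translation, p$k_half,
             p$alpha_unbound, p$alpha_inhibited, p$alpha_activated)
  if (any(rates <= 0)) stop("all rates must be positive", call. = FALSE)
  if (!(p$alpha_inhibited <= p$alpha_unbound &&
        p$alpha_unbound <= p$alpha_activated)) {
    stop("need alpha_inhibited <= alpha_unbound <= alpha_activated",
         call. = FALSE)
  }
  structure(p, class = "thermo_params")
}

#' Parameters of the mass-action gene-circuit model
#'
#' Defaults: basal transcription `k_txn = 1`, decay `k_decay = 0.05`,
#' protein-gene binding `k_on = 0.01`, unbinding `k_off = 0.25`, regulated
#' transcription 10 (activating) or 0.1 (inhibiting), two copies of each
#' gene, stimulus clamped at 20 molecules from time 200 of a 400-time-unit
#' course recorded at 21 equally spaced points. Translation is instantaneous
#' (mRNA and protein are one species) and a gene binds at most one regulator
#' at a time.
#'
#' @param k_txn Basal transcription rate (1/time, per free gene copy).
#' @param k_decay Decay rate (1/time).
#' @param k_on Binding rate (1/(molecules x time)).
#' @param k_off Unbinding rate (1/time).
#' @param k_regulated_act,k_regulated_inh Transcription rate from a bound
#'   complex for activating / inhibiting regulators (1/time).
#' @param gene_copies Copies of each gene.
#' @param literal_basal If `TRUE`, use the basal transcription propensity
#'   `k_txn * x_i` (proportional to the transcript itself) instead of the
#'   gene-templated `k_txn * g_i`. The gene-templated form is the default:
#'   it is the reading consistent with a transcription reaction and gives
#'   the expected stationary mean `k_txn * copies / k_decay`.
#' @inheritParams thermo_params
#' @export
mass_action_params <- function(k_txn = 1, k_decay = 0.05, k_on = 0.01,
                               k_off = 0.25, k_regulated_act = 10,
                               k_regulated_inh = 0.1, gene_copies = 2L,
                               stimulus_level = 20, stimulus_time = 200,
                               t_end = 400, n_records = 21L,
                               literal_basal = FALSE) {
  p <- list(k_txn = k_txn, k_decay = k_decay, k_on = k_on, k_off = k_off,
            k_regulated_act = k_regulated_act,
            k_regulated_inh = k_regulated_inh,
            gene_copies = as.integer(gene_copies),
            stimulus_level = stimulus_level, stimulus_time = stimulus_time,
            t_end = t_end, n_records = as.integer(n_records),
            literal_basal = isTRUE(literal_basal))
  if (any(c(p$k_txn, p$k_decay, p$k_on, p$k_off, p$k_regulated_act,
            p$k_regulated_inh) <= 0)) {
    stop("all rates must be positive", call. = FALSE)
  }
  structure(p, class = "mass_action_params")
}

#' Thermodynamic transcription propensity of one gene
#'
#' Mean-activation transcription rate given the current regulator protein
#' levels: states with zero, one or two bound regulators are weighted by the
#' product of occupancies `chi = level / k`, and the relative rate of a state
#' is `alpha_unbound` (empty), `alpha_inhibited` (any inhibitor bound;
#' inhibition dominates) or `alpha_activated` (activators only). An
#' unregulated gene transcribes at
#' `alpha_transcription * alpha_unbound`.
#'
#' @param gene Index of the target gene in `topology`.
#' @param protein_levels Numeric vector of current protein copy numbers.
#' @param stimulus Current stimulus level (used when the gene is the
#'   stimulus target).
#' @param topology A [circuit_topology()].
#' @param params A [thermo_params()] list.
#' @return Propensity (molecules/time).
#' @export
thermo_transcription_rate <- function(gene, protein_levels, stimulus = 0,
                                      topology, params = thermo_params()) {
  if (any(protein_levels < 0)) stop("protein levels must be >= 0",
                                    call. = FALSE)
  inc <- topology$edges[topology$edges$target == gene, , drop = FALSE]
  lev <- protein_levels[inc$regulator]
  act <- inc$sign > 0
  kk <- rep_len(params$k_half, topology$n_genes)[inc$regulator]
  if (!is.na(topology$stimulus_target) && topology$stimulus_target == gene) {
    lev <- c(lev, stimulus)
    act <- c(act, TRUE)
    kk <- c(kk, rep_len(params$k_half, 1L))
  }
  thermo_rate_cpp(as.numeric(lev), as.logical(act), as.numeric(kk),
                  params$alpha_transcription, params$alpha_unbound,
                  params$alpha_activated, params$alpha_inhibited)
}

#' Exact stochastic simulation of a user-defined reaction system
#'
#' Direct-method Gillespie sampler for a continuous-time Markov jump process:
#' `propensities(state, t)` returns the per-reaction rates and `transitions`
#' gives the state change of each reaction (reactions in rows, species in
#' columns). The state at each requested record time is the state after the
#' last event preceding that time.
#'
#' @param propensities Function `(state, t) -> numeric vector` of
#'   non-negative rates.
#' @param transitions Integer matrix, reactions x species.
#' @param state0 Initial state (integer copy numbers).
#' @param t_end End time.
#' @param record_times Increasing times in `[0, t_end]` at which to record.
#' @param seed Optional RNG seed.
#' @return Matrix of recorded states (times in rows), attribute `times`.
#' @export
gillespie <- function(propensities, transitions, state0, t_end,
                      record_times, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  transitions <- as.matrix(transitions)
  state <- as.numeric(state0)
  nr <- length(record_times)
  out <- matrix(NA_real_, nr, length(state))
  t <- 0
  rec_i <- 1L
  repeat {
    a <- propensities(state, t)
    if (any(a < 0)) {
      stop(sprintf("negative propensity at t = %.4g; state: %s", t,
                   paste(state, collapse = ", ")), call. = FALSE)
    }
    total <- sum(a)
    t_next <- if (total > 0) t + stats::rexp(1L, total) else Inf
    while (rec_i <= nr && record_times[rec_i] < t_next) {
      if (record_times[rec_i] > t_end) break
      out[rec_i, ] <- state
      rec_i <- rec_i + 1L
    }
    if (t_next > t_end) {
      while (rec_i <= nr) {
        out[rec_i, ] <- state
        rec_i <- rec_i + 1L
      }
      break
    }
    j <- sample.int(length(a), 1L, prob = a)
    state <- state + transitions[j, ]
    t <- t_next
  }
  attr(out, "times") <- record_times
  out
}

#' Simulate an ensemble from the thermodynamic model
#'
#' Runs `repeats` exact stochastic trajectories of the thermodynamic circuit
#' model (species: mRNA `x_i`, protein `y_i` per gene, plus the clamped
#' stimulating ligand `s`), each from independently sampled initial
#' conditions (`x_i, y_i ~ U(0, 5)` rounded to integers by default), and
#' records each at the parameterized time grid. Genes may have at most two
#' protein regulators (plus stimulus eligibility); at most two regulators
#' bind simultaneously.
#'
#' @param topology A [circuit_topology()].
#' @param params A [thermo_params()].
#' @param repeats Number of trajectories.
#' @param init_sampler Optional function `(n_genes) -> list(x =, y =)` of
#'   integer initial copy numbers.
#' @param seed Optional RNG seed.
#' @return Object of class `trajectory_ensemble`: list with `species`,
#'   `states` (repeats x times x species integer array), `times`, `model`,
#'   `seed`.
#' @export
simulate_thermo <- function(topology, params = thermo_params(), repeats = 25L,
                            init_sampler = NULL, seed = NULL) {
  stopifnot(inherits(topology, "circuit_topology"))
  n <- topology$n_genes
  indeg <- tabulate(topology$edges$target, n)
  if (any(indeg > 2L)) {
    stop("thermodynamic model allows at most 2 protein regulators per gene",
         call. = FALSE)
  }
  if (repeats < 1L) stop("'repeats' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init_sampler)) {
    init_sampler <- function(n) list(x = round(stats::runif(n, 0, 5)),
                                     y = round(stats::runif(n, 0, 5)))
  }
  times <- seq(0, params$t_end, length.out = params$n_records)
  k <- rep_len(params$k_half, n)
  edges <- cbind(topology$edges$regulator - 1L, topology$edges$target - 1L,
                 as.integer(topology$edges$sign > 0))
  if (nrow(topology$edges) == 0L) edges <- matrix(0L, 0, 3)
  stim <- if (is.na(topology$stimulus_target)) -1L else
    topology$stimulus_target - 1L
  stim_time <- if (is.na(topology$stimulus_target)) Inf else
    params$stimulus_time

  species <- c(paste0("x", seq_len(n)), paste0("y", seq_len(n)), "s")
  states <- array(0L, dim = c(repeats, length(times), length(species)),
                  dimnames = list(NULL, NULL, species))
  for (r in seq_len(repeats)) {
    init <- init_sampler(n)
    states[r, , ] <- ssa_thermo_cpp(
      n, edges, as.integer(init$x), as.integer(init$y), params$lambda,
      params$alpha_transcription, params$alpha_translation, k,
      params$alpha_unbound, params$alpha_activated, params$alpha_inhibited,
      stim, stim_time, params$stimulus_level, rep_len(params$k_half, 1L),
      times, params$t_end)
  }
  new_trajectory_ensemble(species, states, times, "thermo", seed)
}

#' Simulate an ensemble from the mass-action model
#'
#' Runs `repeats` exact stochastic trajectories of the mass-action circuit
#' model (species: combined mRNA/protein `x_i`, free gene copies, one bound
#' complex per regulatory edge, plus the clamped stimulus). Initial state:
#' all gene copies free, `x_i ~ U(0, 50)` rounded to integers by default.
#' The reaction scheme is local to (regulator, target) pairs, so the model
#' extends to any number of genes unchanged.
#'
#' @inheritParams simulate_thermo
#' @param params A [mass_action_params()].
#' @export
simulate_mass_action <- function(topology, params = mass_action_params(),
                                 repeats = 50L, init_sampler = NULL,
                                 seed = NULL) {
  stopifnot(inherits(topology, "circuit_topology"))
  n <- topology$n_genes
  if (repeats < 1L) stop("'repeats' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init_sampler)) {
    init_sampler <- function(n) list(x = round(stats::runif(n, 0, 50)))
  }
  times <- seq(0, params$t_end, length.out = params$n_records)
  edges <- cbind(topology$edges$regulator - 1L, topology$edges$target - 1L,
                 as.integer(topology$edges$sign > 0))
  if (nrow(topology$edges) == 0L) edges <- matrix(0L, 0, 3)
  stim_time <- Inf
  if (!is.na(topology$stimulus_target)) {
    edges <- rbind(edges, c(-1L, topology$stimulus_target - 1L, 1L))
    stim_time <- params$stimulus_time
  }
  species <- c(paste0("x", seq_len(n)),
               if (nrow(edges)) paste0("b", seq_len(nrow(edges))), "s")
  states <- array(0L, dim = c(repeats, length(times), length(species)),
                  dimnames = list(NULL, NULL, species))
  for (r in seq_len(repeats)) {
    init <- init_sampler(n)
    states[r, , ] <- ssa_mass_action_cpp(
      n, edges, as.integer(init$x), params$gene_copies, params$k_txn,
      params$k_decay, params$k_on, params$k_off, params$k_regulated_act,
      params$k_regulated_inh, -1L, stim_time, params$stimulus_level,
      times, params$t_end, params$literal_basal)
  }
  ens <- new_trajectory_ensemble(species, states, times, "mass_action", seed)
  ens$edge_index <- if (nrow(edges)) {
    data.frame(regulator = edges[, 1] + 1L, target = edges[, 2] + 1L,
               activating = edges[, 3] == 1L)
  } else {
    NULL
  }
  ens$gene_copies <- params$gene_copies
  ens
}

new_trajectory_ensemble <- function(species, states, times, model, seed) {
  structure(list(species = species, states = states, times = times,
                 model = model, seed = seed),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf(
    "Trajectory ensemble (%s model): %d repeats x %d times x %d species\n",
    x$model, dim(x$states)[1], dim(x$states)[2], dim(x$states)[3]))
  invisible(x)
}

#' Sample single cells from a trajectory ensemble
#'
#' Emulates a single-cell snapshot experiment: at each scheme time, a fixed
#' number of cells is drawn (without replacement across repeats within that
#' time) and the mRNA copy numbers of the sampled trajectories become the
#' cells' expression values. Schemes (on a 21-point grid over `[0, 1000]`,
#' step 50):
#' \describe{
#'   \item{large}{100 cells at every grid time (2100 cells).}
#'   \item{medium}{100 cells at times 0, 150, ..., 900 (700 cells).}
#'   \item{small}{20 cells at every grid time in `[0, 300]` (140 cells).}
#' }
#' A custom scheme is given via `times` and `per_time`.
#'
#' @param ensemble A `trajectory_ensemble`.
#' @param scheme `"small"`, `"medium"` or `"large"`; ignored when `times` is
#'   supplied.
#' @param times Optional custom sampling times (must lie on the ensemble
#'   grid).
#' @param per_time Cells per sampling time for a custom scheme.
#' @param seed Optional RNG seed.
#' @return Expression matrix (genes x cells) of mRNA counts, with attribute
#'   `cell_times`.
#' @export
sample_cells <- function(ensemble, scheme = c("medium", "small", "large"),
                         times = NULL, per_time = NULL, seed = NULL) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  grid <- ensemble$times
  if (is.null(times)) {
    scheme <- match.arg(scheme)
    times <- switch(scheme,
                    large = grid,
                    medium = seq(0, 900, by = 150),
                    small = grid[grid <= 300 + 1e-9])
    per_time <- switch(scheme, large = 100L, medium = 100L, small = 20L)
  } else if (is.null(per_time)) {
    stop("'per_time' must be given with custom 'times'", call. = FALSE)
  }
  ti <- match(round(times, 9), round(grid, 9))
  if (anyNA(ti)) {
    stop(sprintf("sampling times not on the ensemble grid: %s",
                 paste(times[is.na(ti)], collapse = ", ")), call. = FALSE)
  }
  repeats <- dim(ensemble$states)[1]
  if (repeats < per_time) {
    stop(sprintf("scheme needs %d repeats per time point, ensemble has %d",
                 per_time, repeats), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  mrna <- grep("^x", ensemble$species)
  genes <- paste0("G", seq_along(mrna))
  cells <- matrix(0, length(mrna), length(ti) * per_time)
  cell_times <- numeric(ncol(cells))
  col <- 0L
  for (k in seq_along(ti)) {
    reps <- sample.int(repeats, per_time)
    for (r in reps) {
      col <- col + 1L
      cells[, col] <- ensemble$states[r, ti[k], mrna]
      cell_times[col] <- grid[ti[k]]
    }
  }
  dimnames(cells) <- list(genes, paste0("cell", seq_len(ncol(cells))))
  attr(cells, "cell_times") <- cell_times
  cells
}

#' Inject dropout events into an expression matrix
#'
#' Models technical zeros of single-cell assays: per gene, values strictly
#' below the gene's empirical `quantile` each become 0 independently with
#' probability `drop_prob`. The conventional high rate is `quantile = 0.5`,
#' the low rate `quantile = 0.2`, both with `drop_prob = 0.5`.
#'
#' @param data Expression matrix, genes in rows.
#' @param quantile Per-gene quantile defining "low" expression, in `(0, 1]`.
#' @param drop_prob Probability that a low value is recorded as 0.
#' @param seed Optional RNG seed.
#' @export
add_dropouts <- function(data, quantile = 0.5, drop_prob = 0.5, seed = NULL) {
  if (quantile <= 0 || quantile > 1) stop("'quantile' must be in (0, 1]",
                                          call. = FALSE)
  if (drop_prob < 0 || drop_prob > 1) stop("'drop_prob' must be in [0, 1]",
                                           call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  data <- as_expression_matrix(data)
  out <- data
  for (i in seq_len(nrow(data))) {
    thr <- stats::quantile(data[i, ], probs = quantile, names = FALSE)
    low <- which(data[i, ] < thr)
    if (length(low)) {
      hit <- low[stats::runif(length(low)) < drop_prob]
      out[i, hit] <- 0
    }
  }
  out
}

#' Random acyclic signed circuit
#'
#' Generates a signed DAG with no self-loops, at most one edge per ordered
#' pair and no feedback loops: genes get a random topological order and each
#' forward pair carries an edge independently with probability
#' `mean_degree / (n - 1)` (expected total `n * mean_degree / 2` edges).
#'
#' @param n_genes Number of genes.
#' @param mean_degree Expected (undirected) degree per gene.
#' @param sign_prob Probability that an edge is activating.
#' @param seed Optional RNG seed.
#' @return A [circuit_topology()].
#' @export
random_dag <- function(n_genes, mean_degree = 2, sign_prob = 0.5,
                       seed = NULL) {
  if (n_genes < 2L) stop("need at least 2 genes", call. = FALSE)
  if (mean_degree < 0) stop("'mean_degree' must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ord <- sample.int(n_genes)
  p <- min(1, mean_degree / (n_genes - 1))
  reg <- integer(0); tgt <- integer(0)
  for (i in seq_len(n_genes - 1L)) {
    for (j in (i + 1L):n_genes) {
      if (stats::runif(1) < p) {
        reg <- c(reg, ord[i]); tgt <- c(tgt, ord[j])
      }
    }
  }
  sgn <- ifelse(stats::runif(length(reg)) < sign_prob, 1L, -1L)
  circuit_topology(n_genes,
                   data.frame(regulator = reg, target = tgt, sign = sgn))
}
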