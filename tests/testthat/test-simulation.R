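one_edge_topology <- function(stim = 1L) {
  circuit_topology(3, data.frame(regulator = 1, target = 2, sign = 1),
                   stimulus_target = stim)
}

test_that("generic gillespie: birth-death process hits its stationary mean", {
  beta <- 10; delta <- 0.5   # stationary mean beta/delta = 20, var = 20
  out <- gillespie(
    propensities = function(state, t) c(beta, delta * state[1]),
    transitions = matrix(c(1, -1), 2, 1),
    state0 = 0, t_end = 2000, record_times = seq(100, 2000, by = 2),
    seed = 30)
  m <- mean(out[, 1])
  se <- sd(out[, 1]) / sqrt(200)  # generous effective sample size
  expect_lt(abs(m - 20), 3 * max(se, 0.5))
  # all-zero rates freeze the state
  frozen <- gillespie(function(s, t) c(0), matrix(1, 1, 1), 7, 10, c(0, 5, 10))
  expect_equal(as.numeric(frozen), c(7, 7, 7))
  expect_error(gillespie(function(s, t) c(-1), matrix(1, 1, 1), 0, 1, 1),
               "negative propensity")
})

test_that("seeded runs are exactly reproducible", {
  top <- one_edge_topology()
  e1 <- simulate_thermo(top, repeats = 3, seed = 5)
  e2 <- simulate_thermo(top, repeats = 3, seed = 5)
  expect_identical(e1$states, e2$states)
  m1 <- simulate_mass_action(top, repeats = 3, seed = 5)
  m2 <- simulate_mass_action(top, repeats = 3, seed = 5)
  expect_identical(m1$states, m2$states)
  c1 <- sample_cells(m1, times = c(0, 200, 400), per_time = 3, seed = 9)
  c2 <- sample_cells(m2, times = c(0, 200, 400), per_time = 3, seed = 9)
  expect_identical(c1, c2)
})

test_that("thermodynamic protocol: record counts and stimulus clamping", {
  top <- one_edge_topology()
  ens <- simulate_thermo(top, repeats = 25, seed = 6)
  expect_equal(dim(ens$states)[1] * dim(ens$states)[2], 1025L)
  expect_equal(length(ens$times), 41L)
  expect_equal(range(ens$times), c(0, 1000))
  s <- ens$states[, , "s"]
  expect_true(all(s[, ens$times < 500] == 0))
  expect_true(all(s[, ens$times >= 500] == 20))
  expect_true(all(ens$states >= 0))
})

test_that("thermodynamic transcription rates match the printed operating points", {
  top <- one_edge_topology(stim = NA)
  p <- thermo_params()
  # unregulated gene: alpha_transcription * alpha_unbound = 0.2
  expect_equal(thermo_transcription_rate(3, c(0, 0, 0), 0, top, p), 0.2)
  # one activator at its dissociation constant: 2 * (0.1 + 5)/2 = 5.1
  expect_equal(thermo_transcription_rate(2, c(50, 0, 0), 0, top, p), 5.1)
  # bound inhibitors shrink the rate monotonically
  topi <- circuit_topology(3, data.frame(regulator = 1, target = 2, sign = -1))
  rates <- sapply(c(0, 50, 500), function(y)
    thermo_transcription_rate(2, c(y, 0, 0), 0, topi, p))
  expect_true(all(diff(rates) < 0))
  expect_equal(rates[1], 0.2)
})

test_that("mass-action protocol: counts, conservation, stationary mean", {
  top <- one_edge_topology()
  ens <- simulate_mass_action(top, repeats = 50, seed = 7)
  expect_equal(dim(ens$states)[1] * dim(ens$states)[2], 1050L)
  expect_equal(length(ens$times), 21L)
  expect_equal(range(ens$times), c(0, 400))
  # gene copy conservation for the regulated gene 2 (bound by protein 1)
  b <- ens$states[, , "b1"]
  expect_true(all(b >= 0 & b <= 2))
  # unregulated gene 3: stationary mean k_txn * copies / k_decay = 40
  x3 <- ens$states[, 21, "x3"]
  expect_lt(abs(mean(x3) - 40), 3 * sd(x3) / sqrt(length(x3)) + 1)
  s <- ens$states[, , "s"]
  expect_true(all(s[, ens$times < 200] == 0))
  expect_true(all(s[, ens$times >= 200] == 20))
})

test_that("three-target stimulus sweep yields 75 thermodynamic simulations", {
  total <- 0L
  for (target in 1:3) {
    top <- one_edge_topology(stim = target)
    ens <- simulate_thermo(top, repeats = 25, seed = 100 + target)
    total <- total + dim(ens$states)[1]
    expect_equal(dim(ens$states)[2], 41L)
  }
  expect_equal(total, 75L)
})

test_that("cell sampling schemes produce the documented cell counts", {
  top <- one_edge_topology()
  pars <- mass_action_params(t_end = 1000, stimulus_time = 500,
                             n_records = 21L)
  ens <- simulate_mass_action(top, pars, repeats = 100, seed = 8)
  expect_equal(ncol(sample_cells(ens, "small", seed = 1)), 140L)
  expect_equal(ncol(sample_cells(ens, "medium", seed = 1)), 700L)
  expect_equal(ncol(sample_cells(ens, "large", seed = 1)), 2100L)
  cells <- sample_cells(ens, "medium", seed = 1)
  expect_equal(nrow(cells), 3L)          # mRNA species only
  expect_equal(sort(unique(attr(cells, "cell_times"))), seq(0, 900, 150))
  small <- simulate_mass_action(top, pars, repeats = 10, seed = 8)
  expect_error(sample_cells(small, "medium"), "repeats")
  expect_error(sample_cells(ens, times = 123, per_time = 5), "grid")
})

test_that("dropout injection follows the quantile/probability contract", {
  m <- matrix(rep(1:10, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("G1", "G2"), paste0("c", 1:10)))
  # deterministic limit: the 2 values below the 20% quantile become zero
  d <- add_dropouts(m, quantile = 0.2, drop_prob = 1, seed = 1)
  expect_equal(sum(d == 0), 2L * 2L)
  expect_equal(d[, 3:10], m[, 3:10])
  # identity at drop_prob 0
  expect_equal(add_dropouts(m, 0.5, 0, seed = 1), m)
  # binomial expectation: quantile 0.2 x prob 0.5 ~ 10% zeroed
  set.seed(33)
  big <- matrix(runif(10000, 1, 2), nrow = 1, dimnames = list("G1", NULL))
  colnames(big) <- paste0("c", 1:10000)
  dd <- add_dropouts(big, quantile = 0.2, drop_prob = 0.5, seed = 2)
  expect_lt(abs(mean(dd == 0) - 0.10), 0.01)
})

test_that("random DAGs respect the structural constraints", {
  edge_counts <- integer(20)
  for (s in 1:20) {
    topo <- random_dag(50, mean_degree = 2, seed = 200 + s)
    e <- topo$edges
    edge_counts[s] <- nrow(e)
    expect_true(all(e$regulator != e$target))
    expect_equal(anyDuplicated(e[, 1:2]), 0L)
    # acyclicity via iterative sink removal
    adj <- e
    nodes <- seq_len(50)
    repeat {
      sinks <- setdiff(nodes, adj$regulator)
      if (!length(sinks)) break
      nodes <- setdiff(nodes, sinks)
      adj <- adj[!(adj$target %in% sinks), , drop = FALSE]
      if (!nrow(adj)) break
    }
    expect_equal(nrow(adj), 0L)
  }
  expect_lt(abs(mean(edge_counts) - 50), 15)  # expected n*deg/2 = 50, +-30%
  expect_equal(nrow(random_dag(10, 0, seed = 1)$edges), 0L)
})

test_that("connected unique information dominates in one-edge circuits", {
  # activating X -> Y with the stimulus on X: the unique information between
  # the connected pair should exceed both the redundancy and the unique
  # information between unconnected pairs, in most seed sets
  hits <- 0L
  for (s in 1:3) {
    prof <- one_edge_pid_profile(seed = 500 + s)
    if (prof["unique_connected"] > prof["redundancy"] &&
        prof["unique_connected"] > prof["unique_unconnected"]) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 2L)
})
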