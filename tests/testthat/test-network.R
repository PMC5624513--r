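test_that("mi_matrix is symmetric with the duplicated pair dominating", {
  m <- toy_expression(n_cells = 80, n_noise = 1)
  mi <- mi_matrix(m, discretizer = "uniform_width")
  expect_equal(mi, t(mi))
  expect_equal(diag(mi), c(G1 = 0, G2 = 0, G3 = 0))
  off <- mi; diag(off) <- -Inf
  expect_equal(which(off == max(off), arr.ind = TRUE)[1, ],
               c(row = 2L, col = 1L), ignore_attr = TRUE)
  # duplicated gene: MI equals the gene's entropy
  dup <- rbind(m, G4 = m["G1", ] )
  mid <- mi_matrix(dup, discretizer = "uniform_width")
  d <- discretize_gene(m["G1", ], "uniform_width")
  h <- entropy(tabulate(d$labels, d$n_bins) / length(d$labels))
  expect_equal(mid["G1", "G4"], h, tolerance = 1e-9)
})

test_that("mi_matrix rejects constant genes by name and permutes cleanly", {
  m <- toy_expression()
  m2 <- rbind(m, FLAT = rep(1, ncol(m)))
  expect_error(mi_matrix(m2, discretizer = "uniform_width"), "FLAT")
  mi <- mi_matrix(m, discretizer = "uniform_width")
  perm <- c(3, 1, 2)
  mip <- mi_matrix(m[perm, ], discretizer = "uniform_width")
  expect_equal(mip, mi[perm, perm])
})

test_that("relevance ranking is deterministic and monotone invariant", {
  m <- toy_expression()
  mi <- mi_matrix(m, discretizer = "uniform_width")
  r <- relevance_network(mi)
  expect_equal(r$gene_a[1], "G1")
  expect_equal(r$gene_b[1], "G2")
  expect_equal(r$rank, seq_len(nrow(r)))
  # strictly monotone transform leaves the order unchanged
  r3 <- relevance_network(mi^3)
  expect_equal(r3[, c("gene_a", "gene_b")], r[, c("gene_a", "gene_b")])
  # all-equal scores fall back to lexicographic pair order
  eq <- matrix(1, 3, 3, dimnames = list(c("b", "a", "c"), c("b", "a", "c")))
  re <- relevance_network(eq)
  expect_equal(paste(re$gene_a, re$gene_b), c("a b", "a c", "b c"))
})

test_that("clr combines per-gene z-scores and zeroes flat backgrounds", {
  genes <- paste0("G", 1:4)
  mi <- matrix(0.2, 4, 4, dimnames = list(genes, genes))
  diag(mi) <- 0
  mi["G1", "G2"] <- mi["G2", "G1"] <- 0.9
  r <- clr_network(mi)
  expect_equal(c(r$gene_a[1], r$gene_b[1]), c("G1", "G2"))
  rel <- relevance_network(mi)
  expect_equal(c(rel$gene_a[1], rel$gene_b[1]), c("G1", "G2"))
  # a gene with a constant MI row contributes zero z everywhere
  flat <- matrix(0.3, 3, 3, dimnames = list(paste0("G", 1:3), paste0("G", 1:3)))
  diag(flat) <- 0
  rf <- clr_network(flat)
  expect_equal(rf$score, rep(0, 3))
})

test_that("aracne removes the weak edge of indirect-interaction triangles", {
  set.seed(20)
  n <- 400
  x <- rnorm(n); y <- x + rnorm(n, sd = 0.3); z <- y + rnorm(n, sd = 0.3)
  m <- rbind(GX = x, GY = y, GZ = z)
  mi <- mi_matrix(m, discretizer = "uniform_width")
  r <- aracne_network(mi, tau = 0.1)
  xz <- r[r$gene_a == "GX" & r$gene_b == "GZ", ]
  expect_equal(xz$score, 0)     # indirect edge pruned
  expect_gt(r$score[1], 0)
  # tau ~ 1 disables pruning entirely
  r_all <- aracne_network(mi, tau = 0.999)
  expect_true(all(r_all$score > 0))
  expect_error(aracne_network(mi, tau = 1), "tau")
  # two genes: no triangles, nothing to prune
  r2 <- aracne_network(mi[1:2, 1:2], tau = 0.1)
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$score[1], mi["GX", "GY"])
})

test_that("puc scores: duplicated pair saturates at 2(n-2), bounds hold", {
  set.seed(21)
  n <- 500
  g1 <- rnorm(n)
  m <- rbind(G1 = g1, G2 = g1, G3 = rnorm(n), G4 = rnorm(n), G5 = rnorm(n))
  # few bins keep the spurious sample redundancy with the noise genes small
  u <- puc_matrix(m, discretizer = "uniform_width", n_bins = 3)
  ng <- nrow(m)
  # identical pair with independent third genes: every ratio is ~1
  expect_equal(u["G1", "G2"], 2 * (ng - 2), tolerance = 0.05)
  expect_true(all(u >= 0))
  expect_true(all(u <= 2 * (ng - 2) + 1e-6))
  expect_equal(u, t(u))
  expect_error(puc_matrix(m[1:2, ]), "at least 3")
})

test_that("general-estimator puc path agrees with the ml fast path", {
  m <- toy_expression(n_cells = 50, n_noise = 2, seed = 31)
  u_fast <- puc_matrix(m, discretizer = "uniform_width", estimator = "ml")
  disc <- discretize_matrix(m, method = "uniform_width")
  u_slow <- pidnet:::puc_general(disc, rownames(m), "ml", 1)
  expect_equal(unclass(u_fast), unclass(u_slow), ignore_attr = TRUE,
               tolerance = 1e-9)
})

test_that("gene score distributions fit by moments with sane fallbacks", {
  set.seed(22)
  draws <- rgamma(500, shape = 3, scale = 2)
  fit <- fit_gene_distribution(draws, "gamma")
  expect_equal(unname(fit$params["shape"]), 3, tolerance = 0.25)
  expect_equal(unname(fit$params["scale"]), 2, tolerance = 0.3)
  g <- fit_gene_distribution(c(1, 2, 3, 4), "gaussian")
  expect_equal(score_cdf(g, 2.5), 0.5)
  # degenerate spread: gamma moments invalid, gaussian step CDF
  expect_warning(f0 <- fit_gene_distribution(rep(2, 5), "gamma"), "Gaussian")
  expect_equal(score_cdf(f0, c(1.9, 2, 2.1)), c(0, 1, 1))
  expect_error(fit_gene_distribution(1), "at least 2")
})

test_that("pidc confidence lies in [0,2], tops the dominant pair, and is
           invariant to cell order", {
  set.seed(23)
  n <- 120
  g1 <- rnorm(n)
  m <- rbind(G1 = g1, G2 = g1 + rnorm(n, sd = 0.1), G3 = rnorm(n),
             G4 = rnorm(n))
  r <- pidc_network(m, discretizer = "uniform_width")
  expect_true(all(r$score >= 0 & r$score <= 2))
  expect_equal(c(r$gene_a[1], r$gene_b[1]), c("G1", "G2"))
  perm <- sample(n)
  r2 <- pidc_network(m[, perm], discretizer = "uniform_width")
  expect_equal(r, r2, ignore_attr = TRUE)
})

test_that("threshold_top_percent counts against all possible pairs", {
  genes <- paste0("G", 1:50)
  sc <- matrix(runif(2500), 50, 50, dimnames = list(genes, genes))
  sc[lower.tri(sc)] <- t(sc)[lower.tri(sc)]
  r <- relevance_network(sc)
  expect_equal(nrow(threshold_top_percent(r, 2.5)), 31L)  # ceil(.025*1225)
  expect_equal(nrow(threshold_top_percent(r, 100)), nrow(r))
  small <- relevance_network(sc[1:10, 1:10])
  expect_equal(nrow(threshold_top_percent(small, 1e-4)), 1L)
  expect_error(threshold_top_percent(r, 0), "percent")
})

test_that("infer_network returns a grn with consistent methods", {
  m <- toy_expression(n_cells = 60, n_noise = 2)
  fit <- infer_network(m, method = "pidc", discretizer = "uniform_width")
  expect_s3_class(fit, "grn")
  expect_equal(fit$genes, rownames(m))
  expect_equal(nrow(fit$edges), choose(nrow(m), 2))
  co <- coef(fit)
  expect_equal(unname(co), fit$edges$score)
  s <- summary(fit)
  expect_s3_class(s, "summary.grn")
  expect_output(print(fit), "pidc")
  # byte-identical reruns
  fit2 <- infer_network(m, method = "pidc", discretizer = "uniform_width")
  expect_identical(fit$edges$score, fit2$edges$score)
})
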