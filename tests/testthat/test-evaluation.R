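chain_gold <- function() {
  gold_standard(data.frame(regulator = c("G1", "G2"), target = c("G2", "G3")),
                genes = paste0("G", 1:4))
}

ranked_from_pairs <- function(pairs, genes) {
  # build a ranked_edges object from an ordered list of "a b" strings
  df <- do.call(rbind, strsplit(pairs, " "))
  structure(data.frame(gene_a = df[, 1], gene_b = df[, 2],
                       score = rev(seq_along(pairs)),
                       rank = seq_along(pairs)),
            genes = sort(genes), class = c("ranked_edges", "data.frame"))
}

test_that("perfect and worst-case rankings hit the closed-form areas", {
  gold <- gold_standard(data.frame(regulator = "G1", target = "G2"),
                        genes = paste0("G", 1:3))
  perfect <- ranked_from_pairs(c("G1 G2", "G1 G3", "G2 G3"), gold$genes)
  r <- pr_and_roc(perfect, gold)
  expect_equal(r$aupr, 1)
  expect_equal(r$auroc, 1)
  # single true edge ranked last out of 3 pairs: AUPR = 1/3, AUROC = 0
  worst <- ranked_from_pairs(c("G1 G3", "G2 G3", "G1 G2"), gold$genes)
  rw <- pr_and_roc(worst, gold)
  expect_equal(rw$aupr, 1 / 3)
  expect_equal(rw$auroc, 0)
})

test_that("aupr/auroc match the brute-force sweep on all small rankings", {
  gold <- gold_standard(
    data.frame(regulator = c("A", "B"), target = c("B", "C")),
    genes = c("A", "B", "C", "D"))
  pos <- c("A B", "B C")
  pairs <- c("A B", "A C", "A D", "B C", "B D")   # 5 ranked of 6 total pairs
  perms <- NULL
  idx <- seq_along(pairs)
  # all 120 orderings of the 5 ranked pairs
  for (p in combinat_perms(idx)) {
    ranked <- ranked_from_pairs(pairs[p], gold$genes)
    got <- pr_and_roc(ranked, gold)
    # unranked pair C D appended last; it is a negative
    ordered_pos <- c(pairs[p], "C D") %in% pos
    want <- oracle_pr_roc(ordered_pos, n_pos = 2, n_neg = 4)
    expect_equal(got$aupr, want$aupr, tolerance = 1e-12)
    expect_equal(got$auroc, want$auroc, tolerance = 1e-12)
  }
})

test_that("random rankings of a sparse gold standard match the null rates", {
  set.seed(40)
  genes <- paste0("G", 1:8)
  gold <- gold_standard(data.frame(regulator = c("G1", "G3"),
                                   target = c("G2", "G4")), genes = genes)
  all_pairs <- t(combn(genes, 2))
  keys <- paste(all_pairs[, 1], all_pairs[, 2])
  auprs <- aurocs <- numeric(400)
  for (i in seq_len(400)) {
    ranked <- ranked_from_pairs(sample(keys), genes)
    r <- pr_and_roc(ranked, gold)
    auprs[i] <- r$aupr
    aurocs[i] <- r$auroc
  }
  expect_lt(abs(mean(aurocs) - 0.5), 0.03)
  # exact null expectation: positives uniformly at positions i < j of 28,
  # AUPR = (1/2) (1/i + 2/j)
  exact <- mean(apply(combn(28, 2), 2, function(ij)
    0.5 * (1 / ij[1] + 2 / ij[2])))
  expect_lt(abs(mean(auprs) - exact), 0.02)
  expect_gt(exact, 2 / 28)  # null AUPR mean is inflated above the positive
                            # rate by the early-rank harmonic terms
})

test_that("evaluation is invariant to relabelling genes", {
  set.seed(41)
  genes <- paste0("G", 1:6)
  gold <- gold_standard(data.frame(regulator = c("G1", "G2"),
                                   target = c("G4", "G5")), genes = genes)
  all_pairs <- t(combn(genes, 2))
  ranked <- ranked_from_pairs(sample(paste(all_pairs[, 1], all_pairs[, 2])),
                              genes)
  before <- pr_and_roc(ranked, gold)
  relab <- setNames(paste0("Z", sample(6)), genes)
  fix <- function(a, b) paste(pmin(relab[a], relab[b]),
                              pmax(relab[a], relab[b]))
  df <- do.call(rbind, strsplit(fix(ranked$gene_a, ranked$gene_b), " "))
  ranked2 <- structure(
    data.frame(gene_a = df[, 1], gene_b = df[, 2], score = ranked$score,
               rank = ranked$rank),
    genes = sort(unname(relab)), class = c("ranked_edges", "data.frame"))
  gold2 <- gold_standard(data.frame(regulator = relab[gold$edges$regulator],
                                    target = relab[gold$edges$target]),
                         genes = unname(relab))
  after <- pr_and_roc(ranked2, gold2)
  expect_equal(before$aupr, after$aupr)
  expect_equal(before$auroc, after$auroc)
})

test_that("auroc inflates relative to aupr on sparse gold standards", {
  # ranking that finds the few true edges only mid-list: AUROC stays high
  # because true negatives dominate, AUPR collapses
  genes <- paste0("G", sprintf("%02d", 1:30))
  gold <- gold_standard(data.frame(regulator = genes[1:3],
                                   target = genes[4:6]), genes = genes)
  all_pairs <- t(combn(genes, 2))
  keys <- paste(all_pairs[, 1], all_pairs[, 2])
  pos <- paste(pmin(gold$edges$regulator, gold$edges$target),
               pmax(gold$edges$regulator, gold$edges$target))
  neg <- setdiff(keys, pos)
  ranked <- ranked_from_pairs(c(neg[1:40], pos, neg[-(1:40)]), genes)
  r <- pr_and_roc(ranked, gold)
  expect_gt(r$auroc - r$aupr, 0.2)
})

test_that("triplet classification covers the six acyclic classes", {
  gold <- gold_standard(
    data.frame(regulator = c("X", "X", "Y"), target = c("Y", "Z", "Z")),
    genes = c("X", "Y", "Z", "W", "V"))
  expect_equal(classify_triplet(gold, c("X", "Y", "Z")), "feed_forward_loop")
  expect_equal(classify_triplet(gold, c("X", "W", "V")), "unconnected")
  expect_equal(classify_triplet(gold, c("X", "Y", "W")), "one_edge")
  chain <- gold_standard(
    data.frame(regulator = c("A", "B"), target = c("B", "C")),
    genes = c("A", "B", "C"))
  expect_equal(classify_triplet(chain, c("A", "B", "C")), "chain")
  fan_out <- gold_standard(
    data.frame(regulator = c("A", "A"), target = c("B", "C")))
  expect_equal(classify_triplet(fan_out, c("A", "B", "C")), "fan_out")
  fan_in <- gold_standard(
    data.frame(regulator = c("A", "B"), target = c("C", "C")))
  expect_equal(classify_triplet(fan_in, c("A", "B", "C")), "fan_in")
  cyc <- gold_standard(data.frame(regulator = c("A", "B"),
                                  target = c("B", "A")), genes = c("A", "B", "C"))
  expect_error(classify_triplet(cyc, c("A", "B", "C")), "2-cycle")
})

test_that("triplet census counts match combinatorial expectations", {
  empty <- gold_standard(data.frame(regulator = character(0),
                                    target = character(0)),
                         genes = paste0("G", 1:5))
  cen <- triplet_census(empty)
  expect_equal(cen$count[cen$class == "unconnected"], 10)
  expect_equal(sum(cen$fraction), 1)
  one <- gold_standard(data.frame(regulator = "G1", target = "G2"),
                       genes = paste0("G", 1:5))
  cen1 <- triplet_census(one)
  expect_equal(cen1$count[cen1$class == "one_edge"], 3)
  expect_equal(cen1$count[cen1$class == "unconnected"], 7)
  set.seed(42)
  topo <- random_dag(8, 2)
  cenr <- triplet_census(as_gold_standard(topo))
  expect_equal(sum(cenr$fraction), 1, tolerance = 1e-12)
  expect_equal(sum(cenr$count), choose(8, 3))
})

test_that("subset comparison labels partition the retained edges", {
  genes <- paste0("G", 1:6)
  sc <- function(seed) {
    set.seed(seed)
    m <- matrix(runif(36), 6, 6, dimnames = list(genes, genes))
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    relevance_network(m)
  }
  full <- sc(1); a <- sc(2); b <- sc(3)
  lab <- compare_subset_networks(full, a, b, percent = 40)
  expect_true(all(lab$label %in% c("A_specific", "B_specific",
                                   "shared_or_full_only")))
  expect_equal(nrow(lab), nrow(threshold_top_percent(full, 40)))
  same <- compare_subset_networks(full, a, a, percent = 40)
  expect_true(all(same$label == "shared_or_full_only"))
  # an edge only in A's top set gets labelled A_specific
  topA <- threshold_top_percent(a, 40)
  topB <- threshold_top_percent(b, 40)
  keysA <- paste(topA$gene_a, topA$gene_b)
  keysB <- paste(topB$gene_a, topB$gene_b)
  only_a <- setdiff(intersect(paste(lab$gene_a, lab$gene_b), keysA), keysB)
  if (length(only_a)) {
    expect_true(all(lab$label[paste(lab$gene_a, lab$gene_b) %in% only_a] ==
                      "A_specific"))
  }
})

test_that("connected fraction rises monotonically to one", {
  genes <- paste0("G", 1:6)
  set.seed(43)
  m <- matrix(runif(36), 6, 6, dimnames = list(genes, genes))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  ranked <- relevance_network(m)
  curve <- connected_fraction_curve(ranked)
  expect_true(all(diff(curve$fraction) >= 0))
  expect_equal(curve$fraction[nrow(curve)], 1)
  expect_equal(curve$fraction[1], 0)
  # star ranking: all nodes connected after n - 1 edges
  star <- ranked_from_pairs(c("G1 G2", "G1 G3", "G1 G4", "G1 G5", "G1 G6",
                              "G2 G3"), genes)
  cs <- connected_fraction_curve(star)
  expect_equal(cs$fraction[cs$n_edges == 5], 1)
})

test_that("gold standard io round-trips and rejects malformed rows", {
  path <- tempfile(fileext = ".tsv")
  gold <- gold_standard(data.frame(regulator = c("G1", "G2"),
                                   target = c("G2", "G3")),
                        genes = paste0("G", 1:4),
                        negatives = data.frame(regulator = "G1",
                                               target = "G4"))
  write_gold_standard(gold, path)
  back <- read_gold_standard(path)
  expect_equal(back$edges$regulator, gold$edges$regulator)
  expect_equal(back$edges$target, gold$edges$target)
  expect_equal(nrow(back$negatives), 1L)
  writeLines(c("G1\tG2\t1", "G1\tG1\t1"), path)
  expect_error(read_gold_standard(path), "self-edges")
  writeLines(c("G1\tG2\t1", "G1\tG3"), path)
  expect_error(read_gold_standard(path), "malformed")
})
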