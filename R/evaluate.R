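#' Gold-standard network
#'
#' The known directed network behind a simulated dataset, used to score
#' inferred rankings. Self-edges are rejected; an undirected pair set is
#' derived for scoring (a predicted pair counts as true if either direction
#' exists, since the inferred networks are undirected).
#'
#' @param edges Data frame with columns regulator, target (gene ids,
#'   character) and optionally sign.
#' @param genes Character vector of the full gene universe (defaults to the
#'   genes appearing in `edges`).
#' @param negatives Optional data frame of explicitly known non-edges.
#' @return Object of class `gold_standard`.
#' @export
gold_standard <- function(edges, genes = NULL, negatives = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2L) stop("'edges' needs regulator and target columns",
                             call. = FALSE)
  colnames(edges)[1:2] <- c("regulator", "target")
  edges$regulator <- as.character(edges$regulator)
  edges$target <- as.character(edges$target)
  if (any(edges$regulator == edges$target)) {
    stop("self-edges are not allowed in a gold standard", call. = FALSE)
  }
  if (is.null(genes)) {
    genes <- sort(unique(c(edges$regulator, edges$target)), method = "radix")
  } else {
    genes <- sort(as.character(genes), method = "radix")
    missing <- setdiff(c(edges$regulator, edges$target), genes)
    if (length(missing)) {
      stop(sprintf("edge genes not in universe: %s",
                   paste(unique(missing), collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(genes = genes, edges = edges, negatives = negatives),
            class = "gold_standard")
}

#' Gold standard from a simulated circuit topology
#'
#' @param topology A [circuit_topology()].
#' @param gene_names Optional gene names (default `G1..Gn`, matching
#'   [sample_cells()]).
#' @export
as_gold_standard <- function(topology, gene_names = NULL) {
  stopifnot(inherits(topology, "circuit_topology"))
  if (is.null(gene_names)) gene_names <- paste0("G", seq_len(topology$n_genes))
  gold_standard(
    data.frame(regulator = gene_names[topology$edges$regulator],
               target = gene_names[topology$edges$target],
               sign = topology$edges$sign),
    genes = gene_names)
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("Gold standard: %d genes, %d directed edges (%d undirected pairs)\n",
              length(x$genes), nrow(x$edges),
              length(undirected_pair_keys(x))))
  invisible(x)
}

undirected_pair_keys <- function(gold) {
  if (nrow(gold$edges) == 0L) return(character(0))
  a <- pmin(gold$edges$regulator, gold$edges$target)
  b <- pmax(gold$edges$regulator, gold$edges$target)
  unique(paste(a, b, sep = "\r"))
}

#' Precision-recall and ROC evaluation of a ranked edge list
#'
#' Sweeps the ranking one edge at a time (ties resolved by the list's
#' deterministic order), counting a predicted pair as a true positive if the
#' gold standard contains an edge between the two genes in either direction.
#' Gene pairs absent from the ranking are appended at the bottom in
#' lexicographic order. AUPR uses step-wise precision interpolation (the
#' precision attained when each positive is recovered, weighted by the recall
#' increment); AUROC uses the trapezoid rule.
#'
#' @param ranked A `ranked_edges` data frame (see [infer_network()]).
#' @param gold A [gold_standard()] whose genes cover the ranking's universe.
#' @return List with `aupr`, `auroc`, and `curves` (data frames `pr` and
#'   `roc`).
#' @export
pr_and_roc <- function(ranked, gold) {
  genes <- attr(ranked, "genes")
  if (is.null(genes)) genes <- sort(unique(c(ranked$gene_a, ranked$gene_b)),
                                    method = "radix")
  if (!all(genes %in% gold$genes)) {
    stop("ranking contains genes absent from the gold standard",
         call. = FALSE)
  }
  pos_keys <- undirected_pair_keys(gold)
  # restrict positives to the evaluated gene universe
  if (length(pos_keys)) {
    parts <- strsplit(pos_keys, "\r", fixed = TRUE)
    keep <- vapply(parts, function(p) all(p %in% genes), logical(1))
    pos_keys <- pos_keys[keep]
  }
  n <- length(genes)
  total_pairs <- n * (n - 1) / 2
  n_pos <- length(pos_keys)
  n_neg <- total_pairs - n_pos
  if (n_pos == 0L || n_neg == 0L) {
    stop("gold standard must contain at least one positive and one negative pair",
         call. = FALSE)
  }

  ranked_keys <- paste(pmin(ranked$gene_a, ranked$gene_b),
                       pmax(ranked$gene_a, ranked$gene_b), sep = "\r")
  if (anyDuplicated(ranked_keys)) {
    stop("duplicate gene pairs in ranking", call. = FALSE)
  }
  # append unranked pairs in lexicographic order
  all_keys <- all_pair_keys(genes)
  keys <- c(ranked_keys, setdiff(all_keys, ranked_keys))

  is_pos <- keys %in% pos_keys
  tp <- cumsum(is_pos)
  k <- seq_along(keys)
  recall <- tp / n_pos
  precision <- tp / k
  fpr <- (k - tp) / n_neg

  aupr <- sum(precision[is_pos]) / n_pos
  auroc <- sum(diff(c(0, fpr)) * (c(0, recall[-length(recall)]) + recall) / 2)

  list(aupr = aupr, auroc = auroc,
       curves = list(pr = data.frame(recall = recall, precision = precision),
                     roc = data.frame(fpr = fpr, tpr = recall)))
}

all_pair_keys <- function(genes) {
  genes <- sort(genes, method = "radix")
  n <- length(genes)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keys <- paste(genes[idx[, 1]], genes[idx[, 2]], sep = "\r")
  sort(keys, method = "radix")
}

#' Classify a gene triplet by its gold-standard topology
#'
#' Under the gold-standard constraints (at most one edge per pair, no
#' self-regulation, no feedback loops) exactly six triplet topologies exist:
#' unconnected, one edge, chain (X -> Y -> Z), fan-out (one regulator, two
#' targets), fan-in (two regulators, one target) and the feed-forward loop
#' (all three edges, acyclic).
#'
#' @param gold A [gold_standard()].
#' @param triplet Character vector of three distinct gene ids.
#' @return One of `"unconnected"`, `"one_edge"`, `"chain"`, `"fan_out"`,
#'   `"fan_in"`, `"feed_forward_loop"`.
#' @export
classify_triplet <- function(gold, triplet) {
  triplet <- as.character(triplet)
  if (length(triplet) != 3L || anyDuplicated(triplet)) {
    stop("'triplet' must be three distinct genes", call. = FALSE)
  }
  if (!all(triplet %in% gold$genes)) {
    stop("triplet genes must be in the gold standard", call. = FALSE)
  }
  e <- gold$edges
  e <- e[e$regulator %in% triplet & e$target %in% triplet, , drop = FALSE]
  m <- nrow(e)
  key <- paste(e$regulator, e$target, sep = "\r")
  rev_key <- paste(e$target, e$regulator, sep = "\r")
  if (any(rev_key %in% key)) {
    stop("triplet contains a 2-cycle", call. = FALSE)
  }
  if (m == 0L) return("unconnected")
  if (m == 1L) return("one_edge")
  outdeg <- table(factor(e$regulator, levels = triplet))
  indeg <- table(factor(e$target, levels = triplet))
  if (m == 2L) {
    if (any(outdeg == 2L)) return("fan_out")
    if (any(indeg == 2L)) return("fan_in")
    return("chain")
  }
  if (m == 3L) {
    if (any(outdeg == 2L) && any(indeg == 2L)) return("feed_forward_loop")
    stop("triplet contains a directed cycle", call. = FALSE)
  }
  stop("more than one edge per gene pair in triplet", call. = FALSE)
}

#' Census of triplet topologies in a gold-standard network
#'
#' Classifies all `choose(n, 3)` gene triplets and tabulates counts and
#' fractions per class. In realistic sparse networks the unconnected and
#' one-edge classes dominate, which is the structural fact the proportional
#' unique contribution exploits.
#'
#' @param gold A [gold_standard()] satisfying the DAG constraints.
#' @return Data frame with class, count and fraction rows for all six
#'   classes; fractions sum to 1.
#' @export
triplet_census <- function(gold) {
  classes <- c("unconnected", "one_edge", "chain", "fan_out", "fan_in",
               "feed_forward_loop")
  counts <- stats::setNames(numeric(length(classes)), classes)
  combos <- utils::combn(gold$genes, 3L)
  for (i in seq_len(ncol(combos))) {
    cl <- classify_triplet(gold, combos[, i])
    counts[cl] <- counts[cl] + 1
  }
  data.frame(class = classes, count = as.numeric(counts),
             fraction = as.numeric(counts) / ncol(combos))
}

#' Label edges by presence in data-subset networks
#'
#' Thresholds the full-data network and two subset networks at the same top
#' percentage and labels each retained full-network edge by which subset
#' networks also contain it: `A_specific` (in subset A's top set only),
#' `B_specific` (subset B only), or `shared_or_full_only`.
#'
#' @param full,subsetA,subsetB `ranked_edges` lists over the same gene
#'   universe.
#' @param percent Top percentage of possible edges to retain in each list.
#' @return The thresholded full edge list with an extra `label` column.
#' @export
compare_subset_networks <- function(full, subsetA, subsetB, percent) {
  ga <- attr(full, "genes")
  if (!identical(ga, attr(subsetA, "genes")) ||
      !identical(ga, attr(subsetB, "genes"))) {
    stop("edge lists must share one gene universe", call. = FALSE)
  }
  keys <- function(x) paste(x$gene_a, x$gene_b, sep = "\r")
  top_full <- threshold_top_percent(full, percent)
  in_a <- keys(top_full) %in% keys(threshold_top_percent(subsetA, percent))
  in_b <- keys(top_full) %in% keys(threshold_top_percent(subsetB, percent))
  label <- ifelse(in_a & !in_b, "A_specific",
                  ifelse(in_b & !in_a, "B_specific", "shared_or_full_only"))
  out <- as.data.frame(top_full)
  out$label <- label
  out
}

#' Fraction of connected genes versus edge-inclusion threshold
#'
#' Walks down the ranking one edge at a time and reports the fraction of
#' genes touched by at least one included edge, as a function of the
#' percentage of possible edges admitted. Nondecreasing; reaches 1 at 100%
#' for any ranking covering all pairs. Rankings whose top edges concentrate
#' on few hub genes rise slowly; context-aware scores spread edges across
#' genes and rise faster.
#'
#' @param ranked A `ranked_edges` data frame.
#' @param n_genes Size of the gene universe (defaults to the ranking's
#'   attribute).
#' @return Data frame with `n_edges`, `percent` and `fraction` columns
#'   (including the empty-network row).
#' @export
connected_fraction_curve <- function(ranked, n_genes = NULL) {
  genes <- attr(ranked, "genes")
  if (is.null(n_genes)) n_genes <- length(genes)
  total_pairs <- n_genes * (n_genes - 1) / 2
  seen <- new.env(hash = TRUE)
  frac <- numeric(nrow(ranked) + 1L)
  count <- 0L
  for (i in seq_len(nrow(ranked))) {
    for (g in c(ranked$gene_a[i], ranked$gene_b[i])) {
      if (is.null(seen[[g]])) {
        assign(g, TRUE, envir = seen)
        count <- count + 1L
      }
    }
    frac[i + 1L] <- count / n_genes
  }
  data.frame(n_edges = 0:nrow(ranked),
             percent = 100 * (0:nrow(ranked)) / total_pairs,
             fraction = frac)
}
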