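#' Coerce to a validated expression matrix
#'
#' Ensures a numeric genes-by-cells matrix with unique, non-empty gene and
#' cell ids and finite values. Data frames are converted; missing dimnames
#' get `G1..` / `cell1..` defaults.
#'
#' @param data Matrix or data frame of expression values, genes in rows.
#' @return Numeric matrix with validated dimnames.
#' @export
as_expression_matrix <- function(data) {
  if (is.data.frame(data)) data <- as.matrix(data)
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("expression data must be a numeric matrix (genes x cells)",
         call. = FALSE)
  }
  if (is.null(rownames(data))) rownames(data) <- paste0("G", seq_len(nrow(data)))
  if (is.null(colnames(data))) colnames(data) <- paste0("cell", seq_len(ncol(data)))
  if (anyDuplicated(rownames(data))) {
    stop(sprintf("duplicate gene ids: %s",
                 paste(unique(rownames(data)[duplicated(rownames(data))]),
                       collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(colnames(data))) {
    stop(sprintf("duplicate cell ids: %s",
                 paste(unique(colnames(data)[duplicated(colnames(data))]),
                       collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(data))) {
    stop("expression values must be finite", call. = FALSE)
  }
  data
}

reject_constant_genes <- function(data) {
  ranges <- apply(data, 1, function(v) diff(range(v)))
  flat <- rownames(data)[ranges == 0]
  if (length(flat)) {
    stop(sprintf(
      "genes with no expression variability must be removed before inference: %s",
      paste(flat, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a delimited expression matrix
#'
#' Expects rectangular delimited text with a header row of cell ids and a
#' first column of gene ids. Genes with constant values are reported with a
#' warning but kept (reading is lossless; inference rejects them).
#'
#' @param path File path.
#' @param delimiter Field delimiter (default tab).
#' @param transpose If `TRUE` the file has cells in rows and is transposed
#'   on reading.
#' @return Numeric genes-by-cells matrix.
#' @export
read_expression_matrix <- function(path, delimiter = "\t",
                                   transpose = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("expression file needs a header and data rows",
                               call. = FALSE)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths[-1L])) != 1L) {
    stop(sprintf("ragged rows at lines: %s",
                 paste(which(widths[-1L] != widths[2L]) + 1L, collapse = ", ")),
         call. = FALSE)
  }
  header <- fields[[1L]]
  body_width <- widths[2L]
  # header may or may not carry a label over the id column
  col_ids <- if (length(header) == body_width) header[-1L] else header
  ids <- vapply(fields[-1L], `[[`, character(1), 1L)
  vals <- lapply(seq_along(fields[-1L]), function(i) {
    v <- suppressWarnings(as.numeric(fields[[i + 1L]][-1L]))
    if (anyNA(v)) {
      stop(sprintf("non-numeric value at line %d", i + 1L), call. = FALSE)
    }
    v
  })
  m <- do.call(rbind, vals)
  rownames(m) <- ids
  colnames(m) <- col_ids
  if (transpose) m <- t(m)
  m <- as_expression_matrix(m)
  ranges <- apply(m, 1, function(v) diff(range(v)))
  if (any(ranges == 0)) {
    warning(sprintf("constant-valued genes (remove before inference): %s",
                    paste(rownames(m)[ranges == 0], collapse = ", ")),
            call. = FALSE)
  }
  m
}

#' Convert qPCR Ct values to expression
#'
#' Inverts cycle-threshold values (`expression = assumed_max - Ct`, so higher
#' means more transcript), optionally normalizes each cell by subtracting its
#' mean housekeeping-gene expression, and optionally floors measurements
#' below the limit of detection at a fixed value.
#'
#' @param ct Numeric matrix of Ct values, genes in rows.
#' @param assumed_max The assumed maximal cycle number (e.g. 40).
#' @param housekeeping Optional character vector of housekeeping gene ids
#'   used for per-cell normalization.
#' @param floor_value Optional value assigned to below-detection entries
#'   after normalization.
#' @param detection_limit Ct value at/beyond which a measurement counts as
#'   below the limit of detection (defaults to `assumed_max`).
#' @return Expression matrix (same shape as `ct`).
#' @export
ct_to_expression <- function(ct, assumed_max, housekeeping = NULL,
                             floor_value = NULL,
                             detection_limit = assumed_max) {
  ct <- as_expression_matrix(ct)
  expr <- assumed_max - ct
  below <- ct >= detection_limit
  if (!is.null(housekeeping)) {
    missing <- setdiff(housekeeping, rownames(ct))
    if (length(missing)) {
      stop(sprintf("housekeeping genes not found: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    hk <- colMeans(expr[housekeeping, , drop = FALSE])
    expr <- sweep(expr, 2L, hk)
  }
  if (!is.null(floor_value)) expr[below] <- floor_value
  expr
}

#' Write a ranked edge list with a provenance header
#'
#' Tab-separated columns gene_a, gene_b, score, rank, preceded by `#`
#' comment lines echoing the configuration that produced the list, so a
#' result file records the discretizer/estimator choices it depends on.
#' Byte-identical across reruns of the same configuration.
#'
#' @param ranked A `ranked_edges` data frame.
#' @param path Output path.
#' @param config Optional named list echoed into the header.
#' @export
write_ranked_edges <- function(ranked, path, config = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(config)) {
    for (key in names(config)) {
      writeLines(sprintf("# %s=%s", key, paste(config[[key]], collapse = ",")),
                 con)
    }
  }
  writeLines(paste(c("gene_a", "gene_b", "score", "rank"), collapse = "\t"),
             con)
  if (nrow(ranked)) {
    writeLines(sprintf("%s\t%s\t%.17g\t%d", ranked$gene_a, ranked$gene_b,
                       ranked$score, ranked$rank), con)
  }
  invisible(path)
}

#' Read a ranked edge list written by [write_ranked_edges()]
#'
#' @param path File path.
#' @return A `ranked_edges` data frame (gene universe taken from the listed
#'   genes).
#' @export
read_ranked_edges <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE)
  structure(df,
            genes = sort(unique(c(df$gene_a, df$gene_b)), method = "radix"),
            class = c("ranked_edges", "data.frame"))
}

#' Read a gold-standard edge list
#'
#' Three-column delimited text: regulator, target, flag (1 = edge, 0 =
#' explicit non-edge). Malformed and self-edge rows are rejected with their
#' line numbers.
#'
#' @param path File path.
#' @param delimiter Field delimiter (default any whitespace via tab/space
#'   splitting).
#' @param genes Optional gene universe.
#' @return A [gold_standard()].
#' @export
read_gold_standard <- function(path, delimiter = "\t", genes = NULL) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  parts <- strsplit(trimws(lines[keep]), "[\t ]+")
  bad <- keep[lengths(parts) != 3L]
  if (length(bad)) {
    stop(sprintf("malformed gold-standard rows at lines: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  reg <- vapply(parts, `[[`, character(1), 1L)
  tgt <- vapply(parts, `[[`, character(1), 2L)
  flag <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 3L)))
  if (anyNA(flag) || !all(flag %in% c(0L, 1L))) {
    stop(sprintf("gold-standard flags must be 0/1; bad lines: %s",
                 paste(keep[is.na(flag) | !(flag %in% c(0L, 1L))],
                       collapse = ", ")), call. = FALSE)
  }
  self <- reg == tgt
  if (any(self)) {
    stop(sprintf("self-edges at lines: %s", paste(keep[self], collapse = ", ")),
         call. = FALSE)
  }
  pos <- data.frame(regulator = reg[flag == 1L], target = tgt[flag == 1L])
  neg <- if (any(flag == 0L)) {
    data.frame(regulator = reg[flag == 0L], target = tgt[flag == 0L])
  } else {
    NULL
  }
  if (is.null(genes)) genes <- sort(unique(c(reg, tgt)), method = "radix")
  gold_standard(pos, genes = genes, negatives = neg)
}

#' Write a gold standard as a three-column edge list
#'
#' @param gold A [gold_standard()].
#' @param path Output path.
#' @export
write_gold_standard <- function(gold, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(gold$edges)) {
    writeLines(sprintf("%s\t%s\t1", gold$edges$regulator, gold$edges$target),
               con)
  }
  if (!is.null(gold$negatives) && nrow(gold$negatives)) {
    writeLines(sprintf("%s\t%s\t0", gold$negatives$regulator,
                       gold$negatives$target), con)
  }
  invisible(path)
}
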