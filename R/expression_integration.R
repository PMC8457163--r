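# Expression status of DMR-associated genes: low-pH subject exclusion,
# reliability filtering, per-probe Welch tests at nominal alpha (no
# multiple-testing correction at this stage, by design).

#' Exclude subjects with low (or missing) brain pH
#'
#' Postmortem-tissue QC: subjects with brain pH below `cutoff` are removed;
#' subjects with missing pH are also removed (and counted in the message).
#' Errors if a whole group would be removed, since the case-control test
#' would become impossible.
#'
#' @param matrix an [ExpressionMatrix].
#' @param cutoff pH threshold (default 6.0, a conventional brain-bank QC
#'   bound).
#' @return The filtered [ExpressionMatrix].
#' @export
exclude_low_ph <- function(matrix, cutoff = 6.0) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  ph <- matrix$sheet$brain_pH
  drop_missing <- is.na(ph)
  drop_low <- !is.na(ph) & ph < cutoff
  keep <- !(drop_missing | drop_low)
  if (any(drop_missing))
    message(sum(drop_missing), " subject(s) with missing brain pH excluded")
  if (any(drop_low))
    message(sum(drop_low), " subject(s) with brain pH < ", cutoff, " excluded")
  for (g in c("CT", "SZ")) {
    if (!any(keep & matrix$sheet$group == g))
      stop("pH filter removed every ", g,
           " subject; expression testing impossible")
  }
  ExpressionMatrix(matrix$values[, keep, drop = FALSE],
                   matrix$probe_to_gene,
                   as.data.frame(matrix$sheet[keep, , drop = FALSE]))
}

#' Keep probes with reliable expression in both groups
#'
#' A probe is reliable when its signal exceeds `floor` in at least
#' `min_expressed_fraction` of subjects within each group separately.
#'
#' @param matrix an [ExpressionMatrix] (pH-filter first: the pipeline order
#'   is pH, then reliability on the retained subjects).
#' @param min_expressed_fraction minimum fraction of above-floor subjects per
#'   group (default 0.8).
#' @param floor log2-signal detection floor.
#' @return The filtered [ExpressionMatrix] (possibly with zero probes,
#'   logged).
#' @export
filter_reliable <- function(matrix, min_expressed_fraction = 0.8, floor = 5) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  keep <- rep(TRUE, nrow(matrix$values))
  for (g in c("CT", "SZ")) {
    cols <- matrix$sheet$group == g
    frac <- rowMeans(matrix$values[, cols, drop = FALSE] > floor)
    keep <- keep & frac >= min_expressed_fraction
  }
  if (!any(keep)) message("reliability filter removed every probe")
  ExpressionMatrix(matrix$values[keep, , drop = FALSE],
                   matrix$probe_to_gene[keep],
                   as.data.frame(matrix$sheet))
}

#' Welch tests of DMR-associated gene expression (SZ vs CT)
#'
#' Restricts to probes mapping to `dmr_genes` and runs a two-sided Welch
#' t-test per probe. Genes without any (retained) probe are logged and
#' skipped. Significance is nominal (uncorrected) at `alpha`.
#'
#' @param matrix an [ExpressionMatrix], already pH- and reliability-filtered.
#' @param dmr_genes character vector of DMR-associated gene symbols.
#' @param alpha nominal significance level (default 0.05).
#' @return data.frame of class `welch_results` with columns `probe_id`,
#'   `gene_symbol`, `t`, `df`, `p`, `mean_CT`, `mean_SZ`, `significant`;
#'   attributes `n_significant_probes` and `n_significant_genes` give the
#'   probe count and the distinct-gene count among significant probes.
#' @export
test_dmr_gene_expression <- function(matrix, dmr_genes, alpha = 0.05) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  dmr_genes <- unique(as.character(dmr_genes))
  absent <- setdiff(dmr_genes, matrix$probe_to_gene)
  if (length(absent))
    message(length(absent), " DMR-associated gene(s) absent from the ",
            "expression matrix skipped: ",
            paste(utils::head(absent, 5L), collapse = ", "),
            if (length(absent) > 5L) ", ..." else "")
  rows <- which(matrix$probe_to_gene %in% dmr_genes)
  idx_sz <- which(matrix$sheet$group == "SZ")
  idx_ct <- which(matrix$sheet$group == "CT")
  if (length(rows) == 0L) {
    out <- data.frame(probe_id = character(), gene_symbol = character(),
                      t = numeric(), df = numeric(), p = numeric(),
                      mean_CT = numeric(), mean_SZ = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  } else {
    X <- matrix$values[rows, , drop = FALSE]
    w <- .welch_rows(X, idx_sz, idx_ct)
    p <- 2 * stats::pt(-abs(w$t), w$df)
    out <- data.frame(probe_id = rownames(X),
                      gene_symbol = unname(matrix$probe_to_gene[rows]),
                      t = w$t, df = w$df, p = p,
                      mean_CT = rowMeans(X[, idx_ct, drop = FALSE]),
                      mean_SZ = rowMeans(X[, idx_sz, drop = FALSE]),
                      significant = p < alpha,
                      stringsAsFactors = FALSE, row.names = NULL)
  }
  attr(out, "alpha") <- alpha
  attr(out, "n_significant_probes") <- sum(out$significant)
  attr(out, "n_significant_genes") <-
    length(unique(out$gene_symbol[out$significant]))
  class(out) <- c("welch_results", "data.frame")
  out
}

#' @export
print.welch_results <- function(x, ...) {
  cat(sprintf("Welch expression tests: %d probes covering %d genes; %d probe(s) for %d gene(s) significant at nominal P < %g\n",
              nrow(x), length(unique(x$gene_symbol)),
              attr(x, "n_significant_probes"), attr(x, "n_significant_genes"),
              attr(x, "alpha")))
  print.data.frame(x, ...)
  invisible(x)
}
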