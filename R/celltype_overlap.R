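# Cross-cell-type sharing of DMR-associated genes (Venn-style summary) and
# direction concordance of shared genes.

# Half-up rounding to `digits` decimals (round() is round-half-even; the
# reported sharing percentages are defined with conventional half-up ties).
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Two-set overlap summary of DMR-associated genes
#'
#' Exact set intersection of two gene lists with sharing percentages
#' (100 * shared / set size) rounded half-up to one decimal. Empty inputs
#' give `NA` percentages (undefined), not 0.
#'
#' @param genes_a,genes_b character vectors of gene symbols (deduplicated
#'   defensively; comparison is case-sensitive exact match).
#' @param labels length-2 character labels for the two sets.
#' @return A list of class `VennSummary`: `n_a`, `n_b`, `n_shared`,
#'   `pct_a_shared`, `pct_b_shared`, `labels`.
#' @examples
#' overlap_summary(c("CHGA", "LINGO1", "ATP2B2"), c("CHGA", "PEG10"),
#'                 labels = c("nonneuron", "neuron"))
#' @export
overlap_summary <- function(genes_a, genes_b, labels = c("A", "B")) {
  genes_a <- unique(as.character(genes_a))
  genes_b <- unique(as.character(genes_b))
  n_a <- length(genes_a); n_b <- length(genes_b)
  n_shared <- length(intersect(genes_a, genes_b))
  structure(list(
    n_a = n_a, n_b = n_b, n_shared = n_shared,
    pct_a_shared = if (n_a > 0L) round_half_up(100 * n_shared / n_a) else NA_real_,
    pct_b_shared = if (n_b > 0L) round_half_up(100 * n_shared / n_b) else NA_real_,
    labels = as.character(labels)[1:2]), class = "VennSummary")
}

#' @export
print.VennSummary <- function(x, ...) {
  cat(sprintf("Gene overlap: %s n=%d | shared n=%d | %s n=%d\n",
              x$labels[1L], x$n_a, x$n_shared, x$labels[2L], x$n_b))
  cat(sprintf("  shared: %s%% of %s, %s%% of %s\n",
              format(x$pct_a_shared), x$labels[1L],
              format(x$pct_b_shared), x$labels[2L]))
  invisible(x)
}

# Per-gene direction within one DMRSet; genes whose DMRs disagree -> "mixed".
.gene_directions <- function(dmrs, universe) {
  d <- dmrs$dmrs
  genes <- universe$promoters$gene_symbol[
    match(d$promoter_id, universe$promoters$promoter_id)]
  tapply(d$direction, genes, function(v)
    if (length(unique(v)) == 1L) v[1L] else "mixed")
}

#' Direction concordance of genes shared between two DMR sets
#'
#' For every gene with DMRs in both sets, reports the per-set direction
#' (`hyper`, `hypo`, or `mixed` when one cell type's DMRs disagree) and
#' whether the two agree. `concordant` is `NA` when either side is mixed.
#'
#' @param dmrs_a,dmrs_b [DMRSet] objects from the same universe.
#' @param universe the shared [PromoterUniverse].
#' @return data.frame with columns `gene_symbol`, `direction_a`,
#'   `direction_b`, `concordant`.
#' @export
direction_concordance <- function(dmrs_a, dmrs_b, universe) {
  stopifnot(inherits(dmrs_a, "DMRSet"), inherits(dmrs_b, "DMRSet"))
  da <- .gene_directions(dmrs_a, universe)
  db <- .gene_directions(dmrs_b, universe)
  shared <- sort(intersect(names(da), names(db)))
  out <- data.frame(gene_symbol = shared,
                    direction_a = unname(unlist(da[shared])),
                    direction_b = unname(unlist(db[shared])),
                    stringsAsFactors = FALSE)
  out$concordant <- ifelse(out$direction_a == "mixed" | out$direction_b == "mixed",
                           NA, out$direction_a == out$direction_b)
  out
}
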