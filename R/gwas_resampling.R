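# Promoter-based random-sampling test of DMR enrichment/depletion in GWAS
# loci. The unit is the promoter: the observed statistic is the number of
# distinct DMR-bearing promoters overlapping >= 1 locus, and the null draws
# equally many promoters uniformly without replacement from the full
# universe. Under this design the exact null is hypergeometric, which serves
# as the closed-form oracle in tests. Empirical p-values are add-one
# corrected and reported separately for enrichment and depletion.

# Binary overlap indicator per promoter (>= 1 bp intersection, strand
# ignored).
.promoter_hits <- function(universe, loci) {
  gr <- promoter_granges(universe)
  lg <- interval_granges(loci)
  if (length(lg) == 0L) return(rep(FALSE, length(gr)))
  GenomicRanges::countOverlaps(gr, lg) > 0L
}

#' Observed promoter-level overlap of a DMR set with loci
#'
#' Counts distinct DMR-bearing promoters (a promoter with several DMRs
#' counts once) and how many of them intersect at least one locus by >= 1 bp.
#'
#' @param dmrs a [DMRSet].
#' @param universe the [PromoterUniverse] the DMRs belong to.
#' @param loci an [IntervalSet] of GWAS loci.
#' @return list with `k` (distinct DMR-bearing promoters) and `overlap`.
#' @export
observed_overlap <- function(dmrs, universe, loci) {
  stopifnot(inherits(dmrs, "DMRSet"), inherits(universe, "PromoterUniverse"),
            inherits(loci, "IntervalSet"))
  proms <- unique(dmrs$dmrs$promoter_id)
  if (!all(proms %in% universe$promoters$promoter_id))
    stop("DMR promoter(s) not in universe")
  hits <- .promoter_hits(universe, loci)
  idx <- match(proms, universe$promoters$promoter_id)
  list(k = length(proms), overlap = sum(hits[idx]))
}

#' Null distribution of overlap counts by promoter resampling
#'
#' Each of the `B` draws samples `k` promoters uniformly without replacement
#' from the full universe and counts how many overlap >= 1 locus. Fully
#' deterministic given `seed`.
#'
#' @param universe a [PromoterUniverse] (the sampling frame).
#' @param k sampled-set size (number of DMR-bearing promoters).
#' @param loci an [IntervalSet].
#' @param B number of random samplings (default 10000).
#' @param seed RNG seed.
#' @return integer vector of `B` null overlap counts.
#' @export
resample_null <- function(universe, k, loci, B = 10000L, seed = 1L) {
  stopifnot(inherits(universe, "PromoterUniverse"), inherits(loci, "IntervalSet"))
  N <- nrow(universe$promoters)
  if (k > N) stop("k exceeds the universe size")
  if (B < 1L) stop("B must be >= 1")
  hits <- .promoter_hits(universe, loci)
  with_seed(seed, {
    vapply(seq_len(B), function(b) sum(hits[sample.int(N, k)]), integer(1L))
  })
}

#' Add-one empirical p-values for enrichment and depletion
#'
#' `p_enrich = (1 + #\{null >= observed\}) / (B + 1)` and
#' `p_deplete = (1 + #\{null <= observed\}) / (B + 1)`; both sides count
#' ties, so `p_enrich + p_deplete >= 1 + 1/(B+1)`.
#'
#' @param observed observed overlap count.
#' @param null_counts integer vector of null overlap counts.
#' @return list with `p_enrich` and `p_deplete`.
#' @export
empirical_p <- function(observed, null_counts) {
  B <- length(null_counts)
  if (B < 1L) stop("null_counts must be non-empty")
  list(p_enrich = (1 + sum(null_counts >= observed)) / (B + 1),
       p_deplete = (1 + sum(null_counts <= observed)) / (B + 1))
}

#' Full enrichment/depletion scan: DMR sets x trait locus sets
#'
#' Runs the promoter-resampling test for every combination of DMR set
#' (e.g. stringent and relaxed, per cell type) and trait locus set.
#' Per-combination seeds are derived deterministically from the master seed
#' and the combination index.
#'
#' @param dmr_sets list of [DMRSet] objects.
#' @param loci_sets list of [IntervalSet] objects (one per trait).
#' @param universe the shared [PromoterUniverse].
#' @param B number of random samplings per combination.
#' @param seed master seed.
#' @param alpha per-side significance level for the `significant_*` flags.
#' @return list of `ResamplingResult` objects (one per combination), each
#'   with fields `trait`, `dmr_label`, `cell_type`, `threshold_label`,
#'   `observed_overlap`, `k`, `B`, `null_counts`, `p_enrich`, `p_deplete`,
#'   `significant_enrich`, `significant_deplete`, `seed`. Use
#'   [resampling_table()] for a flat summary.
#' @export
run_enrichment_scan <- function(dmr_sets, loci_sets, universe, B = 10000L,
                                seed = 1L, alpha = 0.05) {
  stopifnot(is.list(dmr_sets), is.list(loci_sets))
  results <- list()
  idx <- 0L
  for (dmrs in dmr_sets) {
    for (loci in loci_sets) {
      idx <- idx + 1L
      sub_seed <- (as.integer(seed) + 7919L * idx) %% .Machine$integer.max
      obs <- observed_overlap(dmrs, universe, loci)
      nulls <- if (obs$k > 0L)
        resample_null(universe, obs$k, loci, B = B, seed = sub_seed)
      else integer(B)
      p <- empirical_p(obs$overlap, nulls)
      results[[idx]] <- structure(list(
        trait = loci$name,
        dmr_label = sprintf("%s_%s", dmrs$cell_type, dmrs$threshold_label),
        cell_type = dmrs$cell_type, threshold_label = dmrs$threshold_label,
        observed_overlap = obs$overlap, k = obs$k, B = as.integer(B),
        null_counts = nulls, p_enrich = p$p_enrich, p_deplete = p$p_deplete,
        significant_enrich = p$p_enrich < alpha,
        significant_deplete = p$p_deplete < alpha,
        seed = sub_seed), class = "ResamplingResult")
    }
  }
  results
}

#' @export
print.ResamplingResult <- function(x, ...) {
  cat(sprintf("Resampling test [%s vs %s]: observed %d/%d promoters in loci (null mean %.2f, B=%d)\n",
              x$dmr_label, x$trait, x$observed_overlap, x$k,
              mean(x$null_counts), x$B))
  cat(sprintf("  p_enrich = %.4g%s, p_deplete = %.4g%s\n",
              x$p_enrich, if (x$significant_enrich) " *" else "",
              x$p_deplete, if (x$significant_deplete) " *" else ""))
  invisible(x)
}

#' Flatten a list of ResamplingResult objects into a data.frame
#'
#' @param results list returned by [run_enrichment_scan()].
#' @return data.frame with one row per DMR-set/trait combination
#'   (null_counts omitted).
#' @export
resampling_table <- function(results) {
  do.call(rbind, lapply(results, function(r) data.frame(
    trait = r$trait, dmr_label = r$dmr_label, cell_type = r$cell_type,
    threshold_label = r$threshold_label, observed_overlap = r$observed_overlap,
    k = r$k, B = r$B, null_mean = mean(r$null_counts),
    p_enrich = r$p_enrich, p_deplete = r$p_deplete,
    significant_enrich = r$significant_enrich,
    significant_deplete = r$significant_deplete,
    stringsAsFactors = FALSE)))
}
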