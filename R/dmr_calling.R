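# Windowed DMR calling. Per-probe Welch t (SZ vs CT) -> sliding windows of
# min_probes consecutive probes within a promoter (adjacent-probe gap <=
# max_gap_bp) -> Stouffer-combined window score S = sum(t)/sqrt(m) -> window
# p-value from a two-sided normal tail (analytic) or from the promoter-level
# label-permutation distribution of max |S| (add-one corrected). Overlapping
# significant windows merge into one DMR keeping the best p.

VAR_FLOOR <- 1e-12  # variance floor for degenerate zero-variance probes

# Vectorised Welch t over matrix rows; a = SZ columns, b = CT columns.
.welch_rows <- function(X, idx_a, idx_b) {
  n1 <- length(idx_a); n2 <- length(idx_b)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  m1 <- rowMeans(X[, idx_a, drop = FALSE])
  m2 <- rowMeans(X[, idx_b, drop = FALSE])
  v1 <- pmax(rowSums((X[, idx_a, drop = FALSE] - m1)^2) / (n1 - 1), VAR_FLOOR)
  v2 <- pmax(rowSums((X[, idx_b, drop = FALSE] - m2)^2) / (n2 - 1), VAR_FLOOR)
  se2 <- v1 / n1 + v2 / n2
  list(t = (m1 - m2) / sqrt(se2),
       df = se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
       mean_diff = m1 - m2)
}

#' Per-probe Welch t statistics (case vs control)
#'
#' For every probe, Welch's unequal-variance t of SZ vs CT log2 signal with
#' Welch-Satterthwaite degrees of freedom; `mean_diff` is mean(SZ) -
#' mean(CT), so positive values indicate hypermethylation in cases. Probes
#' with zero within-group variance are handled with a variance floor of
#' 1e-12.
#'
#' @param matrix a [ProbeSignalMatrix]; both groups need >= 2 samples.
#' @return data.frame (class `probe_stats`) with columns `probe_id`,
#'   `t_value`, `df`, `mean_diff`; the matrix's cell type is carried in
#'   attribute `cell_type`.
#' @export
probe_stats <- function(matrix) {
  stopifnot(inherits(matrix, "ProbeSignalMatrix"))
  idx_a <- which(matrix$sheet$group == "SZ")
  idx_b <- which(matrix$sheet$group == "CT")
  w <- .welch_rows(matrix$values, idx_a, idx_b)
  out <- data.frame(probe_id = rownames(matrix$values), t_value = w$t,
                    df = w$df, mean_diff = w$mean_diff,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "cell_type") <- unique(matrix$sheet$cell_type)[1L]
  class(out) <- c("probe_stats", "data.frame")
  out
}

# Window layout for a universe: probes ordered by (promoter, start), runs
# split at gaps > max_gap_bp, one window per min_probes consecutive probes.
# Returns probe ordering, window index ranges and the sparse Stouffer
# operator W (n_windows x n_probes) with entries 1/sqrt(min_probes).
.build_windows <- function(universe, probe_ids, min_probes, max_gap_bp) {
  pb <- universe$probes
  pb <- pb[pb$probe_id %in% probe_ids, , drop = FALSE]
  pb <- pb[order(pb$promoter_id, pb$start), , drop = FALSE]
  n_skipped <- 0L
  win_from <- integer(); win_to <- integer()
  prom_tab <- table(pb$promoter_id)
  offset <- 0L
  for (pid in names(prom_tab)) {
    k <- prom_tab[[pid]]
    rows <- offset + seq_len(k)
    offset <- offset + k
    if (k < min_probes) { n_skipped <- n_skipped + 1L; next }
    gaps <- pb$start[rows[-1L]] - pb$end[rows[-k]]
    run_id <- cumsum(c(1L, as.integer(gaps > max_gap_bp)))
    for (r in unique(run_id)) {
      rr <- rows[run_id == r]
      L <- length(rr)
      if (L < min_probes) next
      starts <- rr[seq_len(L - min_probes + 1L)]
      win_from <- c(win_from, starts)
      win_to <- c(win_to, starts + min_probes - 1L)
    }
  }
  n_win <- length(win_from)
  W <- if (n_win > 0L) {
    Matrix::sparseMatrix(
      i = rep(seq_len(n_win), each = min_probes),
      j = unlist(lapply(seq_len(n_win), function(w) win_from[w]:win_to[w])),
      x = 1 / sqrt(min_probes), dims = c(n_win, nrow(pb)))
  } else Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(0L, nrow(pb)))
  list(probes = pb, W = W, win_from = win_from, win_to = win_to,
       win_promoter = pb$promoter_id[win_from], n_skipped = n_skipped)
}

# Per-probe Welch t for B label permutations, via matrix products on the
# row-centred signal and its square (one global permutation set).
.perm_t_matrix <- function(X, n_sz, B, seed) {
  n <- ncol(X)
  Xc <- X - rowMeans(X)
  G <- with_seed(seed, {
    g <- matrix(0, n, B)
    for (b in seq_len(B)) g[sample.int(n, n_sz), b] <- 1
    g
  })
  n1 <- n_sz; n2 <- n - n_sz
  S1 <- Xc %*% G
  SS1 <- (Xc * Xc) %*% G
  Tot <- rowSums(Xc); TotSq <- rowSums(Xc * Xc)
  M1 <- S1 / n1
  M2 <- (Tot - S1) / n2
  V1 <- pmax((SS1 - n1 * M1 * M1) / (n1 - 1), VAR_FLOOR)
  V2 <- pmax((TotSq - SS1 - n2 * M2 * M2) / (n2 - 1), VAR_FLOOR)
  as.matrix((M1 - M2) / sqrt(V1 / n1 + V2 / n2))
}

#' Call differentially methylated regions from per-probe statistics
#'
#' Within each promoter, windows of `min_probes` consecutive probes (adjacent
#' probes at most `max_gap_bp` apart) are scored with the Stouffer
#' combination S = sum(t_i)/sqrt(m), treating each Welch t as a z-score. The
#' window p-value is either the two-sided normal tail 2*pnorm(-|S|)
#' (`null = "analytic"`) or, under `null = "permutation"`, the add-one
#' corrected fraction of group-label permutations whose promoter-level
#' max |S| reaches the observed |S| — a promoter-level family-wise null that
#' absorbs within-promoter probe correlation. Overlapping windows passing
#' `threshold_p` are merged into one DMR spanning their union, keeping the
#' best (smallest) p-value and its score; the DMR direction is the sign of
#' the probe-mean `mean_diff` over the merged span (`hyper` = higher in SZ).
#'
#' @param stats `probe_stats` data.frame from [probe_stats()].
#' @param universe the [PromoterUniverse] the probes belong to.
#' @param min_probes window size in probes (default 4).
#' @param max_gap_bp maximum gap between adjacent probes within a window.
#' @param threshold_p DMR-defining p-value threshold (strict `<`), e.g.
#'   `1e-7` stringent, `1e-5` relaxed.
#' @param threshold_label `"stringent"` or `"relaxed"` tag stored on the set.
#' @param null `"analytic"` or `"permutation"`.
#' @param matrix the [ProbeSignalMatrix] the stats came from; required for
#'   the permutation null (labels must be re-permuted on the raw signal).
#' @param n_perm number of label permutations (>= 100).
#' @param seed RNG seed for the permutation null.
#' @param cell_type override for the cell-type tag (defaults to the stats'
#'   attribute).
#' @return A [DMRSet]. An `fdr` column (Benjamini-Hochberg over all tested
#'   windows) is reported for reference but plays no role in set definition.
#' @export
call_dmrs <- function(stats, universe, min_probes = 4L, max_gap_bp = 300L,
                      threshold_p = 1e-7,
                      threshold_label = c("stringent", "relaxed"),
                      null = c("analytic", "permutation"), matrix = NULL,
                      n_perm = 1000L, seed = 1L, cell_type = NULL) {
  null <- match.arg(null)
  threshold_label <- match.arg(threshold_label)
  stopifnot(inherits(stats, "probe_stats"), inherits(universe, "PromoterUniverse"))
  if (!all(stats$probe_id %in% universe$probes$probe_id))
    stop("probe(s) in stats not present in the universe")
  if (is.null(cell_type)) cell_type <- attr(stats, "cell_type")
  if (is.null(cell_type) || cell_type %in% c("bulk", NA)) cell_type <- "neuron"

  bw <- .build_windows(universe, stats$probe_id, min_probes, max_gap_bp)
  if (bw$n_skipped > 0L)
    message(bw$n_skipped, " promoter(s) with fewer than ", min_probes,
            " probes skipped")
  si <- match(bw$probes$probe_id, stats$probe_id)
  t_obs <- stats$t_value[si]
  mean_diff <- stats$mean_diff[si]
  n_win <- length(bw$win_from)
  if (n_win == 0L)
    return(DMRSet(data.frame(), threshold_p, threshold_label, cell_type,
                  null_type = null, n_perm = if (null == "permutation") n_perm else NA_integer_,
                  seed = if (null == "permutation") seed else NA_integer_))

  S_obs <- as.numeric(bw$W %*% t_obs)
  if (null == "analytic") {
    p_win <- 2 * stats::pnorm(-abs(S_obs))
    p_win[p_win == 0] <- .Machine$double.xmin  # keep p in (0, 1]
  } else {
    if (is.null(matrix) || !inherits(matrix, "ProbeSignalMatrix"))
      stop("the permutation null requires the ProbeSignalMatrix via `matrix`")
    if (n_perm < 100L) stop("n_perm must be >= 100 for the permutation null")
    X <- matrix$values[bw$probes$probe_id, , drop = FALSE]
    ord <- c(which(matrix$sheet$group == "SZ"), which(matrix$sheet$group == "CT"))
    Tm <- .perm_t_matrix(X[, ord, drop = FALSE],
                         sum(matrix$sheet$group == "SZ"), n_perm, seed)
    S_perm_abs <- abs(as.matrix(bw$W %*% Tm))
    p_win <- numeric(n_win)
    for (pid in unique(bw$win_promoter)) {
      wi <- which(bw$win_promoter == pid)
      maxs <- if (length(wi) == 1L) S_perm_abs[wi, ] else
        do.call(pmax, lapply(wi, function(i) S_perm_abs[i, ]))
      for (i in wi) p_win[i] <- (1 + sum(maxs >= abs(S_obs[i]))) / (n_perm + 1)
    }
  }

  sig <- which(p_win < threshold_p)
  dmrs <- .merge_windows(bw, sig, S_obs, p_win, mean_diff, universe)
  if (nrow(dmrs) > 0L) {
    # reference-only BH over all tested windows, mapped to each DMR's best window
    fdr_all <- stats::p.adjust(p_win, method = "BH")
    dmrs$fdr <- fdr_all[dmrs$best_window]
    dmrs$best_window <- NULL
    dmrs <- dmrs[order(dmrs$chrom, dmrs$start), , drop = FALSE]
    dmrs$dmr_id <- sprintf("DMR_%s_%03d", cell_type, seq_len(nrow(dmrs)))
  }
  DMRSet(dmrs, threshold_p, threshold_label, cell_type, null_type = null,
         n_perm = if (null == "permutation") n_perm else NA_integer_,
         seed = if (null == "permutation") seed else NA_integer_)
}

# Merge overlapping significant windows within each promoter; windows are in
# probe-index order so a chain merges while the next window starts at or
# before the current merged end.
.merge_windows <- function(bw, sig, S_obs, p_win, mean_diff, universe) {
  empty <- data.frame(dmr_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      promoter_id = character(), gene_symbol = character(),
                      n_probes = integer(), score = numeric(),
                      p_value = numeric(), fdr = numeric(),
                      direction = character(), best_window = integer(),
                      stringsAsFactors = FALSE)
  if (length(sig) == 0L) return(empty)
  out <- list()
  for (pid in unique(bw$win_promoter[sig])) {
    wi <- sig[bw$win_promoter[sig] == pid]
    wi <- wi[order(bw$win_from[wi])]
    cur_from <- bw$win_from[wi[1L]]; cur_to <- bw$win_to[wi[1L]]
    members <- wi[1L]
    flush <- function(from, to, members) {
      probes <- from:to
      best <- members[which.min(p_win[members])]
      md <- mean(mean_diff[probes])
      data.frame(
        dmr_id = NA_character_, chrom = bw$probes$chrom[from],
        start = min(bw$probes$start[probes]), end = max(bw$probes$end[probes]),
        promoter_id = pid,
        gene_symbol = universe$promoters$gene_symbol[
          match(pid, universe$promoters$promoter_id)],
        n_probes = length(probes), score = S_obs[best], p_value = p_win[best],
        fdr = NA_real_, direction = if (md >= 0) "hyper" else "hypo",
        best_window = best, stringsAsFactors = FALSE)
    }
    for (w in wi[-1L]) {
      if (bw$win_from[w] <= cur_to) {
        cur_to <- max(cur_to, bw$win_to[w])
        members <- c(members, w)
      } else {
        out[[length(out) + 1L]] <- flush(cur_from, cur_to, members)
        cur_from <- bw$win_from[w]; cur_to <- bw$win_to[w]; members <- w
      }
    }
    out[[length(out) + 1L]] <- flush(cur_from, cur_to, members)
  }
  do.call(rbind, out)
}

#' DMR-associated genes
#'
#' Unique, sorted gene symbols of promoters containing at least one DMR;
#' multiple DMRs in one promoter collapse to one gene.
#'
#' @param dmrs a [DMRSet].
#' @param universe the matching [PromoterUniverse].
#' @return character vector of gene symbols.
#' @export
dmr_genes <- function(dmrs, universe) {
  stopifnot(inherits(dmrs, "DMRSet"), inherits(universe, "PromoterUniverse"))
  if (nrow(dmrs$dmrs) == 0L) return(character())
  if (!all(dmrs$dmrs$promoter_id %in% universe$promoters$promoter_id))
    stop("DMR promoter(s) not in universe")
  sort(unique(universe$promoters$gene_symbol[
    match(unique(dmrs$dmrs$promoter_id), universe$promoters$promoter_id)]))
}
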