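# Fixture builders and independent brute-force oracles used across the
# suite. Oracles are deliberately slow and simple (plain loops, stats::t.test)
# and share no code with the package's vectorised implementations.

tiny_universe <- function(n_promoters = 2L, probes_per = 4L, width = 1000L,
                          gap = 9000L) {
  start <- (seq_len(n_promoters) - 1L) * (width + gap)
  promoters <- data.frame(
    promoter_id = sprintf("P%02d", seq_len(n_promoters)), chrom = "chrT",
    start = start, end = start + width, strand = "+",
    gene_symbol = sprintf("G%02d", seq_len(n_promoters)),
    stringsAsFactors = FALSE)
  offs <- as.integer(round(seq(0L, width - 50L, length.out = probes_per)))
  probes <- data.frame(
    probe_id = sprintf("P%02d_p%d", rep(seq_len(n_promoters), each = probes_per),
                       rep(seq_len(probes_per), n_promoters)),
    promoter_id = rep(promoters$promoter_id, each = probes_per),
    chrom = "chrT",
    start = rep(start, each = probes_per) + rep(offs, n_promoters),
    stringsAsFactors = FALSE)
  probes$end <- probes$start + 50L
  PromoterUniverse(promoters, probes)
}

make_sheet <- function(n_sz = 3L, n_ct = 3L, cell_type = "neuron", pH = 6.6) {
  SampleSheet(data.frame(
    sample_id = c(sprintf("SZ%02d", seq_len(n_sz)), sprintf("CT%02d", seq_len(n_ct))),
    group = c(rep("SZ", n_sz), rep("CT", n_ct)),
    cell_type = cell_type, brain_pH = pH, stringsAsFactors = FALSE))
}

make_signal_matrix <- function(universe, sheet, fill) {
  n <- nrow(universe$probes)
  vals <- matrix(fill, nrow = n, ncol = nrow(sheet), byrow = TRUE)
  rownames(vals) <- universe$probes$probe_id
  colnames(vals) <- sheet$sample_id
  ProbeSignalMatrix(vals, sheet)
}

# Hand-built probe_stats object (window-level tests craft t-values directly).
make_probe_stats <- function(probe_id, t_value, mean_diff = t_value, df = 4,
                             cell_type = "neuron") {
  out <- data.frame(probe_id = probe_id, t_value = t_value, df = df,
                    mean_diff = mean_diff, stringsAsFactors = FALSE)
  attr(out, "cell_type") <- cell_type
  class(out) <- c("probe_stats", "data.frame")
  out
}

# Welch oracle: loop of stats::t.test calls.
oracle_welch <- function(X, groups) {
  res <- lapply(seq_len(nrow(X)), function(i) {
    tt <- stats::t.test(X[i, groups == "SZ"], X[i, groups == "CT"],
                        var.equal = FALSE)
    c(t = unname(tt$statistic), df = unname(tt$parameter),
      p = unname(tt$p.value))
  })
  do.call(rbind, res)
}

# Brute-force all-pairs interval overlap count (0-based half-open).
oracle_overlap_count <- function(promoters, intervals) {
  hits <- logical(nrow(promoters))
  for (i in seq_len(nrow(promoters))) {
    for (j in seq_len(nrow(intervals))) {
      if (promoters$chrom[i] == intervals$chrom[j] &&
          promoters$start[i] < intervals$end[j] &&
          intervals$start[j] < promoters$end[i]) {
        hits[i] <- TRUE
        break
      }
    }
  }
  hits
}

# Brute-force per-promoter DMR detection with a label-permutation max-|S|
# null, written with plain loops. Returns TRUE/FALSE detection (any window
# with permutation p < threshold) and the sign of the mean difference over
# the promoter's probes, for each requested promoter.
oracle_detect_promoters <- function(matrix, universe, promoter_ids,
                                    min_probes = 4L, threshold_p = 1e-3,
                                    n_perm = 1000L, seed = 1L) {
  set.seed(seed)
  groups <- matrix$sheet$group
  n_sz <- sum(groups == "SZ")
  n <- length(groups)
  welch_t <- function(x, is_sz) {
    a <- x[is_sz]; b <- x[!is_sz]
    v1 <- max(stats::var(a), 1e-12); v2 <- max(stats::var(b), 1e-12)
    (mean(a) - mean(b)) / sqrt(v1 / length(a) + v2 / length(b))
  }
  window_max_S <- function(X, is_sz) {
    m <- nrow(X)
    ts <- numeric(m)
    for (i in seq_len(m)) ts[i] <- welch_t(X[i, ], is_sz)
    n_win <- m - min_probes + 1L
    best <- 0
    for (w in seq_len(n_win)) {
      S <- sum(ts[w:(w + min_probes - 1L)]) / sqrt(min_probes)
      if (abs(S) > best) best <- abs(S)
    }
    best
  }
  detected <- logical(length(promoter_ids))
  sign_diff <- character(length(promoter_ids))
  is_sz_obs <- groups == "SZ"
  for (k in seq_along(promoter_ids)) {
    pid <- promoter_ids[k]
    pr <- universe$probes[universe$probes$promoter_id == pid, ]
    pr <- pr[order(pr$start), ]
    X <- matrix$values[pr$probe_id, , drop = FALSE]
    obs <- window_max_S(X, is_sz_obs)
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      perm_sz <- logical(n)
      perm_sz[sample.int(n, n_sz)] <- TRUE
      if (window_max_S(X, perm_sz) >= obs) cnt <- cnt + 1L
    }
    detected[k] <- (1 + cnt) / (n_perm + 1) < threshold_p
    md <- mean(rowMeans(X[, is_sz_obs, drop = FALSE]) -
               rowMeans(X[, !is_sz_obs, drop = FALSE]))
    sign_diff[k] <- if (md >= 0) "hyper" else "hypo"
  }
  list(detected = detected, direction = sign_diff)
}
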