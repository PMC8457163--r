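test_that("per-probe Welch statistics match the closed form and t.test", {
  u <- tiny_universe(1L, 2L)
  sheet <- make_sheet(3L, 3L)
  # every probe: SZ = [1,2,3], CT = [4,5,6]
  m <- make_signal_matrix(u, sheet, c(1, 2, 3, 4, 5, 6))
  st <- probe_stats(m)
  expect_equal(st$t_value, rep(-3 / sqrt(2 / 3), 2L), tolerance = 1e-12)
  expect_equal(st$t_value, rep(-3.674, 2L), tolerance = 1e-3)
  expect_equal(st$df, rep(4, 2L), tolerance = 1e-12)
  expect_equal(st$mean_diff, rep(-3, 2L), tolerance = 1e-12)

  # random fixture vs stats::t.test oracle at 1e-10 relative tolerance
  set.seed(7)
  sheet2 <- make_sheet(9L, 7L)
  vals <- matrix(rnorm(50L * 16L), 50L, 16L,
                 dimnames = list(sprintf("pr%02d", 1:50), sheet2$sample_id))
  u2 <- tiny_universe(25L, 2L)
  rownames(vals) <- u2$probes$probe_id
  st2 <- probe_stats(ProbeSignalMatrix(vals, sheet2))
  orc <- oracle_welch(vals, sheet2$group)
  expect_equal(st2$t_value, unname(orc[, "t"]), tolerance = 1e-10)
  expect_equal(st2$df, unname(orc[, "df"]), tolerance = 1e-10)
})

test_that("probe statistics are invariant to sample order and degenerate variance", {
  sheet <- make_sheet(4L, 4L)
  u <- tiny_universe(2L, 3L)
  set.seed(11)
  vals <- matrix(rnorm(48L), 6L, 8L,
                 dimnames = list(u$probes$probe_id, sheet$sample_id))
  st <- probe_stats(ProbeSignalMatrix(vals, sheet))
  perm <- sample(8L)
  st_perm <- probe_stats(ProbeSignalMatrix(vals[, perm],
                                           as.data.frame(sheet)[perm, ]))
  expect_equal(st_perm$t_value, st$t_value, tolerance = 1e-12)

  # identical group means with zero noise -> t = 0 via the variance floor
  m0 <- make_signal_matrix(u, sheet, rep(1, 8L))
  expect_true(all(probe_stats(m0)$t_value == 0))

  # a group with < 2 samples is an error
  expect_error(probe_stats(ProbeSignalMatrix(
    vals[, c(1, 5:8)], as.data.frame(sheet)[c(1, 5:8), ])), "at least 2")
})

test_that("window scores follow the Stouffer closed form", {
  u <- tiny_universe(1L, 4L)
  st <- make_probe_stats(u$probes$probe_id, t_value = rep(3, 4L))
  d <- call_dmrs(st, u, threshold_p = 1e-5, threshold_label = "relaxed")
  expect_equal(nrow(d$dmrs), 1L)
  expect_equal(d$dmrs$score, 6.0, tolerance = 1e-12)
  expect_equal(d$dmrs$p_value, 2 * pnorm(-6), tolerance = 1e-12)
  expect_equal(d$dmrs$direction, "hyper")
  expect_equal(d$dmrs$n_probes, 4L)

  # all t = 0 -> empty set
  st0 <- make_probe_stats(u$probes$probe_id, t_value = rep(0, 4L))
  expect_equal(nrow(call_dmrs(st0, u, threshold_p = 1e-5,
                              threshold_label = "relaxed")$dmrs), 0L)
})

test_that("DMR sets are monotone in the p-value threshold", {
  set.seed(13)
  u <- tiny_universe(30L, 6L)
  st <- make_probe_stats(u$probes$probe_id,
                         t_value = rnorm(nrow(u$probes), 0, 3),
                         mean_diff = rnorm(nrow(u$probes)))
  thresholds <- c(1e-3, 1e-5, 1e-8)
  sets <- lapply(thresholds, function(th)
    call_dmrs(st, u, threshold_p = th, threshold_label = "relaxed"))
  for (i in 2:length(sets)) {
    strict <- sets[[i]]$dmrs$promoter_id
    loose <- sets[[i - 1L]]$dmrs$promoter_id
    expect_true(all(strict %in% loose))
  }
})

test_that("overlapping significant windows merge into one spanning DMR", {
  u <- tiny_universe(1L, 8L)
  # probes 1..6 carry S = -10 windows (1-4),(2-5),(3-6); the later windows
  # (4-7) S = -5 and (5-8) S = 0 stay above the 1e-8 threshold
  st <- make_probe_stats(u$probes$probe_id,
                         t_value = c(rep(-5, 6L), 5, 5),
                         mean_diff = c(rep(-1, 6L), 1, 1))
  d <- call_dmrs(st, u, threshold_p = 1e-8, threshold_label = "relaxed")
  expect_equal(nrow(d$dmrs), 1L)
  expect_equal(d$dmrs$n_probes, 6L)
  expect_equal(d$dmrs$direction, "hypo")
  expect_equal(d$dmrs$score, -10, tolerance = 1e-12)
  expect_equal(d$dmrs$start, min(u$probes$start[1:6]))
  expect_equal(d$dmrs$end, max(u$probes$end[1:6]))
})

test_that("probe gaps above max_gap_bp split windows and small promoters are skipped", {
  # two probe clusters 5 kb apart within one wide promoter
  promoters <- data.frame(promoter_id = "P01", chrom = "chrT", start = 0L,
                          end = 20000L, strand = "+", gene_symbol = "G01")
  starts <- c(0L, 100L, 200L, 300L, 6000L, 6100L, 6200L, 6300L)
  probes <- data.frame(probe_id = sprintf("p%d", 1:8), promoter_id = "P01",
                       chrom = "chrT", start = starts, end = starts + 50L)
  u <- PromoterUniverse(promoters, probes)
  st <- make_probe_stats(probes$probe_id, t_value = rep(4, 8L))
  d <- call_dmrs(st, u, threshold_p = 1e-3, threshold_label = "relaxed",
                 max_gap_bp = 300L)
  # the two runs cannot merge across the gap: two DMRs of 4 probes each
  expect_equal(nrow(d$dmrs), 2L)
  expect_equal(d$dmrs$n_probes, c(4L, 4L))

  # promoter with fewer than min_probes probes is skipped with a message
  u2 <- tiny_universe(2L, 3L)
  st2 <- make_probe_stats(u2$probes$probe_id, t_value = rep(5, 6L))
  expect_message(d2 <- call_dmrs(st2, u2, threshold_p = 1e-3,
                                 threshold_label = "relaxed"), "skipped")
  expect_equal(nrow(d2$dmrs), 0L)
})

test_that("analytic and permutation p-values agree on independent-noise single windows", {
  # the permutation null conditions on the observed data, so agreement with
  # the analytic normal tail is asymptotic in sample size; test at n = 100
  # per group where the conditional cross-probe terms are small
  cfg <- sim_config(n_promoters = 150L, probes_per_promoter = 4L,
                    n_case = 100L, n_control = 100L,
                    probe_correlation = 0, dmr_fraction = 0, seed = 17L)
  u <- generate_universe(cfg)
  m <- generate_methylation_dataset(u, cfg)$matrices$neuron
  st <- probe_stats(m)
  da <- call_dmrs(st, u, threshold_p = 1, threshold_label = "relaxed")
  dp <- call_dmrs(st, u, threshold_p = 1, threshold_label = "relaxed",
                  null = "permutation", matrix = m, n_perm = 20000L, seed = 5L)
  pa <- da$dmrs$p_value[match(dp$dmrs$promoter_id, da$dmrs$promoter_id)]
  pp <- dp$dmrs$p_value
  # compare where the permutation resolution supports it
  keep <- pa > 0.02 & pa < 0.5
  expect_gt(sum(keep), 40L)
  expect_lt(max(abs(log10(pa[keep]) - log10(pp[keep]))), 0.3)
})

test_that("permutation null requires the matrix and enough permutations", {
  u <- tiny_universe(1L, 4L)
  st <- make_probe_stats(u$probes$probe_id, t_value = rep(3, 4L))
  expect_error(call_dmrs(st, u, null = "permutation", threshold_p = 0.05,
                         threshold_label = "relaxed"), "requires")
  sheet <- make_sheet(3L, 3L)
  m <- make_signal_matrix(u, sheet, rnorm(6))
  expect_error(call_dmrs(st, u, null = "permutation", matrix = m,
                         n_perm = 50L, threshold_p = 0.05,
                         threshold_label = "relaxed"), ">= 100")
})

test_that("DMR-associated genes collapse promoter multiplicity", {
  u <- tiny_universe(3L, 8L)
  expect_equal(dmr_genes(DMRSet(data.frame(), 1e-5, "relaxed", "neuron"), u),
               character())
  mk_dmr <- function(pid, s, e, i) data.frame(
    dmr_id = sprintf("D%d", i), chrom = "chrT", start = s, end = e,
    promoter_id = pid, gene_symbol = u$promoters$gene_symbol[
      match(pid, u$promoters$promoter_id)],
    n_probes = 4L, score = 6, p_value = 1e-9, fdr = 1e-6,
    direction = "hyper", stringsAsFactors = FALSE)
  # two DMRs in the same promoter -> one gene
  two <- DMRSet(rbind(mk_dmr("P01", 0L, 200L, 1L), mk_dmr("P01", 400L, 600L, 2L)),
                1e-5, "relaxed", "neuron")
  expect_equal(dmr_genes(two, u), "G01")

  # a set whose multiplicity structure collapses many DMRs to fewer genes:
  # 91 DMRs spread over 69 promoters -> exactly 69 genes
  cfg <- sim_config(n_promoters = 69L, seed = 1L)
  u69 <- generate_universe(cfg)
  prom <- u69$promoters$promoter_id[c(seq_len(69L), seq_len(91L - 69L))]
  rows <- lapply(seq_along(prom), function(i) {
    p <- u69$promoters[match(prom[i], u69$promoters$promoter_id), ]
    data.frame(dmr_id = sprintf("D%03d", i), chrom = p$chrom,
               start = p$start + (i %% 2L) * 500L,
               end = p$start + (i %% 2L) * 500L + 300L,
               promoter_id = p$promoter_id, gene_symbol = p$gene_symbol,
               n_probes = 4L, score = 6, p_value = 1e-9, fdr = 1e-6,
               direction = "hyper", stringsAsFactors = FALSE)
  })
  big <- DMRSet(do.call(rbind, rows), 1e-5, "relaxed", "nonneuron")
  expect_equal(nrow(big$dmrs), 91L)
  expect_equal(length(dmr_genes(big, u69)), 69L)
})
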