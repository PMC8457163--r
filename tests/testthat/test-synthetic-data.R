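test_that("generated universes have the requested layout and are disjoint", {
  cfg <- sim_config(n_promoters = 10L, probes_per_promoter = 5L, seed = 3L)
  u <- generate_universe(cfg)
  expect_equal(nrow(u$promoters), 10L)
  expect_equal(nrow(u$probes), 50L)

  # brute-force all-pairs disjointness
  p <- u$promoters
  for (i in seq_len(nrow(p) - 1L)) {
    for (j in (i + 1L):nrow(p)) {
      same <- p$chrom[i] == p$chrom[j] &&
        p$start[i] < p$end[j] && p$start[j] < p$end[i]
      expect_false(same)
    }
  }
})

test_that("all generators are byte-identical under a fixed seed", {
  cfg <- sim_config(n_promoters = 40L, n_case = 6L, n_control = 6L, seed = 9L)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1, s2)
  loci1 <- generate_gwas_loci(s1$universe, 10L, "enriched", s1$truth, seed = 4L)
  loci2 <- generate_gwas_loci(s2$universe, 10L, "enriched", s2$truth, seed = 4L)
  expect_identical(loci1, loci2)
})

test_that("dmr_fraction = 0 yields a null dataset with an empty truth table", {
  cfg <- sim_config(n_promoters = 30L, dmr_fraction = 0, n_case = 5L,
                    n_control = 5L, seed = 2L)
  u <- generate_universe(cfg)
  meth <- generate_methylation_dataset(u, cfg)
  expect_equal(nrow(meth$truth$planted_dmrs), 0L)
  # group means differ only by noise: all |diff| well below effect-size scale
  m <- meth$matrices$neuron
  d <- rowMeans(m$values[, m$sheet$group == "SZ"]) -
    rowMeans(m$values[, m$sheet$group == "CT"])
  expect_lt(max(abs(d)), 6 * cfg$noise_sd * sqrt(2 / 5))
})

test_that("planted case-control differences equal effect_delta in the noise-free limit", {
  cfg <- sim_config(n_promoters = 20L, dmr_fraction = 0.5, effect_delta = 2,
                    noise_sd = 1e-9, n_case = 4L, n_control = 4L, seed = 5L)
  u <- generate_universe(cfg)
  meth <- generate_methylation_dataset(u, cfg)
  for (ct in c("neuron", "nonneuron")) {
    m <- meth$matrices[[ct]]
    d <- rowMeans(m$values[, m$sheet$group == "SZ"]) -
      rowMeans(m$values[, m$sheet$group == "CT"])
    plants <- meth$truth$planted_dmrs
    plants <- plants[plants$cell_type == ct, ]
    planted_probes <- u$probes$probe_id[u$probes$promoter_id %in% plants$promoter_id]
    expected <- plants$effect_delta[match(
      u$probes$promoter_id[match(planted_probes, u$probes$probe_id)],
      plants$promoter_id)]
    expect_equal(unname(d[planted_probes]), expected, tolerance = 1e-6)
    expect_lt(max(abs(d[setdiff(names(d), planted_probes)])), 1e-6)
  }
})

test_that("planted DMR sharing between cell types follows shared_fraction", {
  cfg <- sim_config(n_promoters = 100L, dmr_fraction = 0.2,
                    shared_fraction = 0.6, n_case = 3L, n_control = 3L,
                    seed = 8L)
  meth <- generate_methylation_dataset(generate_universe(cfg), cfg)
  plants <- meth$truth$planted_dmrs
  neu <- plants[plants$cell_type == "neuron", ]
  non <- plants[plants$cell_type == "nonneuron", ]
  expect_equal(nrow(neu), 20L)
  expect_equal(nrow(non), 20L)
  shared <- intersect(neu$promoter_id, non$promoter_id)
  expect_equal(length(shared), 12L)  # round(0.6 * 20)
  # shared plants carry the same direction in both cell types
  expect_identical(neu$direction[match(shared, neu$promoter_id)],
                   non$direction[match(shared, non$promoter_id)])
})

test_that("within-promoter probe correlation is near zero when rho = 0", {
  cfg <- sim_config(n_promoters = 60L, dmr_fraction = 0,
                    probe_correlation = 0, n_case = 30L, n_control = 30L,
                    seed = 12L)
  u <- generate_universe(cfg)
  m <- generate_methylation_dataset(u, cfg)$matrices$neuron
  n <- ncol(m$values)
  # mean pairwise correlation between first two probes of each promoter
  first <- m$values[seq(1L, nrow(m$values), by = cfg$probes_per_promoter), ]
  second <- m$values[seq(2L, nrow(m$values), by = cfg$probes_per_promoter), ]
  r <- vapply(seq_len(nrow(first)),
              function(i) cor(first[i, ], second[i, ]), numeric(1L))
  # Fisher bound on the mean of 60 null correlations at n = 60
  expect_lt(abs(mean(r)), 3 / sqrt(n * length(r)))
  expect_lt(max(abs(r)), 4 / sqrt(n - 3))
})

test_that("GWAS locus regimes behave as constructed", {
  cfg <- sim_config(n_promoters = 80L, dmr_fraction = 0.25, n_case = 3L,
                    n_control = 3L, seed = 21L)
  u <- generate_universe(cfg)
  meth <- generate_methylation_dataset(u, cfg)
  planted <- unique(meth$truth$planted_dmrs$promoter_id)

  expect_equal(nrow(generate_gwas_loci(u, 0L, "neutral", meth$truth,
                                       seed = 1L)$intervals), 0L)

  # depleted: zero loci overlap planted promoters, by brute force
  dep <- generate_gwas_loci(u, 30L, "depleted", meth$truth, seed = 2L)
  pl <- u$promoters[u$promoters$promoter_id %in% planted, ]
  expect_false(any(oracle_overlap_count(pl, dep$intervals)))

  # enriched with weight 5 overlaps plants more often than neutral
  frac_planted <- function(regime, seed) {
    loci <- generate_gwas_loci(u, 20L, regime, meth$truth, seed = seed)
    mean(oracle_overlap_count(pl, loci$intervals))
  }
  enr <- vapply(1:100, function(s) frac_planted("enriched", s), numeric(1L))
  neu <- vapply(1:100, function(s) frac_planted("neutral", s), numeric(1L))
  expect_gt(mean(enr), mean(neu))
})

test_that("planted expression changes are recoverable at the configured power", {
  # direct-simulation power oracle: fc = 1.5, sd = 0.5, n = 35/35
  set.seed(31L)
  oracle_hits <- vapply(seq_len(200L), function(i) {
    stats::t.test(rnorm(35L, 1.5, 0.5), rnorm(35L, 0, 0.5))$p.value < 0.05
  }, logical(1L))
  expect_gte(mean(oracle_hits), 0.95)

  # generator + Welch pipeline recover planted DE genes at the same power
  hits <- integer(); total <- integer()
  for (rep in 1:20) {
    cfg <- sim_config(n_promoters = 30L, dmr_fraction = 0.4, de_fraction = 1,
                      expr_log2fc = 1.5, expr_noise_sd = 0.5,
                      unreliable_fraction = 0, low_pH_fraction = 0,
                      seed = 100L + rep)
    u <- generate_universe(cfg)
    meth <- generate_methylation_dataset(u, cfg)
    ex <- generate_expression_dataset(u, cfg, meth$truth)
    res <- test_dmr_gene_expression(ex$expression,
                                    ex$truth$de_genes$gene_symbol)
    sig_genes <- unique(res$gene_symbol[res$significant])
    hits <- c(hits, sum(ex$truth$de_genes$gene_symbol %in% sig_genes))
    total <- c(total, nrow(ex$truth$de_genes))
  }
  expect_gte(sum(hits) / sum(total), 0.95)
})

test_that("expression generator honours pH and reliability knobs", {
  cfg <- sim_config(n_promoters = 40L, dmr_fraction = 0.2,
                    low_pH_fraction = 0, unreliable_fraction = 0.25,
                    seed = 44L)
  u <- generate_universe(cfg)
  meth <- generate_methylation_dataset(u, cfg)
  ex <- generate_expression_dataset(u, cfg, meth$truth)
  # low_pH_fraction = 0: the pH filter removes nobody
  kept <- exclude_low_ph(ex$expression, cutoff = cfg$pH_cutoff)
  expect_equal(ncol(kept$values), ncol(ex$expression$values))
  # planted unreliable probes removed at 100%, reliable retained at 100%
  unrel <- attr(ex$truth, "unreliable_probes")
  expect_gt(length(unrel), 0L)
  filt <- filter_reliable(kept, floor = cfg$expr_floor)
  expect_false(any(unrel %in% rownames(filt$values)))
  expect_setequal(rownames(filt$values),
                  setdiff(rownames(ex$expression$values), unrel))
})

test_that("simulation artifacts round-trip through the on-disk formats", {
  cfg <- sim_config(n_promoters = 15L, n_case = 3L, n_control = 3L,
                    dmr_fraction = 0.2, seed = 77L)
  sim <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  u <- read_promoter_universe(file.path(dir, "promoters.bed"),
                              file.path(dir, "probes.bed"))
  expect_identical(u, sim$universe)
  sheet <- read_sample_sheet(file.path(dir, "samples_neuron.tsv"))
  m <- read_probe_matrix(file.path(dir, "methylation_neuron.tsv"), sheet)
  expect_identical(m$values, sim$matrices$neuron$values)
  truth <- read.table(file.path(dir, "truth_dmrs.tsv"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(truth), nrow(sim$truth$planted_dmrs))
})
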