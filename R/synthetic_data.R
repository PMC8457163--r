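# Synthetic benchmark generator: promoter-tiled probes, two groups x two
# sorted cell types, planted DMRs with exchangeable within-promoter noise
# correlation, GWAS loci under neutral/enriched/depleted regimes, and matched
# bulk expression with planted differential genes. Every planted signal is
# recorded in a TruthTable so recovery and calibration can be scored.

#' Simulation configuration
#'
#' Defaults emulate the structure of a 25,500-promoter tiling-array
#' case-control study (35 cases vs 35 controls, neuronal and nonneuronal
#' nuclei fractions) at a reduced universe of 2,000 promoters x 8 probes.
#'
#' @param n_promoters number of promoters in the synthetic universe.
#' @param probes_per_promoter probes tiled evenly across each promoter.
#' @param promoter_width promoter width in bp.
#' @param n_case,n_control subjects per group (SZ cases, CT controls).
#' @param noise_sd marginal sd of the log2-signal noise.
#' @param probe_correlation exchangeable within-promoter noise correlation
#'   rho in \[0, 1).
#' @param dmr_fraction fraction of promoters carrying a planted DMR per cell
#'   type.
#' @param effect_delta log2-signal shift added to case samples on planted
#'   promoters (applied over the whole probe span).
#' @param shared_fraction fraction of each cell type's planted DMRs shared
#'   (same promoter, same direction) with the other cell type.
#' @param pH_mean,pH_sd brain-pH distribution for subjects not in the low-pH
#'   tail.
#' @param low_pH_fraction fraction of subjects forced below `pH_cutoff`.
#' @param pH_cutoff boundary defining the low-pH tail (matches the expression
#'   filter's default).
#' @param expr_log2fc planted expression log2 fold change (SZ vs CT).
#' @param expr_noise_sd subject-level sd of log2 expression.
#' @param de_fraction fraction of planted-DMR genes given a planted
#'   expression change.
#' @param unreliable_fraction fraction of expression probes emitted at the
#'   noise floor (to exercise the reliability filter).
#' @param expr_floor log2 noise-floor used when planting unreliable probes.
#' @param seed master RNG seed (integer below 2^31).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_promoters = 2000L, probes_per_promoter = 8L,
                       promoter_width = 1000L, n_case = 35L, n_control = 35L,
                       noise_sd = 0.5, probe_correlation = 0.3,
                       dmr_fraction = 0.05, effect_delta = 0.5,
                       shared_fraction = 0.6, pH_mean = 6.5, pH_sd = 0.25,
                       low_pH_fraction = 0.1, pH_cutoff = 6.0,
                       expr_log2fc = 1.5, expr_noise_sd = 0.5,
                       de_fraction = 0.2, unreliable_fraction = 0.1,
                       expr_floor = 5, seed = 1L) {
  cfg <- list(n_promoters = as.integer(n_promoters),
              probes_per_promoter = as.integer(probes_per_promoter),
              promoter_width = as.integer(promoter_width),
              n_case = as.integer(n_case), n_control = as.integer(n_control),
              noise_sd = noise_sd, probe_correlation = probe_correlation,
              dmr_fraction = dmr_fraction, effect_delta = effect_delta,
              shared_fraction = shared_fraction, pH_mean = pH_mean,
              pH_sd = pH_sd, low_pH_fraction = low_pH_fraction,
              pH_cutoff = pH_cutoff, expr_log2fc = expr_log2fc,
              expr_noise_sd = expr_noise_sd, de_fraction = de_fraction,
              unreliable_fraction = unreliable_fraction,
              expr_floor = expr_floor, seed = as.integer(seed))
  counts <- c("n_promoters", "probes_per_promoter", "promoter_width",
              "n_case", "n_control")
  for (nm in counts) if (cfg[[nm]] <= 0L) stop(nm, " must be > 0")
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (cfg$probe_correlation < 0 || cfg$probe_correlation >= 1)
    stop("probe_correlation must be in [0, 1)")
  if (cfg$dmr_fraction < 0 || cfg$dmr_fraction > 1)
    stop("dmr_fraction must be in [0, 1]")
  if (cfg$shared_fraction < 0 || cfg$shared_fraction > 1)
    stop("shared_fraction must be in [0, 1]")
  if (is.na(cfg$seed) || abs(seed) >= 2^31) stop("seed must be a 32-bit integer")
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @param path YAML file whose keys are `sim_config()` arguments.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown))
    stop("unknown sim config key(s): ", paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}

#' Generate a synthetic promoter universe
#'
#' Promoters are laid out non-overlapping on synthetic chromosomes (100 per
#' chromosome, 10 kb pitch) with `probes_per_promoter` 50-bp probes evenly
#' spaced inside each promoter; one gene symbol per promoter. The layout is
#' fully deterministic given the configuration.
#'
#' @param cfg a [sim_config()].
#' @return A [PromoterUniverse].
#' @export
generate_universe <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_promoters
  per_chrom <- 100L
  chrom_i <- (seq_len(n) - 1L) %/% per_chrom + 1L
  within_i <- (seq_len(n) - 1L) %% per_chrom
  start <- within_i * 10000L
  promoters <- data.frame(
    promoter_id = sprintf("P%05d", seq_len(n)),
    chrom = sprintf("chrS%d", chrom_i),
    start = start, end = start + cfg$promoter_width,
    strand = rep_len(c("+", "-"), n),
    gene_symbol = sprintf("GENE%05d", seq_len(n)),
    stringsAsFactors = FALSE)
  m <- cfg$probes_per_promoter
  probe_w <- min(50L, cfg$promoter_width %/% m)
  offs <- if (m == 1L) 0L else
    as.integer(round(seq(0L, cfg$promoter_width - probe_w, length.out = m)))
  probes <- data.frame(
    probe_id = sprintf("P%05d_p%02d", rep(seq_len(n), each = m),
                       rep(seq_len(m), n)),
    promoter_id = rep(promoters$promoter_id, each = m),
    chrom = rep(promoters$chrom, each = m),
    start = rep(promoters$start, each = m) + rep(offs, n),
    stringsAsFactors = FALSE)
  probes$end <- probes$start + probe_w
  PromoterUniverse(promoters, probes)
}

# Subject-level metadata shared between the methylation and expression
# generators (same subjects, same pH), deterministic given cfg$seed.
generate_subjects <- function(cfg) {
  with_seed(cfg$seed, {
    n <- cfg$n_case + cfg$n_control
    ids <- c(sprintf("SZ%02d", seq_len(cfg$n_case)),
             sprintf("CT%02d", seq_len(cfg$n_control)))
    group <- c(rep("SZ", cfg$n_case), rep("CT", cfg$n_control))
    n_low <- round(cfg$low_pH_fraction * n)
    low <- sample.int(n, n_low)
    pH <- stats::rnorm(n, cfg$pH_mean, cfg$pH_sd)
    # force the planted tail below the cutoff and everyone else above it
    pH[low] <- cfg$pH_cutoff - 0.1 - abs(stats::rnorm(n_low, 0, 0.15))
    hi <- setdiff(seq_len(n), low)
    pH[hi] <- pmax(pH[hi], cfg$pH_cutoff + 0.05)
    data.frame(sample_id = ids, group = group, brain_pH = round(pH, 2),
               stringsAsFactors = FALSE)
  })
}

#' Generate per-cell-type methylation signal with planted DMRs
#'
#' For each cell type (neuron, nonneuron), probe values are baseline +
#' case-group shift on planted promoters + Gaussian noise with exchangeable
#' within-promoter correlation (`probe_correlation`, marginal sd `noise_sd`).
#' A `shared_fraction` of each cell type's planted DMRs sits on the same
#' promoters, with the same direction, in both cell types. Every plant is
#' recorded in the returned truth table.
#'
#' @param universe a [PromoterUniverse], typically from [generate_universe()].
#' @param cfg a [sim_config()].
#' @return A list with `matrices` (named list of [ProbeSignalMatrix] for
#'   `neuron` and `nonneuron`), `truth` (a `TruthTable`: data.frames
#'   `planted_dmrs` and `de_genes`), and `subjects` (subject-level
#'   data.frame).
#' @export
generate_methylation_dataset <- function(universe, cfg) {
  stopifnot(inherits(universe, "PromoterUniverse"), inherits(cfg, "sim_config"))
  n_prom <- nrow(universe$promoters)
  m <- cfg$probes_per_promoter
  subjects <- generate_subjects(cfg)

  with_seed(cfg$seed + 1L, {
    n_dmr <- round(cfg$dmr_fraction * n_prom)
    if (cfg$dmr_fraction > 0 && n_dmr < 1L) {
      warning("dmr_fraction * n_promoters < 1; planting zero DMRs")
      n_dmr <- 0L
    }
    plants <- .plan_plants(universe, cfg, n_dmr)
    mats <- list()
    for (ct in c("neuron", "nonneuron")) {
      mats[[ct]] <- .simulate_celltype_matrix(universe, cfg, subjects,
                                              plants[plants$cell_type == ct, ])
    }
    truth <- structure(list(planted_dmrs = plants,
                            de_genes = data.frame(gene_symbol = character(),
                                                  expression_log2fc = numeric(),
                                                  stringsAsFactors = FALSE)),
                       class = "TruthTable")
    list(matrices = mats, truth = truth, subjects = subjects)
  })
}

# Decide which promoters carry plants per cell type, honouring the shared
# fraction, and assign directions (shared plants keep one direction).
.plan_plants <- function(universe, cfg, n_dmr) {
  empty <- data.frame(promoter_id = character(), cell_type = character(),
                      direction = character(), effect_delta = numeric(),
                      span_start = integer(), span_end = integer(),
                      stringsAsFactors = FALSE)
  if (n_dmr == 0L) return(empty)
  prom_ids <- universe$promoters$promoter_id
  n_shared <- round(cfg$shared_fraction * n_dmr)
  n_unique <- n_dmr - n_shared
  need <- n_shared + 2L * n_unique
  if (need > length(prom_ids))
    stop("dmr_fraction too high to honour shared_fraction without reuse")
  picked <- sample(prom_ids, need)
  shared <- picked[seq_len(n_shared)]
  uniq_neu <- picked[n_shared + seq_len(n_unique)]
  uniq_non <- picked[n_shared + n_unique + seq_len(n_unique)]
  dir_shared <- sample(c("hyper", "hypo"), n_shared, replace = TRUE)
  dir_neu <- sample(c("hyper", "hypo"), n_unique, replace = TRUE)
  dir_non <- sample(c("hyper", "hypo"), n_unique, replace = TRUE)
  m <- cfg$probes_per_promoter
  mk <- function(ids, ct, dirs) {
    if (length(ids) == 0L) return(empty)
    data.frame(promoter_id = ids, cell_type = ct, direction = dirs,
               effect_delta = ifelse(dirs == "hyper", 1, -1) * cfg$effect_delta,
               span_start = 1L, span_end = m, stringsAsFactors = FALSE)
  }
  out <- rbind(mk(shared, "neuron", dir_shared), mk(uniq_neu, "neuron", dir_neu),
               mk(shared, "nonneuron", dir_shared), mk(uniq_non, "nonneuron", dir_non))
  rownames(out) <- NULL
  out
}

.simulate_celltype_matrix <- function(universe, cfg, subjects, plants) {
  ct <- if (nrow(plants)) plants$cell_type[1L] else "neuron"
  n_prom <- nrow(universe$promoters)
  m <- cfg$probes_per_promoter
  n_probe <- nrow(universe$probes)
  n_samp <- nrow(subjects)
  rho <- cfg$probe_correlation
  baseline <- stats::rnorm(n_probe, 0, 1)
  z_prom <- matrix(stats::rnorm(n_prom * n_samp), n_prom, n_samp)
  z_probe <- matrix(stats::rnorm(n_probe * n_samp), n_probe, n_samp)
  prom_of_probe <- match(universe$probes$promoter_id,
                         universe$promoters$promoter_id)
  noise <- cfg$noise_sd * (sqrt(rho) * z_prom[prom_of_probe, , drop = FALSE] +
                           sqrt(1 - rho) * z_probe)
  vals <- baseline + noise
  if (nrow(plants) > 0L) {
    case_cols <- which(subjects$group == "SZ")
    for (i in seq_len(nrow(plants))) {
      pr <- which(universe$probes$promoter_id == plants$promoter_id[i])
      pr <- pr[order(universe$probes$start[pr])]
      span <- pr[plants$span_start[i]:plants$span_end[i]]
      vals[span, case_cols] <- vals[span, case_cols] + plants$effect_delta[i]
    }
  }
  rownames(vals) <- universe$probes$probe_id
  colnames(vals) <- subjects$sample_id
  sheet <- SampleSheet(data.frame(sample_id = subjects$sample_id,
                                  group = subjects$group, cell_type = ct,
                                  brain_pH = subjects$brain_pH,
                                  stringsAsFactors = FALSE))
  ProbeSignalMatrix(vals, sheet)
}

#' Generate synthetic GWAS loci relative to planted DMRs
#'
#' Places each locus over one promoter (the promoter interval plus `flank` on
#' each side). Regimes: `neutral` samples promoters uniformly; `enriched`
#' up-weights promoters carrying a planted DMR by `weight`; `depleted`
#' excludes planted promoters entirely, so zero loci overlap plants by
#' construction.
#'
#' @param universe a [PromoterUniverse].
#' @param n_loci number of loci (must not exceed the eligible promoter
#'   count).
#' @param regime `"neutral"`, `"enriched"` or `"depleted"`.
#' @param truth `TruthTable` from [generate_methylation_dataset()] (defines
#'   the planted promoters).
#' @param seed RNG seed.
#' @param weight sampling weight for planted promoters under `enriched`.
#' @param flank bp added on each side of the chosen promoter.
#' @return An [IntervalSet] named `sim_<regime>`.
#' @export
generate_gwas_loci <- function(universe, n_loci, regime = c("neutral", "enriched", "depleted"),
                               truth, seed = 1L, weight = 5, flank = 500L) {
  regime <- match.arg(regime)
  stopifnot(inherits(universe, "PromoterUniverse"))
  p <- universe$promoters
  planted <- unique(truth$planted_dmrs$promoter_id)
  if (n_loci > nrow(p)) stop("n_loci exceeds the promoter count")
  with_seed(seed, {
    if (regime == "depleted") {
      eligible <- which(!p$promoter_id %in% planted)
      if (length(eligible) == 0L)
        stop("depleted regime impossible: every promoter carries a planted DMR")
      if (n_loci > length(eligible))
        stop("n_loci exceeds the number of unplanted promoters")
      idx <- sample(eligible, n_loci)
    } else if (regime == "enriched") {
      w <- ifelse(p$promoter_id %in% planted, weight, 1)
      idx <- sample.int(nrow(p), n_loci, prob = w)
    } else {
      idx <- sample.int(nrow(p), n_loci)
    }
    iv <- data.frame(chrom = p$chrom[idx],
                     start = pmax(0L, p$start[idx] - as.integer(flank)),
                     end = p$end[idx] + as.integer(flank),
                     stringsAsFactors = FALSE)
    IntervalSet(paste0("sim_", regime), iv[order(iv$chrom, iv$start), ])
  })
}

#' Generate a matched bulk expression dataset with planted DE genes
#'
#' One or two probes per gene, log2 expression baseline Uniform(7.5, 10.5)
#' with Gaussian subject noise. A `de_fraction` of planted-DMR genes receives
#' an `expr_log2fc` shift (random sign) in cases; `unreliable_fraction` of
#' probes are emitted at the noise floor to exercise the reliability filter.
#' Subjects (and their brain pH) are the same as the methylation dataset's.
#'
#' @param universe a [PromoterUniverse].
#' @param cfg a [sim_config()].
#' @param truth `TruthTable` from [generate_methylation_dataset()]; its
#'   `de_genes` table is filled in.
#' @return A list with `expression` (an [ExpressionMatrix]), `sheet` (its
#'   [SampleSheet], cell type `"bulk"`), and `truth` (updated `TruthTable`
#'   with `de_genes` and an `unreliable_probes` character vector attribute).
#' @export
generate_expression_dataset <- function(universe, cfg, truth) {
  stopifnot(inherits(universe, "PromoterUniverse"), inherits(cfg, "sim_config"))
  subjects <- generate_subjects(cfg)
  with_seed(cfg$seed + 2L, {
    genes <- universe$promoters$gene_symbol
    n_probes_per <- sample(1:2, length(genes), replace = TRUE)
    gene_of_probe <- rep(genes, n_probes_per)
    probe_ids <- sprintf("EXPR%05d", seq_along(gene_of_probe))
    n_pr <- length(probe_ids)
    n_s <- nrow(subjects)

    planted_genes <- unique(universe$promoters$gene_symbol[
      universe$promoters$promoter_id %in% truth$planted_dmrs$promoter_id])
    n_de <- round(cfg$de_fraction * length(planted_genes))
    de <- if (n_de > 0L) sample(planted_genes, n_de) else character()
    de_fc <- if (n_de > 0L)
      sample(c(-1, 1), n_de, replace = TRUE) * cfg$expr_log2fc else numeric()

    baseline <- stats::runif(n_pr, 7.5, 10.5)
    vals <- baseline + matrix(stats::rnorm(n_pr * n_s, 0, cfg$expr_noise_sd),
                              n_pr, n_s)
    case_cols <- which(subjects$group == "SZ")
    if (n_de > 0L) {
      for (i in seq_len(n_de)) {
        rows <- which(gene_of_probe == de[i])
        vals[rows, case_cols] <- vals[rows, case_cols] + de_fc[i]
      }
    }
    n_unrel <- round(cfg$unreliable_fraction * n_pr)
    unrel <- if (n_unrel > 0L) sample.int(n_pr, n_unrel) else integer()
    if (n_unrel > 0L)
      vals[unrel, ] <- matrix(stats::rnorm(n_unrel * n_s, cfg$expr_floor - 3, 0.3),
                              n_unrel, n_s)
    rownames(vals) <- probe_ids
    colnames(vals) <- subjects$sample_id
    sheet <- SampleSheet(data.frame(sample_id = subjects$sample_id,
                                    group = subjects$group, cell_type = "bulk",
                                    brain_pH = subjects$brain_pH,
                                    stringsAsFactors = FALSE))
    expr <- ExpressionMatrix(vals, stats::setNames(gene_of_probe, probe_ids),
                             sheet)
    truth$de_genes <- data.frame(gene_symbol = de, expression_log2fc = de_fc,
                                 stringsAsFactors = FALSE)
    attr(truth, "unreliable_probes") <- probe_ids[unrel]
    list(expression = expr, sheet = sheet, truth = truth)
  })
}

#' Run the whole generator and (optionally) write all artifacts
#'
#' @param cfg a [sim_config()].
#' @return A list: `universe`, `matrices` (neuron/nonneuron
#'   [ProbeSignalMatrix]), `expression`, `truth`, `subjects`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  universe <- generate_universe(cfg)
  meth <- generate_methylation_dataset(universe, cfg)
  expr <- generate_expression_dataset(universe, cfg, meth$truth)
  list(universe = universe, matrices = meth$matrices,
       expression = expr$expression, truth = expr$truth,
       subjects = meth$subjects)
}

#' @rdname simulate_study
#' @param sim result of [simulate_study()].
#' @param dir output directory (created if needed); writes promoter/probe
#'   BEDs, per-cell-type matrices and sheets, the expression matrix and
#'   sheet, and ground-truth TSVs (`truth_dmrs.tsv`, `truth_de_genes.tsv`).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_promoter_universe(sim$universe, file.path(dir, "promoters.bed"),
                          file.path(dir, "probes.bed"))
  for (ct in names(sim$matrices)) {
    write_probe_matrix(sim$matrices[[ct]],
                       file.path(dir, paste0("methylation_", ct, ".tsv")))
    write_sample_sheet(sim$matrices[[ct]]$sheet,
                       file.path(dir, paste0("samples_", ct, ".tsv")))
  }
  write_expression_matrix(sim$expression, file.path(dir, "expression.tsv"))
  write_sample_sheet(sim$expression$sheet, file.path(dir, "samples_expression.tsv"))
  utils::write.table(sim$truth$planted_dmrs, file.path(dir, "truth_dmrs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$de_genes, file.path(dir, "truth_de_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
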