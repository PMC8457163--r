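# Core containers. All genomic coordinates are 0-based half-open (BED
# convention) throughout the package; strand is stored but never used in
# overlap computations.

#' Promoter universe: array promoters with gene symbols and probe layout
#'
#' The promoter universe describes the tiling array: every promoter region on
#' the array (with its gene symbol) and every probe, assigned to exactly one
#' promoter. It is both the DMR caller's coordinate frame and the sampling
#' frame for the resampling null.
#'
#' @param promoters data.frame with columns `promoter_id`, `chrom`, `start`,
#'   `end`, `strand` (`"+"`/`"-"`), `gene_symbol`.
#' @param probes data.frame with columns `probe_id`, `promoter_id`, `chrom`,
#'   `start`, `end`. Each probe must lie within its promoter's interval.
#' @return An object of class `PromoterUniverse`: a list with validated
#'   `promoters` and `probes` data.frames.
#' @examples
#' u <- PromoterUniverse(
#'   promoters = data.frame(promoter_id = "P1", chrom = "chr1", start = 0L,
#'                          end = 1000L, strand = "+", gene_symbol = "GENE1"),
#'   probes = data.frame(probe_id = c("P1_1", "P1_2"), promoter_id = "P1",
#'                       chrom = "chr1", start = c(0L, 500L), end = c(50L, 550L))
#' )
#' u
#' @export
PromoterUniverse <- function(promoters, probes) {
  promoters <- as.data.frame(promoters, stringsAsFactors = FALSE)
  probes <- as.data.frame(probes, stringsAsFactors = FALSE)
  need_p <- c("promoter_id", "chrom", "start", "end", "strand", "gene_symbol")
  need_b <- c("probe_id", "promoter_id", "chrom", "start", "end")
  if (!all(need_p %in% names(promoters)))
    stop("promoters must have columns: ", paste(need_p, collapse = ", "))
  if (!all(need_b %in% names(probes)))
    stop("probes must have columns: ", paste(need_b, collapse = ", "))
  promoters <- promoters[need_p]
  probes <- probes[need_b]
  promoters$start <- as.integer(promoters$start)
  promoters$end <- as.integer(promoters$end)
  probes$start <- as.integer(probes$start)
  probes$end <- as.integer(probes$end)

  if (nrow(promoters) == 0L) stop("promoter universe must contain at least one promoter")
  if (anyDuplicated(promoters$promoter_id))
    stop("duplicated promoter_id: ",
         paste(unique(promoters$promoter_id[duplicated(promoters$promoter_id)]), collapse = ", "))
  if (anyDuplicated(probes$probe_id))
    stop("duplicated probe_id: ",
         paste(unique(probes$probe_id[duplicated(probes$probe_id)]), collapse = ", "))
  .check_intervals(promoters, "promoter")
  if (!all(promoters$strand %in% c("+", "-")))
    stop("promoter strand must be '+' or '-'")
  if (nrow(probes) > 0L) {
    .check_intervals(probes, "probe")
    idx <- match(probes$promoter_id, promoters$promoter_id)
    if (anyNA(idx)) {
      bad <- unique(probes$promoter_id[is.na(idx)])
      stop("probe references unknown promoter_id: ", paste(bad, collapse = ", "))
    }
    inside <- probes$chrom == promoters$chrom[idx] &
      probes$start >= promoters$start[idx] &
      probes$end <= promoters$end[idx]
    if (!all(inside)) {
      stop("probe(s) outside their promoter interval: ",
           paste(probes$probe_id[!inside][seq_len(min(5L, sum(!inside)))], collapse = ", "))
    }
  }
  rownames(promoters) <- NULL
  rownames(probes) <- NULL
  structure(list(promoters = promoters, probes = probes),
            class = "PromoterUniverse")
}

.check_intervals <- function(df, what) {
  if (any(df$start < 0L))
    stop(what, " with negative start coordinate")
  bad <- df$start >= df$end
  if (any(bad)) {
    id_col <- intersect(c("promoter_id", "probe_id"), names(df))[1L]
    stop(what, " with start >= end: ",
         paste(df[[id_col]][bad][seq_len(min(5L, sum(bad)))], collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.PromoterUniverse <- function(x, ...) {
  cat(sprintf("PromoterUniverse: %d promoters, %d probes, %d chromosome(s)\n",
              nrow(x$promoters), nrow(x$probes), length(unique(x$promoters$chrom))))
  invisible(x)
}

#' Sample sheet for case-control, cell-type-sorted samples
#'
#' @param df data.frame with columns `sample_id`, `group` (`"CT"` control or
#'   `"SZ"` case), `cell_type` (`"neuron"`, `"nonneuron"`, or `"bulk"` for
#'   unsorted tissue), `brain_pH` (numeric; `NA` permitted, but samples with
#'   missing pH are excluded from expression analysis unless the pH filter is
#'   disabled).
#' @return Validated data.frame of class `SampleSheet`.
#' @export
SampleSheet <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "cell_type", "brain_pH")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  df$brain_pH <- as.numeric(df$brain_pH)
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in sheet")
  if (!all(df$group %in% c("CT", "SZ")))
    stop("group must be 'CT' or 'SZ'; offending values: ",
         paste(unique(setdiff(df$group, c("CT", "SZ"))), collapse = ", "))
  if (!all(df$cell_type %in% c("neuron", "nonneuron", "bulk")))
    stop("cell_type must be 'neuron', 'nonneuron' or 'bulk'")
  rownames(df) <- NULL
  class(df) <- c("SampleSheet", "data.frame")
  df
}

#' Probe-level signal matrix with attached sample metadata
#'
#' Holds the quantified methylation-enrichment readout: log2 enrichment
#' signal, probes in rows and samples in columns, with the matching
#' [SampleSheet] attached.
#'
#' @param values numeric matrix (probes x samples) with rownames = probe ids
#'   and colnames = sample ids; all values must be finite.
#' @param sheet [SampleSheet] covering exactly the matrix's samples.
#' @return Object of class `ProbeSignalMatrix`.
#' @export
ProbeSignalMatrix <- function(values, sheet) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have probe ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values))) stop("duplicated probe ids")
  if (anyDuplicated(colnames(values))) stop("duplicated sample ids")
  if (!all(is.finite(values)))
    stop("signal matrix contains non-finite values")
  sheet <- SampleSheet(sheet)
  if (!setequal(colnames(values), sheet$sample_id))
    stop("matrix samples and sheet samples differ: missing from sheet: ",
         paste(setdiff(colnames(values), sheet$sample_id), collapse = ", "),
         "; missing from matrix: ",
         paste(setdiff(sheet$sample_id, colnames(values)), collapse = ", "))
  sheet <- sheet[match(colnames(values), sheet$sample_id), , drop = FALSE]
  rownames(sheet) <- NULL
  class(sheet) <- c("SampleSheet", "data.frame")
  structure(list(values = values, sheet = sheet), class = "ProbeSignalMatrix")
}

#' @export
print.ProbeSignalMatrix <- function(x, ...) {
  cat(sprintf("ProbeSignalMatrix: %d probes x %d samples (%d CT, %d SZ; cell type: %s)\n",
              nrow(x$values), ncol(x$values),
              sum(x$sheet$group == "CT"), sum(x$sheet$group == "SZ"),
              paste(unique(x$sheet$cell_type), collapse = "/")))
  invisible(x)
}

#' Named set of genomic intervals (e.g. GWAS loci for one trait)
#'
#' @param name label, typically a GWAS trait.
#' @param intervals data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open). May be empty. Overlapping intervals are preserved
#'   un-merged.
#' @return Object of class `IntervalSet`.
#' @export
IntervalSet <- function(name, intervals) {
  intervals <- as.data.frame(intervals, stringsAsFactors = FALSE)
  if (nrow(intervals) == 0L) {
    intervals <- data.frame(chrom = character(), start = integer(),
                            end = integer(), stringsAsFactors = FALSE)
  } else {
    if (!all(c("chrom", "start", "end") %in% names(intervals)))
      stop("intervals must have columns chrom, start, end")
    intervals <- intervals[c("chrom", "start", "end")]
    intervals$start <- as.integer(intervals$start)
    intervals$end <- as.integer(intervals$end)
    if (any(intervals$start < 0L)) stop("interval with negative start")
    if (any(intervals$start >= intervals$end))
      stop("interval with start >= end at line(s): ",
           paste(which(intervals$start >= intervals$end)[1:min(5, sum(intervals$start >= intervals$end))],
                 collapse = ", "))
  }
  rownames(intervals) <- NULL
  structure(list(name = as.character(name)[1L], intervals = intervals),
            class = "IntervalSet")
}

#' @export
print.IntervalSet <- function(x, ...) {
  cat(sprintf("IntervalSet '%s': %d interval(s)\n", x$name, nrow(x$intervals)))
  invisible(x)
}

#' Set of called differentially methylated regions
#'
#' Usually produced by [call_dmrs()]; the constructor validates an existing
#' table (e.g. one read back from disk).
#'
#' @param dmrs data.frame with columns `dmr_id`, `chrom`, `start`, `end`,
#'   `promoter_id`, `gene_symbol`, `n_probes`, `score`, `p_value`, `fdr`,
#'   `direction` (`"hyper"`/`"hypo"`, case vs control).
#' @param threshold_p p-value threshold that defined the set (members have
#'   `p_value < threshold_p`).
#' @param threshold_label `"stringent"` or `"relaxed"`.
#' @param cell_type `"neuron"` or `"nonneuron"`.
#' @param null_type,n_perm,seed provenance of the p-values (analytic or
#'   permutation null).
#' @return Object of class `DMRSet`.
#' @export
DMRSet <- function(dmrs, threshold_p, threshold_label, cell_type,
                   null_type = "analytic", n_perm = NA_integer_,
                   seed = NA_integer_) {
  dmrs <- as.data.frame(dmrs, stringsAsFactors = FALSE)
  need <- c("dmr_id", "chrom", "start", "end", "promoter_id", "gene_symbol",
            "n_probes", "score", "p_value", "fdr", "direction")
  if (nrow(dmrs) == 0L) {
    dmrs <- data.frame(dmr_id = character(), chrom = character(),
                       start = integer(), end = integer(),
                       promoter_id = character(), gene_symbol = character(),
                       n_probes = integer(), score = numeric(),
                       p_value = numeric(), fdr = numeric(),
                       direction = character(), stringsAsFactors = FALSE)
  } else {
    if (!all(need %in% names(dmrs)))
      stop("DMR table must have columns: ", paste(need, collapse = ", "))
    dmrs <- dmrs[need]
    if (any(dmrs$start >= dmrs$end)) stop("DMR with start >= end")
    if (!all(dmrs$direction %in% c("hyper", "hypo")))
      stop("DMR direction must be 'hyper' or 'hypo'")
    if (any(dmrs$p_value > threshold_p))
      stop("DMR p_value above the set's threshold_p")
    if (any(dmrs$p_value <= 0 | dmrs$p_value > 1)) stop("p_value outside (0,1]")
    dmrs <- dmrs[order(dmrs$chrom, dmrs$start), , drop = FALSE]
    rownames(dmrs) <- NULL
  }
  if (!threshold_label %in% c("stringent", "relaxed"))
    stop("threshold_label must be 'stringent' or 'relaxed'")
  if (!cell_type %in% c("neuron", "nonneuron"))
    stop("cell_type must be 'neuron' or 'nonneuron'")
  structure(list(dmrs = dmrs, threshold_p = threshold_p,
                 threshold_label = threshold_label, cell_type = cell_type,
                 null_type = null_type, n_perm = n_perm, seed = seed),
            class = "DMRSet")
}

#' @export
print.DMRSet <- function(x, ...) {
  cat(sprintf("DMRSet (%s, %s threshold P < %g, %s null): %d DMR(s), %d gene(s)\n",
              x$cell_type, x$threshold_label, x$threshold_p, x$null_type,
              nrow(x$dmrs), length(unique(x$dmrs$gene_symbol))))
  if (nrow(x$dmrs) > 0L) {
    cat(sprintf("  direction: %d hyper, %d hypo\n",
                sum(x$dmrs$direction == "hyper"), sum(x$dmrs$direction == "hypo")))
  }
  invisible(x)
}

#' Expression matrix with probe-to-gene map and sample metadata
#'
#' @param values numeric matrix (probes x subjects, log2 expression) with
#'   rownames = probe ids, colnames = subject ids.
#' @param probe_to_gene named character vector mapping every probe id to
#'   exactly one gene symbol.
#' @param sheet [SampleSheet] for the subjects.
#' @return Object of class `ExpressionMatrix`.
#' @export
ExpressionMatrix <- function(values, probe_to_gene, sheet) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have probe ids as rownames and subject ids as colnames")
  if (!all(is.finite(values))) stop("expression matrix contains non-finite values")
  if (is.null(names(probe_to_gene)) ||
      !setequal(names(probe_to_gene), rownames(values)))
    stop("probe_to_gene must be named by exactly the matrix's probe ids")
  probe_to_gene <- probe_to_gene[rownames(values)]
  sheet <- SampleSheet(sheet)
  if (!setequal(colnames(values), sheet$sample_id))
    stop("matrix subjects and sheet samples differ")
  sheet <- sheet[match(colnames(values), sheet$sample_id), , drop = FALSE]
  rownames(sheet) <- NULL
  class(sheet) <- c("SampleSheet", "data.frame")
  structure(list(values = values, probe_to_gene = probe_to_gene, sheet = sheet),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probes (%d genes) x %d subjects (%d CT, %d SZ)\n",
              nrow(x$values), length(unique(x$probe_to_gene)), ncol(x$values),
              sum(x$sheet$group == "CT"), sum(x$sheet$group == "SZ")))
  invisible(x)
}

# GRanges views used by overlap computations (strand deliberately dropped).
promoter_granges <- function(universe) {
  p <- universe$promoters
  GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$start + 1L, p$end))
}

interval_granges <- function(iset) {
  iv <- iset$intervals
  if (nrow(iv) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start + 1L, iv$end))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
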