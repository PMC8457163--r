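# On-disk interchange formats. All BED coordinates 0-based half-open.
# Promoters: BED6 + gene_symbol (chrom, start, end, promoter_id, score ".",
# strand, gene_symbol). Probes: BED4 + promoter_id. Loci: BED3+. Matrices:
# TSV with probe_id first column. Floats are written with full precision
# except DMR p-values (6 significant digits).

.read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

.split_fields <- function(lines, n_min, path) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < n_min)) {
    bad <- which(nf < n_min)[1L]
    stop(sprintf("parse error in %s at line %d: expected >= %d tab-separated fields, got %d",
                 path, bad, n_min, nf[bad]))
  }
  fields
}

.as_coord <- function(x, path, lines) {
  v <- suppressWarnings(as.integer(x))
  if (anyNA(v)) {
    bad <- which(is.na(v))[1L]
    stop(sprintf("parse error in %s at line %d: non-integer coordinate '%s'",
                 path, lines[bad], x[bad]))
  }
  v
}

#' Read a promoter universe from promoter and probe BED files
#'
#' @param promoter_path BED6+gene file: chrom, start, end, promoter_id,
#'   score (ignored), strand, gene_symbol.
#' @param probe_path BED4+promoter file: chrom, start, end, probe_id,
#'   promoter_id.
#' @return A validated [PromoterUniverse].
#' @seealso [write_promoter_universe()]
#' @export
read_promoter_universe <- function(promoter_path, probe_path) {
  plines <- .read_tsv_lines(promoter_path)
  pf <- .split_fields(plines, 7L, promoter_path)
  promoters <- data.frame(
    promoter_id = vapply(pf, `[`, "", 4L),
    chrom = vapply(pf, `[`, "", 1L),
    start = .as_coord(vapply(pf, `[`, "", 2L), promoter_path, seq_along(pf)),
    end = .as_coord(vapply(pf, `[`, "", 3L), promoter_path, seq_along(pf)),
    strand = vapply(pf, `[`, "", 6L),
    gene_symbol = vapply(pf, `[`, "", 7L),
    stringsAsFactors = FALSE)
  blines <- .read_tsv_lines(probe_path)
  bf <- .split_fields(blines, 5L, probe_path)
  probes <- data.frame(
    probe_id = vapply(bf, `[`, "", 4L),
    promoter_id = vapply(bf, `[`, "", 5L),
    chrom = vapply(bf, `[`, "", 1L),
    start = .as_coord(vapply(bf, `[`, "", 2L), probe_path, seq_along(bf)),
    end = .as_coord(vapply(bf, `[`, "", 3L), probe_path, seq_along(bf)),
    stringsAsFactors = FALSE)
  PromoterUniverse(promoters, probes)
}

#' Write a promoter universe to promoter and probe BED files
#'
#' @param universe a [PromoterUniverse].
#' @param promoter_path,probe_path output paths (see
#'   [read_promoter_universe()] for the column layout).
#' @return Invisibly, the universe.
#' @export
write_promoter_universe <- function(universe, promoter_path, probe_path) {
  stopifnot(inherits(universe, "PromoterUniverse"))
  p <- universe$promoters
  writeLines(sprintf("%s\t%d\t%d\t%s\t.\t%s\t%s",
                     p$chrom, p$start, p$end, p$promoter_id, p$strand,
                     p$gene_symbol), promoter_path)
  b <- universe$probes
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s",
                     b$chrom, b$start, b$end, b$probe_id, b$promoter_id),
             probe_path)
  invisible(universe)
}

#' Read a sample sheet TSV
#'
#' Expects a header line `sample_id  group  cell_type  brain_pH`; `NA` or an
#' empty field denotes missing pH.
#'
#' @param path TSV file path.
#' @return A [SampleSheet].
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          colClasses = c("character", "character", "character",
                                         "numeric"))
  SampleSheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet a [SampleSheet] to write.
#' @export
write_sample_sheet <- function(sheet, path) {
  stopifnot(inherits(sheet, "SampleSheet"))
  utils::write.table(as.data.frame(sheet), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(sheet)
}

#' Read a probe-level signal matrix TSV against a sample sheet
#'
#' The TSV header is `probe_id` followed by sample ids; the header samples
#' must match the sheet's samples exactly (any order). Missing or
#' non-numeric cells are rejected.
#'
#' @param path TSV file path.
#' @param sheet [SampleSheet] describing the samples.
#' @return A [ProbeSignalMatrix] with rows in file order.
#' @export
read_probe_matrix <- function(path, sheet) {
  if (!file.exists(path)) stop("file not found: ", path)
  sheet <- SampleSheet(sheet)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (names(df)[1L] != "probe_id") stop("first column must be 'probe_id'")
  ids <- names(df)[-1L]
  extra <- setdiff(ids, sheet$sample_id)
  missing <- setdiff(sheet$sample_id, ids)
  if (length(extra) || length(missing))
    stop("sample_id mismatch with sheet; not in sheet: ",
         paste(extra, collapse = ", "), "; not in matrix: ",
         paste(missing, collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "numeric")
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing or non-numeric value at probe '%s', sample '%s'",
                 df$probe_id[bad[1L]], ids[bad[2L]]))
  }
  rownames(vals) <- df$probe_id
  ProbeSignalMatrix(vals, sheet)
}

#' @rdname read_probe_matrix
#' @param matrix a [ProbeSignalMatrix] to write; values are written with full
#'   (17 significant digit) precision so write/read round-trips are exact.
#' @export
write_probe_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "ProbeSignalMatrix"))
  v <- matrix$values
  out <- data.frame(probe_id = rownames(v),
                    apply(v, 2L, function(col) sprintf("%.17g", col)),
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c("probe_id", colnames(v))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(matrix)
}

#' Read a BED3+ interval file into an IntervalSet
#'
#' @param path BED file; columns beyond the third are ignored. An empty file
#'   yields an empty (valid) set. Overlapping intervals are preserved
#'   un-merged, in file order.
#' @param name set label; defaults to the file stem.
#' @return An [IntervalSet].
#' @export
read_interval_bed <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  lines <- .read_tsv_lines(path)
  if (length(lines) == 0L)
    return(IntervalSet(name, data.frame()))
  f <- .split_fields(lines, 3L, path)
  IntervalSet(name, data.frame(
    chrom = vapply(f, `[`, "", 1L),
    start = .as_coord(vapply(f, `[`, "", 2L), path, seq_along(f)),
    end = .as_coord(vapply(f, `[`, "", 3L), path, seq_along(f)),
    stringsAsFactors = FALSE))
}

#' @rdname read_interval_bed
#' @param iset an [IntervalSet] to write as BED3.
#' @export
write_interval_bed <- function(iset, path) {
  stopifnot(inherits(iset, "IntervalSet"))
  iv <- iset$intervals
  writeLines(sprintf("%s\t%d\t%d", iv$chrom, iv$start, iv$end), path)
  invisible(iset)
}

#' Write a DMR set as a BED6+ table
#'
#' Columns: chrom, start, end, dmr_id, score, strand (always `.`), p_value,
#' direction, promoter_id, gene_symbol, fdr; sorted by (chrom, start), with a
#' commented header carrying the set's threshold and provenance. P-values are
#' written with 6 significant digits.
#'
#' @param dmrs a [DMRSet].
#' @param path output path.
#' @return Invisibly, the DMRSet.
#' @seealso [read_dmr_table()]
#' @export
write_dmr_table <- function(dmrs, path) {
  stopifnot(inherits(dmrs, "DMRSet"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("#threshold_p=%.6e\tthreshold_label=%s\tcell_type=%s\tnull=%s",
                     dmrs$threshold_p, dmrs$threshold_label, dmrs$cell_type,
                     dmrs$null_type), con)
  writeLines(paste(c("#chrom", "start", "end", "dmr_id", "score", "strand",
                     "p_value", "direction", "promoter_id", "gene_symbol",
                     "fdr"), collapse = "\t"), con)
  d <- dmrs$dmrs
  if (nrow(d) > 0L) {
    d <- d[order(d$chrom, d$start), , drop = FALSE]
    writeLines(sprintf("%s\t%d\t%d\t%s\t%.6g\t.\t%.6g\t%s\t%s\t%s\t%.6g",
                       d$chrom, d$start, d$end, d$dmr_id, d$score, d$p_value,
                       d$direction, d$promoter_id, d$gene_symbol, d$fdr), con)
  }
  invisible(dmrs)
}

#' @rdname write_dmr_table
#' @export
read_dmr_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1L], "#threshold_p="))
    stop("not a DMR table (missing '#threshold_p=' header): ", path)
  meta <- strsplit(sub("^#", "", lines[1L]), "\t", fixed = TRUE)[[1L]]
  kv <- do.call(rbind, strsplit(meta, "=", fixed = TRUE))
  meta <- stats::setNames(kv[, 2L], kv[, 1L])
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0L) {
    d <- data.frame()
  } else {
    f <- .split_fields(body, 11L, path)
    d <- data.frame(
      dmr_id = vapply(f, `[`, "", 4L),
      chrom = vapply(f, `[`, "", 1L),
      start = .as_coord(vapply(f, `[`, "", 2L), path, seq_along(f)),
      end = .as_coord(vapply(f, `[`, "", 3L), path, seq_along(f)),
      promoter_id = vapply(f, `[`, "", 9L),
      gene_symbol = vapply(f, `[`, "", 10L),
      n_probes = NA_integer_,
      score = as.numeric(vapply(f, `[`, "", 5L)),
      p_value = as.numeric(vapply(f, `[`, "", 7L)),
      fdr = as.numeric(vapply(f, `[`, "", 11L)),
      direction = vapply(f, `[`, "", 8L),
      stringsAsFactors = FALSE)
  }
  DMRSet(d, threshold_p = as.numeric(meta[["threshold_p"]]),
         threshold_label = meta[["threshold_label"]],
         cell_type = meta[["cell_type"]], null_type = meta[["null"]])
}

#' Read/write an expression matrix TSV
#'
#' Layout: header `probe_id  gene_symbol  <subject ids...>`; one row per
#' probe, each probe mapped to exactly one gene.
#'
#' @param path TSV file path.
#' @param sheet [SampleSheet] for the subjects.
#' @return An [ExpressionMatrix].
#' @export
read_expression_matrix <- function(path, sheet) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(names(df)[1:2], c("probe_id", "gene_symbol")))
    stop("first two columns must be 'probe_id' and 'gene_symbol'")
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(vals) <- "numeric"
  rownames(vals) <- df$probe_id
  ExpressionMatrix(vals, stats::setNames(df$gene_symbol, df$probe_id), sheet)
}

#' @rdname read_expression_matrix
#' @param matrix an [ExpressionMatrix] to write.
#' @export
write_expression_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  v <- matrix$values
  out <- data.frame(probe_id = rownames(v),
                    gene_symbol = unname(matrix$probe_to_gene[rownames(v)]),
                    apply(v, 2L, function(col) sprintf("%.17g", col)),
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c("probe_id", "gene_symbol", colnames(v))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(matrix)
}
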