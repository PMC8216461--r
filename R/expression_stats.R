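#' Counts-per-million normalization
#'
#' Scales each sample (column) so the column total is one million; the
#' library size is the column sum of the genes supplied, so every CPM
#' column sums to 1e6 when restricted to those genes.
#'
#' @param counts non-negative numeric matrix, genes in rows, samples in
#'   columns.
#' @param lib_sizes optional per-sample library sizes; defaults to the
#'   column sums of `counts`.
#' @return Matrix of CPM values, same dimensions as `counts`.
#' @export
cpm_normalize <- function(counts, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) stop("zero-library sample: ",
                                paste(colnames(counts)[lib_sizes <= 0],
                                      collapse = ", "))
  edgeR::cpm(counts, lib.size = lib_sizes)
}

#' Sample QC filter on mapping and assignment rates
#'
#' A sample is excluded iff its percentage of uniquely mapped reads is
#' below `min_uniquely_mapped` OR its percentage of reads assigned to an
#' annotation is below `min_assigned` (strict `<`; samples exactly at a
#' threshold are kept). Samples missing either metric are flagged
#' `unevaluable`, never silently kept.
#'
#' @param metrics data frame with columns `sample`,
#'   `pct_uniquely_mapped`, `pct_assigned`.
#' @param min_uniquely_mapped,min_assigned thresholds in percent
#'   (defaults 60 and 10).
#' @return Tibble with columns `sample`, `status`
#'   (`kept`/`excluded`/`unevaluable`) and `reason` (comma-separated
#'   triggering metric(s), `""` for kept samples).
#' @export
qc_filter <- function(metrics, min_uniquely_mapped = 60, min_assigned = 10) {
  required <- c("sample", "pct_uniquely_mapped", "pct_assigned")
  if (!all(required %in% names(metrics)))
    stop("metrics must have columns: ", paste(required, collapse = ", "))
  metrics <- as_tibble(metrics)
  status <- character(nrow(metrics))
  reason <- character(nrow(metrics))
  for (i in seq_len(nrow(metrics))) {
    um <- metrics$pct_uniquely_mapped[i]
    pa <- metrics$pct_assigned[i]
    if (is.na(um) || is.na(pa)) {
      status[i] <- "unevaluable"
      reason[i] <- paste(c("pct_uniquely_mapped", "pct_assigned")[
        c(is.na(um), is.na(pa))], collapse = ",")
      next
    }
    why <- c(if (um < min_uniquely_mapped) "pct_uniquely_mapped",
             if (pa < min_assigned) "pct_assigned")
    status[i] <- if (length(why) > 0) "excluded" else "kept"
    reason[i] <- paste(why, collapse = ",")
  }
  tibble(sample = metrics$sample, status = status, reason = reason)
}

#' Keep samples whose value lies within a reference range
#'
#' Retains the samples whose scalar value falls inside
#' `[min(reference), max(reference)]` (inclusive). Used to restrict an
#' analysis to test samples whose expression of a gene is comparable to
#' the control group's range.
#'
#' @param values named numeric vector, one value per sample.
#' @param reference_samples names of the reference (control) samples;
#'   must be a non-empty subset of `names(values)`.
#' @return Character vector of kept non-reference sample names.
#' @export
select_in_reference_range <- function(values, reference_samples) {
  if (length(reference_samples) == 0) stop("reference subset is empty")
  if (!all(reference_samples %in% names(values)))
    stop("reference samples missing from values")
  ref <- values[reference_samples]
  lo <- min(ref); hi <- max(ref)
  cand <- setdiff(names(values), reference_samples)
  cand[values[cand] >= lo & values[cand] <= hi]
}

#' Paired differential-expression calls
#'
#' Computes per-gene log2 fold changes on `log2(CPM + 1)` and a paired
#' two-tailed t-test across matched pairs; a gene is called `up` or
#' `down` iff `|log2FC| > lfc_threshold` AND `p < p_threshold`, otherwise
#' `unchanged`. Genes with zero counts everywhere, or degenerate paired
#' differences, are `unchanged` with `p = NA`.
#'
#' @param counts gene-by-sample count matrix with column names.
#' @param group named character/factor: group label (two levels) per
#'   sample; the first level (or `level_a`) is the numerator of the fold
#'   change.
#' @param pair named vector: pairing key per sample; each key must occur
#'   once in each group.
#' @param level_a group treated as condition A (numerator); default the
#'   first level.
#' @param lfc_threshold,p_threshold call thresholds (defaults 1 and 0.05).
#' @return Tibble: `gene`, `log2fc`, `p`, `call`.
#' @export
paired_de <- function(counts, group, pair, level_a = NULL,
                      lfc_threshold = 1, p_threshold = 0.05) {
  counts <- as.matrix(counts)
  samples <- colnames(counts)
  group <- group[samples]; pair <- pair[samples]
  levels_g <- unique(as.character(group))
  if (length(levels_g) != 2) stop("group must have exactly two levels")
  if (is.null(level_a)) level_a <- levels_g[1]
  level_b <- setdiff(levels_g, level_a)
  a <- samples[group == level_a]; b <- samples[group == level_b]
  a <- a[order(pair[a])]; b <- b[order(pair[b])]
  if (length(a) != length(b) || !identical(unname(pair[a]), unname(pair[b])))
    stop("pairing keys must match samples one-to-one across the two groups")
  if (length(a) < 2) stop("need at least 2 matched pairs")
  lg <- log2(cpm_normalize(counts) + 1)
  diffs <- lg[, a, drop = FALSE] - lg[, b, drop = FALSE]
  log2fc <- rowMeans(diffs)
  p <- apply(diffs, 1, function(d) {
    if (all(d == 0) || stats::sd(d) == 0) return(NA_real_)
    t.test(d)$p.value
  })
  all_zero <- rowSums(counts) == 0
  p[all_zero] <- NA_real_
  log2fc[all_zero] <- 0
  call <- ifelse(!is.na(p) & p < p_threshold & abs(log2fc) > lfc_threshold,
                 ifelse(log2fc > 0, "up", "down"), "unchanged")
  tibble(gene = rownames(counts) %||% as.character(seq_len(nrow(counts))),
         log2fc = unname(log2fc), p = unname(p), call = unname(call))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Constitutive expression from junction reads
#'
#' Per-sample global expression of the gene, measured as the sum of
#' CPM-normalized read counts over junctions joining two constant exons
#' (both junction boundaries abut constant exons of the model). Doubling
#' a library at unchanged composition leaves the value unchanged.
#'
#' @param junctions a junction table.
#' @param model a `gene_model`.
#' @param lib_sizes per-sample library sizes used for the CPM scaling;
#'   defaults to the per-sample total junction reads in `junctions`.
#' @return Named numeric vector, one value per sample. Zero with a
#'   warning when no constitutive junction is detected.
#' @export
constitutive_expression <- function(junctions, model, lib_sizes = NULL) {
  if (sum(model$role == "constant") < 2)
    stop("model needs at least two constant exons")
  samples <- junction_samples(junctions)
  exon_role_at <- function(start_match, value) {
    # role of the exon whose boundary equals value, NA if none
    i <- if (start_match) which(model$start == value) else which(model$end == value)
    if (length(i) != 1) NA_character_ else model$role[i]
  }
  is_const <- vapply(seq_len(nrow(junctions)), function(i) {
    donor <- exon_role_at(FALSE, junctions$intron_start[i])
    acceptor <- exon_role_at(TRUE, junctions$intron_end[i])
    identical(donor, "constant") && identical(acceptor, "constant") &&
      all(junctions$chrom[i] == model$chrom[1])
  }, logical(1))
  cnt <- as.matrix(junctions[, samples, drop = FALSE])
  if (is.null(lib_sizes)) lib_sizes <- colSums(cnt)
  if (!any(is_const)) {
    warning("no constitutive junction detected")
    return(setNames(rep(0, length(samples)), samples))
  }
  cpm <- t(t(cnt) / lib_sizes) * 1e6
  setNames(colSums(cpm[is_const, , drop = FALSE]), samples)
}

#' Read a count matrix / sample metadata TSV
#'
#' `read_count_matrix()` expects genes in rows (first column = gene id,
#' header = sample ids); `read_sample_metadata()` expects one row per
#' sample with at least a `sample` column.
#'
#' @param path TSV file.
#' @return A matrix (counts) or tibble (metadata).
#' @export
read_count_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  if (any(m < 0)) stop("negative entries in count matrix ", path)
  m
}

#' @rdname read_count_matrix
#' @export
read_sample_metadata <- function(path) {
  as_tibble(read.table(path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE))
}
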