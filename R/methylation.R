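#' MeDIP enrichment as percent of input
#'
#' `100 * ip / input` per locus. Loci with zero input are flagged missing
#' (`NA`) rather than dropped.
#'
#' @param ip,input non-negative numeric vectors of immunoprecipitated and
#'   input DNA quantities, matched by position (or by names when both are
#'   named).
#' @return Numeric vector of percent-input values.
#' @export
medip_percent_input <- function(ip, input) {
  if (!is.null(names(ip)) && !is.null(names(input)))
    input <- input[names(ip)]
  if (length(ip) != length(input)) stop("ip and input lengths differ")
  if (any(ip < 0, na.rm = TRUE) || any(input < 0, na.rm = TRUE))
    stop("negative quantities")
  out <- ifelse(input > 0, 100 * ip / input, NA_real_)
  if (any(input == 0, na.rm = TRUE))
    warning(sum(input == 0, na.rm = TRUE), " locus/loci with zero input flagged missing")
  out
}

#' TMM library scale factors
#'
#' Trimmed-mean-of-M-values scale factors for a region-of-interest count
#' matrix, with a 30% trim on M-values and a 5% trim on A-values and the
#' reference sample chosen as the column whose upper-quartile count is
#' closest to the mean upper quartile. Factors are normalized to
#' geometric mean 1, so a column identical to the reference gets
#' factor 1. Computed with edgeR's TMM implementation.
#'
#' @param counts ROI-by-sample count matrix (at least 2 samples).
#' @param trim_m,trim_a trim fractions for M and A values (defaults 0.30
#'   and 0.05).
#' @return Named numeric vector of per-sample scale factors.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least 2 samples")
  zero <- colSums(counts) == 0
  if (any(zero))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[zero], collapse = ", "))
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a)
  setNames(f, colnames(counts))
}

#' Call differentially methylated regions
#'
#' Per region of interest (ROI), counts are normalized to log2-CPM with a
#' pseudocount of 1 using TMM-scaled effective library sizes, compared
#' between the two groups with a two-tailed test, and
#' Bonferroni-corrected over the number of tested ROIs. The default test
#' is limma's moderated t with a mean-variance trend — the standard
#' choice for group comparisons of normalized log-counts at small sample
#' sizes, where per-ROI variance estimates on their own are too noisy
#' for adequate power; `method = "t"` gives the unmoderated per-ROI
#' Welch t-test instead. The log2 fold change is `mean(A) - mean(B)` on
#' the log2 scale under the convention that group A is the
#' perturbed/tumor condition, so `hypo` means less methylation signal in
#' A (`log2fc < 0`). A DMR is significant iff `p_adj < alpha` (strict).
#'
#' @param counts ROI-by-sample count matrix; row order matches `roi`.
#' @param roi data frame of ROI intervals with columns `chrom`, `start`,
#'   `end` (0-based half-open); must be non-empty.
#' @param group named character vector: group label per sample.
#' @param group_a,group_b labels of the test (A) and reference (B)
#'   groups; each needs at least 2 samples.
#' @param alpha family-wise significance level (default 0.05).
#' @param method `"moderated_t"` (default) or `"t"`.
#' @return Tibble of DMRs: `chrom`, `start`, `end`, `log2fc`, `p_raw`,
#'   `p_adj`, `direction` (`hypo`/`hyper`), `significant`.
#' @export
call_dmrs <- function(counts, roi, group, group_a, group_b, alpha = 0.05,
                      method = c("moderated_t", "t")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (is.null(roi) || nrow(roi) == 0) stop("empty ROI list")
  if (nrow(roi) != nrow(counts))
    stop("counts rows and ROI rows differ")
  a <- names(group)[group == group_a]
  b <- names(group)[group == group_b]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 samples")
  sel <- c(a, b)
  counts <- counts[, sel, drop = FALSE]
  f <- tmm_factors(counts)
  eff_lib <- colSums(counts) * f
  lg <- log2(t(t(counts) / eff_lib) * 1e6 + 1)
  log2fc <- rowMeans(lg[, a, drop = FALSE]) - rowMeans(lg[, b, drop = FALSE])
  if (method == "moderated_t") {
    design <- cbind(intercept = 1, a_vs_b = as.integer(colnames(lg) %in% a))
    fit <- limma::eBayes(limma::lmFit(lg, design), trend = nrow(lg) >= 10)
    p_raw <- fit$p.value[, "a_vs_b"]
  } else {
    p_raw <- apply(lg, 1, function(v) {
      va <- v[a]; vb <- v[b]
      if (stats::sd(va) == 0 && stats::sd(vb) == 0)
        return(if (mean(va) == mean(vb)) 1 else NA_real_)
      t.test(va, vb)$p.value
    })
  }
  p_adj <- p.adjust(p_raw, method = "bonferroni")
  tibble(chrom = roi$chrom, start = roi$start, end = roi$end,
         log2fc = unname(log2fc), p_raw = unname(p_raw),
         p_adj = unname(p_adj),
         direction = ifelse(log2fc < 0, "hypo", "hyper"),
         significant = !is.na(p_adj) & p_adj < alpha)
}

#' Fixed-width tiling ROIs over an interval
#'
#' Fallback ROI generator for runs without an external peak list: tiles
#' `[start, end)` with non-overlapping windows of `width` bp (the last
#' window is truncated at `end`).
#'
#' @param chrom contig name.
#' @param start,end interval to tile (0-based half-open).
#' @param width bin width in bp (default 500).
#' @return Tibble with columns `chrom`, `start`, `end`.
#' @export
tile_rois <- function(chrom, start, end, width = 500) {
  stopifnot(end > start, width > 0)
  s <- seq(start, end - 1, by = width)
  tibble(chrom = chrom, start = as.integer(s),
         end = as.integer(pmin(s + width, end)))
}

#' Read ROI intervals from a BED file
#' @param path BED file (first three columns used).
#' @return Tibble with columns `chrom`, `start`, `end` and, when present,
#'   `name`.
#' @export
read_roi_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                start = GenomicRanges::start(gr) - 1L,
                end = GenomicRanges::end(gr))
  nm <- S4Vectors::mcols(gr)$name
  if (!is.null(nm)) out$name <- nm
  out
}

#' Write a DMR table to TSV
#' @param dmrs tibble from [call_dmrs()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dmr_table <- function(dmrs, path) {
  write.table(as.data.frame(dmrs), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Locus panel and locus groups for a CD44-like MeDIP walk
#'
#' The qPCR walking panel used for percent-input profiles: a distal
#' upstream locus `D`, each constant and variant exon of the model, the
#' introns downstream of v8, v9 and v10 (named `i10`, `i11`, `i15` after
#' their host-gene intron numbering), plus a high positive control
#' (`H2BWT`-like germline promoter) and a low background control
#' (`GAPDHp`-like unmethylated CpG island). `cd44_locus_groups()` returns
#' the locus-id sets compared group-wise: all loci; constant exons;
#' variant region including the introns; variant exons only; introns
#' only.
#'
#' @param model a `gene_model` (default [cd44_gene_model()]).
#' @return `cd44_locus_panel()`: character vector of locus ids;
#'   `cd44_locus_groups()`: named list of locus-id vectors.
#' @export
cd44_locus_panel <- function(model = cd44_gene_model()) {
  c("D", model$exon_id, c("i10", "i11", "i15"), "H2BWT", "GAPDHp")
}

#' @rdname cd44_locus_panel
#' @export
cd44_locus_groups <- function(model = cd44_gene_model()) {
  introns <- c("i10", "i11", "i15")
  variant <- model$exon_id[model$role == "variant"]
  constant <- model$exon_id[model$role == "constant"]
  list(
    all_loci = c("D", model$exon_id, introns),
    constant_exons = constant,
    variant_region_incl_introns = c(variant, introns),
    variant_exons_only = variant,
    introns_only = introns
  )
}

#' Pairwise locus-group comparisons across cell lines
#'
#' For each locus group and each non-baseline cell line, a paired
#' two-tailed Student's t-test across loci (pairing = locus identity)
#' against the baseline cell line, as used to compare percent-input
#' methylation profiles between related cell lines.
#'
#' @param values locus-by-cellline numeric matrix (rownames = locus ids)
#'   of percent-input values.
#' @param group_def named list of locus-id vectors (e.g.
#'   [cd44_locus_groups()]); every group needs at least 2 loci.
#' @param baseline column name of the baseline cell line.
#' @return Tibble: `group`, `cellline`, `n_loci`, `p`.
#' @export
compare_locus_groups <- function(values, group_def, baseline) {
  values <- as.matrix(values)
  if (!baseline %in% colnames(values))
    stop("baseline cell line not in values")
  others <- setdiff(colnames(values), baseline)
  rows <- list()
  for (g in names(group_def)) {
    loci <- intersect(group_def[[g]], rownames(values))
    if (length(loci) < 2) stop("group '", g, "' has fewer than 2 loci")
    for (cl in others) {
      d <- values[loci, cl] - values[loci, baseline]
      p <- if (all(d == 0) || stats::sd(d) == 0) {
        if (all(d == 0)) 1 else NA_real_
      } else t.test(d)$p.value
      rows[[length(rows) + 1]] <- tibble(group = g, cellline = cl,
                                         n_loci = length(loci), p = p)
    }
  }
  do.call(rbind, rows)
}
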