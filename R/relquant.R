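#' Reference-gene normalization of qPCR relative quantities
#'
#' Each target is divided by the per-sample geometric mean of the
#' reference targets (the standard multi-reference convention), then by
#' the control-sample mean of that ratio, so the control group averages
#' exactly 1 for every target. Any per-sample multiplicative scale
#' (input amount, efficiency drift) cancels through the references.
#'
#' @param quantities target-by-sample matrix of positive relative
#'   quantities (efficiency-corrected; Ct conversion is out of scope).
#' @param references row names of the reference targets; must be > 0 in
#'   every sample.
#' @param controls column names of the control samples.
#' @return Matrix of normalized fold changes (references rows included,
#'   normalized like any other target).
#' @export
normalize_to_references <- function(quantities, references, controls) {
  q <- as.matrix(quantities)
  if (!all(references %in% rownames(q)))
    stop("reference target(s) missing from table")
  if (!all(controls %in% colnames(q)))
    stop("control sample(s) missing from table")
  refq <- q[references, , drop = FALSE]
  if (any(refq <= 0)) stop("non-positive reference quantity")
  geo <- exp(colMeans(log(refq)))
  norm <- sweep(q, 2, geo, "/")
  ctrl_mean <- rowMeans(norm[, controls, drop = FALSE])
  if (any(ctrl_mean <= 0)) stop("non-positive control mean")
  sweep(norm, 1, ctrl_mean, "/")
}

#' Splicing index
#'
#' `SI = 100 * variant / (variant + skipped)`, the percentage of
#' variant-exon-containing signal relative to the fully skipped isoform
#' used as reference. Vectorized; positions where both quantities are 0
#' are flagged missing (`NA`).
#'
#' @param variant,skipped non-negative quantities of the
#'   variant-containing and fully skipped isoforms.
#' @return Numeric vector of SI values in \[0, 100\].
#' @export
splicing_index <- function(variant, skipped) {
  if (any(variant < 0, na.rm = TRUE) || any(skipped < 0, na.rm = TRUE))
    stop("negative quantities")
  total <- variant + skipped
  ifelse(total > 0, 100 * variant / total, NA_real_)
}

#' Read a long-format relative-quantity table
#' @param path TSV with columns `target`, `sample`, `quantity`.
#' @return Target-by-sample matrix.
#' @export
read_relquant_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  required <- c("target", "sample", "quantity")
  if (!all(required %in% names(df)))
    stop("relquant table needs columns: ", paste(required, collapse = ", "))
  targets <- unique(df$target); samples <- unique(df$sample)
  m <- matrix(NA_real_, length(targets), length(samples),
              dimnames = list(targets, samples))
  m[cbind(match(df$target, targets), match(df$sample, samples))] <- df$quantity
  m
}
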