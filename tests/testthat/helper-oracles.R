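# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check.

# Exact Wilcoxon signed-rank p-value by full enumeration of all 2^n sign
# assignments of the non-zero paired differences.
oracle_wilcoxon_exact <- function(d,
                                  alternative = c("two.sided", "greater",
                                                  "less")) {
  alternative <- match.arg(alternative)
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 16, !any(duplicated(abs(d))))
  r <- rank(abs(d))
  t_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  t_null <- as.vector(signs %*% r)
  p_ge <- mean(t_null >= t_obs)
  p_le <- mean(t_null <= t_obs)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# Trimmed mean of M-values, written straight from the published
# definition (doubly trimmed, precision-weighted mean of per-gene
# log-ratios against a reference sample).
oracle_tmm <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  f75 <- vapply(seq_len(ncol(counts)), function(j)
    quantile(counts[, j] / lib[j], 0.75), numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  one <- function(j) {
    x <- counts[, j] / lib[j]
    r <- counts[, ref] / lib[ref]
    keep0 <- x > 0 & r > 0
    x <- x[keep0]; r <- r[keep0]
    M <- log2(x / r)
    A <- (log2(x) + log2(r)) / 2
    w <- (lib[j] - counts[keep0, j]) / (lib[j] * counts[keep0, j]) +
         (lib[ref] - counts[keep0, ref]) / (lib[ref] * counts[keep0, ref])
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
            rank(A) >= loA & rank(A) <= hiA
    if (max(abs(M)) < 1e-6) return(1)
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }
  f <- vapply(seq_len(ncol(counts)), one, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

# Brute-force interval containment over all exons of a model.
oracle_exon_at <- function(model, chrom, position) {
  for (i in seq_len(nrow(model))) {
    if (model$chrom[i] == chrom && model$start[i] <= position &&
        position < model$end[i]) return(model$exon_id[i])
  }
  NA_character_
}

# Small junction-table builder for toy cases: junctions given as
# "<donor_exon>><acceptor_exon>" labels resolved against a model.
toy_junctions <- function(model, spec, counts, strand = "+") {
  parts <- strsplit(spec, ">", fixed = TRUE)
  donor <- vapply(parts, `[[`, character(1), 1)
  acceptor <- vapply(parts, `[[`, character(1), 2)
  jx <- tibble::tibble(
    chrom = model$chrom[1],
    intron_start = model$end[match(donor, model$exon_id)],
    intron_end = model$start[match(acceptor, model$exon_id)],
    strand = strand)
  if (is.matrix(counts)) {
    for (k in seq_len(ncol(counts))) jx[[colnames(counts)[k]]] <- counts[, k]
  } else jx$s1 <- counts
  jx
}
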