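#' Junction tables
#'
#' A junction table is a tibble with coordinate columns `chrom`,
#' `intron_start`, `intron_end` (0-based half-open intron interval),
#' `strand` (`"+"`, `"-"` or `"*"` for unknown), and one non-negative
#' integer count column per sample. [read_junction_table()] reads one
#' sample; [merge_junction_tables()] aligns several samples on shared
#' intron coordinates.
#'
#' The SJ-tab dialect (splice-junction output of spliced aligners) stores
#' the 1-based first and last intron bases; with first base `f` and last
#' base `l` the internal interval is `[f - 1, l)`. Only the unique-read
#' count column is used; multi-mapped read counts are ignored.
#'
#' @param path junction file.
#' @param dialect `"sj_tab"` (9-column aligner splice-junction format) or
#'   `"bed"` (intron intervals, count in the score column).
#' @param sample sample name for the count column (default: file base name).
#' @return A single-sample junction table.
#' @export
read_junction_table <- function(path, dialect = c("sj_tab", "bed"),
                                sample = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(sample))
    sample <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty junction file: ", path)
    out <- tibble(chrom = character(), intron_start = integer(),
                  intron_end = integer(), strand = character())
    out[[sample]] <- integer()
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nmin <- if (dialect == "sj_tab") 7L else 5L
  bad <- which(vapply(fields, length, integer(1)) < nmin)
  if (length(bad) > 0)
    stop("malformed ", dialect, " line ", bad[1], " in ", path)
  get <- function(i) vapply(fields, `[[`, character(1), i)
  if (dialect == "sj_tab") {
    first <- as.integer(get(2)); last <- as.integer(get(3))
    strand <- c("0" = "*", "1" = "+", "2" = "-")[get(4)]
    strand[is.na(strand)] <- "*"
    count <- as.integer(get(7))
    out <- tibble(chrom = get(1), intron_start = first - 1L,
                  intron_end = last, strand = unname(strand))
  } else {
    out <- tibble(chrom = get(1), intron_start = as.integer(get(2)),
                  intron_end = as.integer(get(3)),
                  strand = if (all(lengths(fields) >= 6)) get(6) else "*")
    count <- as.integer(get(5))
  }
  if (anyNA(out$intron_start) || anyNA(out$intron_end) || anyNA(count))
    stop("non-numeric coordinate or count in ", path)
  if (any(count < 0))
    stop("negative junction count in ", path)
  if (any(out$intron_start >= out$intron_end))
    stop("intron_start >= intron_end in ", path)
  out[[sample]] <- count
  out
}

#' @rdname read_junction_table
#' @param tables list of single-sample junction tables.
#' @return `merge_junction_tables()`: one junction table whose count
#'   columns are the union of samples; absent junctions count 0.
#' @export
merge_junction_tables <- function(tables) {
  stopifnot(length(tables) > 0)
  key_cols <- c("chrom", "intron_start", "intron_end", "strand")
  out <- NULL
  for (tb in tables) {
    samp <- setdiff(names(tb), key_cols)
    if (is.null(out)) { out <- tb; next }
    out <- merge(out, tb, by = key_cols, all = TRUE)
  }
  out <- as_tibble(out)
  count_cols <- setdiff(names(out), key_cols)
  for (cc in count_cols) out[[cc]][is.na(out[[cc]])] <- 0L
  out[order(out$chrom, out$intron_start, out$intron_end), ]
}

#' Sample (count column) names of a junction table
#' @param junctions a junction table.
#' @export
junction_samples <- function(junctions)
  setdiff(names(junctions), c("chrom", "intron_start", "intron_end",
                              "strand", "class"))

resolve_anchor <- function(model, anchor) {
  if (is.character(anchor)) {
    i <- match(anchor, model$exon_id)
    if (is.na(i)) stop("anchor exon '", anchor, "' not in gene model")
    return(model[i, ])
  }
  anchor
}

#' Classify junctions relative to an anchor exon
#'
#' A junction boundary abuts an exon iff `intron_start == exon end`
#' (donor side) or `intron_end == exon start` (acceptor side). A junction
#' that abuts the anchor exon is classified by the exon at its other
#' boundary: a variant exon gives `inclusion`; a constant exon on the far
#' side of the variant block (so the junction skips every variant exon)
#' gives `skipping`; anything else — no exon at the far boundary, or a
#' constant exon on the anchor's own side — gives `other`, as do
#' junctions not involving the anchor at all. Junctions of unknown strand
#' are matched by coordinates alone.
#'
#' @param junctions a junction table (any number of rows).
#' @param model a `gene_model`.
#' @param anchor anchor exon id (e.g. `"C5"`) or a one-row exon tibble.
#' @return Character vector `"inclusion"` / `"skipping"` / `"other"`,
#'   one per junction row.
#' @export
classify_junction <- function(junctions, model, anchor) {
  anchor <- resolve_anchor(model, anchor)
  vb <- variant_block(model)
  same_chrom <- junctions$chrom == anchor$chrom
  strand_ok <- junctions$strand %in% c("*", attr(model, "strand"))
  donor_at_anchor <- junctions$intron_start == anchor$end
  acceptor_at_anchor <- junctions$intron_end == anchor$start
  out <- rep("other", nrow(junctions))
  for (i in seq_len(nrow(junctions))) {
    if (!same_chrom[i] || !strand_ok[i]) next
    if (donor_at_anchor[i]) {
      partner <- model[model$start == junctions$intron_end[i] &
                         model$chrom == junctions$chrom[i], ]
    } else if (acceptor_at_anchor[i]) {
      partner <- model[model$end == junctions$intron_start[i] &
                         model$chrom == junctions$chrom[i], ]
    } else next
    if (nrow(partner) != 1) next
    if (partner$role == "variant") {
      out[i] <- "inclusion"
    } else {
      far_side <- (anchor$ordinal < min(vb) && partner$ordinal > max(vb)) ||
                  (anchor$ordinal > max(vb) && partner$ordinal < min(vb))
      if (far_side) out[i] <- "skipping"
    }
  }
  out
}

#' Anchor junction set: inclusion/skipping junctions with detection filter
#'
#' Keeps junctions classified `inclusion` or `skipping` relative to the
#' anchor and applies a per-sample detection filter: counts below
#' `min_reads` in a sample are treated as undetected (0) in that sample
#' only, so each sample has its own detected-junction set. Junctions
#' below the threshold in every sample are dropped.
#'
#' @inheritParams classify_junction
#' @param min_reads minimum unique reads for a junction to count as
#'   detected in a sample (default 2).
#' @return An `anchor_junction_set`: the filtered junction table with a
#'   `class` column and attributes `anchor`, `min_reads`.
#' @export
enumerate_anchor_junctions <- function(junctions, model, anchor,
                                       min_reads = 2) {
  stopifnot(min_reads >= 1)
  anchor <- resolve_anchor(model, anchor)
  cls <- classify_junction(junctions, model, anchor)
  keep <- cls %in% c("inclusion", "skipping")
  out <- junctions[keep, , drop = FALSE]
  out$class <- cls[keep]
  samples <- junction_samples(out)
  for (s in samples) out[[s]][out[[s]] < min_reads] <- 0L
  detected <- if (length(samples) == 1) out[[samples]] > 0
              else rowSums(as.matrix(out[, samples])) > 0
  out <- out[detected, , drop = FALSE]
  structure(out, anchor = anchor$exon_id, min_reads = min_reads,
            class = c("anchor_junction_set", class(out)))
}

#' Anchor-exon inclusion percentage
#'
#' Per sample, the percentage of anchor-involving junction signal on
#' inclusion junctions:
#' `inclusion_pct = 100 * sum(inclusion) / sum(inclusion + skipping)`.
#' The default weights junctions by their read counts; `weight =
#' "junctions"` instead counts each detected junction once (the
#' alternative reading of "percentage of inclusion or skipping
#' junctions"). Samples whose denominator is zero are flagged missing
#' (`NA`), never reported as 0.
#'
#' @param set an `anchor_junction_set` from [enumerate_anchor_junctions()].
#' @param weight `"reads"` (default) or `"junctions"`.
#' @return Tibble with one row per sample: `sample`, `inclusion`,
#'   `skipping`, `total` (reads or junction counts according to
#'   `weight`), `inclusion_pct`, `skipping_pct`.
#' @export
inclusion_percentage <- function(set, weight = c("reads", "junctions")) {
  weight <- match.arg(weight)
  samples <- junction_samples(set)
  if (length(samples) == 0) stop("anchor junction set has no sample columns")
  incl <- set$class == "inclusion"
  stat <- function(s) {
    x <- set[[s]]
    if (weight == "junctions") x <- as.integer(x > 0)
    c(inclusion = sum(x[incl]), skipping = sum(x[!incl]))
  }
  m <- vapply(samples, stat, numeric(2))
  total <- colSums(m)
  pct <- ifelse(total > 0, 100 * m["inclusion", ] / total, NA_real_)
  tibble(sample = samples,
         inclusion = m["inclusion", ], skipping = m["skipping", ],
         total = total,
         inclusion_pct = unname(pct),
         skipping_pct = unname(ifelse(total > 0, 100 - pct, NA_real_)))
}

#' Compare inclusion percentages between two groups
#'
#' Paired or unpaired Student's t-test, or the paired Wilcoxon
#' signed-rank test, on per-sample inclusion percentages (or any other
#' per-sample scalar). The signed-rank test drops zero differences
#' (standard convention), uses the exact null distribution up to 25
#' informative pairs, and a normal approximation with continuity
#' correction beyond.
#'
#' @param x,y numeric vectors of per-sample values; matched by position
#'   when `design = "paired"`.
#' @param design `"paired"` or `"unpaired"`.
#' @param test `"t"` or `"wilcoxon_signed_rank"` (paired designs only).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`,
#'   on `x - y`.
#' @return List with `statistic`, `p.value`, `method`, `n` (pairs or
#'   per-group sizes), `alternative`. All-zero paired differences give
#'   `p = 1` with a warning; a degenerate t (zero variance) gives
#'   `p = NA` with a warning.
#' @export
compare_inclusion <- function(x, y,
                              design = c("paired", "unpaired"),
                              test = c("t", "wilcoxon_signed_rank"),
                              alternative = c("two.sided", "greater", "less")) {
  design <- match.arg(design)
  test <- match.arg(test)
  alternative <- match.arg(alternative)
  if (test == "wilcoxon_signed_rank" && design != "paired")
    stop("the Wilcoxon signed-rank test requires a paired design")
  if (design == "paired") {
    if (length(x) != length(y))
      stop("paired design requires equal-length matched vectors")
    ok <- complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
  } else {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
  }
  if (length(x) < 2 || length(y) < 2)
    stop("need at least 2 observations per group")
  if (test == "t") {
    res <- tryCatch(
      t.test(x, y, paired = design == "paired", alternative = alternative),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("degenerate t-test (", conditionMessage(res), "); p = NA")
      return(list(statistic = NA_real_, p.value = NA_real_,
                  method = "t", n = length(x), alternative = alternative))
    }
    return(list(statistic = unname(res$statistic), p.value = res$p.value,
                method = res$method, n = length(x),
                alternative = alternative))
  }
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = NA_real_, p.value = 1, method = "Wilcoxon signed rank",
                n = 0L, alternative = alternative))
  }
  res <- suppressWarnings(
    wilcox.test(d, exact = length(d) <= 25 && !any(duplicated(abs(d))),
                correct = TRUE, alternative = alternative))
  list(statistic = unname(res$statistic), p.value = res$p.value,
       method = res$method, n = length(d), alternative = alternative)
}

#' Write per-sample inclusion results or classified junctions to TSV
#' @param x tibble (e.g. from [inclusion_percentage()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
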