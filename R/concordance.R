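#' Splicing event tables
#'
#' An event table has one row per differential-splicing event:
#' `gene`, `chrom`, `source_site`, `target_site` (genomic splice-site
#' coordinates, `source_site < target_site`), `kind` (`"cassette"`,
#' `"alt_promoter"` or `"other"`), `dpsi` (differential percent spliced
#' in, in \[-1, 1\], positive = more inclusion in condition A) and
#' `confidence` (posterior probability that `|dpsi|` exceeds the caller's
#' threshold). dPSI and its confidence are consumed as produced by an
#' external differential-splicing caller; the high-confidence filter
#' (e.g. `P(|dPSI| > 0.2) > 0.95`) is assumed applied upstream.
#'
#' @param path TSV with the columns above.
#' @return Tibble of events.
#' @export
read_event_table <- function(path) {
  df <- as_tibble(read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE))
  required <- c("gene", "chrom", "source_site", "target_site", "kind", "dpsi")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("event table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (any(abs(df$dpsi) > 1)) stop("|dpsi| > 1 in ", path)
  df
}

event_sites <- function(ev) c(ev$source_site, ev$target_site)

shared_site_count <- function(e1, e2, tol) {
  s1 <- event_sites(e1); s2 <- event_sites(e2)
  sum(vapply(s1, function(s) any(abs(s - s2) <= tol), logical(1)))
}

#' Match differential-splicing events between two systems
#'
#' Pairs events from two systems (e.g. two cellular models) that lie in
#' the same gene and share at least one splice-site coordinate within
#' `site_tolerance` bp. A gene contributes at most one pair: the pair
#' sharing the most sites, ties broken by the smallest combined genomic
#' span.
#'
#' @param events1,events2 event tables (see [read_event_table()]) in the
#'   same genome coordinate space.
#' @param site_tolerance matching tolerance in bp (default 0, exact).
#' @return List with `pairs` (tibble: `gene`, `chrom`, per-system event
#'   columns suffixed `_1`/`_2`, `n_shared`), and `unmatched1`,
#'   `unmatched2` (events in genes with no shared site).
#' @export
match_events <- function(events1, events2, site_tolerance = 0) {
  genes <- intersect(unique(events1$gene), unique(events2$gene))
  pairs <- list()
  matched1 <- matched2 <- integer(0)
  for (g in genes) {
    i1 <- which(events1$gene == g)
    i2 <- which(events2$gene == g)
    best <- NULL
    for (a in i1) for (b in i2) {
      ns <- shared_site_count(events1[a, ], events2[b, ], site_tolerance)
      if (ns == 0) next
      span <- (events1$target_site[a] - events1$source_site[a]) +
              (events2$target_site[b] - events2$source_site[b])
      cand <- list(a = a, b = b, n_shared = ns, span = span)
      if (is.null(best) || ns > best$n_shared ||
          (ns == best$n_shared && span < best$span)) best <- cand
    }
    if (is.null(best)) next
    e1 <- events1[best$a, ]; e2 <- events2[best$b, ]
    matched1 <- c(matched1, best$a); matched2 <- c(matched2, best$b)
    pairs[[length(pairs) + 1]] <- tibble(
      gene = g, chrom = e1$chrom,
      source_1 = e1$source_site, target_1 = e1$target_site,
      kind_1 = e1$kind, dpsi_1 = e1$dpsi,
      source_2 = e2$source_site, target_2 = e2$target_site,
      kind_2 = e2$kind, dpsi_2 = e2$dpsi,
      n_shared = best$n_shared)
  }
  list(
    pairs = if (length(pairs) > 0) do.call(rbind, pairs)
            else tibble(gene = character()),
    unmatched1 = events1[setdiff(seq_len(nrow(events1)), matched1), ],
    unmatched2 = events2[setdiff(seq_len(nrow(events2)), matched2), ]
  )
}

#' Classify a matched event pair by structural agreement
#'
#' `same_local` iff both splice sites match (within tolerance) and both
#' events are cassette/other; `alt_promoter` iff either event is an
#' alternative-promoter event; `different_event` otherwise (a shared
#' site, but a different far site).
#'
#' @param pairs tibble from [match_events()]`$pairs`.
#' @param site_tolerance bp tolerance used for the both-sites test.
#' @return Character vector, one label per pair.
#' @export
classify_event_pair <- function(pairs, site_tolerance = 0) {
  vapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    if (p$kind_1 == "alt_promoter" || p$kind_2 == "alt_promoter")
      return("alt_promoter")
    both <- abs(p$source_1 - p$source_2) <= site_tolerance &&
            abs(p$target_1 - p$target_2) <= site_tolerance
    if (both) "same_local" else "different_event"
  }, character(1))
}

#' DMRs in the neighborhood of an event
#'
#' Returns the DMRs whose interval overlaps the event's splice-site span
#' extended by `window` bp on each side.
#'
#' @param event one-row event tibble (or list with `chrom`,
#'   `source_site`, `target_site`).
#' @param dmrs DMR tibble (columns `chrom`, `start`, `end`, `log2fc`,
#'   `p_adj`, `significant`; see [call_dmrs()]).
#' @param window flank in bp (default 5000).
#' @return The overlapping subset of `dmrs`.
#' @export
dmr_proximity <- function(event, dmrs, window = 5000) {
  stopifnot(window >= 0)
  if (is.null(dmrs) || nrow(dmrs) == 0) return(dmrs)
  lo <- min(event$source_site, event$target_site) - window
  hi <- max(event$source_site, event$target_site) + window
  keep <- dmrs$chrom == event$chrom & dmrs$start < hi & dmrs$end > lo
  dmrs[keep, , drop = FALSE]
}

system_meth_sign <- function(event, dmrs) {
  # direction of the nearest significant matched DMR: +1 / -1,
  # NA if no significant DMR among the matches, 0 if significant DMRs conflict
  if (is.null(dmrs) || nrow(dmrs) == 0) return(NA_real_)
  sig <- dmrs[dmrs$significant, , drop = FALSE]
  if (nrow(sig) == 0) return(NA_real_)
  signs <- sign(sig$log2fc)
  if (length(unique(signs[signs != 0])) > 1) return(0)
  center <- (min(event$source_site, event$target_site) +
             max(event$source_site, event$target_site)) / 2
  d <- abs((sig$start + sig$end) / 2 - center)
  sign(sig$log2fc[which.min(d)])
}

#' Direction-concordance category of a same-local event pair
#'
#' With `s_i = sign(dpsi)` and `m_i` the direction of the nearest
#' significant matched DMR in system i: `meDNA_absent` when no DMR is
#' matched in either system; `concordant` iff `s_i == m_i` in both
#' systems (less methylation with less inclusion, or more with more);
#' `opposite` iff `s_i == -m_i` in both; `uncertain` otherwise — mixed
#' signs between systems, conflicting significant DMRs within a system,
#' no significant DMR among the matches, or `dpsi == 0`. With
#' `require = "either"`, systems without a usable DMR direction are
#' ignored and agreement is assessed over the remaining system(s).
#'
#' @param dpsi1,dpsi2 dPSI of the event in systems 1 and 2.
#' @param dmrs1,dmrs2 matched DMRs per system (from [dmr_proximity()]).
#' @param event1,event2 one-row events (for nearest-DMR distances).
#' @param require `"both"` (default) or `"either"`.
#' @return One of `"concordant"`, `"opposite"`, `"meDNA_absent"`,
#'   `"uncertain"`.
#' @export
concordance_category <- function(dpsi1, dpsi2, dmrs1, dmrs2,
                                 event1, event2,
                                 require = c("both", "either")) {
  require <- match.arg(require)
  n1 <- if (is.null(dmrs1)) 0 else nrow(dmrs1)
  n2 <- if (is.null(dmrs2)) 0 else nrow(dmrs2)
  if (n1 == 0 && n2 == 0) return("meDNA_absent")
  s <- c(sign(dpsi1), sign(dpsi2))
  m <- c(system_meth_sign(event1, dmrs1), system_meth_sign(event2, dmrs2))
  if (any(s == 0)) return("uncertain")
  if (any(!is.na(m) & m == 0)) return("uncertain")  # conflicting DMRs
  usable <- !is.na(m)
  if (require == "both" && !all(usable)) return("uncertain")
  if (!any(usable)) return("uncertain")
  agree <- s[usable] == m[usable]
  if (all(agree)) "concordant" else if (all(!agree)) "opposite" else "uncertain"
}

#' Classify all shared events between two systems
#'
#' End-to-end classifier: matches events across the two systems, labels
#' each matched pair structurally (`same_local` / `alt_promoter` /
#' `different_event`), and assigns each `same_local` pair a
#' direction-concordance category from the DMRs within `window` bp of
#' its splice-site span.
#'
#' @param events1,events2 event tables for systems 1 and 2.
#' @param dmrs1,dmrs2 DMR tables for systems 1 and 2.
#' @param window DMR neighborhood in bp (default 5000).
#' @param site_tolerance splice-site matching tolerance in bp.
#' @param require DMR-direction requirement, see [concordance_category()].
#' @return Tibble of concordance records: `gene`, `pair_class`,
#'   `category`, `dpsi_1`, `dpsi_2`, `n_dmrs_1`, `n_dmrs_2`. For
#'   non-`same_local` pairs the category equals the structural label.
#' @export
classify_concordance <- function(events1, events2, dmrs1, dmrs2,
                                 window = 5000, site_tolerance = 0,
                                 require = c("both", "either")) {
  require <- match.arg(require)
  m <- match_events(events1, events2, site_tolerance)
  pairs <- m$pairs
  if (nrow(pairs) == 0)
    return(tibble(gene = character(), pair_class = character(),
                  category = character(), dpsi_1 = numeric(),
                  dpsi_2 = numeric(), n_dmrs_1 = integer(),
                  n_dmrs_2 = integer()))
  pair_class <- classify_event_pair(pairs, site_tolerance)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    e1 <- list(chrom = p$chrom, source_site = p$source_1,
               target_site = p$target_1)
    e2 <- list(chrom = p$chrom, source_site = p$source_2,
               target_site = p$target_2)
    d1 <- dmr_proximity(e1, dmrs1, window)
    d2 <- dmr_proximity(e2, dmrs2, window)
    category <- if (pair_class[i] != "same_local") pair_class[i]
      else concordance_category(p$dpsi_1, p$dpsi_2, d1, d2, e1, e2, require)
    tibble(gene = p$gene, pair_class = pair_class[i], category = category,
           dpsi_1 = p$dpsi_1, dpsi_2 = p$dpsi_2,
           n_dmrs_1 = if (is.null(d1)) 0L else nrow(d1),
           n_dmrs_2 = if (is.null(d2)) 0L else nrow(d2))
  })
  do.call(rbind, rows)
}

#' Tally concordance categories
#'
#' Category counts over a set of concordance records plus the derived
#' summary fractions: the DMR-proximal count (`same_local` records minus
#' `meDNA_absent`), the DMR-proximal fraction of same-local events, the
#' concordant and uncorrelated (opposite-direction) fractions of
#' DMR-proximal events, and the concordant fraction of direction-decided
#' (concordant or opposite) events. Percentages are reported both exact
#' and rounded to the nearest integer; they are `NA` when the
#' denominator is zero.
#'
#' @param records tibble from [classify_concordance()] (needs a
#'   `category` column).
#' @return List with `counts` (named integer vector over all six
#'   categories), `n`, `same_local`, `dmr_proximal`, and the percentage
#'   fields `pct_dmr_proximal`, `pct_concordant_of_proximal`,
#'   `pct_uncorrelated_of_proximal`, `pct_concordant_of_decided`, each
#'   with a `_rounded` companion.
#' @export
tally_categories <- function(records) {
  cats <- c("concordant", "opposite", "uncertain", "meDNA_absent",
            "alt_promoter", "different_event")
  counts <- setNames(integer(length(cats)), cats)
  tab <- table(records$category)
  counts[names(tab)] <- as.integer(tab)
  unknown <- setdiff(names(tab), cats)
  if (length(unknown) > 0)
    stop("unknown category: ", paste(unknown, collapse = ", "))
  same_local <- sum(counts[c("concordant", "opposite", "uncertain",
                             "meDNA_absent")])
  proximal <- same_local - counts[["meDNA_absent"]]
  decided <- counts[["concordant"]] + counts[["opposite"]]
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  out <- list(
    counts = counts,
    n = nrow(records),
    same_local = same_local,
    dmr_proximal = proximal,
    pct_dmr_proximal = pct(proximal, same_local),
    pct_concordant_of_proximal = pct(counts[["concordant"]], proximal),
    pct_uncorrelated_of_proximal = pct(counts[["opposite"]], proximal),
    pct_concordant_of_decided = pct(counts[["concordant"]], decided)
  )
  for (f in grep("^pct_", names(out), value = TRUE))
    out[[paste0(f, "_rounded")]] <- if (is.na(out[[f]])) NA_integer_
                                    else as.integer(round(out[[f]]))
  out
}

#' Write concordance records / category summary
#' @param records tibble from [classify_concordance()].
#' @param path output TSV (records) or JSON (summary).
#' @return `path`, invisibly.
#' @export
write_concordance_records <- function(records, path) {
  write.table(as.data.frame(records), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_concordance_records
#' @param tally list from [tally_categories()].
#' @export
write_category_summary <- function(tally, path) {
  tally$counts <- as.list(tally$counts)
  jsonlite::write_json(tally, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
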