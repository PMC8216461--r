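#' Gene models: exon architecture with constant/variant roles
#'
#' A `gene_model` is a tibble of exons (one row per exon) carrying the
#' attributes `gene_id` and `strand`. Columns:
#' \describe{
#'   \item{exon_id}{label, e.g. `"C5"` or `"v6"`; unique within the gene.}
#'   \item{chrom}{sequence name.}
#'   \item{start,end}{genomic coordinates, 0-based half-open. All readers
#'     normalize to this convention (GFF3 is 1-based inclusive on disk).}
#'   \item{role}{`"constant"` or `"variant"`.}
#'   \item{ordinal}{transcription-order index, 1-based; on the `-` strand
#'     this runs against genomic coordinates.}
#' }
#' Invariants enforced at construction: `start < end`, non-overlapping
#' exon intervals, unique ids, a single contiguous variant block flanked
#' on both sides by at least one constant exon (required so that a
#' skipping junction — constant flank to constant flank — is defined).
#'
#' @param exons data frame with columns `exon_id`, `chrom`, `start`,
#'   `end`, `role`, given in transcription order (ordinals are assigned
#'   1..n in row order).
#' @param gene_id gene label.
#' @param strand `"+"` or `"-"`.
#' @return A `gene_model` tibble.
#' @export
gene_model <- function(exons, gene_id, strand = c("+", "-")) {
  strand <- match.arg(strand)
  exons <- as_tibble(exons)
  required <- c("exon_id", "chrom", "start", "end", "role")
  missing_cols <- setdiff(required, names(exons))
  if (length(missing_cols) > 0)
    stop("exon table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(exons) < 3)
    stop("a gene model needs at least three exons (variant block plus flanks)")
  exons$role <- as.character(exons$role)
  if (!all(exons$role %in% c("constant", "variant")))
    stop("exon roles must be 'constant' or 'variant'")
  if (anyDuplicated(exons$exon_id))
    stop("duplicated exon_id in gene model")
  if (any(exons$start >= exons$end))
    stop("every exon must satisfy start < end")
  ord <- order(exons$start)
  if (any(exons$end[ord][-nrow(exons)] > exons$start[ord][-1]))
    stop("overlapping exons in gene model")
  exons$ordinal <- seq_len(nrow(exons))
  # transcription order must agree with genomic order given the strand
  genomic_ok <- if (strand == "+") !is.unsorted(exons$start, strictly = TRUE)
                else !is.unsorted(rev(exons$start), strictly = TRUE)
  if (!genomic_ok)
    stop("exon rows are not in transcription order for strand ", strand)
  vb <- which(exons$role == "variant")
  if (length(vb) == 0)
    stop("gene model has no variant exon")
  if (!all(diff(vb) == 1))
    stop("variant exons must form one contiguous block")
  if (min(vb) == 1 || max(vb) == nrow(exons))
    stop("the variant block must be flanked by constant exons on both sides")
  structure(
    exons[, c("exon_id", "chrom", "start", "end", "role", "ordinal")],
    gene_id = gene_id, strand = strand,
    class = c("gene_model", class(exons))
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s strand), %d exons (%d variant)\n",
              attr(x, "gene_id"), attr(x, "strand"), nrow(x),
              sum(x$role == "variant")))
  NextMethod()
}

#' Variant-block ordinals of a gene model
#' @param model a `gene_model`.
#' @return Integer vector of ordinals of the variant exons.
#' @export
variant_block <- function(model) model$ordinal[model$role == "variant"]

#' Built-in CD44-like gene model
#'
#' A topological stand-in for the human CD44 exon architecture: constant
#' exons C1–C5, the contiguous variant cassette block v2–v10, and the
#' constant flank C16–C17, on the `+` strand. Coordinates are compressed
#' (100 bp exons, 300 bp introns, synthetic contig `chrS`): every
#' downstream operation depends only on the topology, not on real
#' genomic positions.
#'
#' @param exon_len,intron_len exon and intron lengths in bp.
#' @param offset genomic start of the first exon.
#' @param chrom contig name.
#' @return A `gene_model` with 16 exons.
#' @export
cd44_gene_model <- function(exon_len = 100, intron_len = 300,
                            offset = 1000, chrom = "chrS") {
  ids <- c(paste0("C", 1:5), paste0("v", 2:10), "C16", "C17")
  roles <- c(rep("constant", 5), rep("variant", 9), "constant", "constant")
  starts <- offset + (seq_along(ids) - 1) * (exon_len + intron_len)
  gene_model(
    tibble(exon_id = ids, chrom = chrom, start = starts,
           end = starts + exon_len, role = roles),
    gene_id = "CD44like", strand = "+"
  )
}

#' Load a gene model from a GFF3 or BED annotation
#'
#' Reads exon features for one gene and attaches constant/variant roles.
#' GFF3 coordinates (1-based inclusive) are converted to the internal
#' 0-based half-open convention; BED is already 0-based half-open.
#' Exons are ordered by transcription direction (reverse genomic order on
#' the `-` strand).
#'
#' @param path annotation file (`.gff3`/`.gff` or `.bed`).
#' @param gene_id gene to extract. For GFF3, exon features are selected
#'   when any of their `gene_id`, `Parent`, `ID` or `Name` attributes
#'   contains `gene_id`; for BED, the record name is `<gene_id>:<exon_id>`
#'   or just `<exon_id>` (then all records are taken).
#' @param role_map named character vector, data frame with columns
#'   `exon_id` and `role`, or path to a two-column TSV / YAML file
#'   mapping every exon id to `"constant"` or `"variant"`.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @return A `gene_model`.
#' @export
load_gene_model <- function(path, gene_id, role_map, format = "auto") {
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3"
              else if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
              else stop("cannot infer annotation format from ", path)
  }
  role_map <- read_role_map(role_map)
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed")
  if (format == "gff3") {
    mc <- S4Vectors::mcols(gr)
    if (!is.null(mc$type)) gr <- gr[as.character(mc$type) == "exon"]
    mc <- S4Vectors::mcols(gr)
    hit <- rep(FALSE, length(gr))
    for (col in intersect(c("gene_id", "Parent", "ID", "Name"), names(mc))) {
      v <- vapply(mc[[col]], function(x) paste(as.character(x), collapse = ","),
                  character(1))
      hit <- hit | grepl(gene_id, v, fixed = TRUE)
    }
    if (!any(hit)) stop("gene '", gene_id, "' not found in ", path)
    gr <- gr[hit]
    mc <- S4Vectors::mcols(gr)
    exon_id <- if (!is.null(mc$exon_id)) as.character(mc$exon_id)
               else if (!is.null(mc$Name)) as.character(mc$Name)
               else as.character(mc$ID)
  } else {
    nm <- S4Vectors::mcols(gr)$name
    if (is.null(nm)) stop("BED gene models need a name column")
    has_gene <- grepl(":", nm, fixed = TRUE)
    if (any(has_gene)) {
      keep <- sub(":.*$", "", nm) == gene_id
      if (!any(keep)) stop("gene '", gene_id, "' not found in ", path)
      gr <- gr[keep]
      exon_id <- sub("^[^:]*:", "", nm[keep])
    } else {
      exon_id <- nm
    }
  }
  strand <- unique(as.character(GenomicRanges::strand(gr)))
  strand <- setdiff(strand, "*")
  if (length(strand) != 1) strand <- "+"
  exons <- tibble(
    exon_id = exon_id,
    chrom   = as.character(GenomicRanges::seqnames(gr)),
    start   = GenomicRanges::start(gr) - 1L,  # GRanges is 1-based inclusive
    end     = GenomicRanges::end(gr),
    role    = NA_character_
  )
  unknown <- setdiff(exons$exon_id, names(role_map))
  if (length(unknown) > 0)
    stop("role_map lacks exon(s): ", paste(unknown, collapse = ", "))
  exons$role <- unname(role_map[exons$exon_id])
  exons <- exons[order(exons$start, decreasing = (strand == "-")), ]
  gene_model(exons, gene_id = gene_id, strand = strand)
}

read_role_map <- function(role_map) {
  if (is.character(role_map) && length(role_map) == 1 && file.exists(role_map)) {
    if (grepl("\\.ya?ml$", role_map, ignore.case = TRUE)) {
      lst <- yaml::read_yaml(role_map)
      return(vapply(lst, as.character, character(1)))
    }
    df <- read.table(role_map, header = FALSE, sep = "\t",
                     col.names = c("exon_id", "role"),
                     stringsAsFactors = FALSE)
    return(setNames(df$role, df$exon_id))
  }
  if (is.data.frame(role_map))
    return(setNames(as.character(role_map$role), role_map$exon_id))
  if (is.character(role_map) && !is.null(names(role_map))) return(role_map)
  stop("role_map must be a named vector, a data frame, or a file path")
}

#' Write a gene model to BED
#'
#' One BED6 record per exon, named `<gene_id>:<exon_id>`, score = ordinal.
#' Re-loading with [load_gene_model()] round-trips coordinates and
#' ordinals exactly.
#'
#' @param model a `gene_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_model_bed <- function(model, path) {
  df <- data.frame(
    chrom = model$chrom, start = model$start, end = model$end,
    name = paste0(attr(model, "gene_id"), ":", model$exon_id),
    score = model$ordinal, strand = attr(model, "strand")
  )
  df <- df[order(df$start), ]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Exon containing a genomic position
#'
#' @param model a `gene_model`.
#' @param chrom sequence name.
#' @param position genomic coordinate (0-based). Containment is half-open:
#'   `start <= position < end`.
#' @return The matching exon as a one-row tibble, or `NULL` when the
#'   position falls in an intron or outside the gene.
#' @export
exon_at <- function(model, chrom, position) {
  hit <- model$chrom == chrom & model$start <= position & position < model$end
  if (!any(hit)) return(NULL)
  model[which(hit)[1], ]
}
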