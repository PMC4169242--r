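#' Construct a genome layout
#'
#' A genome layout is the coordinate space all intervals live in: an ordered
#' set of named chromosomes with known lengths. It is represented as a
#' [GenomeInfoDb::Seqinfo] object, the standard container for chromosome
#' bounds in the Bioconductor stack.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param lengths Integer vector of strictly positive chromosome lengths (bp),
#'   one per chromosome.
#' @return A `Seqinfo` object.
#' @examples
#' genome_layout(c("chr2L", "chr3R"), c(23011544, 27905053))
#' @export
genome_layout <- function(chrom, lengths) {
  chrom <- as.character(chrom)
  lengths <- as.integer(lengths)
  if (length(chrom) != length(lengths)) {
    stop("`chrom` and `lengths` must have the same length")
  }
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(is.na(lengths)) || any(lengths <= 0)) {
    stop("chromosome lengths must be strictly positive integers")
  }
  GenomeInfoDb::Seqinfo(seqnames = chrom, seqlengths = lengths)
}

#' Validate and normalise a peak set
#'
#' A peak set is a sorted, internally disjoint `GRanges`. Overlapping (or
#' bookended-overlapping) input intervals are merged with a warning when
#' `merge = TRUE`, and rejected otherwise; merging keeps the maximum score.
#'
#' @param x A `GRanges` (strand is carried but ignored by all overlap
#'   arithmetic in this package).
#' @param source_label Optional label recording where the peaks came from.
#' @param merge Merge overlapping intervals instead of failing.
#' @return A sorted, disjoint `GRanges` with `source_label` stored in its
#'   metadata.
#' @export
peak_set <- function(x, source_label = NULL, merge = FALSE) {
  if (!methods::is(x, "GRanges")) stop("`x` must be a GRanges")
  if (length(x) && any(IRanges::width(x) < 1)) {
    stop("peak intervals must have width >= 1 (end > start)")
  }
  x <- GenomicRanges::sort(x, ignore.strand = TRUE)
  if (!IRanges::isDisjoint(GenomicRanges::granges(x), ignore.strand = TRUE)) {
    if (!merge) stop("peak set contains overlapping intervals")
    warning("merging overlapping intervals in peak set")
    merged <- GenomicRanges::reduce(x, ignore.strand = TRUE)
    if (!is.null(x$score)) {
      hits <- GenomicRanges::findOverlaps(merged, x, ignore.strand = TRUE)
      merged$score <- vapply(
        split(x$score[S4Vectors::subjectHits(hits)], S4Vectors::queryHits(hits)),
        max, numeric(1)
      )
    }
    x <- merged
  }
  if (!is.null(source_label)) S4Vectors::metadata(x)$source_label <- source_label
  x
}

#' Read a peak set from a BED file
#'
#' BED coordinates (0-based half-open) are converted to the in-memory 1-based
#' closed convention by [rtracklayer::import]; the numbers written back by
#' [write_bed()] are identical to the input. Overlapping records are merged
#' with a warning, because a peak set is disjoint by definition.
#'
#' @param path Path to a BED file with at least 3 tab-separated columns.
#' @param genome Optional `Seqinfo` from [genome_layout()]; when supplied,
#'   intervals are bounds-checked against it.
#' @return A sorted, disjoint `GRanges`.
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) stop("failed to parse BED file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(genome)
    GenomeInfoDb::seqinfo(gr) <- genome
  }
  peak_set(gr, source_label = basename(path), merge = TRUE)
}

#' Write a peak set to a BED file
#'
#' @param peaks A `GRanges` peak set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  rtracklayer::export(peaks, path, format = "BED")
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene` features (requiring an `ID` attribute) and, when present,
#' their `exon` children. GFF3 1-based closed coordinates are kept as-is in
#' the GRanges convention. Exons must lie within their parent gene span.
#'
#' @param path Path to a GFF3 file.
#' @param genome Optional `Seqinfo`.
#' @return A `GRanges` of genes with a `gene_id` metadata column; exons, if
#'   any, are attached as a `GRangesList` (named by gene id) in
#'   `S4Vectors::metadata(genes)$exons`.
#' @export
read_gff3 <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  if (length(genes) && (is.null(genes$ID) || anyNA(genes$ID))) {
    stop("every gene feature must carry an ID attribute")
  }
  out <- GenomicRanges::granges(genes)
  out$gene_id <- as.character(genes$ID)
  out <- GenomicRanges::sort(out, ignore.strand = TRUE)
  exons <- gr[gr$type == "exon"]
  if (length(exons)) {
    parent <- as.character(S4Vectors::unstrsplit(exons$Parent, ","))
    if (anyNA(parent) || any(parent == "")) {
      stop("every exon feature must carry a Parent attribute")
    }
    span <- out[match(parent, out$gene_id)]
    if (anyNA(GenomicRanges::start(span))) stop("exon Parent refers to unknown gene")
    inside <- GenomicRanges::start(exons) >= GenomicRanges::start(span) &
      GenomicRanges::end(exons) <= GenomicRanges::end(span) &
      as.character(GenomicRanges::seqnames(exons)) ==
        as.character(GenomicRanges::seqnames(span))
    if (!all(inside)) stop("exon outside the span of its parent gene")
    ex <- GenomicRanges::granges(exons)
    exl <- GenomicRanges::sort(
      methods::as(S4Vectors::split(ex, factor(parent, levels = out$gene_id)),
                  "GRangesList"))
    if (any(vapply(exl, function(g) !IRanges::isDisjoint(g), logical(1)))) {
      stop("exons of a gene must be non-overlapping")
    }
    S4Vectors::metadata(out)$exons <- exl
  }
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(out) <- GenomeInfoDb::seqlevels(genome)
    GenomeInfoDb::seqinfo(out) <- genome
  }
  out
}

#' Write gene models to a GFF3 file
#'
#' @param genes `GRanges` with a `gene_id` column, as from [read_gff3()] or
#'   [generate_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  out <- genes
  out$type <- "gene"
  out$ID <- genes$gene_id
  out$gene_id <- NULL
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' Total basepair overlap between two peak sets
#'
#' The total length of the intersection of two internally disjoint interval
#' sets; symmetric in its arguments and strand-agnostic.
#'
#' @param a,b `GRanges` peak sets (each internally non-overlapping).
#' @return Total overlapping basepairs (numeric scalar).
#' @export
basepair_overlap <- function(a, b) {
  for (x in list(a, b)) {
    if (!IRanges::isDisjoint(GenomicRanges::granges(x), ignore.strand = TRUE)) {
      stop("peak sets must be internally non-overlapping")
    }
  }
  ov <- GenomicRanges::intersect(GenomicRanges::granges(a),
                                 GenomicRanges::granges(b),
                                 ignore.strand = TRUE)
  sum(as.numeric(IRanges::width(ov)))
}

#' Directional peak-overlap counts
#'
#' Counts how many intervals of each set intersect (>= 1 bp) at least one
#' interval of the other. Because peak lengths differ between experiments,
#' one peak can overlap several peaks in the other set, so the two
#' directional counts differ; their average is also reported.
#'
#' @param a,b `GRanges` peak sets.
#' @return A list with `count_a`, `count_b`, `mean`, and the directional
#'   fractions `frac_a = count_a/length(a)`, `frac_b = count_b/length(b)`.
#' @export
directional_peak_overlap_counts <- function(a, b) {
  count_a <- sum(GenomicRanges::countOverlaps(a, b, ignore.strand = TRUE) > 0)
  count_b <- sum(GenomicRanges::countOverlaps(b, a, ignore.strand = TRUE) > 0)
  list(
    count_a = count_a,
    count_b = count_b,
    mean = (count_a + count_b) / 2,
    frac_a = if (length(a)) count_a / length(a) else NA_real_,
    frac_b = if (length(b)) count_b / length(b) else NA_real_
  )
}
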