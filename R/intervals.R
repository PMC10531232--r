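#' Construct a set of genomic intervals
#'
#' Intervals are represented as [GenomicRanges::GRanges] throughout the
#' package, using the R/Bioconductor convention of 1-based, fully closed
#' coordinates. Coordinates printed in genome browsers, GTF files and
#' published tables follow the same convention and are taken as-is; BED input
#' (0-based, half-open) is converted on read by [read_bed()].
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 1-based inclusive; `end >= start`.
#' @param strand strand codes (`"+"`, `"-"` or `"*"`); recycled.
#' @param id optional names for the intervals.
#' @return a `GRanges` object.
#' @examples
#' genomic_intervals("chr1", 101, 200)
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*", id = NULL) {
  if (any(end < start)) {
    stopf("invalid interval: end < start at index %d", which(end < start)[1])
  }
  if (any(start < 1)) {
    stopf("invalid interval: start < 1 at index %d", which(start < 1)[1])
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand
  )
  if (!is.null(id)) names(gr) <- id
  gr
}

#' Parse printed region strings into intervals
#'
#' Accepts strings in the browser display style, e.g.
#' `"chr1: 88,402,354-88,403,436"`; thousands separators, surrounding
#' whitespace and en dashes are tolerated. Coordinates are interpreted as
#' 1-based inclusive.
#'
#' @param x character vector of region strings.
#' @return a `GRanges` with one range per input string.
#' @export
parse_regions <- function(x) {
  x2 <- gsub(",", "", x)
  x2 <- gsub("–", "-", x2) # en dash
  m <- regmatches(x2, regexec("^\\s*([^: ]+)\\s*:\\s*([0-9]+)\\s*-\\s*([0-9]+)\\s*$", x2))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stopf("cannot parse region string: '%s'", x[bad][1])
  genomic_intervals(
    chrom = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L))
  )
}

#' Pairwise interval overlap test
#'
#' Two intervals overlap iff they share a chromosome and at least one base.
#' Strand is ignored: common-transcript matching between conditions compares
#' strandless genome coordinates.
#'
#' @param a,b `GRanges` of equal length (or length one, recycled).
#' @return logical vector.
#' @examples
#' a <- genomic_intervals("chr1", 101, 200)
#' b <- genomic_intervals("chr1", 201, 300)
#' interval_overlaps(a, b) # FALSE: abutting, no shared base
#' @export
interval_overlaps <- function(a, b) {
  if (length(a) == 1L && length(b) > 1L) a <- rep(a, length(b))
  if (length(b) == 1L && length(a) > 1L) b <- rep(b, length(a))
  stopifnot(length(a) == length(b))
  as.logical(IRanges::poverlaps(a, b, ignore.strand = TRUE))
}

#' Merge overlapping and book-ended intervals
#'
#' Produces the minimal sorted set of disjoint intervals covering the input,
#' per chromosome. Book-ended intervals (zero gap) are merged, matching the
#' default behaviour of `bedtools merge`. Strand is ignored.
#'
#' @param gr a `GRanges`.
#' @return a sorted, strand-`*` `GRanges` of disjoint intervals.
#' @export
merge_intervals <- function(gr) {
  if (length(gr) == 0L) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::reduce(gr, min.gapwidth = 1L, ignore.strand = TRUE)
}
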