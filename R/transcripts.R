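#' Assemble a transcript set
#'
#' A `TranscriptSet` bundles the multi-exon structure of assembled
#' transcripts with their tissue condition and, optionally, their spliced
#' nucleotide sequences. It is the common currency of the filtering,
#' profiling and matching stages.
#'
#' @param exons a named [GenomicRanges::GRangesList], one element per
#'   transcript, holding its exon intervals. Exons must be sorted by start
#'   and non-overlapping within a transcript; every transcript has at least
#'   one exon.
#' @param condition `NULL`, a single label recycled to all transcripts, or a
#'   character vector named by transcript id. Conventional labels are
#'   `"dry"` and `"lactating"`.
#' @param seqs `NULL` or a [Biostrings::DNAStringSet] named by transcript id
#'   (spliced transcript sequences).
#' @return an object of class `TranscriptSet`.
#' @export
transcript_set <- function(exons, condition = NULL, seqs = NULL) {
  if (!methods::is(exons, "GRangesList")) {
    stopf("`exons` must be a GRangesList named by transcript id")
  }
  ids <- names(exons)
  if (is.null(ids) || anyDuplicated(ids)) {
    stopf("transcript ids must be unique, non-NULL names on `exons`")
  }
  if (any(lengths(exons) < 1L)) stopf("every transcript needs at least one exon")
  # validate per-transcript exon structure
  starts <- BiocGenerics::start(exons)
  unsorted <- any(vapply(starts, is.unsorted, TRUE))
  if (unsorted) stopf("exons must be sorted by start within each transcript")
  n_red <- lengths(GenomicRanges::reduce(exons, min.gapwidth = 0L))
  if (any(n_red < lengths(exons))) {
    stopf("exons overlap within transcript '%s'", ids[which(n_red < lengths(exons))[1]])
  }
  if (!is.null(condition)) {
    if (length(condition) == 1L && is.null(names(condition))) {
      condition <- stats::setNames(rep(condition, length(ids)), ids)
    }
    if (!all(ids %in% names(condition))) stopf("`condition` must cover all transcript ids")
    condition <- condition[ids]
  }
  if (!is.null(seqs)) {
    if (!all(ids %in% names(seqs))) stopf("`seqs` must cover all transcript ids")
    seqs <- seqs[ids]
  }
  span <- unlist(range(exons))
  names(span) <- ids
  structure(
    list(exons = exons, span = span, condition = condition, seqs = seqs),
    class = "TranscriptSet"
  )
}

#' @export
length.TranscriptSet <- function(x) length(x$exons)

#' @export
names.TranscriptSet <- function(x) names(x$exons)

#' @export
`[.TranscriptSet` <- function(x, i) {
  if (is.logical(i)) i <- which(i)
  if (is.numeric(i)) i <- names(x$exons)[i]
  transcript_set(
    exons = x$exons[i],
    condition = if (is.null(x$condition)) NULL else x$condition[i],
    seqs = if (is.null(x$seqs)) NULL else x$seqs[i]
  )
}

#' @export
print.TranscriptSet <- function(x, ...) {
  cat(sprintf(
    "TranscriptSet: %d transcripts%s%s\n", length(x),
    if (is.null(x$condition)) "" else sprintf(" (%s)", paste(unique(x$condition), collapse = "/")),
    if (is.null(x$seqs)) "" else ", with sequences"
  ))
  invisible(x)
}

#' Transcript lengths, spans and exon counts
#'
#' The length of a transcript is its spliced length, the sum of its exon
#' widths; for the mono-exonic transcripts typical of lncRNA candidates this
#' equals the genomic span.
#'
#' @param ts a `TranscriptSet`.
#' @return `tx_lengths()` and `tx_exon_counts()` return named integer
#'   vectors; `tx_spans()` a named `GRanges` of genomic spans.
#' @export
tx_lengths <- function(ts) {
  stats::setNames(vapply(BiocGenerics::width(ts$exons), sum, 1L), names(ts))
}

#' @rdname tx_lengths
#' @export
tx_spans <- function(ts) ts$span

#' @rdname tx_lengths
#' @export
tx_exon_counts <- function(ts) stats::setNames(lengths(ts$exons), names(ts))

#' Attach spliced sequences to a transcript set
#'
#' @param ts a `TranscriptSet`.
#' @param seqs a [Biostrings::DNAStringSet] named by transcript id, or a path
#'   to a FASTA file keyed the same way.
#' @return `ts` with sequences attached.
#' @export
attach_sequences <- function(ts, seqs) {
  if (is.character(seqs)) seqs <- Biostrings::readDNAStringSet(seqs)
  # FASTA headers may carry descriptions after the id
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  transcript_set(ts$exons, condition = ts$condition, seqs = seqs)
}
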