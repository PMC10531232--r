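#' Summarize a transcript group
#'
#' Computes the length profile (min, mean, max of spliced lengths), the mean
#' exon count and, when an expression matrix is supplied, the grand mean
#' over all (transcript, sample) cells in the group (zeros included), i.e.
#' a single-number group abundance in the matrix's units.
#'
#' @param ts a non-empty `TranscriptSet`.
#' @param expr optional `ExpressionMatrix` containing the group's rows.
#' @param label group label carried through to the output.
#' @return a one-row data.frame: `group`, `n`, `length_min`, `length_mean`,
#'   `length_max`, `exon_mean`, `expr_mean`, `expr_units`.
#' @export
summarize_group <- function(ts, expr = NULL, label = "group") {
  if (length(ts) == 0L) stopf("cannot profile an empty group")
  len <- tx_lengths(ts)
  expr_mean <- NA_real_
  units <- NA_character_
  if (!is.null(expr)) {
    rows <- intersect(names(ts), rownames(expr$values))
    if (length(rows)) {
      expr_mean <- mean(expr$values[rows, , drop = FALSE])
      units <- expr$units
    }
  }
  data.frame(
    group = label, n = length(ts),
    length_min = min(len), length_mean = mean(len), length_max = max(len),
    exon_mean = mean(tx_exon_counts(ts)),
    expr_mean = expr_mean, expr_units = units,
    stringsAsFactors = FALSE
  )
}

#' Plot-ready histogram table of transcript lengths
#'
#' Bins lengths into fixed-width bins; values above `truncate_at` are
#' excluded from the binned counts (for readability when a few transcripts
#' are far longer than the rest) while the mean marker is always computed on
#' the untruncated data.
#'
#' @param lengths numeric vector of transcript lengths.
#' @param bin_width bin width in nucleotides.
#' @param origin left edge of the first bin; defaults to 0.
#' @param truncate_at optional upper limit; values strictly above it are
#'   dropped from the binned export.
#' @return list with `bins` (data.frame: `bin_start`, `bin_end`, `count`),
#'   `mean` (untruncated mean), `n` and `n_truncated`.
#' @export
histogram_data <- function(lengths, bin_width = 500, origin = 0, truncate_at = NULL) {
  if (bin_width <= 0) stopf("`bin_width` must be positive")
  full_mean <- mean(lengths)
  kept <- lengths
  if (!is.null(truncate_at)) kept <- lengths[lengths <= truncate_at]
  idx <- floor((kept - origin) / bin_width)
  counts <- table(idx)
  bin_start <- origin + as.integer(names(counts)) * bin_width
  list(
    bins = data.frame(
      bin_start = bin_start,
      bin_end = bin_start + bin_width,
      count = as.integer(counts)
    ),
    mean = full_mean,
    n = length(kept),
    n_truncated = length(lengths) - length(kept)
  )
}
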