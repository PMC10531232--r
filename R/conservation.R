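#' Per-base conservation tracks
#'
#' A `ConservationTrack` stores one numeric vector of per-base scores in
#' `[0, 1]` per chromosome (phastCons-style posterior probabilities of
#' conservation). `NA` marks bases with no data, e.g. positions that failed
#' cross-genome coordinate mapping.
#'
#' @param scores named list of numeric vectors, one per chromosome.
#' @return an object of class `ConservationTrack`.
#' @export
conservation_track <- function(scores) {
  if (is.null(names(scores)) || anyDuplicated(names(scores))) {
    stopf("`scores` must be a list named by chromosome")
  }
  rng <- range(unlist(lapply(scores, range, na.rm = TRUE), use.names = FALSE))
  if (rng[1] < 0 || rng[2] > 1) stopf("conservation scores must lie in [0, 1]")
  structure(list(scores = scores), class = "ConservationTrack")
}

#' @export
print.ConservationTrack <- function(x, ...) {
  cat(sprintf(
    "ConservationTrack: %d chromosomes, %s scored bases\n",
    length(x$scores), format(sum(lengths(x$scores)), big.mark = ",")
  ))
  invisible(x)
}

#' Read/write a conservation track as TSV
#'
#' Layout: columns `chrom`, `pos` (1-based), `score`; unlisted positions are
#' treated as missing data.
#'
#' @param path TSV path.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param track a `ConservationTrack` to write.
#' @return `read_track()` a `ConservationTrack`.
#' @export
read_track <- function(path, chrom_sizes) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  scores <- lapply(names(chrom_sizes), function(ch) {
    v <- rep(NA_real_, chrom_sizes[[ch]])
    sel <- df$chrom == ch
    v[df$pos[sel]] <- df$score[sel]
    v
  })
  names(scores) <- names(chrom_sizes)
  conservation_track(scores)
}

#' @rdname read_track
#' @export
write_track <- function(track, path) {
  parts <- lapply(names(track$scores), function(ch) {
    v <- track$scores[[ch]]
    keep <- !is.na(v)
    data.frame(chrom = ch, pos = which(keep), score = v[keep])
  })
  utils::write.table(do.call(rbind, parts), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Mean conservation score over intervals
#'
#' Aggregates per-base scores by the arithmetic mean over each interval,
#' the default statistic of bigWig summary tools. Bases with missing data
#' are excluded from both numerator and denominator; an interval with no
#' scored base at all (e.g. a failed coordinate lift) yields `NA` and is
#' reported as unmapped by downstream steps.
#'
#' @param track a [conservation_track()].
#' @param intervals a `GRanges`.
#' @return numeric vector of mean scores (named if `intervals` has names).
#' @export
interval_mean_score <- function(track, intervals) {
  out <- rep(NA_real_, length(intervals))
  chrom <- as.character(GenomicRanges::seqnames(intervals))
  s <- BiocGenerics::start(intervals)
  e <- BiocGenerics::end(intervals)
  for (i in seq_along(intervals)) {
    v <- track$scores[[chrom[i]]]
    if (is.null(v) || s[i] > length(v)) next
    out[i] <- mean(v[s[i]:min(e[i], length(v))], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  names(out) <- names(intervals)
  out
}

#' Rank conservation scores and apply retention thresholds
#'
#' Scores are ranked ascending (rank 1 = least conserved; ties broken by
#' transcript id for reproducibility). Retention uses a strict cutoff:
#' candidates in the `"lncRNA"` group are retained above `cutoff_all`
#' (default 0.5), candidates in the `"common"` group above the laxer
#' `cutoff_common` (default 0.25). Transcripts with missing scores are
#' excluded and counted as unmapped.
#'
#' @param scores data.frame with columns `id`, `group` (one of `"all"`,
#'   `"intergenic"`, `"lncRNA"`, `"common"`) and `score`.
#' @param cutoff_all retention cutoff for the lncRNA group.
#' @param cutoff_common retention cutoff for the common group.
#' @return list with `table` (scores plus `rank` and `retained` columns,
#'   ranked within group), `retained` (character ids) and `n_unmapped`.
#' @export
rank_and_threshold <- function(scores, cutoff_all = 0.5, cutoff_common = 0.25) {
  stopifnot(all(c("id", "group", "score") %in% names(scores)))
  unmapped <- is.na(scores$score)
  tab <- scores[!unmapped, , drop = FALSE]
  tab <- tab[order(tab$group, tab$score, tab$id), , drop = FALSE]
  tab$rank <- stats::ave(seq_len(nrow(tab)), tab$group, FUN = seq_along)
  cutoff <- ifelse(tab$group == "common", cutoff_common, cutoff_all)
  tab$retained <- tab$group %in% c("lncRNA", "common") & tab$score > cutoff
  rownames(tab) <- NULL
  list(
    table = tab,
    retained = tab$id[tab$retained],
    n_unmapped = sum(unmapped)
  )
}
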