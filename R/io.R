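#' Read assembled transcript models from a GTF file
#'
#' Parses `exon` features (GTF 2.2 dialect, 1-based inclusive coordinates)
#' and groups them under their `transcript_id` attribute. If `transcript`
#' rows are present, exons falling outside their transcript span raise a
#' validation error.
#'
#' @param path path to a GTF file.
#' @param condition optional condition label attached to every transcript.
#' @return a [transcript_set()].
#' @export
read_gtf <- function(path, condition = NULL) {
  if (!file.exists(path)) stopf("GTF file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gtf")
  if (is.null(gr$transcript_id)) stopf("GTF has no transcript_id attributes: %s", path)
  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(ex) == 0L) stopf("GTF contains no exon features: %s", path)
  exl <- GenomicRanges::GRangesList(lapply(
    split(ex, ex$transcript_id),
    function(g) GenomicRanges::sort(g[, character(0)])
  ))
  tx <- gr[tolower(as.character(gr$type)) == "transcript"]
  if (length(tx) > 0L) {
    spans <- unlist(range(exl))
    m <- match(tx$transcript_id, names(exl))
    ok <- is.na(m) |
      (BiocGenerics::start(spans)[m] >= BiocGenerics::start(tx) &
        BiocGenerics::end(spans)[m] <= BiocGenerics::end(tx))
    if (!all(ok)) {
      stopf("exon outside its transcript span for '%s'", tx$transcript_id[!ok][1])
    }
  }
  transcript_set(exl, condition = condition)
}

#' Write a transcript set to GTF
#'
#' Emits one `transcript` row plus one `exon` row per exon, with
#' `gene_id`/`transcript_id` attributes, in GTF 2.2 layout.
#'
#' @param ts a `TranscriptSet`.
#' @param path output path.
#' @param source source field for column 2.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ts, path, source = "mammolnc") {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(chrom, type, start, end, strand, id) {
    sprintf(
      "%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
      chrom, source, type, start, end, strand, id, id
    )
  }
  for (id in names(ts)) {
    ex <- ts$exons[[id]]
    sp <- range(ex)
    strand <- as.character(BiocGenerics::strand(sp))
    if (strand == "*") strand <- "."
    writeLines(fmt(
      as.character(GenomicRanges::seqnames(sp)), "transcript",
      BiocGenerics::start(sp), BiocGenerics::end(sp), strand, id
    ), con)
    for (k in seq_along(ex)) {
      writeLines(fmt(
        as.character(GenomicRanges::seqnames(ex))[k], "exon",
        BiocGenerics::start(ex)[k], BiocGenerics::end(ex)[k], strand, id
      ), con)
    }
  }
  invisible(path)
}

#' Read and write BED intervals
#'
#' BED uses 0-based half-open coordinates; conversion to the internal
#' 1-based closed convention is handled by rtracklayer.
#'
#' @param path file path.
#' @param gr a `GRanges` to write.
#' @return `read_bed()` a `GRanges`; `write_bed()` the path, invisibly.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  rtracklayer::import(path, format = "bed")
}

#' @rdname read_bed
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Expression matrices
#'
#' An `ExpressionMatrix` is a non-negative transcripts-by-samples matrix
#' tagged with its abundance units (`"FPKM"` for the differential-expression
#' stage, `"TPM"` for co-expression) and a per-sample condition label.
#'
#' @param values numeric matrix, rows named by transcript, columns by sample.
#' @param units `"FPKM"` or `"TPM"`.
#' @param conditions character vector of per-sample condition labels, named
#'   by sample id (or unnamed, in column order).
#' @return an object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, units = c("FPKM", "TPM"), conditions) {
  units <- match.arg(units)
  if (!is.matrix(values) || !is.numeric(values)) stopf("`values` must be a numeric matrix")
  if (any(values < 0)) stopf("expression values must be non-negative")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stopf("row (transcript) ids must be unique and non-NULL")
  }
  if (ncol(values) < 1L) stopf("need at least one sample column")
  if (is.null(names(conditions))) {
    if (length(conditions) != ncol(values)) stopf("`conditions` must match sample count")
    names(conditions) <- colnames(values)
  }
  if (!all(colnames(values) %in% names(conditions))) {
    stopf("`conditions` must cover every sample id")
  }
  structure(
    list(values = values, units = units, conditions = conditions[colnames(values)]),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf(
    "ExpressionMatrix: %d transcripts x %d samples [%s] (%s)\n",
    nrow(x$values), ncol(x$values), x$units,
    paste(sprintf("%s=%d", names(table(x$conditions)), table(x$conditions)), collapse = ", ")
  ))
  invisible(x)
}

#' Read/write an expression matrix as TSV
#'
#' The TSV layout is one row per transcript with the id in the first column
#' and one column per sample; conditions travel in a two-column sidecar TSV
#' (`sample`, `condition`).
#'
#' @param path expression TSV path.
#' @param conditions a named condition vector, or path to the sidecar TSV.
#' @param units abundance units tag.
#' @param em an `ExpressionMatrix` to write.
#' @param cond_path sidecar TSV path to write conditions to.
#' @return `read_expression()` an `ExpressionMatrix`.
#' @export
read_expression <- function(path, conditions, units = c("FPKM", "TPM")) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- as.character(df[[1]])
  if (is.character(conditions) && length(conditions) == 1L && file.exists(conditions)) {
    cd <- utils::read.delim(conditions, stringsAsFactors = FALSE)
    conditions <- stats::setNames(cd$condition, cd$sample)
  }
  expression_matrix(values, units = match.arg(units), conditions = conditions)
}

#' @rdname read_expression
#' @export
write_expression <- function(em, path, cond_path = NULL) {
  df <- data.frame(transcript = rownames(em$values), em$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cond_path)) {
    utils::write.table(
      data.frame(sample = names(em$conditions), condition = unname(em$conditions)),
      cond_path,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(path)
}
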