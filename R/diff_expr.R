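#' Match common candidates between conditions
#'
#' Pairs every dry candidate interval with every lactating candidate it
#' overlaps by at least one base (same chromosome, strand ignored). With
#' merged (disjoint) candidate sets each candidate has at most one partner,
#' yielding the "common" lncRNAs present in both physiological states.
#'
#' @param dry,lact `GRanges` of merged candidate intervals, named by
#'   candidate id (unnamed inputs get positional ids).
#' @return data.frame: `pair`, `dry_id`, `lact_id` plus interval columns.
#' @export
match_common <- function(dry, lact) {
  if (is.null(names(dry))) names(dry) <- sprintf("dry_%d", seq_along(dry))
  if (is.null(names(lact))) names(lact) <- sprintf("lact_%d", seq_along(lact))
  h <- GenomicRanges::findOverlaps(dry, lact, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(h)
  si <- S4Vectors::subjectHits(h)
  data.frame(
    pair = sprintf("pair_%d", seq_along(qi)),
    dry_id = names(dry)[qi],
    lact_id = names(lact)[si],
    chrom = as.character(GenomicRanges::seqnames(dry))[qi],
    dry_start = BiocGenerics::start(dry)[qi],
    dry_end = BiocGenerics::end(dry)[qi],
    lact_start = BiocGenerics::start(lact)[si],
    lact_end = BiocGenerics::end(lact)[si],
    stringsAsFactors = FALSE
  )
}

#' Presence filter for common pairs
#'
#' A pair is retained only if its dry transcript shows non-zero expression
#' in at least half of the dry samples and its lactating transcript in at
#' least half of the lactating samples (ceiling for odd counts).
#'
#' @param pairs data.frame from [match_common()].
#' @param expr an `ExpressionMatrix` (FPKM) with both conditions.
#' @return `pairs` restricted to surviving rows, with `dry_present` /
#'   `lact_present` count columns appended.
#' @export
presence_filter_pairs <- function(pairs, expr) {
  dry_samples <- names(expr$conditions)[expr$conditions == "dry"]
  lact_samples <- names(expr$conditions)[expr$conditions == "lactating"]
  need_dry <- ceiling(length(dry_samples) / 2)
  need_lact <- ceiling(length(lact_samples) / 2)
  dp <- rowSums(expr$values[pairs$dry_id, dry_samples, drop = FALSE] > 0)
  lp <- rowSums(expr$values[pairs$lact_id, lact_samples, drop = FALSE] > 0)
  pairs$dry_present <- as.integer(dp)
  pairs$lact_present <- as.integer(lp)
  pairs[dp >= need_dry & lp >= need_lact, , drop = FALSE]
}

#' Choose between pooled and Welch t-tests
#'
#' Operationalizes "t-test chosen based on variance" as a two-sided F
#' pre-test of the variance ratio (larger sample variance in the numerator):
#' if the F-test rejects at `alpha_var` the group variances are treated as
#' unequal and Welch's t-test is used, otherwise the pooled-variance test.
#' The decision is symmetric in its arguments.
#'
#' @param x,y numeric expression vectors (length >= 2).
#' @param alpha_var significance level of the variance pre-test.
#' @return `"pooled"`, `"welch"`, or `"degenerate"` when both groups have
#'   zero variance; the pre-test p-value is attached as attribute `"p"`.
#' @export
choose_test <- function(x, y, alpha_var = 0.05) {
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    return("degenerate")
  }
  if (vx >= vy) {
    f <- vx / vy
    df1 <- length(x) - 1L
    df2 <- length(y) - 1L
  } else {
    f <- vy / vx
    df1 <- length(y) - 1L
    df2 <- length(x) - 1L
  }
  pf_up <- stats::pf(f, df1, df2, lower.tail = FALSE)
  p <- min(1, 2 * min(pf_up, 1 - pf_up))
  structure(if (p < alpha_var) "welch" else "pooled", p = p)
}

#' Two-sample t-test (pooled or Welch)
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param test `"pooled"` (equal-variance) or `"welch"`
#'   (Welch-Satterthwaite).
#' @return list with `t` and two-sided `p`.
#' @export
ttest_pair <- function(x, y, test = c("pooled", "welch")) {
  test <- match.arg(test)
  if (length(x) < 2L || length(y) < 2L) stopf("each group needs at least 2 values")
  res <- stats::t.test(x, y, var.equal = (test == "pooled"))
  list(t = unname(res$statistic), p = unname(res$p.value))
}

#' Differential expression over common pairs
#'
#' For each pair, extracts the dry transcript's FPKM across dry samples and
#' the lactating transcript's FPKM across lactating samples, picks the test
#' with [choose_test()], and reports the two-sided t-test. Calls are made at
#' a strict `p < alpha`: significant pairs are `up_dry` or `up_lact` by the
#' sign of the mean difference, the rest `ns`.
#'
#' @param pairs data.frame from [match_common()] (after presence filtering).
#' @param expr an `ExpressionMatrix` (FPKM) covering both conditions.
#' @param alpha significance threshold.
#' @param alpha_var variance pre-test level.
#' @return data.frame: `pair`, `dry_id`, `lact_id`, `dry_mean`, `lact_mean`,
#'   `test`, `t`, `p`, `call`.
#' @export
run_de <- function(pairs, expr, alpha = 0.05, alpha_var = 0.05) {
  dry_samples <- names(expr$conditions)[expr$conditions == "dry"]
  lact_samples <- names(expr$conditions)[expr$conditions == "lactating"]
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- expr$values[pairs$dry_id[i], dry_samples]
    y <- expr$values[pairs$lact_id[i], lact_samples]
    test <- choose_test(x, y, alpha_var = alpha_var)
    if (test == "degenerate") {
      return(data.frame(
        pair = pairs$pair[i], dry_id = pairs$dry_id[i], lact_id = pairs$lact_id[i],
        dry_mean = mean(x), lact_mean = mean(y),
        test = "degenerate", t = NA_real_, p = NA_real_, call = "ns",
        stringsAsFactors = FALSE
      ))
    }
    tt <- ttest_pair(x, y, test)
    data.frame(
      pair = pairs$pair[i], dry_id = pairs$dry_id[i], lact_id = pairs$lact_id[i],
      dry_mean = mean(x), lact_mean = mean(y),
      test = test, t = tt$t, p = tt$p,
      call = if (!is.na(tt$p) && tt$p < alpha) {
        if (mean(x) > mean(y)) "up_dry" else "up_lact"
      } else {
        "ns"
      },
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Summarize differential expression calls
#'
#' Counts significant pairs at a strict `p < alpha` and splits them by the
#' direction of the mean difference. Accepts either the output of
#' [run_de()] or any data.frame with `dry_mean`, `lact_mean` and `p`
#' columns, such as a published table of per-condition means and p-values.
#'
#' @param results data.frame with columns `dry_mean`, `lact_mean`, `p`.
#' @param alpha significance threshold.
#' @return list with counts: `total`, `significant`, `up_dry`, `up_lact`,
#'   `ns`.
#' @export
summarize_de <- function(results, alpha = 0.05) {
  stopifnot(all(c("dry_mean", "lact_mean", "p") %in% names(results)))
  sig <- !is.na(results$p) & results$p < alpha
  up_dry <- sig & results$dry_mean > results$lact_mean
  list(
    total = nrow(results),
    significant = sum(sig),
    up_dry = sum(up_dry),
    up_lact = sum(sig) - sum(up_dry),
    ns = nrow(results) - sum(sig)
  )
}

#' Bundled common-lncRNA differential expression table
#'
#' A curated summary table of common lncRNAs between dry and lactating
#' bovine mammary tissue: one row per common pair with the genomic region
#' of the candidate in each condition, its mean expression (FPKM) per
#' condition, and the reported two-sided t-test p-value. Censored p-values
#' printed as "< x" are parsed to x, which is exact for every thresholding
#' purpose at usual significance levels.
#'
#' @return data.frame with columns `dry_region`, `dry_mean`, `lact_region`,
#'   `lact_mean`, `p` plus parsed interval columns.
#' @export
common_lncrna_table <- function() {
  path <- system.file("extdata", "common_lncrna_de.tsv", package = "mammolnc")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$dry_mean <- df$dry_fpkm
  df$lact_mean <- df$lact_fpkm
  df$p <- as.numeric(sub("^<", "", df$p_value))
  dry <- parse_regions(df$dry_region)
  lact <- parse_regions(df$lact_region)
  df$chrom <- as.character(GenomicRanges::seqnames(dry))
  df$dry_start <- BiocGenerics::start(dry)
  df$dry_end <- BiocGenerics::end(dry)
  df$lact_start <- BiocGenerics::start(lact)
  df$lact_end <- BiocGenerics::end(lact)
  df
}
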