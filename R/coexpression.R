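#' Presence filter for an expression matrix
#'
#' Removes low-presence rows before correlation analysis: a transcript is
#' kept only if it shows non-zero expression in at least `min_samples`
#' samples. The rationale is that rows dominated by zeros generate spurious
#' correlations; the mirrored literal rule (drop rows with `min_samples` or
#' more zero samples) is available via `rule = "max_zeros"`.
#'
#' @param em an `ExpressionMatrix`.
#' @param min_samples presence threshold (default 5).
#' @param rule `"min_expressed"` (default) or `"max_zeros"`.
#' @return the filtered `ExpressionMatrix`.
#' @export
presence_filter_matrix <- function(em, min_samples = 5L,
                                   rule = c("min_expressed", "max_zeros")) {
  rule <- match.arg(rule)
  nz <- rowSums(em$values > 0)
  keep <- if (rule == "min_expressed") {
    nz >= min_samples
  } else {
    (ncol(em$values) - nz) < min_samples
  }
  expression_matrix(em$values[keep, , drop = FALSE], em$units, em$conditions)
}

#' Correlate lncRNA expression with coding-gene expression
#'
#' Computes the Pearson correlation (Spearman via `method`) between every
#' lncRNA row and every gene row across the shared samples, with the
#' two-sided p-value from the t transform ([r_to_p()]). lncRNA-lncRNA and
#' gene-gene pairs are excluded. Zero-variance rows cannot be correlated and
#' are skipped with a warning. A Benjamini-Hochberg adjusted column is
#' appended for information only; selection downstream uses raw p-values.
#'
#' @param em an `ExpressionMatrix` (typically TPM, presence-filtered).
#' @param lnc_ids character vector of row ids flagged as lncRNAs; all other
#'   rows are treated as coding genes.
#' @param method correlation method.
#' @return data.frame: `lnc`, `gene`, `r`, `n`, `p`, `padj`.
#' @export
correlate_lnc_genes <- function(em, lnc_ids, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ids <- rownames(em$values)
  lnc_ids <- intersect(lnc_ids, ids)
  gene_ids <- setdiff(ids, lnc_ids)
  if (length(lnc_ids) == 0L || length(gene_ids) == 0L) {
    stopf("need at least one lncRNA row and one gene row")
  }
  n <- ncol(em$values)
  if (n < 3L) stopf("need at least 3 samples")
  lv <- t(em$values[lnc_ids, , drop = FALSE])
  gv <- t(em$values[gene_ids, , drop = FALSE])
  zero_l <- apply(lv, 2, stats::sd) == 0
  zero_g <- apply(gv, 2, stats::sd) == 0
  if (any(zero_l) || any(zero_g)) {
    warnf("%d zero-variance rows skipped", sum(zero_l) + sum(zero_g))
    lv <- lv[, !zero_l, drop = FALSE]
    gv <- gv[, !zero_g, drop = FALSE]
  }
  if (ncol(lv) == 0L || ncol(gv) == 0L) {
    return(data.frame(
      lnc = character(0), gene = character(0), r = numeric(0),
      n = integer(0), p = numeric(0), padj = numeric(0)
    ))
  }
  rmat <- stats::cor(lv, gv, method = method)
  out <- data.frame(
    lnc = rep(colnames(lv), times = ncol(gv)),
    gene = rep(colnames(gv), each = ncol(lv)),
    r = as.vector(rmat),
    n = n,
    stringsAsFactors = FALSE
  )
  out$p <- r_to_p(out$r, n)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Convert a correlation coefficient to a two-sided p-value
#'
#' Uses the exact null distribution of the Pearson correlation under
#' bivariate normality: `t = r * sqrt(n - 2) / sqrt(1 - r^2)` referred to a
#' t distribution with `n - 2` degrees of freedom. `|r| = 1` maps to
#' `p = 0`.
#'
#' @param r correlation coefficient(s) in `[-1, 1]`.
#' @param n number of paired samples (>= 3).
#' @return two-sided p-value(s).
#' @export
r_to_p <- function(r, n) {
  if (any(n < 3L)) stopf("need n >= 3")
  if (any(abs(r) > 1 + 1e-12)) stopf("|r| must not exceed 1")
  r <- pmin(1, pmax(-1, r))
  p <- rep(0, length(r))
  ok <- abs(r) < 1
  tstat <- r[ok] * sqrt(n - 2) / sqrt(1 - r[ok]^2)
  p[ok] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p
}

#' Per-lncRNA gene clusters and top correlate
#'
#' For each lncRNA: the cluster of genes correlated at raw `p < alpha`
#' (sorted by ascending p), and the single most significant correlate (ties
#' broken by larger `|r|`, then lexicographic gene id). lncRNAs with an
#' empty cluster are flagged as having no association.
#'
#' @param results data.frame from [correlate_lnc_genes()].
#' @param alpha significance threshold.
#' @return list with `clusters` (named list of data.frames), `top`
#'   (data.frame: `lnc`, `gene`, `r`, `p`, `no_association`).
#' @export
coexpression_clusters <- function(results, alpha = 0.05) {
  split_res <- split(results, results$lnc)
  clusters <- lapply(split_res, function(df) {
    cl <- df[df$p < alpha, , drop = FALSE]
    cl[order(cl$p, -abs(cl$r), cl$gene), , drop = FALSE]
  })
  top <- do.call(rbind, lapply(names(split_res), function(l) {
    df <- split_res[[l]]
    df <- df[order(df$p, -abs(df$r), df$gene), , drop = FALSE]
    hit <- df[1, , drop = FALSE]
    data.frame(
      lnc = l, gene = hit$gene, r = hit$r, p = hit$p,
      no_association = nrow(clusters[[l]]) == 0L,
      stringsAsFactors = FALSE
    )
  }))
  rownames(top) <- NULL
  list(clusters = clusters, top = top)
}
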