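#' Genotype containers
#'
#' A `GenotypeMatrix` couples an individuals-by-variants dosage matrix
#' (values 0/1/2, `NA` allowed) with variant metadata (`chrom`, `pos`,
#' `id`).
#'
#' @param dosages integer/numeric matrix, individuals in rows, variants in
#'   columns (column names = variant ids).
#' @param map data.frame with one row per variant: `chrom`, `pos` and
#'   optionally `id`.
#' @return an object of class `GenotypeMatrix`.
#' @export
genotype_matrix <- function(dosages, map) {
  rng <- suppressWarnings(range(dosages, na.rm = TRUE))
  if (rng[1] < 0 || rng[2] > 2 ||
    (!is.integer(dosages) && !all(dosages == round(dosages), na.rm = TRUE))) {
    stopf("dosages must be 0, 1, 2 or NA")
  }
  if (nrow(map) != ncol(dosages)) stopf("`map` must have one row per variant")
  if (is.null(map$id)) {
    map$id <- colnames(dosages) %||% sprintf("var_%d", seq_len(nrow(map)))
  }
  colnames(dosages) <- map$id
  structure(list(dosages = dosages, map = map), class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf(
    "GenotypeMatrix: %d individuals x %d variants\n",
    nrow(x$dosages), ncol(x$dosages)
  ))
  invisible(x)
}

#' Variant quality control
#'
#' Removes variants with observed minor allele frequency below `maf_min` or
#' a 1-df Hardy-Weinberg chi-square p-value below `hwe_p_min`. Frequencies
#' and genotype counts are computed from observed (non-missing) dosages;
#' monomorphic variants have MAF 0 and are removed.
#'
#' @param geno a `GenotypeMatrix`.
#' @param maf_min minimum minor allele frequency (default 0.005).
#' @param hwe_p_min minimum HWE p-value (default 1e-8).
#' @return the filtered `GenotypeMatrix`, with a `qc` attribute (data.frame
#'   of per-variant `maf`, `hwe_p`, `kept`).
#' @export
variant_qc <- function(geno, maf_min = 0.005, hwe_p_min = 1e-8) {
  d <- geno$dosages
  n1 <- colSums(d == 1, na.rm = TRUE)
  n2 <- colSums(d == 2, na.rm = TRUE)
  nt <- if (anyNA(d)) colSums(!is.na(d)) else rep(nrow(d), ncol(d))
  n0 <- nt - n1 - n2
  p <- (n1 + 2 * n2) / (2 * nt) # alt allele frequency
  maf <- pmin(p, 1 - p)
  hwe_p <- hwe_chisq_p(n0, n1, n2)
  kept <- maf >= maf_min & hwe_p >= hwe_p_min
  # already-validated dosages: rebuild without a second validation pass
  out <- structure(
    list(
      dosages = d[, kept, drop = FALSE],
      map = geno$map[kept, , drop = FALSE]
    ),
    class = "GenotypeMatrix"
  )
  attr(out, "qc") <- data.frame(
    id = geno$map$id, maf = maf, hwe_p = hwe_p, kept = kept,
    stringsAsFactors = FALSE
  )
  out
}

# 1-df chi-square HWE test from genotype counts (vectorized).
hwe_chisq_p <- function(n0, n1, n2) {
  nt <- n0 + n1 + n2
  p <- (n1 + 2 * n2) / (2 * nt)
  q <- 1 - p
  e0 <- nt * q^2
  e1 <- nt * 2 * p * q
  e2 <- nt * p^2
  chi <- rep(0, length(nt))
  poly <- p > 0 & p < 1
  chi[poly] <- (n0[poly] - e0[poly])^2 / e0[poly] +
    (n1[poly] - e1[poly])^2 / e1[poly] +
    (n2[poly] - e2[poly])^2 / e2[poly]
  stats::pchisq(chi, df = 1, lower.tail = FALSE)
}

#' Partition variants by proximity to lncRNA intervals
#'
#' A variant belongs to the `lnc` partition iff its position falls within
#' any candidate interval extended by `window` bases on both sides (the
#' extension captures linked flanking variation); all other variants form
#' the `rest` partition.
#'
#' @param map variant metadata data.frame (`chrom`, `pos`).
#' @param lnc a `GRanges` of lncRNA candidate intervals.
#' @param window extension in bases on each side (default 10 kb).
#' @return list with `assignment` (factor `lnc`/`rest` per variant), `m1`,
#'   `m2`.
#' @export
assign_partition <- function(map, lnc, window = 10000L) {
  if (length(lnc) == 0L) stopf("`lnc` interval set must be non-empty")
  pts <- GenomicRanges::GRanges(map$chrom, IRanges::IRanges(map$pos, map$pos))
  ext <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(lnc),
    IRanges::IRanges(
      pmax(1L, BiocGenerics::start(lnc) - window),
      BiocGenerics::end(lnc) + window
    )
  )
  inside <- GenomicRanges::countOverlaps(pts, ext, ignore.strand = TRUE) > 0L
  m1 <- sum(inside)
  m2 <- sum(!inside)
  if (m1 == 0L || m2 == 0L) {
    stopf("degenerate partition: m1 = %d, m2 = %d (need both >= 1)", m1, m2)
  }
  list(
    assignment = factor(ifelse(inside, "lnc", "rest"), levels = c("lnc", "rest")),
    m1 = m1, m2 = m2
  )
}

#' Build a genomic relationship matrix
#'
#' `G = Z Z' / m` over standardized genotypes: each variant column is
#' mean-imputed for missing dosages, centered, and scaled to unit
#' *population* variance (divide-by-n), which makes `mean(diag(G)) = 1`
#' exactly for any variant set.
#'
#' @param dosages dosage matrix (individuals x variants) or a
#'   `GenotypeMatrix`.
#' @return the `n x n` GRM with attribute `m` (number of variants).
#' @export
build_grm <- function(dosages) {
  if (methods::is(dosages, "GenotypeMatrix")) dosages <- dosages$dosages
  if (ncol(dosages) < 1L) stopf("need at least one variant")
  Z <- dosages
  storage.mode(Z) <- "double"
  if (anyNA(Z)) {
    na_at <- which(is.na(Z), arr.ind = TRUE)
    Z[na_at] <- colMeans(Z, na.rm = TRUE)[na_at[, 2]]
  }
  n <- nrow(Z)
  mu <- colMeans(Z)
  Z <- Z - rep(mu, each = n)
  sdp <- sqrt(colMeans(Z^2))
  if (any(sdp == 0)) {
    stopf("zero-variance variant after imputation: %s",
      paste(colnames(dosages)[sdp == 0], collapse = ", ")
    )
  }
  Z <- Z / rep(sdp, each = n)
  G <- tcrossprod(Z) / ncol(Z)
  attr(G, "m") <- ncol(Z)
  G
}

#' Two-component REML for partitioned genetic variance
#'
#' Fits `y = Xb + g1 + g2 + e` with `g1 ~ N(0, G1 s1)`, `g2 ~ N(0, G2 s2)`,
#' `e ~ N(0, R se)` where `R = diag(1/r)` inflates residual variance for
#' records with reliability `r < 1`. The restricted likelihood is maximized
#' by Fisher scoring on `(s1, s2, se)` with the expected information matrix;
#' components driven negative are pinned at a small non-negative floor. The
#' covariance of the estimates is the inverse expected information at the
#' optimum. `method = "mc"` replaces the exact trace terms by seeded
#' Hutchinson (Rademacher probe) estimates, trading exactness for fewer
#' large matrix products; it reproduces exact-mode estimates up to Monte
#' Carlo error.
#'
#' @param y phenotype vector (e.g. deregressed PTAs).
#' @param G1,G2 genomic relationship matrices (n x n).
#' @param X fixed-effect design matrix; default intercept only.
#' @param reliability per-record reliabilities in (0, 1]; default 1.
#' @param init optional starting values `c(s1, s2, se)`.
#' @param max_iter,tol iteration control (relative parameter change).
#' @param method `"exact"` or `"mc"`.
#' @param n_probes number of Hutchinson probes for `method = "mc"`.
#' @param seed RNG seed for the probes.
#' @return list: `varcomp` (named estimates), `vcov` (3x3), `loglik`,
#'   `iterations`, `converged`, `pinned` (logical per component),
#'   `identifiable` (FALSE when the information matrix is near-singular,
#'   e.g. `G1 == G2`).
#' @export
reml_two_vc <- function(y, G1, G2, X = NULL, reliability = NULL, init = NULL,
                        max_iter = 50L, tol = 1e-5,
                        method = c("exact", "mc"), n_probes = 30L, seed = NULL) {
  method <- match.arg(method)
  n <- length(y)
  stopifnot(nrow(G1) == n, nrow(G2) == n)
  if (is.null(X)) X <- matrix(1, n, 1)
  if (is.null(reliability)) reliability <- rep(1, n)
  if (any(reliability <= 0 | reliability > 1)) stopf("reliabilities must be in (0, 1]")
  rdiag <- 1 / reliability
  vy <- stats::var(y)
  floor_v <- 1e-6 * vy
  rmat <- diag(rdiag)
  if (is.null(init)) {
    # Haseman-Elston moment regression of y-cross-products on the
    # relationship matrices: a cheap, consistent starting point that
    # typically halves the number of scoring iterations
    yc <- y - mean(y)
    mats <- list(G1, G2, rmat)
    A <- matrix(0, 3, 3)
    b <- numeric(3)
    for (a in 1:3) {
      for (bb in a:3) A[a, bb] <- A[bb, a] <- sum(mats[[a]] * mats[[bb]])
      b[a] <- sum(yc * (mats[[a]] %*% yc))
    }
    init <- tryCatch(solve(A, b), error = function(e) NULL)
    if (!is.null(init)) init <- pmin(pmax(init, 0.01 * vy), vy)
  }
  theta <- init %||% (c(0.25, 0.25, 0.5) * vy)
  probes <- NULL
  if (method == "mc") {
    probes <- with_seed(
      seed %||% 1L,
      matrix(sample(c(-1, 1), n * n_probes, replace = TRUE), n, n_probes)
    )
  }
  vmats <- list(G1, G2, rmat)
  pinned <- rep(FALSE, 3L)
  converged <- FALSE
  iter <- 0L
  ll <- -Inf
  FI <- NULL
  sc <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    V <- theta[1] * G1 + theta[2] * G2 + theta[3] * diag(rdiag)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) stopf("V is not positive definite at iteration %d", iter)
    Vinv <- chol2inv(ch)
    VinvX <- Vinv %*% X
    XtVinvX <- crossprod(X, VinvX)
    P <- Vinv - VinvX %*% solve(XtVinvX, t(VinvX))
    Py <- P %*% y
    ll_new <- -0.5 * (2 * sum(log(diag(ch))) +
      determinant(XtVinvX, logarithm = TRUE)$modulus +
      sum(y * Py))
    if (method == "exact") {
      PG1 <- P %*% G1
      PG2 <- P %*% G2
      PRw <- P * rep(rdiag, each = n) # P %*% diag(rdiag)
      trP <- c(sum(diag(PG1)), sum(diag(PG2)), sum(diag(PRw)))
      pg <- list(PG1, PG2, PRw)
      pgt <- lapply(pg, t) # transpose once per component
      FI <- matrix(0, 3, 3)
      for (a in 1:3) {
        for (b in a:3) {
          FI[a, b] <- FI[b, a] <- 0.5 * sum(pg[[a]] * pgt[[b]])
        }
      }
    } else {
      # Hutchinson probes: tr(P Vi) = E[(Pz)' Vi z],
      # tr(P Vi P Vj) = E[(Vi P z)' P (Vj z)]
      W <- P %*% probes
      Tz <- lapply(vmats, function(M) M %*% probes)
      Sz <- lapply(Tz, function(Tj) P %*% Tj)
      Bw <- lapply(vmats, function(M) M %*% W)
      trP <- vapply(1:3, function(a) mean(colSums(W * Tz[[a]])), 0)
      FI <- matrix(0, 3, 3)
      for (a in 1:3) {
        for (b in a:3) {
          FI[a, b] <- FI[b, a] <- 0.5 * mean(colSums(Bw[[a]] * Sz[[b]]))
        }
      }
    }
    quad <- vapply(vmats, function(M) sum(Py * (M %*% Py)), 0)
    sc <- -0.5 * (trP - quad)
    # near-singular information signals an unidentifiable model (e.g. G1 == G2)
    ev <- eigen(FI, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10 * max(ev)) {
      return(list(
        varcomp = stats::setNames(theta, c("g1", "g2", "e")),
        vcov = NULL, loglik = as.numeric(ll_new), iterations = iter,
        converged = FALSE, pinned = pinned, identifiable = FALSE
      ))
    }
    step <- solve(FI, sc)
    theta_new <- theta + step
    # pin negatives at the floor, allow release when the score turns positive
    pinned <- theta_new < floor_v
    theta_new[pinned] <- floor_v
    delta <- max(abs(theta_new - theta) / pmax(abs(theta), floor_v))
    theta <- theta_new
    ll <- ll_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(
    varcomp = stats::setNames(as.numeric(theta), c("g1", "g2", "e")),
    vcov = solve(FI),
    loglik = as.numeric(ll),
    iterations = iter,
    converged = converged,
    pinned = pinned,
    identifiable = TRUE
  )
}

#' Per-SNP heritability enrichment
#'
#' The enrichment of a variant partition is the ratio of its average
#' per-variant genetic variance to the genome-wide average:
#' `rho = (s1 / m1) / ((s1 + s2) / (m1 + m2))`. Its standard error follows
#' from the delta method applied to the 2x2 covariance block of
#' `(s1, s2)`, and the p-value from a one-sided test of no enrichment
#' (`rho = 1` against `rho > 1`) referring `(rho - 1) / SE` to the standard
#' normal.
#'
#' @param varcomp named variance-component estimates (`g1`, `g2`, `e`).
#' @param vcov 3x3 covariance of the estimates (rows/cols g1, g2, e).
#' @param m1,m2 partition sizes.
#' @return object of class `EnrichmentResult`: list with `rho`, `se`, `p`,
#'   `varcomp`, `vcov`, `m1`, `m2`.
#' @export
heritability_enrichment <- function(varcomp, vcov, m1, m2) {
  if (m1 < 1 || m2 < 1) stopf("need m1 >= 1 and m2 >= 1")
  s1 <- varcomp[["g1"]]
  s2 <- varcomp[["g2"]]
  tot <- s1 + s2
  if (tot <= 0) stopf("total genetic variance must be positive")
  cc <- (m1 + m2) / m1
  rho <- cc * s1 / tot
  se <- NA_real_
  p <- NA_real_
  if (!is.null(vcov)) {
    grad <- c(cc * s2 / tot^2, -cc * s1 / tot^2)
    se <- sqrt(drop(t(grad) %*% vcov[1:2, 1:2] %*% grad))
    p <- stats::pnorm((rho - 1) / se, lower.tail = FALSE)
  }
  structure(
    list(rho = rho, se = se, p = p, varcomp = varcomp, vcov = vcov, m1 = m1, m2 = m2),
    class = "EnrichmentResult"
  )
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf(
    "Per-SNP heritability enrichment\n  m1 = %d, m2 = %d\n  varcomp: g1 = %.4g, g2 = %.4g, e = %.4g\n  rho = %.3f (SE %.3f), one-sided p[rho > 1] = %.3g\n",
    x$m1, x$m2, x$varcomp[["g1"]], x$varcomp[["g2"]], x$varcomp[["e"]],
    x$rho, x$se, x$p
  ))
  invisible(x)
}

#' Full enrichment analysis from genotypes, phenotypes and candidates
#'
#' Convenience driver chaining [variant_qc()], [assign_partition()],
#' [build_grm()] per partition, [reml_two_vc()] and
#' [heritability_enrichment()].
#'
#' @param geno a `GenotypeMatrix`.
#' @param pheno data.frame with columns `y` and optionally `reliability`.
#' @param lnc `GRanges` of lncRNA candidate intervals.
#' @param window partition window in bases.
#' @param maf_min,hwe_p_min QC thresholds.
#' @param ... passed to [reml_two_vc()].
#' @return an `EnrichmentResult` with the fitted model under `$fit`.
#' @export
fit_enrichment <- function(geno, pheno, lnc, window = 10000L,
                           maf_min = 0.005, hwe_p_min = 1e-8, ...) {
  geno <- variant_qc(geno, maf_min = maf_min, hwe_p_min = hwe_p_min)
  part <- assign_partition(geno$map, lnc, window = window)
  sel <- part$assignment == "lnc"
  G1 <- build_grm(geno$dosages[, sel, drop = FALSE])
  G2 <- build_grm(geno$dosages[, !sel, drop = FALSE])
  fit <- reml_two_vc(pheno$y, G1, G2, reliability = pheno$reliability, ...)
  if (!fit$identifiable) stopf("model not identifiable: information matrix near-singular")
  res <- heritability_enrichment(fit$varcomp, fit$vcov, part$m1, part$m2)
  res$fit <- fit
  res
}
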