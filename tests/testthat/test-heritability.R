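make_geno <- function(dosages, chrom = "chr1", pos = NULL) {
  if (is.null(pos)) pos <- seq_len(ncol(dosages)) * 1000L
  genotype_matrix(dosages, data.frame(chrom = chrom, pos = pos))
}

test_that("variant QC enforces MAF and Hardy-Weinberg thresholds", {
  n <- 1000
  # 8 alt alleles in 2000: MAF 0.004 < 0.005 -> removed
  low <- c(rep(1L, 8), rep(0L, n - 8))
  # perfect HWE at p = 0.5: chi-square 0 -> kept
  hwe_ok <- rep(c(0L, 1L, 1L, 2L), each = 250)
  # only homozygotes: chi-square = n -> p far below 1e-8 -> removed
  hwe_bad <- rep(c(0L, 2L), each = 500)
  # hand-computed chi-square for the homozygote-only variant
  p_hat <- 0.5
  expected <- n * c(0.25, 0.5, 0.25)
  chi <- sum((c(500, 0, 500) - expected)^2 / expected)
  expect_equal(chi, n)
  expect_lt(pchisq(chi, 1, lower.tail = FALSE), 1e-8)

  geno <- make_geno(cbind(low = low, ok = hwe_ok, bad = hwe_bad))
  kept <- variant_qc(geno)
  expect_equal(colnames(kept$dosages), "ok")
  qc <- attr(kept, "qc")
  expect_equal(qc$maf[qc$id == "low"], 0.004)
  expect_equal(qc$hwe_p[qc$id == "ok"], 1)
  # monomorphic variants are removed via MAF 0
  mono <- make_geno(cbind(m = rep(0L, n), ok = hwe_ok))
  expect_equal(colnames(variant_qc(mono)$dosages), "ok")
})

test_that("window partitioning assigns variants by extended proximity", {
  lnc <- genomic_intervals("chr1", 50000, 52000)
  map <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    pos = c(45000, 35000, 51000, 51000) # 5 kb upstream, 15 kb away, inside, wrong chrom
  )
  part <- assign_partition(map, lnc, window = 10000)
  expect_equal(as.character(part$assignment), c("lnc", "rest", "lnc", "rest"))
  expect_equal(part$m1, 2L)
  expect_equal(part$m2, 2L)
  expect_error(
    assign_partition(data.frame(chrom = "chr1", pos = 51000), lnc),
    "degenerate partition"
  )
})

test_that("GRM standardization yields the worked two-individual example", {
  G <- build_grm(matrix(c(0, 2), ncol = 1))
  expect_equal(unclass(G)[1:2, 1:2], matrix(c(1, -1, -1, 1), 2), ignore_attr = TRUE)
  # brute-force double loop on a random fixture
  withr::local_seed(52)
  d <- matrix(rbinom(20 * 30, 2, 0.3), nrow = 20)
  G2 <- build_grm(d)
  Z <- apply(d, 2, function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2)))
  oracle <- matrix(0, 20, 20)
  for (i in 1:20) {
    for (j in 1:20) {
      oracle[i, j] <- sum(Z[i, ] * Z[j, ]) / ncol(d)
    }
  }
  expect_equal(unclass(G2), oracle, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("GRM diagonals average one and ignore variant order", {
  withr::local_seed(53)
  for (i in 1:3) {
    d <- matrix(rbinom(30 * 50, 2, runif(1, 0.1, 0.5)), nrow = 30)
    G <- build_grm(d)
    expect_equal(mean(diag(G)), 1, tolerance = 1e-12)
    Gs <- build_grm(d[, sample(ncol(d))])
    expect_equal(unclass(G), unclass(Gs), ignore_attr = TRUE, tolerance = 1e-12)
  }
  # missing dosages are mean-imputed
  d <- matrix(rbinom(30 * 10, 2, 0.4), nrow = 30)
  d[1, 1] <- NA
  expect_equal(mean(diag(build_grm(d))), 1, tolerance = 1e-12)
  expect_error(build_grm(matrix(c(1L, 1L, 1L), ncol = 1)), "zero-variance")
})

test_that("enrichment follows the per-SNP ratio formula", {
  vcov0 <- diag(c(1e-4, 1e-4, 1e-4))
  # equal per-SNP variance in both partitions: rho = 1
  r1 <- heritability_enrichment(c(g1 = 0.05, g2 = 0.45, e = 0.5), vcov0, 100, 900)
  expect_equal(r1$rho, 1)
  # no partition variance: rho = 0
  r0 <- heritability_enrichment(c(g1 = 0, g2 = 0.5, e = 0.5), vcov0, 100, 900)
  expect_equal(r0$rho, 0)
  # hand-evaluated: (0.2/100) / (0.5/1000) = 4
  r4 <- heritability_enrichment(c(g1 = 0.2, g2 = 0.3, e = 0.5), vcov0, 100, 900)
  expect_equal(r4$rho, 4)
  expect_true(r4$se > 0)
  expect_true(r4$p >= 0 && r4$p <= 1)
  expect_error(
    heritability_enrichment(c(g1 = 0, g2 = 0, e = 1), vcov0, 100, 900),
    "positive"
  )
})

test_that("REML pins an absent component and flags unidentifiable models", {
  withr::local_seed(54)
  gp <- sim_genetics(
    n = 400, m = 1000, m1 = 200,
    vc = c(g1 = 0, g2 = 0.5, e = 0.5), seed = 61
  )
  part <- assign_partition(gp$geno$map, gp$lnc)
  sel <- part$assignment == "lnc"
  G1 <- build_grm(gp$geno$dosages[, sel, drop = FALSE])
  G2 <- build_grm(gp$geno$dosages[, !sel, drop = FALSE])
  fit <- reml_two_vc(gp$pheno$y, G1, G2, reliability = gp$pheno$reliability)
  expect_true(fit$converged)
  expect_lt(fit$varcomp[["g1"]], 0.05)
  expect_equal(
    fit$varcomp[["g2"]] + fit$varcomp[["e"]],
    stats::var(gp$pheno$y),
    tolerance = 0.3
  )
  # identical relationship matrices cannot separate the two components
  fit_bad <- reml_two_vc(gp$pheno$y, G2, G2, reliability = gp$pheno$reliability)
  expect_false(fit_bad$identifiable)
})

test_that("enrichment is invariant to phenotype rescaling", {
  gp <- sim_genetics(
    n = 300, m = 800, m1 = 150,
    vc = c(g1 = 0.2, g2 = 0.3, e = 0.5), seed = 62
  )
  part <- assign_partition(gp$geno$map, gp$lnc)
  sel <- part$assignment == "lnc"
  G1 <- build_grm(gp$geno$dosages[, sel, drop = FALSE])
  G2 <- build_grm(gp$geno$dosages[, !sel, drop = FALSE])
  f1 <- reml_two_vc(gp$pheno$y, G1, G2)
  f2 <- reml_two_vc(3 * gp$pheno$y, G1, G2)
  e1 <- heritability_enrichment(f1$varcomp, f1$vcov, part$m1, part$m2)
  e2 <- heritability_enrichment(f2$varcomp, f2$vcov, part$m1, part$m2)
  expect_equal(e1$rho, e2$rho, tolerance = 1e-4)
  expect_equal(f2$varcomp, f1$varcomp * 9, tolerance = 1e-3)
})

test_that("Monte Carlo trace mode agrees with exact REML within probe error", {
  gp <- sim_genetics(
    n = 250, m = 600, m1 = 120,
    vc = c(g1 = 0.2, g2 = 0.3, e = 0.5), seed = 63
  )
  part <- assign_partition(gp$geno$map, gp$lnc)
  sel <- part$assignment == "lnc"
  G1 <- build_grm(gp$geno$dosages[, sel, drop = FALSE])
  G2 <- build_grm(gp$geno$dosages[, !sel, drop = FALSE])
  exact <- reml_two_vc(gp$pheno$y, G1, G2)
  mc <- lapply(1:5, function(s) {
    reml_two_vc(gp$pheno$y, G1, G2, method = "mc", n_probes = 40, seed = s)
  })
  est <- vapply(mc, function(f) f$varcomp, numeric(3))
  mc_sd <- apply(est, 1, stats::sd)
  diff <- abs(rowMeans(est) - exact$varcomp)
  expect_true(all(diff <= 3 * pmax(mc_sd, 1e-4)))
  # MC mode is reproducible under a fixed probe seed
  mc_rep <- reml_two_vc(gp$pheno$y, G1, G2, method = "mc", n_probes = 40, seed = 1)
  expect_identical(mc_rep$varcomp, mc[[1]]$varcomp)
})

test_that("delta-method SE tracks the empirical spread of the estimator", {
  vc <- c(g1 = 0.1, g2 = 0.4, e = 0.5)
  gp <- sim_genetics(n = 800, m = 4000, m1 = 200, vc = vc, seed = 70)
  geno <- variant_qc(gp$geno)
  part <- assign_partition(geno$map, gp$lnc)
  sel <- part$assignment == "lnc"
  G1 <- build_grm(geno$dosages[, sel, drop = FALSE])
  G2 <- build_grm(geno$dosages[, !sel, drop = FALSE])
  res <- vapply(1:50, function(r) {
    ph <- sim_phenotype(geno, part$assignment, vc,
      reliability = gp$pheno$reliability, seed = 300 + r
    )
    fit <- reml_two_vc(ph$pheno$y, G1, G2, reliability = ph$pheno$reliability)
    enr <- heritability_enrichment(fit$varcomp, fit$vcov, part$m1, part$m2)
    c(enr$rho, enr$se)
  }, numeric(2))
  expect_lt(abs(mean(res[2, ]) - stats::sd(res[1, ])) / stats::sd(res[1, ]), 0.15)
})
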