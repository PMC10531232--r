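test_that("common-candidate matching pairs overlapping intervals only", {
  dry <- parse_regions(c("chr10: 28,036,993-28,037,708", "chr2: 1,000-2,000"))
  names(dry) <- c("d1", "d2")
  lact <- parse_regions(c("chr10: 28,036,875-28,037,846", "chr2: 5,000-6,000"))
  names(lact) <- c("l1", "l2")
  pairs <- match_common(dry, lact)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$dry_id, "d1")
  expect_equal(pairs$lact_id, "l1")
})

test_that("presence filter requires half the samples per condition", {
  n_dry <- 60
  n_lact <- 43
  samples <- c(sprintf("d%02d", 1:n_dry), sprintf("l%02d", 1:n_lact))
  conds <- stats::setNames(rep(c("dry", "lactating"), c(n_dry, n_lact)), samples)
  mk_row <- function(nd, nl) {
    c(rep(1, nd), rep(0, n_dry - nd), rep(1, nl), rep(0, n_lact - nl))
  }
  values <- rbind(
    dA = mk_row(29, 43), lA = mk_row(60, 43), # 29/60 dry: removed
    dB = mk_row(30, 43), lB = mk_row(60, 22) # 30/60 and 22/43: kept
  )
  colnames(values) <- samples
  em <- expression_matrix(values, units = "FPKM", conditions = conds)
  pairs <- data.frame(
    pair = c("p1", "p2"), dry_id = c("dA", "dB"), lact_id = c("lA", "lB")
  )
  kept <- presence_filter_pairs(pairs, em)
  expect_equal(kept$pair, "p2")
  expect_equal(kept$dry_present, 30L)
  expect_equal(kept$lact_present, 22L)
})

test_that("the variance pre-test picks the conventional test and is symmetric", {
  withr::local_seed(2)
  x <- rnorm(30)
  y <- x + 5 # identical variances
  expect_equal(as.character(choose_test(x, y)), "pooled")
  expect_equal(attr(choose_test(x, x + 1), "p"), 1)
  big <- rnorm(30, sd = 10)
  small <- rnorm(30, sd = 1) # variance ratio ~100
  expect_equal(as.character(choose_test(big, small)), "welch")
  expect_identical(
    as.character(choose_test(big, small)),
    as.character(choose_test(small, big))
  )
  expect_equal(as.character(choose_test(rep(1, 5), rep(2, 5))), "degenerate")
})

test_that("t-tests reproduce hand-computed and reference values", {
  res <- ttest_pair(1:5, 2:6, "pooled")
  expect_equal(res$t, -1, tolerance = 1e-12)
  expect_equal(res$p, 0.3466, tolerance = 1e-3)
  same <- ttest_pair(c(1, 2, 3), c(1, 2, 3), "pooled")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("statistical kernels match brute-force formulas on random cases", {
  withr::local_seed(12)
  for (i in 1:100) {
    nx <- sample(5:40, 1)
    ny <- sample(5:40, 1)
    x <- rnorm(nx, sd = runif(1, 0.5, 3))
    y <- rnorm(ny, sd = runif(1, 0.5, 3))
    vx <- var(x)
    vy <- var(y)
    # pooled t from first principles
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    t_pool <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    p_pool <- 2 * pt(-abs(t_pool), nx + ny - 2)
    got <- ttest_pair(x, y, "pooled")
    expect_equal(got$t, t_pool, tolerance = 1e-10)
    expect_equal(got$p, p_pool, tolerance = 1e-10)
    # Welch-Satterthwaite from first principles
    se2 <- vx / nx + vy / ny
    t_w <- (mean(x) - mean(y)) / sqrt(se2)
    df_w <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    p_w <- 2 * pt(-abs(t_w), df_w)
    got_w <- ttest_pair(x, y, "welch")
    expect_equal(got_w$t, t_w, tolerance = 1e-10)
    expect_equal(got_w$p, p_w, tolerance = 1e-10)
    # F pre-test against the reference implementation (absolute scale: for
    # near-zero p the reference's 1 - pf(f) computation carries cancellation)
    expect_lt(abs(attr(choose_test(x, y), "p") - var.test(x, y)$p.value), 1e-10)
    # both tests agree in sign
    expect_equal(sign(got$t), sign(got_w$t))
  }
})

test_that("the pre-test plus t-test pipeline keeps its nominal type-I error", {
  withr::local_seed(99)
  reject <- logical(5000)
  for (i in seq_len(5000)) {
    x <- exp(rnorm(30, 0, 0.5))
    y <- exp(rnorm(30, 0, 0.5))
    tt <- choose_test(x, y)
    reject[i] <- ttest_pair(x, y, as.character(tt))$p < 0.05
  }
  expect_gt(mean(reject), 0.04)
  expect_lt(mean(reject), 0.06)
})

test_that("the bundled common-lncRNA table yields the published call counts", {
  tab <- common_lncrna_table()
  expect_equal(nrow(tab), 53L)
  s <- summarize_de(tab)
  expect_equal(s$significant, 44L)
  expect_equal(s$up_dry, 22L)
  expect_equal(s$up_lact, 22L)
  expect_equal(s$ns, 9L)
  expect_equal(s$significant + s$ns, s$total)
})

test_that("DE summary handles degenerate inputs and conserves counts", {
  df <- data.frame(dry_mean = c(1, 2), lact_mean = c(2, 1), p = c(1, 1))
  s <- summarize_de(df)
  expect_equal(s$significant, 0L)
  expect_equal(s$ns, 2L)

  withr::local_seed(6)
  df2 <- data.frame(
    dry_mean = runif(50), lact_mean = runif(50), p = runif(50)
  )
  s2 <- summarize_de(df2)
  expect_equal(s2$significant + s2$ns, 50L)
  expect_equal(s2$up_dry + s2$up_lact, s2$significant)
})

test_that("run_de plants calls consistent with the planted effects", {
  sim <- sim_expression(c("d_hit", "l_hit", "d_null", "l_null"),
    design = c(dry = 30, lactating = 30),
    fold = c(d_hit = 6),
    baseline = c(d_hit = 5, l_hit = 5, d_null = 5, l_null = 5),
    seed = 21
  )
  pairs <- data.frame(
    pair = c("p1", "p2"),
    dry_id = c("d_hit", "d_null"), lact_id = c("l_hit", "l_null")
  )
  de <- run_de(pairs, sim$expr)
  expect_equal(de$call[1], "up_dry")
  expect_true(all(de$p >= 0 & de$p <= 1))
  expect_equal(de$call[de$p >= 0.05], rep("ns", sum(de$p >= 0.05)))
})
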