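test_that("ICC(2,1): perfect agreement, symmetry, and hand-checkable tables", {
  x <- c(10, 20, 30, 40)
  perfect <- icc21(cbind(x, x))
  expect_equal(perfect$value, 1)
  expect_true(perfect$degenerate)

  ## 4-lesion table checked against mean squares from an independent aov fit
  m <- cbind(r1 = c(9, 6, 8, 7), r2 = c(2, 1, 4, 1))
  got <- icc21(m)
  expect_equal(got$value, oracle_icc21_aov(m), tolerance = 1e-12)
  ## value sits inside its own confidence interval
  expect_true(got$ci[1] <= got$value && got$value <= got$ci[2])

  ## swapping the two columns leaves ICC unchanged
  expect_equal(icc21(m[, 2:1])$value, got$value, tolerance = 1e-12)

  ## all-identical values: zero total variance, flagged degenerate
  flat <- icc21(cbind(rep(5, 4), rep(5, 4)))
  expect_equal(flat$value, 1)
  expect_true(flat$degenerate)

  expect_error(icc21(cbind(1:2, 1:2)), class = "hsp_contract_error")
  expect_error(icc21(cbind(c(1, NA, 3), 1:3)), class = "hsp_contract_error")
})

test_that("ICC(2,1) matches aov-derived mean squares on random complete designs", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    m <- matrix(rnorm(2 * n, 100, 25), n, 2) +
      rnorm(n, 0, 40)   # shared subject effect, recycled across columns
    expect_equal(icc21(m)$value, oracle_icc21_aov(m), tolerance = 1e-10)
  }
})

test_that("simulated ICC converges to the analytic variance ratio", {
  set.seed(13)
  sigma_b <- 30; sigma_e <- 15
  target <- sigma_b^2 / (sigma_b^2 + sigma_e^2)
  n <- 200
  lesions <- rnorm(n, 300, sigma_b)
  m <- cbind(lesions + rnorm(n, 0, sigma_e), lesions + rnorm(n, 0, sigma_e))
  expect_equal(icc21(m)$value, target, tolerance = 0.05)
})

test_that("Bland-Altman: zero case, constant offset, formula oracle, percent mode", {
  a <- c(100, 150, 200, 250, 320)
  z <- bland_altman(a, a)
  expect_equal(c(z$bias, z$loa_low, z$loa_high), c(0, 0, 0))

  off <- bland_altman(a + 10, a)
  expect_equal(c(off$bias, off$loa_low, off$loa_high), c(10, 10, 10))

  set.seed(17)
  x <- rnorm(40, 200, 50); y <- x + rnorm(40, 5, 12)
  ba <- bland_altman(x, y)
  d <- x - y
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d))
  expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d))

  pc <- bland_altman(x, y, mode = "percent")
  dp <- 100 * (x - y) / ((x + y) / 2)
  expect_equal(pc$bias, mean(dp))
  expect_equal(pc$loa_high, mean(dp) + 1.96 * sd(dp))
  expect_error(bland_altman(c(1, -1, 2), c(-1, 1, 2), mode = "percent"),
               class = "hsp_contract_error")
  expect_error(bland_altman(1:5, 1:4), class = "hsp_contract_error")
})

test_that("Spearman: monotone transforms, reversal, ties, constant rejection", {
  x <- c(3, 9, 27, 81, 243)
  expect_equal(spearman_rho(x, log(x)), 1)
  expect_equal(spearman_rho(x, exp(seq_along(x))), 1)
  expect_equal(spearman_rho(x, rev(x)), -1)

  ## ties: equals rank-then-Pearson computed directly
  a <- c(1, 2, 2, 3, 5, 5, 5)
  b <- c(2, 1, 4, 4, 6, 7, 6)
  expect_equal(spearman_rho(a, b), cor(rank(a), rank(b)))

  ## invariance under strictly monotone transforms of either series
  set.seed(23)
  u <- rnorm(30); v <- rnorm(30)
  expect_equal(spearman_rho(exp(u), v^3 + 2 * v), spearman_rho(u, v))

  expect_error(spearman_rho(rep(1, 5), 1:5), class = "hsp_contract_error")
})

test_that("rater tables validate, pivot, and feed the full agreement report", {
  df <- data.frame(
    lesion_id = rep(sprintf("L%02d", 1:6), times = 2),
    rater = rep(c("A", "B"), each = 6),
    session = 1L,
    volume_mm3 = c(120, 340, 80, 510, 95, 260,
                   131, 330, 90, 498, 101, 255))
  tab <- rater_table(df)
  m <- rater_matrix(tab, c("A", "B"), by = "rater")
  expect_equal(dim(m), c(6L, 2L))
  expect_equal(m["L04", "B"], 498)

  rep_ <- agreement_report(m)
  expect_true(rep_$loa_low <= rep_$bias && rep_$bias <= rep_$loa_high)
  expect_equal(rep_$bias, mean(m[, 1] - m[, 2]))
  expect_true(abs(rep_$spearman_rho) <= 1)
  expect_equal(rep_$n, 6)

  ## duplicates and negative volumes are rejected
  expect_error(rater_table(rbind(df, df[1, ])), class = "hsp_contract_error")
  bad <- df; bad$volume_mm3[1] <- -5
  expect_error(rater_table(bad), class = "hsp_data_error")
  ## incomplete designs are rejected
  expect_error(rater_matrix(tab[-1, ], c("A", "B"), by = "rater"),
               class = "hsp_contract_error")

  ## CSV round-trip
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE)
  expect_equal(rater_matrix(read_rater_table(p), c("A", "B")), m)
})
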