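test_that("log-normal CV vanishes when observers agree exactly and matches
           sigma for small noise", {
  mat <- matrix(rep(runif(8, 100, 900), 6), nrow = 8)
  cv0 <- lognormal_cv(cells_from_matrix(mat))
  expect_lt(cv0$estimate, 0.01)

  # small-sigma limit: CV ~ sigma to first order
  set.seed(42)
  sigma <- 0.02
  lv <- rep(log(runif(16, 400, 900)), 6) + rnorm(96, 0, sigma)
  d <- cells_from_matrix(matrix(exp(lv), nrow = 16))
  fit <- lognormal_cv(d)
  expect_lt(abs(fit$estimate - sigma), 0.25 * sigma)
  expect_true(fit$lower <= fit$estimate && fit$estimate <= fit$upper)
  expect_identical(fit$interval, "credible")
})

test_that("log-normal CV rejects bad input and drops singleton cells", {
  d <- cells_from_matrix(matrix(1:12, nrow = 4))
  d$value[1] <- -1
  expect_error(lognormal_cv(d), "positive")
  d2 <- cells_from_matrix(matrix(exp(rnorm(12, 5)), nrow = 4))
  d2 <- d2[-c(5, 9), ]  # p01 left with a single observer
  expect_warning(lognormal_cv(d2), "singleton")
})

test_that("beta SD closed form and degenerate flags", {
  expect_identical(cardatlas:::beta_sd_value(0.2, 15), 0.1)

  zero <- cells_from_matrix(matrix(0, nrow = 4, ncol = 3))
  est <- beta_sd(zero, B = 10)
  expect_identical(est$flag, "not_calculated")
  expect_true(is.na(est$estimate))

  one <- cells_from_matrix(matrix(1, nrow = 4, ncol = 3))
  expect_identical(beta_sd(one, B = 10)$flag, "not_calculated")

  bad <- cells_from_matrix(matrix(1.5, nrow = 4, ncol = 3))
  expect_error(beta_sd(bad), "\\[0, 1\\]")
})

test_that("beta SD recovers a known precision on simulated data", {
  set.seed(9)
  mu_c <- plogis(rnorm(16, qlogis(0.25), 0.5))
  phi <- 30
  y <- rbeta(16 * 6, rep(mu_c, 6) * phi, rep(1 - mu_c, 6) * phi)
  d <- cells_from_matrix(matrix(y, nrow = 16))
  est <- beta_sd(d, B = 200, seed = 11)
  truth <- cardatlas:::beta_sd_value(mean(mu_c), phi)
  expect_lt(abs(est$estimate - truth), 0.35 * truth)
  expect_lt(est$lower, est$upper)
})

test_that("ICC(2,1) equals the from-scratch ANOVA oracle on a toy grid", {
  mat <- matrix(c(9, 6, 8, 7,
                  2, 1, 4, 1,
                  5, 3, 6, 2), nrow = 4)
  est <- icc2(cells_from_matrix(mat))
  expect_equal(est$estimate, icc2_oracle(mat), tolerance = 1e-12)
  expect_true(est$lower <= est$estimate && est$estimate <= est$upper)
  expect_identical(est$interval, "confidence")
})

test_that("ICC behaves at the null and perfect-agreement limits", {
  set.seed(5)
  noise <- matrix(rnorm(200 * 4), nrow = 200)  # no patient effect
  est0 <- icc2(cells_from_matrix(noise))
  expect_lt(abs(est0$estimate), 0.1)

  base <- runif(50, 10, 90)
  copies <- matrix(rep(base, 5), nrow = 50) +
    matrix(rnorm(250, 0, 1e-4), nrow = 50)
  # lm warns about an essentially perfect fit here, which is the point
  est1 <- suppressWarnings(icc2(cells_from_matrix(copies)))
  expect_gt(est1$estimate, 0.999)
})

test_that("ICC input validation: design size, missingness, zero variance", {
  expect_error(icc2(cells_from_matrix(matrix(1:4, nrow = 4, ncol = 1))),
               ">= 2")
  d <- cells_from_matrix(matrix(rnorm(40), nrow = 10))
  expect_error(icc2(d[-(1:8), ]), "missing")
  flat <- cells_from_matrix(matrix(5, nrow = 4, ncol = 3))
  expect_identical(icc2(flat)$flag, "not_calculated")
})

test_that("the variability table assembles all estimates per structure", {
  set.seed(21)
  mk <- function(structure, mu) {
    d <- cells_from_matrix(
      matrix(exp(log(mu) + rnorm(24, 0, 0.05)), nrow = 8), structure)
    d
  }
  vols <- rbind(mk("heart", 700), mk("pulmonary_valve", 8))
  dm <- rbind(mk("heart", 4), mk("pulmonary_valve", 4))
  dc <- rbind(mk("heart", 44), mk("pulmonary_valve", 5))
  v5 <- rbind(cells_from_matrix(matrix(plogis(rnorm(24, -2, 0.3)), 8),
                                "heart"),
              cells_from_matrix(matrix(0, 8, 3), "pulmonary_valve"))
  tab <- variability_report(vols, dm, dc, v5, B = 20, seed = 3)
  expect_s3_class(tab, "variability_table")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$structure[1], "heart")
  expect_true(all(c("cv_volume", "cv_dmean", "cv_d2cc", "sd_v5gy",
                    "icc_volume", "icc_dmean", "icc_d2cc", "icc_v5gy")
                  %in% names(tab)))
  expect_true(all(tab$cv_volume >= 0))
  pv <- tab[tab$structure == "pulmonary_valve", ]
  expect_true(grepl("sd_v5gy:not_calculated", pv$flags))
  expect_true(is.na(pv$sd_v5gy))

  # deterministic given data + seeds
  tab2 <- variability_report(vols, dm, dc, v5, B = 20, seed = 3)
  expect_identical(tab, tab2)
})

test_that("cell_values validates its schema", {
  expect_error(cell_values(data.frame(a = 1)), "missing columns")
  d <- cells_from_matrix(matrix(1:6, 2))
  expect_error(cell_values(rbind(d, d[1, ])), "duplicate")
})
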