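test_that("McFadden pseudo-R2 follows its definition on fixed numbers", {
  expect_equal(mcfadden_r2(-90, loglik0 = -100), 0.1)
  expect_equal(mcfadden_r2(-100, loglik0 = -100), 0)
  expect_error(mcfadden_r2(-90), "loglik0")
})

test_that("McFadden from a glm equals the two-loglik computation", {
  set.seed(1)
  d <- data.frame(y = rbinom(300, 1, 0.4), x = rnorm(300))
  d$y <- rbinom(300, 1, stats::plogis(-0.3 + 0.8 * d$x))
  fit <- glm(y ~ x, data = d, family = binomial())
  null <- glm(y ~ 1, data = d, family = binomial())
  expect_equal(mcfadden_r2(fit),
               1 - as.numeric(logLik(fit)) / as.numeric(logLik(null)),
               tolerance = 1e-10)
})

test_that("marginal R2 matches the variance-component formula", {
  expect_equal(nakagawa_marginal(2, 1, 1), 0.5)
  expect_equal(nakagawa_marginal(0, 3, 1), 0)
})

test_that("marginal R2 of an lm equals its coefficient of determination", {
  set.seed(2)
  d <- data.frame(x = rnorm(200))
  d$y <- 0.7 * d$x + rnorm(200)
  fit <- lm(y ~ x, data = d)
  expect_equal(marginal_r2(fit), summary(fit)$r.squared, tolerance = 1e-12)
})

test_that("mixed-model marginal R2 reflects known variance components", {
  set.seed(3)
  n <- 4000
  site <- sample(paste0("g", 1:20), n, TRUE)
  u <- rnorm(20); names(u) <- paste0("g", 1:20)
  x <- rnorm(n)
  d <- data.frame(y = x + u[site] + rnorm(n), x = x, site = site)
  fit <- lme4::lmer(y ~ x + (1 | site), data = d, REML = FALSE)
  # var(fixed) = 1, random = 1, residual = 1 -> 1/3
  expect_lt(abs(marginal_r2(fit) - 1 / 3), 0.05)
})

test_that("OLS delta-R2 recovers the generative signal fraction", {
  set.seed(4)
  n <- 10000
  x <- rnorm(n)
  d <- data.frame(y = x + rnorm(n), x = x, z = rnorm(n))
  null <- lm(y ~ z, data = d)
  full <- lm(y ~ z + x, data = d)
  dr <- delta_r2(null, full, "ols")
  expect_lt(abs(dr - 50), 2)               # percentage points
  expect_lt(abs(summary(null)$r.squared), 0.01)
})

test_that("delta-R2 validates nesting and row agreement", {
  d <- data.frame(y = rnorm(50), x = rnorm(50), z = rnorm(50))
  expect_error(delta_r2(lm(y ~ z, d), lm(y ~ x, d)), "not nested")
  expect_error(delta_r2(lm(y ~ x, d), lm(y ~ x + z, d[1:40, ])),
               "different row sets")
})

test_that("a pure-noise extra predictor adds a tiny non-negative delta-R2", {
  set.seed(5)
  deltas <- replicate(40, {
    d <- data.frame(y = rnorm(400), x = rnorm(400), noise = rnorm(400))
    d$y <- d$y + 0.4 * d$x
    delta_r2(lm(y ~ x, d), lm(y ~ x + noise, d), "ols")
  })
  expect_true(all(deltas >= 0))
  expect_lt(stats::median(deltas), 1)      # < 1 percentage point
})

test_that("logistic delta pseudo-R2 is the score's contribution over the null", {
  set.seed(6)
  n <- 1500
  x <- rnorm(n); z <- rnorm(n)
  y <- rbinom(n, 1, stats::plogis(0.3 * z + 0.8 * x))
  d <- data.frame(y = y, x = x, z = z)
  null <- glm(y ~ z, d, family = binomial())
  full <- glm(y ~ z + x, d, family = binomial())
  ll0 <- as.numeric(logLik(glm(y ~ 1, d, family = binomial())))
  manual <- 100 * ((1 - as.numeric(logLik(full)) / ll0) -
                   (1 - as.numeric(logLik(null)) / ll0))
  expect_equal(delta_r2(null, full, "mcfadden"), manual, tolerance = 1e-8)
  expect_gt(delta_r2(null, full, "mcfadden"), 0)
})

make_ladder_data <- function(n = 2000, rvi_signal = 0.4, prs_signal = 0.3,
                             seed = 11) {
  set.seed(seed)
  rvi <- rnorm(n); prs <- rnorm(n); age <- rnorm(n, 50, 10)
  pc1 <- rnorm(n); plate <- sample(c("p1", "p2"), n, TRUE)
  eta <- rvi_signal * rvi + prs_signal * prs - 0.01 * (age - 50)
  data.frame(y = rbinom(n, 1, stats::plogis(eta)),
             ycont = eta + rnorm(n),
             rvi = rvi, prs = prs, age = age, pc1 = pc1, plate = plate,
             site = sample(paste0("s", 1:4), n, TRUE),
             stringsAsFactors = FALSE)
}

test_that("the AIC identity holds exactly for every ladder row", {
  d <- make_ladder_data(500)
  lad <- aic_ladder(d, "y", "binary", rvi = "rvi", prs = "prs",
                    covariates = "age", prs_covariates = c("pc1", "plate"))
  expect_equal(lad$aic, 2 * lad$k - 2 * lad$loglik, tolerance = 1e-12)
  expect_identical(lad$model, c("M1", "M2", "M3", "M4", "M5"))
  # adding a predictor to a nested ML fit cannot decrease the log-likelihood
  expect_gte(lad$loglik[2], lad$loglik[1] - 1e-8)
  expect_gte(lad$loglik[4], lad$loglik[3] - 1e-8)
  expect_gte(lad$loglik[5], lad$loglik[4] - 1e-8)
  expect_gte(lad$r2[2], lad$r2[1] - 1e-10)
})

test_that("a real signal clears the 2-AIC margin; the ladder flags it", {
  d <- make_ladder_data(2000)
  lad <- aic_ladder(d, "y", "binary", rvi = "rvi", prs = "prs",
                    covariates = "age", prs_covariates = c("pc1", "plate"))
  deltas <- attr(lad, "deltas")
  expect_lt(deltas$delta_aic[deltas$contrast == "M2-M1"], -2)
  expect_lt(deltas$delta_aic[deltas$contrast == "M5-M4"], -2)
  expect_true(all(deltas$meaningful[deltas$contrast %in%
                                      c("M2-M1", "M5-M4")]))
})

test_that("all five ladder models share one complete-case row set", {
  d <- make_ladder_data(400)
  d$pc1[1:50] <- NA                        # PRS covariates add missingness
  lad <- aic_ladder(d, "y", "binary", rvi = "rvi", prs = "prs",
                    covariates = "age", prs_covariates = c("pc1", "plate"))
  expect_identical(attr(lad, "n"), 350L)
  # M1 ignores pc1 but must still be fit on the restricted rows: its
  # log-likelihood corresponds to 350 observations, not 400
  fit_all <- glm(y ~ age + rvi, data = d, family = binomial())
  expect_lt(lad$loglik[2], as.numeric(logLik(fit_all)) + 50)
})

test_that("continuous ladders use marginal R2 with a grouping factor", {
  d <- make_ladder_data(800)
  lad <- aic_ladder(d, "ycont", "continuous", rvi = "rvi", prs = "prs",
                    covariates = "age", prs_covariates = "pc1",
                    random_intercept = "site")
  expect_identical(attr(lad, "r2_kind"), "marginal")
  expect_true(all(is.finite(lad$r2)))
  lad2 <- aic_ladder(d, "ycont", "continuous", rvi = "rvi", prs = "prs",
                     covariates = "age", prs_covariates = "pc1")
  expect_identical(attr(lad2, "r2_kind"), "ols")
})
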