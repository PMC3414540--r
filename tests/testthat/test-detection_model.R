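# Bivariate-probit observation model: design building, correlation,
# orthant probabilities, latent Gibbs updates, detection curves.

vi_basic <- list(observer = list(type = "factor", levels = c("o1", "o2")),
                 distance = list(type = "numeric"),
                 size = list(type = "numeric"),
                 exposure = list(type = "factor", levels = c("0", "1")))

test_that("design builder reproduces model.matrix with treatment coding", {
  set.seed(4)
  n <- 40
  df <- data.frame(observer = factor(sample(c("o1", "o2"), n, TRUE),
                                     levels = c("o1", "o2")),
                   distance = runif(n), size = rpois(n, 3) + 1,
                   exposure = factor(sample(c("0", "1"), n, TRUE),
                                     levels = c("0", "1")))
  for (f in list(~ 1, ~ observer + distance,
                 ~ observer + distance + size + exposure +
                   distance:exposure,
                 ~ observer * distance)) {
    b <- rjds:::make_design_builder(f, vi_basic)
    got <- b(list(observer = as.integer(df$observer), distance = df$distance,
                  size = df$size, exposure = as.integer(df$exposure)))
    want <- model.matrix(f, df)
    expect_equal(unname(got), unname(want), ignore_attr = TRUE,
                 label = deparse(f))
    expect_setequal(colnames(got), colnames(want))
  }
})

test_that("build_detection_design emits one row per observer with interactions", {
  g <- data.frame(distance = c(0.4, 1), size = c(2, 5),
                  exposure = c("1", "0"))
  X <- build_detection_design(g, c("o1", "o2"),
                              ~ observer + distance + exposure +
                                distance:exposure, vi_basic)
  expect_equal(nrow(X), 4L)
  expect_equal(unname(X[2, "distance:exposure1"]), 0)   # unexposed
  expect_equal(unname(X[1, "distance:exposure1"]), 0.4) # distance x exposure
  expect_equal(unname(X[, "observero2"]), c(0, 0, 1, 1))
  # observer 2 of 2, distance 0.4, intercept + observer + distance
  X2 <- build_detection_design(data.frame(distance = 0.4), c("o1", "o2"),
                               ~ observer + distance, vi_basic)
  expect_equal(unname(X2[2, ]), c(1, 1, 0.4))
})

test_that("compiled design representation matches the builder", {
  set.seed(9)
  n <- 30
  data <- list(observer = sample(1:2, n, TRUE), distance = runif(n),
               size = rpois(n, 3) + 1, exposure = sample(1:2, n, TRUE))
  f <- ~ observer + distance + size + exposure + distance:exposure
  b <- rjds:::make_design_builder(f, vi_basic)
  want <- b(data)
  cd <- rjds:::.compile_design(f, vi_basic, c("distance", "size", "exposure"),
                               list(observer = data$observer),
                               list(observer = data$observer))
  # reconstruct: column = static part x product of dynamic factors
  Zs <- list(data$distance, data$size, data$exposure)
  got <- vapply(seq_along(cd$dyn_cov), function(j) {
    v <- cd$S1[, j]
    dc <- cd$dyn_cov[[j]]; dk <- cd$dyn_kind[[j]]
    for (m in seq_along(dc)) {
      z <- Zs[[dc[m] + 1L]]
      v <- v * if (dk[m] < 0) z else as.numeric(z == dk[m])
    }
    v
  }, numeric(n))
  expect_equal(unname(got), unname(want))
})

test_that("correlation is zero on the line and linear out to rho", {
  expect_equal(correlation_at(0.7, 0, "continuous"), 0)
  expect_equal(correlation_at(0.5, 1, "continuous"), 0.5)
  expect_equal(correlation_at(0.5, 0.4, "continuous"), 0.2)
  expect_equal(correlation_at(0.5, 1, "binned", n_bins = 5), 0)
  expect_equal(correlation_at(0.5, 3, "binned", n_bins = 5), 0.25)
  expect_equal(correlation_at(0.5, 5, "binned", n_bins = 5), 0.5)
  expect_error(correlation_at(1.2, 1, "continuous"), "correlation")
})

test_that("bivariate normal CDF matches an independent quadrature oracle", {
  hs <- c(-2.5, -1, -0.3, 0, 0.4, 1.3, 2.2)
  rs <- c(-0.99, -0.9, -0.5, 0, 0.3, 0.8, 0.924, 0.926, 0.99)
  for (h in hs) for (k in hs) for (r in rs) {
    expect_lt(abs(pbvnorm(h, k, r) - pbvn_oracle(h, k, r)), 1e-10)
  }
  # the compiled copy used inside the sweep agrees with the R routine
  set.seed(2)
  h <- rnorm(100); k <- rnorm(100); r <- runif(100, -0.99, 0.99)
  expect_equal(rjds:::.cpp_bvnu(-h, -k, r), pbvnorm(h, k, r))
})

test_that("prob_detect_any: closed-form cases and Monte Carlo agreement", {
  expect_equal(prob_detect_any(c(0, 0), 0), 0.75)
  expect_equal(prob_detect_any(0), 0.5)
  expect_lt(abs(prob_detect_any(c(0, 0), 0.999) - 0.5), 0.01)
  set.seed(7)
  n <- 2e6
  z1 <- rnorm(n); z2 <- 0.4 * z1 + sqrt(1 - 0.16) * rnorm(n)
  mc <- mean(z1 > -0.3 | z2 > 0.2)
  se <- sqrt(mc * (1 - mc) / n)
  expect_lt(abs(prob_detect_any(c(0.3, -0.2), 0.4) - mc), 3 * se)
})

test_that("detection probability orderings hold over a parameter sweep", {
  set.seed(11)
  for (i in 1:200) {
    mu <- rnorm(2); r <- runif(1, -0.95, 0.95)
    p1 <- pnorm(mu[1]); p2 <- pnorm(mu[2])
    dup <- pbvnorm(mu[1], mu[2], r)
    pooled <- prob_detect_any(mu, r)
    expect_gte(dup, 0); expect_lte(dup, min(p1, p2) + 1e-12)
    expect_lte(max(p1, p2), pooled + 1e-12)
    expect_lte(pooled, 1)
    expect_equal(pooled, p1 + p2 - dup, tolerance = 1e-9)
  }
  # monotone in each mean; nonincreasing in corr for positive means
  mus <- seq(-2, 2, length.out = 9)
  p_by_mu <- prob_detect_any(cbind(mus, 0.3), 0.2)
  expect_true(all(diff(p_by_mu) > 0))
  rs <- seq(0, 0.9, by = 0.1)
  p_by_r <- prob_detect_any(cbind(rep(0.5, length(rs)), 0.8), rs)
  expect_true(all(diff(p_by_r) < 1e-12))
})

test_that("latent Gibbs update is sign-consistent with the stated conditional law", {
  set.seed(5)
  n <- 20000
  y <- cbind(rep(1L, n), rep(0L, n))
  mu <- cbind(rep(0.3, n), rep(-0.2, n))
  ys <- gibbs_update_latent(y, mu, corr = 0.5)
  expect_true(all(ys[, 1] > 0))
  expect_true(all(ys[, 2] <= 0))
  # conditional law of y2 before truncation: normal(mu2 + r (y1 - mu1), 1 - r^2);
  # check against direct truncated draws from that law
  m2 <- mu[, 2] + 0.5 * (ys[, 1] - mu[, 1])
  direct <- rjds:::rtnorm(n, m2, sqrt(0.75), upper = 0)
  expect_lt(abs(mean(ys[, 2]) - mean(direct)), 4 * sd(direct) / sqrt(n) * 2)
  # independence limit: matches independent truncated normals
  ys0 <- gibbs_update_latent(y, mu, corr = 0)
  ref <- rjds:::rtnorm(n, mu[, 1], 1, lower = 0)
  expect_lt(abs(mean(ys0[, 1]) - mean(ref)), 4 * sd(ref) / sqrt(n) * 2)
})

test_that("beta_det full conditional reduces to least squares under a flat prior", {
  set.seed(6)
  n <- 400
  X1 <- cbind(1, runif(n)); X2 <- cbind(1, runif(n))
  ys <- cbind(rnorm(n, X1 %*% c(0.5, -1)), rnorm(n, X2 %*% c(0.5, -1)))
  fc <- rjds:::beta_det_fullcond(ys, X1, X2, corr = 0, prior_sd = 1e6)
  lsfit <- lm.fit(rbind(X1, X2), c(ys[, 1], ys[, 2]))
  expect_equal(unname(fc$mean), unname(lsfit$coefficients), tolerance = 1e-6)
  # an all-zero column is rejected
  expect_error(rjds:::beta_det_fullcond(ys, cbind(X1, 0), cbind(X2, 0), 0),
               "all-zero")
})

test_that("rho MH auto-rejects invalid proposals and accepts symmetric moves", {
  set.seed(8)
  n <- 500
  ys <- matrix(rnorm(2 * n), ncol = 2)
  mu <- matrix(0, n, 2)
  # widths so large every proposal lands outside the prior -> never moves
  st <- mh_update_rho(0.98, ys, mu, rep(1, n), prior = c(-0.99, 0.99),
                      width = 0)
  expect_identical(st$rho, 0.98)
  moved <- replicate(50, mh_update_rho(0, ys, mu, rep(1, n),
                                       width = 0.05)$accepted)
  expect_gt(mean(moved), 0)    # symmetric proposal: posterior-ratio only
})

test_that("detection curves obey the independence identities and point anchor", {
  beta <- c(0.8, -0.3, -1.0)   # intercept, observer o2, distance
  vi <- vi_basic[c("observer", "distance")]
  crv0 <- detection_curves(beta, rho = 0, ~ observer + distance, vi,
                           c("o1", "o2"))
  expect_equal(crv0$delta, rep(1, nrow(crv0)), tolerance = 1e-10)
  expect_equal(crv0$dup, crv0$p1 * crv0$p2, tolerance = 1e-10)
  crv <- detection_curves(beta, rho = 0.5, ~ observer + distance, vi,
                          c("o1", "o2"))
  expect_equal(crv$delta[crv$distance == 0], 1, tolerance = 1e-10)
  expect_true(all(crv$delta >= 1 - 1e-10))           # positive dependence
  expect_equal(crv$pooled, crv$p1 + crv$p2 - crv$dup, tolerance = 1e-10)
  expect_equal(crv$cond, crv$dup / crv$p1, tolerance = 1e-12)
  # duplicate probability against Monte Carlo at one grid point
  set.seed(3)
  i <- which.min(abs(crv$distance - 0.6))
  mu1 <- qnorm(crv$p1[i]); mu2 <- qnorm(crv$p2[i])
  z1 <- rnorm(1e6); z2 <- 0.3 * z1 + sqrt(1 - 0.09) * rnorm(1e6)
  mc <- mean(z1 > -mu1 & z2 > -mu2)
  expect_lt(abs(crv$dup[i] - mc), 3 * sqrt(mc * (1 - mc) / 1e6))
})
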