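# Parametric individual-covariate models: densities, sampling, updates.

test_that("densities match closed forms and vanish off-support", {
  zt <- covariate_model("poisson_zt", theta = 0)          # lambda = 1
  expect_equal(covariate_density(1, zt), exp(-1) / (1 - exp(-1)),
               tolerance = 1e-12)
  expect_equal(covariate_density(0, zt), 0)
  expect_equal(covariate_density(2.5, zt), 0)
  un <- covariate_model("uniform", min = 0, max = 1)
  expect_equal(covariate_density(0.3, un), 1)
  expect_equal(covariate_density(1.3, un), 0)
  ca <- covariate_model("categorical", levels = c("a", "b"),
                        probs = c(0.25, 0.75))
  expect_equal(covariate_density(2, ca), 0.75)
  expect_equal(covariate_density("a", ca), 0.25)
  expect_equal(covariate_density(3, ca), 0)
  od <- covariate_model("poisson_od", theta = 0.5, sigma = 0.4)
  expect_equal(covariate_density(2, od, eps = 0.3),
               dpois(2, exp(0.8)), tolerance = 1e-12)
})

test_that("every Poisson-family pmf sums to one over its support", {
  for (th in c(-0.5, 0, 1, 2)) {
    for (fam in c("poisson", "poisson_zt")) {
      m <- covariate_model(fam, theta = th)
      expect_lt(abs(sum(covariate_density(0:200, m)) - 1), 1e-10,
                label = paste(fam, th))
    }
  }
})

test_that("sampling is self-consistent with the density (chi-squared)", {
  set.seed(21)
  m <- covariate_model("poisson_zt", theta = 0)
  z <- covariate_sample(1e5, m)$value
  expect_true(all(z >= 1))
  sup <- 1:4                                   # lump the sparse tail
  obs <- c(tabulate(pmin(z, 5), nbins = 5))
  pr <- covariate_density(sup, m)
  chi <- chisq.test(obs, p = c(pr, 1 - sum(pr)))
  expect_gt(chi$p.value, 0.01)
  # fair-coin categorical
  ca <- covariate_model("categorical", levels = c("a", "b"))
  zc <- covariate_sample(1e5, ca)$value
  expect_lt(abs(mean(zc == 1) - 0.5), 3 * sqrt(0.25 / 1e5))
  # uniform distances stay in [0, 1]
  zu <- covariate_sample(1e4, covariate_model("uniform"))$value
  expect_true(all(zu >= 0 & zu <= 1))
})

test_that("zero-truncated mean identity E[z] = lambda / (1 - exp(-lambda))", {
  set.seed(22)
  lam <- 1.7
  m <- covariate_model("poisson_zt", theta = log(lam))
  z <- covariate_sample(1e6, m)$value
  want <- lam / (1 - exp(-lam))
  expect_lt(abs(mean(z) - want), 3 * sd(z) / sqrt(1e6))
})

test_that("categorical update is the conjugate Dirichlet draw", {
  set.seed(23)
  m <- covariate_model("categorical", levels = c("a", "b"), alpha = 10)
  vals <- rep(c(1, 2), c(46, 54))
  draws <- replicate(4000, update_covariate_theta(m, vals)$model$probs[1])
  # full conditional Dirichlet(56, 64): mean 56/120, var ab/((a+b)^2 (a+b+1))
  expect_lt(abs(mean(draws) - 56 / 120), 4 * sqrt(56 * 64 / 120^2 / 121 / 4000))
  # exchangeable in observation order
  set.seed(99); d1 <- update_covariate_theta(m, vals)$model$probs
  set.seed(99); d2 <- update_covariate_theta(m, rev(vals))$model$probs
  expect_equal(d1, d2)
  # no data: posterior equals the prior Dirichlet(10, 10)
  prior_draws <- replicate(4000,
    update_covariate_theta(m, numeric(0))$model$probs[1])
  expect_lt(abs(mean(prior_draws) - 0.5), 4 * sqrt(100 / 400 / 21 / 4000))
})

test_that("Poisson-family MH updates recover a known rate", {
  set.seed(24)
  lam_true <- 4                                # mean ~ 4.07 for the ZT law
  m <- covariate_model("poisson_zt", theta = 0, theta_sd = 2)
  vals <- rjds:::rztpois(600, lam_true)
  th <- numeric(2000)
  for (i in seq_len(2000)) {
    m <- update_covariate_theta(m, vals, width = 0.1)$model
    th[i] <- m$theta
  }
  keep <- th[501:2000]
  ci <- quantile(exp(keep), c(0.025, 0.975))
  expect_gt(lam_true, ci[1]); expect_lt(lam_true, ci[2])
})

test_that("overdispersed updates move sigma and the random effects", {
  set.seed(25)
  m <- covariate_model("poisson_zt_od", theta = log(3), sigma = 0.5)
  d <- covariate_sample(400, m)
  eps <- d$eps
  st <- rjds:::update_covariate_eps(m, d$value, eps, width = 0.5)
  expect_gt(st$accept, 0)
  expect_equal(length(st$eps), 400)
  up <- update_covariate_theta(m, d$value, eps = st$eps, width = 0.2)
  expect_named(up$accept, c("theta", "sigma"))
  expect_true(up$model$sigma > 0 && up$model$sigma < m$sigma_max)
})
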