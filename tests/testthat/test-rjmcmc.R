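# Reversible-jump kernels and the orchestrating chain.

test_that("group-count proposals are uniform on the window minus the center", {
  set.seed(41)
  p1 <- replicate(4000, propose_group_count(10L, 1L))
  expect_setequal(unique(p1), c(9L, 11L))
  expect_lt(abs(mean(p1 == 9L) - 0.5), 3 * sqrt(0.25 / 4000))
  p3 <- replicate(8000, propose_group_count(10L, 3L))
  expect_setequal(unique(p3), c(7:9, 11:13))
  expect_gt(chisq.test(tabulate(factor(p3)))$p.value, 0.01)
})

test_that("acceptance ratio matches the complete-data closed form", {
  # c = 0, constant p* = 0.5, lambda A = 2, addition 0 -> 1: r = 2*0.5/1
  expect_equal(accept_ratio(0L, 1L, 2, 0.5, c = 0), 1)
  # one-step addition formula lambda A (1 - p*) / (G + 1 - c)
  expect_equal(accept_ratio(7L, 8L, 3, 0.4, c = 2), 3 * 0.6 / 6)
  # deletion is the reciprocal with the removed slot's p*
  expect_equal(accept_ratio(8L, 7L, 3, 0.4, c = 2), 6 / (3 * 0.6))
  # multi-step jumps multiply one-step factors
  r2 <- accept_ratio(5L, 7L, 2.5, c(0.3, 0.6), c = 1)
  expect_equal(r2, (2.5 * 0.7 / 5) * (2.5 * 0.4 / 6))
  # certain detection can never be added as a missed group
  expect_equal(accept_ratio(4L, 5L, 10, 1, c = 0), 0)
})

test_that("latent pairs for additions respect truncation and dependence sign", {
  set.seed(42)
  mu <- cbind(rep(0, 2000), rep(0, 2000))
  ys <- sample_latents_for_additions(mu, corr = 0)
  expect_true(all(ys <= 0))
  # independent lower-truncated standard normals: mean -sqrt(2/pi)
  expect_lt(abs(mean(ys[, 1]) + sqrt(2 / pi)), 4 * 0.6 / sqrt(2000))
  ys8 <- sample_latents_for_additions(mu, corr = 0.8)
  expect_gt(cor(ys8[, 1], ys8[, 2]), 0.3)
  # high-detection case exercises the Gibbs fallback; still sign-consistent
  ysh <- sample_latents_for_additions(cbind(rep(3.5, 50), rep(3.5, 50)), 0.2)
  expect_true(all(ysh <= 0))
})

test_that("retained-draw bookkeeping is exact for all settings", {
  expect_identical(n_retained(270000, 20000, 20, 2), 25000L)
  expect_identical(n_retained(100, 10, 7, 1), 13L)
  expect_identical(n_retained(10, 0, 1, 3), 30L)
  sim <- simulate_survey(sim_design(n_transects = 4), seed = 5)
  for (cfg in list(c(40, 10, 3, 1), c(55, 5, 7, 2))) {
    fit <- fit_hds(sim$detections, sim$cells, sim$model,
                   sampler = sampler_config(n_iter = cfg[1], burn_in = cfg[2],
                                            thin = cfg[3], n_chains = cfg[4],
                                            pilot_iters = 0, adapt = FALSE,
                                            seed = 2))
    expect_identical(nrow(fit$draws$samples),
                     n_retained(cfg[1], cfg[2], cfg[3], cfg[4]))
  }
})

test_that("a fixed seed reproduces the chain bit-exactly", {
  sim <- simulate_survey(sim_design(n_transects = 5), seed = 6)
  samp <- sampler_config(n_iter = 150, burn_in = 20, thin = 2,
                         pilot_iters = 50, seed = 123, n_chains = 2)
  f1 <- fit_hds(sim$detections, sim$cells, sim$model, sampler = samp)
  f2 <- fit_hds(sim$detections, sim$cells, sim$model, sampler = samp)
  expect_identical(f1$draws$samples, f2$draws$samples)
  samp$seed <- 124
  f3 <- fit_hds(sim$detections, sim$cells, sim$model, sampler = samp)
  expect_false(identical(f1$draws$samples, f3$draws$samples))
})

test_that("latent covariate resampling reaches the (1-p*) g stationary law", {
  # two-level mark with p*(level 1) high and p*(level 2) low, G fixed:
  # long-run level-2 frequency must be (1-p2) g2 / sum_k (1-pk) gk
  cells <- toy_cells()
  det <- rjds:::.make_detections(data.frame(
    transect = "t1", group = 1:2, y1 = 1L, y2 = 1L,
    distance = c(0.2, 0.6), mark = c("a", "b")))
  model <- model_spec(~ mark, ~ 1, list(
    distance = covariate_model("uniform"),
    mark = covariate_model("categorical", levels = c("a", "b"),
                           probs = c(0.5, 0.5), fixed = TRUE)))
  # beta: intercept and markb chosen so p*(a) ~ 0.9, p*(b) ~ 0.1
  mu_a <- qnorm(1 - sqrt(1 - 0.9))   # per-observer mu giving pooled 0.9
  mu_b <- qnorm(1 - sqrt(1 - 0.1))
  beta <- c(mu_a, mu_b - mu_a)
  samp <- sampler_config(n_iter = 30000, burn_in = 2000, thin = 1,
                         pilot_iters = 0, adapt = FALSE, seed = 31,
                         g_max_min = 12,
                         update = list(beta_det = FALSE, rho = FALSE,
                                       theta = FALSE, process = FALSE,
                                       G = FALSE))
  # hold G fixed at 6 (4 latent slots beyond the 2 observed groups)
  fit <- fit_hds(det, cells, model, sampler = samp,
                 init = list(beta_det = beta, rho = 0, v = log(6), G = 6),
                 track = "mark")
  expect_true(all(fit$draws$samples[, "G.total"] == 6))
  g2 <- fit$draws$samples[, "Gclass.b"] - 1   # one observed 'b' group
  p_want <- (1 - 0.1) * 0.5 / ((1 - 0.9) * 0.5 + (1 - 0.1) * 0.5)
  expect_lt(abs(mean(g2) / 4 - p_want), 0.02)
})

test_that("degenerate run with certain detection keeps G at the observed count", {
  cells <- toy_cells()
  det <- rjds:::.make_detections(data.frame(
    transect = "t1", group = 1:4, y1 = 1L, y2 = 1L,
    distance = c(0.1, 0.3, 0.5, 0.7)))
  model <- model_spec(~ 1, ~ 1, list(distance = covariate_model("uniform")))
  samp <- sampler_config(n_iter = 2000, burn_in = 100, thin = 1,
                         pilot_iters = 0, adapt = FALSE, seed = 7,
                         update = list(beta_det = FALSE, rho = FALSE,
                                       theta = FALSE, process = FALSE))
  fit <- fit_hds(det, cells, model, sampler = samp,
                 init = list(beta_det = 8, rho = 0, v = log(4)))
  expect_true(all(fit$draws$samples[, "G.total"] == 4))
})

test_that("slot-bound saturation triggers a warning", {
  cells <- toy_cells()
  det <- rjds:::.make_detections(data.frame(
    transect = "t1", group = 1:2, y1 = 1L, y2 = 0L, distance = c(0.2, 0.5)))
  model <- model_spec(~ 1, ~ 1, list(distance = covariate_model("uniform")))
  samp <- sampler_config(n_iter = 800, burn_in = 100, thin = 1,
                         pilot_iters = 0, adapt = FALSE, seed = 8,
                         g_max_min = 4, g_max_mult = 0, g_max_add = 2,
                         update = list(beta_det = FALSE, rho = FALSE,
                                       theta = FALSE, process = FALSE))
  # huge intensity and invisible groups push G against the tiny bound
  expect_warning(
    fit_hds(det, cells, model, sampler = samp,
            init = list(beta_det = -2, rho = 0, v = log(50))),
    "slot bound")
})

test_that("pilot adaptation drives acceptance toward the target band", {
  sim <- simulate_survey(sim_design(), seed = 9)
  fit <- fit_hds(sim$detections, sim$cells, sim$model,
                 sampler = sampler_config(n_iter = 1500, burn_in = 300,
                                          thin = 3, pilot_iters = 1200,
                                          seed = 10))
  expect_gt(fit$accept["G"], 0.2)
  expect_lt(fit$accept["G"], 0.55)
  expect_gt(fit$accept["v"], 0.15)
  expect_lt(fit$accept["v"], 0.6)
})
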