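# Readers, validation, area scaling, posterior round trips.

test_that("detection rows collapse to one record per group, ordered by the cell table", {
  p <- write_toy_tables()
  cells <- read_cell_table(p$cells)
  det <- read_detection_table(p$det, cells)
  expect_equal(nrow(det), 3L)
  g1 <- det[det$transect == "t1" & det$group == 1, ]
  expect_equal(c(g1$y1, g1$y2), c(1L, 0L))      # seen by a, missed by b
  g2 <- det[det$transect == "t2" & det$group == 1, ]
  expect_equal(c(g2$y1, g2$y2), c(0L, 1L))      # order is b then c
  expect_equal(det$size[det$transect == "t1" & det$group == 2], 1L)
})

test_that("invalid detection tables are rejected with informative errors", {
  p <- write_toy_tables()
  cells <- read_cell_table(p$cells)

  bad <- read.csv(p$det)
  bad$seen[bad$group == 2] <- 0L              # a group nobody saw
  f <- file.path(p$dir, "allzero.csv"); write.csv(bad, f, row.names = FALSE)
  expect_error(read_detection_table(f, cells), "no detection")

  bad <- read.csv(p$det)
  bad <- rbind(bad, bad[1, ])                  # duplicate (transect,group,obs)
  f <- file.path(p$dir, "dup.csv"); write.csv(bad, f, row.names = FALSE)
  expect_error(read_detection_table(f, cells), "duplicate")

  bad <- read.csv(p$det)
  names(bad)[names(bad) == "distance"] <- "dist"
  f <- file.path(p$dir, "miss.csv"); write.csv(bad, f, row.names = FALSE)
  expect_error(read_detection_table(f, cells), "distance")
})

test_that("cell tables validate areas, observers, and count J and L", {
  p <- write_toy_tables()
  cells <- read_cell_table(p$cells)
  expect_equal(attr(cells, "J"), 2L)
  expect_equal(attr(cells, "L"), 3L)

  bad <- read.csv(p$cells, colClasses = c(observers = "character"))
  bad$area[1] <- 0
  f <- file.path(p$dir, "area0.csv"); write.csv(bad, f, row.names = FALSE)
  expect_error(read_cell_table(f), "positive")

  bad <- read.csv(p$cells, colClasses = c(observers = "character"))
  bad$observers[1] <- ""
  f <- file.path(p$dir, "noobs.csv"); write.csv(bad, f, row.names = FALSE)
  expect_error(read_cell_table(f), "observers")

  bad <- read.csv(p$cells, colClasses = c(observers = "character"))
  bad$observers[2] <- "a;b;c"
  f <- file.path(p$dir, "threeobs.csv"); write.csv(bad, f, row.names = FALSE)
  expect_error(read_cell_table(f), "two observers")
})

test_that("scale_areas divides by the mean and is idempotent", {
  p <- write_toy_tables()
  cells <- read_cell_table(p$cells)
  sc <- scale_areas(cells)
  expect_equal(sc$area, c(0.5, 1.0, 1.5))
  expect_equal(mean(sc$area), 1)
  expect_equal(scale_areas(sc)$area, sc$area)
  one <- cells; one$area <- rep(7, 3)
  expect_equal(scale_areas(one)$area, rep(1, 3))
})

test_that("detection and cell tables round-trip through their writers", {
  sim <- simulate_survey(sim_design(), seed = 3)
  dir <- tempfile(); dir.create(dir)
  cp <- write_cell_table(sim$cells, file.path(dir, "cells.csv"))
  dp <- write_detection_table(sim$detections, sim$cells,
                              file.path(dir, "det.csv"))
  cells2 <- read_cell_table(cp)
  expect_equal(cells2$area, sim$cells$area)
  expect_equal(attr(cells2, "observers"), attr(sim$cells, "observers"))
  det2 <- read_detection_table(dp, cells2, sim$model)
  ord <- order(det2$transect, det2$group)
  ord0 <- order(sim$detections$transect, sim$detections$group)
  for (cl in c("y1", "y2", "distance", "size", "species")) {
    expect_equal(det2[[cl]][ord], sim$detections[[cl]][ord0], label = cl)
  }
})

test_that("posterior draws round-trip bit-exactly through CSV", {
  sim <- simulate_survey(sim_design(n_transects = 4), seed = 2)
  fit <- fit_hds(sim$detections, sim$cells, sim$model,
                 sampler = sampler_config(n_iter = 60, burn_in = 10, thin = 5,
                                          pilot_iters = 0, adapt = FALSE,
                                          seed = 1))
  f <- tempfile(fileext = ".csv")
  write_posterior(fit$draws, f)
  back <- read_posterior(f)
  expect_equal(back$samples, fit$draws$samples)
  expect_equal(back$chain, fit$draws$chain)
  expect_equal(nrow(back$samples), n_retained(60, 10, 5, 1))
})

test_that("config files build model, prior and sampler objects", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "model:",
    "  detection_formula: '~ observer + distance + size'",
    "  habitat_formula: '~ 1'",
    "  covariate_models:",
    "    size: {family: poisson_zt, theta: 1.0}",
    "priors:",
    "  beta_sd: 5",
    "  tau_a: 2",
    "  tau_b: 0.5",
    "sampler:",
    "  n_iter: 500",
    "  burn_in: 100",
    "  thin: 2"), f)
  cfg <- read_config(f)
  expect_s3_class(cfg$model, "rjds_model")
  expect_equal(cfg$model$covariate_models$size$family, "poisson_zt")
  expect_true("distance" %in% names(cfg$model$covariate_models))
  expect_equal(cfg$priors$beta_sd, 5)
  expect_equal(cfg$sampler$n_iter, 500L)
})
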