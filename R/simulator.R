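# Synthetic survey generator: the two-species simulation design (25
# transects, a pool of three observers, linear and quadratic
# intensity-covariate relationships, distance-growing observer dependence)
# and a known-truth golf-tee-style fixture. All truth is retained so
# estimator recovery can be verified.

# in-memory constructors mirroring read_cell_table / read_detection_table
.make_cells <- function(df, observers) {
  stopifnot(!anyDuplicated(df$cell), all(df$area > 0))
  names(observers) <- as.character(df$cell)
  attr(df, "observers") <- observers
  attr(df, "J") <- sum(df$sampled == 1)
  attr(df, "L") <- nrow(df)
  class(df) <- c("rjds_cells", "data.frame")
  df
}

.make_detections <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("rjds_detections", "data.frame")
  df
}

# solve the zero-truncated-Poisson rate giving a target mean
ztpois_rate_for_mean <- function(mean) {
  stopifnot(mean > 1)
  stats::uniroot(function(l) l / (1 - exp(-l)) - mean,
                 c(1e-8, 5 * mean), tol = 1e-12)$root
}

#' Simulation design for a two-species double-observer survey
#'
#' Defaults encode the reference study conditions: 25 transects each
#' surveyed by two observers picked at random from a pool of three with
#' different detective abilities; a common probit detection function of
#' observer, distance, group size and species; observer correlation growing
#' linearly with distance to a maximum of 0.5; species 1 log-intensity
#' linear in an arbitrary cell covariate (the scaled transect number),
#' species 2 quadratic; zero-truncated Poisson group sizes with species
#' means 4 and 2.
#'
#' @param n_transects number of surveyed cells.
#' @param observer_pool observer labels.
#' @param beta_det true detection coefficients, in the column order of
#'   \code{detection_formula}.
#' @param rho true dependence parameter (correlation at distance 1).
#' @param beta_hab named true habitat coefficients (see default for the
#'   column naming of the cell-by-species design).
#' @param tau_v true process precision.
#' @param size_means true mean group size per species.
#' @param detection_formula,habitat_formula model formulas (also used by the
#'   companion \code{model} spec in \code{\link{simulate_survey}} output).
#' @return list of class \code{rjds_sim_design}.
#' @export
sim_design <- function(n_transects = 25,
                       observer_pool = c("obs1", "obs2", "obs3"),
                       beta_det = c(`(Intercept)` = 0.9, observerobs2 = -0.3,
                                    observerobs3 = -0.6, distance = -1.2,
                                    size = 0.2, speciessp2 = -0.4),
                       rho = 0.5,
                       beta_hab = c(speciessp1 = 2.4, speciessp2 = 2.4,
                                    `speciessp1:x` = 1.0,
                                    `speciessp2:x` = 0,
                                    `speciessp1:I(x^2)` = 0,
                                    `speciessp2:I(x^2)` = -1.5),
                       tau_v = 20,
                       size_means = c(sp1 = 4, sp2 = 2),
                       detection_formula =
                         ~ observer + distance + size + species,
                       habitat_formula =
                         ~ 0 + species + species:x + species:I(x^2)) {
  structure(list(n_transects = n_transects, observer_pool = observer_pool,
                 beta_det = beta_det, rho = rho, beta_hab = beta_hab,
                 tau_v = tau_v, size_means = size_means,
                 size_lambda = vapply(size_means, ztpois_rate_for_mean, 0),
                 detection_formula = detection_formula,
                 habitat_formula = habitat_formula,
                 species = names(size_means)),
            class = "rjds_sim_design")
}

# simulate correlated probit detections for groups with linear predictors
# mu (n x 2) and correlations corr; returns 0/1 matrix
.sim_detections <- function(mu, corr) {
  n <- nrow(mu)
  z1 <- stats::rnorm(n)
  z2 <- corr * z1 + sqrt(1 - corr^2) * stats::rnorm(n)
  cbind(as.integer(mu[, 1L] + z1 > 0), as.integer(mu[, 2L] + z2 > 0))
}

#' Simulate a double-observer line-transect survey
#'
#' Generates cell intensities from the lognormal-Poisson process, group
#' covariates from the true covariate models, observer assignments from the
#' pool, and correlated probit detections; groups seen by nobody are dropped
#' from the detection table but retained in the truth roster.
#'
#' @param design a \code{\link{sim_design}}.
#' @param seed RNG seed (bit-reproducible output for a fixed seed).
#' @return list with \code{detections} (class \code{rjds_detections}),
#'   \code{cells} (class \code{rjds_cells}), \code{truth} (roster, true
#'   parameters, per-cell counts), and \code{model} (a matching
#'   \code{\link{model_spec}} for fitting).
#' @export
simulate_survey <- function(design = sim_design(), seed = 1) {
  set.seed(seed)
  nt <- design$n_transects
  x <- (seq_len(nt) - (nt + 1) / 2) / ((nt - 1) / 2)   # scaled to [-1, 1]
  obs <- lapply(seq_len(nt), function(i) sample(design$observer_pool, 2L))
  cells <- .make_cells(
    data.frame(cell = sprintf("t%02d", seq_len(nt)), area = 1,
               sampled = 1L,
               observers = vapply(obs, paste, "", collapse = ";"),
               x = x, stringsAsFactors = FALSE), obs)

  sp <- design$species
  hab_df <- data.frame(x = rep(x, each = length(sp)),
                       species = factor(rep(sp, nt), levels = sp))
  Xh <- stats::model.matrix(design$habitat_formula, hab_df)
  stopifnot(setequal(colnames(Xh), names(design$beta_hab)))
  eta <- drop(Xh %*% design$beta_hab[colnames(Xh)])
  v <- stats::rnorm(length(eta), eta, 1 / sqrt(design$tau_v))
  G <- stats::rpois(length(eta), exp(v))
  unit_cell <- rep(seq_len(nt), each = length(sp))
  unit_sp <- rep(seq_along(sp), nt)

  roster <- data.frame(
    transect = cells$cell[rep(unit_cell, G)],
    species = sp[rep(unit_sp, G)],
    stringsAsFactors = FALSE)
  n <- nrow(roster)
  roster$distance <- stats::runif(n)
  roster$size <- rztpois(n, design$size_lambda[roster$species])
  ti <- match(roster$transect, cells$cell)
  o1 <- vapply(obs, `[`, "", 1L)[ti]
  o2 <- vapply(obs, `[`, "", 2L)[ti]
  var_info <- list(observer = list(type = "factor",
                                   levels = sort(design$observer_pool)),
                   distance = list(type = "numeric"),
                   size = list(type = "numeric"),
                   species = list(type = "factor", levels = sp))
  builder <- make_design_builder(design$detection_formula, var_info)
  ddata <- list(distance = roster$distance, size = roster$size,
                species = match(roster$species, sp))
  mu <- cbind(
    drop(builder(c(ddata, list(observer = o1))) %*% design$beta_det),
    drop(builder(c(ddata, list(observer = o2))) %*% design$beta_det))
  y <- .sim_detections(mu, design$rho * roster$distance)
  roster$y1 <- y[, 1L]; roster$y2 <- y[, 2L]
  roster$detected <- roster$y1 + roster$y2 > 0

  seen <- roster[roster$detected, ]
  seen$group <- stats::ave(seq_len(nrow(seen)), seen$transect,
                           FUN = seq_along)
  det <- .make_detections(seen[, c("transect", "group", "y1", "y2",
                                   "distance", "size", "species")])
  fixture_id <- sprintf("sim2sp_seed%d", seed)
  attr(det, "fixture_id") <- fixture_id

  covms <- list(
    distance = covariate_model("uniform"),
    size = covariate_model("poisson_zt", theta = log(3)))
  model <- model_spec(detection_formula = design$detection_formula,
                      habitat_formula = design$habitat_formula,
                      covariate_models = covms,
                      species_mode = "partitioned", species_levels = sp)
  truth <- list(
    fixture_id = fixture_id,
    roster = roster,
    params = c(
      stats::setNames(design$beta_det,
                      paste0("det.", names(design$beta_det))),
      rho = design$rho,
      stats::setNames(design$beta_hab[colnames(Xh)],
                      paste0("hab.", colnames(Xh))),
      stats::setNames(log(design$size_lambda),
                      paste0("cov.size.", names(design$size_lambda),
                             ".theta"))),
    total_groups = n,
    groups_by_species = table(roster$species),
    detected_groups = sum(roster$detected),
    G_by_unit = G, v = v)
  list(detections = det, cells = cells, truth = truth, model = model)
}

#' Known-truth golf-tee-style fixture
#'
#' A synthetic population emulating the classic double-observer golf-tee
#' experiment: exactly 250 groups of tees of two colors ("species") with the
#' printed composition — 108 green and 142 yellow in total, of which 44
#' green and 86 yellow lie in the northern stratum — group sizes 1-8 drawn
#' from a declared zero-truncated Poisson law conditioned to the 1-8 range,
#' a binary exposure mark with color-specific unexposed proportions 0.56
#' (green) and 0.53 (yellow), uniform distances in 11 full-coverage transect
#' cells, and detections by two pooled observer teams simulated from a
#' configurable probit model with distance-growing dependence. This is a
#' synthetic stand-in with known truth, not the published dataset.
#'
#' @param seed RNG seed.
#' @param beta_det true detection coefficients (column order of the default
#'   team/distance/size/exposure/species model with a distance-by-exposure
#'   interaction).
#' @param rho true dependence parameter.
#' @param size_lambda rate of the zero-truncated Poisson size law before
#'   conditioning to 1-8.
#' @param p_exposed probability a group is exposed, per color.
#' @return list with \code{detections}, \code{cells}, \code{truth}, and a
#'   matching \code{model} specification (species-specific stratum effects on
#'   intensity; overdispersed zero-truncated size model; Dirichlet(10,10)
#'   exposure model).
#' @export
golf_tee_fixture <- function(seed = 1,
                             beta_det = c(0.7, -0.2, -1.5, 0.25, 0.8,
                                          0.2, 0.7),
                             rho = 0.4, size_lambda = 2.82,
                             p_exposed = c(green = 0.44, yellow = 0.47)) {
  set.seed(seed)
  n_cells <- 11L
  north <- 1:5
  areas <- c(1.1, 0.9, 1.05, 1.0, 1.15, 0.95, 1.0, 1.1, 0.85, 1.0, 0.9)
  obs <- rep(list(c("team1", "team2")), n_cells)
  cells <- .make_cells(
    data.frame(cell = sprintf("t%02d", seq_len(n_cells)), area = areas,
               sampled = 1L, observers = "team1;team2",
               stratum = ifelse(seq_len(n_cells) %in% north,
                                "north", "south"),
               stringsAsFactors = FALSE), obs)

  comp <- data.frame(species = c("green", "yellow", "green", "yellow"),
                     stratum = c("north", "north", "south", "south"),
                     n = c(44L, 86L, 64L, 56L))
  place <- function(stratum, n) {
    idx <- which(cells$stratum == stratum)
    sample(idx, n, replace = TRUE, prob = areas[idx])
  }
  roster <- do.call(rbind, lapply(seq_len(nrow(comp)), function(i) {
    data.frame(transect = cells$cell[place(comp$stratum[i], comp$n[i])],
               species = comp$species[i], stratum = comp$stratum[i],
               stringsAsFactors = FALSE)
  }))
  n <- nrow(roster)
  stopifnot(n == 250L)
  roster$distance <- stats::runif(n)
  # zero-truncated Poisson conditioned to sizes 1-8
  sz <- rztpois(4L * n, size_lambda)
  sz <- sz[sz <= 8L]
  while (length(sz) < n) sz <- c(sz, rztpois(n, size_lambda))
  roster$size <- sz[seq_len(n)]
  roster$exposure <- stats::rbinom(n, 1L, p_exposed[roster$species])

  formula <- ~ observer + distance + size + exposure + species +
    distance:exposure
  var_info <- list(observer = list(type = "factor",
                                   levels = c("team1", "team2")),
                   distance = list(type = "numeric"),
                   size = list(type = "numeric"),
                   exposure = list(type = "factor", levels = c("0", "1")),
                   species = list(type = "factor",
                                  levels = c("green", "yellow")))
  builder <- make_design_builder(formula, var_info)
  ddata <- list(distance = roster$distance, size = roster$size,
                exposure = roster$exposure + 1L,
                species = match(roster$species, c("green", "yellow")))
  nr <- nrow(roster)
  mu <- cbind(
    drop(builder(c(ddata, list(observer = rep("team1", nr)))) %*% beta_det),
    drop(builder(c(ddata, list(observer = rep("team2", nr)))) %*% beta_det))
  y <- .sim_detections(mu, rho * roster$distance)
  roster$y1 <- y[, 1L]; roster$y2 <- y[, 2L]
  roster$detected <- roster$y1 + roster$y2 > 0

  seen <- roster[roster$detected, ]
  seen$group <- stats::ave(seq_len(nrow(seen)), seen$transect,
                           FUN = seq_along)
  seen$exposure <- as.character(seen$exposure)
  det <- .make_detections(seen[, c("transect", "group", "y1", "y2",
                                   "distance", "size", "exposure",
                                   "species")])
  fixture_id <- sprintf("golf_tee_seed%d", seed)
  attr(det, "fixture_id") <- fixture_id

  model <- model_spec(
    detection_formula = formula,
    habitat_formula = ~ 0 + species + species:stratum,
    covariate_models = list(
      distance = covariate_model("uniform"),
      size = covariate_model("poisson_zt_od", theta = log(2.5),
                             sigma = 0.3),
      exposure = covariate_model("categorical", levels = c("0", "1"),
                                 alpha = 10)),
    species_mode = "partitioned", species_levels = c("green", "yellow"))

  unexposed <- tapply(roster$exposure == 0, roster$species, mean)
  truth <- list(
    fixture_id = fixture_id,
    roster = roster,
    params = c(stats::setNames(
      beta_det, paste0("det.", attr(builder, "colnames"))),
      rho = rho, size_lambda = size_lambda),
    total_groups = 250L,
    groups_by_species = c(green = 108L, yellow = 142L),
    north_by_species = c(green = 44L, yellow = 86L),
    detected_groups = sum(roster$detected),
    prop_unexposed = unexposed)
  list(detections = det, cells = cells, truth = truth, model = model)
}

#' Coverage report against known truth
#'
#' For each truth quantity that the fit tracked (parameters by name, total
#' and per-species group counts), reports the true value, the posterior mean
#' and equal-tailed 95\% interval, and whether the interval covers truth.
#'
#' @param truth the \code{truth} element of a simulator output.
#' @param fit the \code{\link{fit_hds}} result for the same fixture.
#' @return data.frame with columns \code{quantity, truth, mean, lo, hi,
#'   covered}.
#' @export
truth_report <- function(truth, fit) {
  stopifnot(inherits(fit, "rjds_fit"))
  if (!is.null(truth$fixture_id) && !is.null(fit$fixture_id) &&
      !identical(truth$fixture_id, fit$fixture_id)) {
    stop("fixture ids do not match: truth is '", truth$fixture_id,
         "', fit is '", fit$fixture_id, "'")
  }
  cn <- colnames(fit$draws$samples)
  want <- c(truth$params, G.total = truth$total_groups)
  if (!is.null(truth$groups_by_species)) {
    gs <- truth$groups_by_species
    want <- c(want, stats::setNames(as.numeric(gs),
                                    paste0("G.total.", names(gs))))
  }
  want <- want[names(want) %in% cn]
  if (!length(want)) stop("no truth quantity matches a tracked draw column")
  s <- summarize_draws(fit, names(want), level = 0.95)
  data.frame(quantity = s$quantity, truth = as.numeric(want),
             mean = s$mean, lo = s$lo95, hi = s$hi95,
             covered = as.numeric(want) >= s$lo95 &
               as.numeric(want) <= s$hi95)
}
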