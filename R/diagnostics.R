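# Convergence diagnostics (potential scale reduction, effective sample
# size) and report-bundle generation (posterior densities, detection
# curves, size pmf, trace plots).

# Gelman-Rubin potential scale reduction over chains (no splitting).
.rhat <- function(x, chain) {
  ch <- split(x, chain)
  m <- length(ch)
  if (m < 2L) return(NA_real_)
  n <- min(lengths(ch))
  ch <- lapply(ch, utils::head, n)
  means <- vapply(ch, mean, 0)
  vars <- vapply(ch, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W < .Machine$double.eps) {
    return(if (B < .Machine$double.eps) 1 else Inf)
  }
  # clamped at 1: sampling noise can push the raw ratio slightly below
  sqrt(max(1, ((n - 1) / n * W + B / n) / W))
}

# effective sample size via the initial positive sequence of autocovariances
.ess <- function(x, chain) {
  ch <- split(x, chain)
  total <- 0
  for (y in ch) {
    n <- length(y)
    if (stats::var(y) < .Machine$double.eps) { total <- total + n; next }
    ac <- stats::acf(y, lag.max = min(n - 1L, 200L), plot = FALSE,
                     demean = TRUE)$acf[, 1L, 1L]
    s <- 0
    for (k in seq(2L, length(ac), by = 2L)) {
      pair <- ac[k] + if (k < length(ac)) ac[k + 1L] else 0
      if (pair < 0) break
      s <- s + pair
    }
    total <- total + n / (1 + 2 * s)
  }
  total
}

#' Convergence diagnostics
#'
#' Potential scale reduction (between/within-chain variance ratio) and
#' effective sample size for every scalar draw column. With a single chain
#' the scale-reduction statistic is \code{NA} and a warning is issued.
#'
#' @param x an \code{rjds_fit} or \code{rjds_draws} object.
#' @param quantities columns to diagnose; default all.
#' @return data.frame with columns \code{quantity, rhat, ess}.
#' @export
diagnose <- function(x, quantities = NULL) {
  draws <- if (inherits(x, "rjds_fit")) x$draws else x
  stopifnot(inherits(draws, "rjds_draws"))
  if (is.null(quantities)) quantities <- colnames(draws$samples)
  if (draws$n_chains < 2L) {
    warning("single chain: between-chain scale reduction unavailable")
  }
  data.frame(
    quantity = quantities,
    rhat = vapply(quantities, function(q)
      .rhat(draws$samples[, q], draws$chain), 0),
    ess = vapply(quantities, function(q)
      .ess(draws$samples[, q], draws$chain), 0),
    row.names = NULL)
}

#' Write a report bundle
#'
#' Emits posterior-density panels (with optional truth overlays),
#' trace plots, the posterior predictive group-size pmf, the
#' detection-curve panel (individual, conditional, duplicate, pooled and the
#' dependence ratio delta at posterior-mean parameters), and a posterior
#' summary CSV.
#'
#' @param fit an \code{rjds_fit}.
#' @param dir output directory (created if needed).
#' @param truth optional simulator truth for overlays.
#' @param curve_covariates fixed covariate profile for the detection curves
#'   (defaults: size 1 and the first level of each categorical covariate).
#' @return invisibly, the vector of files written.
#' @export
report <- function(fit, dir, truth = NULL, curve_covariates = list()) {
  stopifnot(inherits(fit, "rjds_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  s <- fit$draws$samples
  param_cols <- grep("^(det\\.|rho$|cov\\.|hab\\.|tau_v$)", colnames(s),
                     value = TRUE)

  put <- function(name, expr) {
    f <- file.path(dir, name)
    grDevices::png(f, width = 1400, height = 1000, res = 120)
    on.exit(grDevices::dev.off(), add = TRUE)
    force(expr)
    files <<- c(files, f)
  }

  put("posterior_densities.png", {
    k <- length(param_cols)
    nc <- ceiling(sqrt(k)); nr <- ceiling(k / nc)
    graphics::par(mfrow = c(nr, nc), mar = c(2.5, 2.5, 2, 0.5))
    for (cl in param_cols) {
      lab <- if (cl == "rho") "cor" else cl
      d <- stats::density(s[, cl])
      graphics::plot(d, main = lab, xlab = "", ylab = "")
      tv <- truth$params[cl]
      if (length(tv) && !is.na(tv)) {
        graphics::abline(v = tv, col = "red", lwd = 2)
      }
    }
  })
  put("traces.png", {
    k <- length(param_cols)
    nc <- ceiling(sqrt(k)); nr <- ceiling(k / nc)
    graphics::par(mfrow = c(nr, nc), mar = c(2.5, 2.5, 2, 0.5))
    for (cl in param_cols) {
      graphics::plot(s[, cl], type = "l", main = cl, xlab = "", ylab = "",
                     col = fit$draws$chain)
    }
  })

  if ("size" %in% names(fit$model$covariate_models)) {
    pmf <- size_pmf(fit)
    utils::write.csv(pmf, file.path(dir, "size_pmf.csv"), row.names = FALSE)
    files <- c(files, file.path(dir, "size_pmf.csv"))
    put("size_pmf.png", {
      graphics::barplot(pmf$probability, names.arg = pmf$size,
                        xlab = "group size", ylab = "probability",
                        main = "posterior predictive group size")
    })
  }

  if ("rho" %in% colnames(s)) {
    bd <- colMeans(s[, paste0("det.", fit$design$det_colnames),
                     drop = FALSE])
    vi <- fit$design$var_info
    fixed <- curve_covariates
    for (vn in setdiff(names(vi), c("observer", "distance"))) {
      if (is.null(fixed[[vn]])) {
        fixed[[vn]] <- if (identical(vi[[vn]]$type, "factor")) 1 else 1
      }
    }
    obs_pair <- utils::head(vi$observer$levels, 2L)
    crv <- detection_curves(unname(bd), mean(s[, "rho"]),
                            fit$model$detection_formula, vi, obs_pair,
                            fixed_covariates = fixed,
                            mode = fit$model$distance_mode,
                            n_bins = fit$model$n_bins)
    utils::write.csv(crv, file.path(dir, "detection_curves.csv"),
                     row.names = FALSE)
    files <- c(files, file.path(dir, "detection_curves.csv"))
    put("detection_curves.png", {
      graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 0.5))
      graphics::matplot(crv$distance, crv[, c("p1", "cond", "dup", "pooled")],
                        type = "l", lty = 1:4, col = 1:4,
                        xlab = "distance", ylab = "detection probability",
                        main = "detection functions")
      graphics::legend("topright", c("individual", "conditional",
                                     "duplicate", "pooled"),
                       lty = 1:4, col = 1:4, bty = "n")
      graphics::plot(crv$distance, crv$delta, type = "l",
                     xlab = "distance", ylab = expression(delta),
                     main = "observer dependence")
      graphics::abline(h = 1, lty = 3)
    })
  }

  sm <- summarize_draws(fit)
  utils::write.csv(sm, file.path(dir, "posterior_summary.csv"),
                   row.names = FALSE)
  files <- c(files, file.path(dir, "posterior_summary.csv"))
  invisible(files)
}

#' Run manifest
#'
#' Assembles the reproducibility manifest of a fit: seeds, chain and
#' iteration counts, acceptance rates per update block, and the slot-bound
#' saturation fraction.
#'
#' @param fit an \code{rjds_fit}.
#' @return a list of class \code{rjds_manifest}.
#' @export
run_manifest <- function(fit) {
  stopifnot(inherits(fit, "rjds_fit"))
  structure(list(
    seed = fit$sampler$seed,
    n_chains = fit$sampler$n_chains,
    n_iter = fit$sampler$n_iter,
    burn_in = fit$sampler$burn_in,
    thin = fit$sampler$thin,
    pilot_iters = fit$sampler$pilot_iters,
    retained = nrow(fit$draws$samples),
    accept = fit$accept,
    g_max_saturation = fit$saturation),
    class = "rjds_manifest")
}
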