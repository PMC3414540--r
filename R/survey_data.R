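# Domain types, validation, and readers/writers: detection tables, cell
# tables, model/prior/sampler specifications, posterior draw files, configs.
# File dialect everywhere: comma-separated, mandatory header, UTF-8, "."
# decimal.

#' Declare the model structure
#'
#' @param detection_formula formula (or string) for the probit detection
#'   model; may use \code{observer}, individual covariates (always including
#'   \code{distance}), and unit-level covariates such as \code{species} in
#'   partitioned mode. Interactions use the usual \code{:} / \code{*} syntax.
#' @param habitat_formula formula for the log abundance intensity over cell
#'   (and, in partitioned mode, species) covariates.
#' @param covariate_models named list of \code{\link{covariate_model}}
#'   objects, one per modeled individual covariate. A uniform model for
#'   \code{distance} is added if absent.
#' @param distance_mode \code{"continuous"} (distances pre-scaled to
#'   \eqn{[0,1]}, half-width = 1) or \code{"binned"} (1-based integer bins).
#' @param n_bins number of distance bins (binned mode).
#' @param species_mode \code{"partitioned"} (species-specific abundance
#'   intensity; species a fixed covariate) or \code{"joint_latent"} (shared
#'   cell intensity; species a latent categorical covariate of never-observed
#'   groups).
#' @param species_levels category labels for species (partitioned mode; taken
#'   from the data if omitted).
#' @return an object of class \code{rjds_model}.
#' @export
model_spec <- function(detection_formula = ~ observer + distance,
                       habitat_formula = ~ 1,
                       covariate_models = list(),
                       distance_mode = c("continuous", "binned"),
                       n_bins = NULL,
                       species_mode = c("partitioned", "joint_latent"),
                       species_levels = NULL) {
  distance_mode <- match.arg(distance_mode)
  species_mode <- match.arg(species_mode)
  if (distance_mode == "binned" && is.null(n_bins)) {
    stop("binned distance mode needs 'n_bins'")
  }
  if (!"distance" %in% names(covariate_models)) {
    covariate_models$distance <- if (distance_mode == "continuous") {
      covariate_model("uniform", min = 0, max = 1)
    } else {
      covariate_model("categorical", levels = as.character(seq_len(n_bins)),
                      alpha = 1)
    }
  }
  if (distance_mode == "binned") {
    covariate_models$distance$fixed <- TRUE  # pseudo-group distances: uniform
  }
  stopifnot(all(vapply(covariate_models, inherits, TRUE, "rjds_covmodel")))
  spec <- list(detection_formula = stats::as.formula(detection_formula),
               habitat_formula = stats::as.formula(habitat_formula),
               covariate_models = covariate_models,
               distance_mode = distance_mode, n_bins = n_bins,
               species_mode = species_mode, species_levels = species_levels)
  class(spec) <- "rjds_model"
  spec
}

#' Declare prior distributions
#'
#' Regression coefficients (detection and habitat) get independent vague
#' normal priors; the process precision a conjugate gamma; the dependence
#' parameter a uniform prior on an interval keeping every implied
#' correlation inside \eqn{(-1, 1)}. Hyperpriors for covariate models live
#' on the \code{\link{covariate_model}} objects.
#'
#' @param beta_sd prior SD of regression coefficients.
#' @param tau_a,tau_b gamma prior shape and rate for \eqn{\tau_v}.
#' @param rho_bounds support of the uniform prior on \eqn{\rho}.
#' @return an object of class \code{rjds_priors}.
#' @export
prior_spec <- function(beta_sd = 10, tau_a = 1, tau_b = 0.01,
                       rho_bounds = c(-0.99, 0.99)) {
  stopifnot(beta_sd > 0, tau_a > 0, tau_b > 0,
            rho_bounds[1] < rho_bounds[2],
            rho_bounds[1] > -1, rho_bounds[2] < 1)
  structure(list(beta_sd = beta_sd, tau_a = tau_a, tau_b = tau_b,
                 rho_bounds = rho_bounds),
            class = "rjds_priors")
}

#' Configure the sampler
#'
#' @param n_iter iterations per chain (post-pilot).
#' @param burn_in iterations discarded from the front of each chain.
#' @param thin keep one of every \code{thin} iterations.
#' @param n_chains number of independent chains.
#' @param seed master seed; chain \eqn{c} uses \code{seed + c - 1}.
#' @param psi initial reversible-jump window half-width (integer, >= 1).
#' @param adapt tune proposal widths during the pilot phase to a 0.3-0.4
#'   acceptance band, then freeze?
#' @param pilot_iters pilot-phase length (not retained).
#' @param target_accept acceptance band targeted by adaptation.
#' @param g_max_min,g_max_mult,g_max_add per-unit slot bound
#'   \code{max(g_max_min, g_max_mult * c + g_max_add)}.
#' @param update named list of logical switches to freeze parameter blocks
#'   (\code{beta_det}, \code{rho}, \code{theta}, \code{process}, \code{G},
#'   \code{latent_covariates}); used mainly for validation runs.
#' @param saturation_warn warn if the group count sits at its slot bound in
#'   more than this fraction of iterations.
#' @return an object of class \code{rjds_sampler}.
#' @export
sampler_config <- function(n_iter = 20000, burn_in = 2000, thin = 10,
                           n_chains = 1, seed = NULL, psi = 3,
                           adapt = TRUE, pilot_iters = 1000,
                           target_accept = c(0.3, 0.4),
                           g_max_min = 20, g_max_mult = 5, g_max_add = 20,
                           update = list(), saturation_warn = 0.01) {
  stopifnot(burn_in < n_iter, thin >= 1, psi >= 1, n_chains >= 1)
  upd <- list(beta_det = TRUE, rho = TRUE, theta = TRUE, process = TRUE,
              G = TRUE, latent_covariates = TRUE)
  upd[names(update)] <- update
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = seed, psi = as.integer(psi), adapt = adapt,
                 pilot_iters = as.integer(pilot_iters),
                 target_accept = target_accept,
                 g_max_min = g_max_min, g_max_mult = g_max_mult,
                 g_max_add = g_max_add, update = upd,
                 saturation_warn = saturation_warn),
            class = "rjds_sampler")
}

#' Read a detection table
#'
#' One input row per detected group per observer; rows are collapsed into
#' one record per (transect, group) with the detection vector ordered by the
#' cell table's observer assignment (not by file order).
#'
#' @param path CSV with columns
#'   \code{transect,group,observer,seen,distance[,size,species,...]}.
#' @param cells a \code{\link{read_cell_table}} result (observer ordering).
#' @param spec optional \code{\link{model_spec}} used to validate covariate
#'   support.
#' @return data.frame of class \code{rjds_detections}: columns
#'   \code{transect}, \code{group}, \code{y1}, \code{y2} (NA on
#'   single-observer transects), and one column per covariate.
#' @export
read_detection_table <- function(path, cells, spec = NULL) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("transect", "group", "observer", "seen", "distance")
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    stop("detection table is missing column(s): ", paste(miss, collapse = ", "))
  }
  key <- paste(raw$transect, raw$group, raw$observer, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (transect, group, observer) rows in detection table")
  }
  covs <- setdiff(names(raw), c("transect", "group", "observer", "seen"))
  obs_by_cell <- attr(cells, "observers")
  first <- !duplicated(paste(raw$transect, raw$group, sep = "\r"))
  out <- raw[first, c("transect", "group", covs), drop = FALSE]
  out$y1 <- NA_integer_; out$y2 <- NA_integer_
  for (i in seq_len(nrow(out))) {
    tr <- as.character(out$transect[i])
    obs <- obs_by_cell[[tr]]
    if (is.null(obs)) stop("transect '", tr, "' not present in cell table")
    rows <- raw[raw$transect == out$transect[i] & raw$group == out$group[i], ]
    seen <- integer(length(obs))
    m <- match(as.character(rows$observer), obs)
    if (anyNA(m)) {
      stop("observer not assigned to transect '", tr, "': ",
           paste(rows$observer[is.na(m)], collapse = ", "))
    }
    seen[m] <- as.integer(rows$seen)
    if (!any(seen == 1)) {
      stop("group ", out$group[i], " on transect '", tr,
           "' has no detection; observed data are conditioned on >= 1")
    }
    cv <- unique(rows[, covs, drop = FALSE])
    if (nrow(cv) != 1L) {
      stop("inconsistent covariate values for group ", out$group[i],
           " on transect '", tr, "'")
    }
    out[i, covs] <- cv
    out$y1[i] <- seen[1L]
    out$y2[i] <- if (length(obs) > 1L) seen[2L] else NA_integer_
  }
  out <- out[, c("transect", "group", "y1", "y2", covs)]
  .validate_detections(out, spec)
  rownames(out) <- NULL
  class(out) <- c("rjds_detections", "data.frame")
  out
}

.validate_detections <- function(det, spec) {
  if ("size" %in% names(det)) {
    if (any(is.na(det$size)) || any(det$size < 1)) {
      stop("group sizes must be present and >= 1")
    }
  }
  if (anyNA(det$distance)) stop("missing distance values are not supported")
  if (!is.null(spec)) {
    if (spec$distance_mode == "continuous") {
      if (any(det$distance < 0 | det$distance > 1)) {
        stop("continuous distances must lie in [0, 1] (scaled to half-width)")
      }
    } else if (any(det$distance < 1 | det$distance > spec$n_bins |
                   det$distance != floor(det$distance))) {
      stop("binned distances must be integers in 1..", spec$n_bins)
    }
    covs <- setdiff(names(det), c("transect", "group", "y1", "y2"))
    modeled <- names(spec$covariate_models)
    det_vars <- all.vars(spec$detection_formula)
    need <- setdiff(det_vars, c("observer", "species", covs))
    bad <- setdiff(need, modeled)
    if (length(bad)) {
      stop("detection formula uses covariate(s) with neither observed values ",
           "nor a covariate model: ", paste(bad, collapse = ", "))
    }
    for (cv in intersect(covs, modeled)) {
      m <- spec$covariate_models[[cv]]
      if (m$family == "categorical" &&
          anyNA(.cat_code(det[[cv]], m))) {
        stop("covariate '", cv, "' has values outside its declared levels")
      }
    }
    if (anyNA(det[, covs, drop = FALSE])) {
      stop("missing covariate values on observed groups are not supported")
    }
  }
  invisible(det)
}

#' Read a cell table
#'
#' @param path CSV with columns \code{cell,area,sampled,observers} plus any
#'   habitat covariates; \code{observers} is a \code{;}-separated list of
#'   observer labels (empty for unsampled cells).
#' @return data.frame of class \code{rjds_cells} with attributes
#'   \code{observers} (named list per cell), \code{J} (sampled cells) and
#'   \code{L} (total cells).
#' @export
read_cell_table <- function(path) {
  stopifnot(file.exists(path))
  cells <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(observers = "character"))
  required <- c("cell", "area", "sampled", "observers")
  miss <- setdiff(required, names(cells))
  if (length(miss)) {
    stop("cell table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(cells$cell)) stop("cell labels must be unique")
  if (any(!is.finite(cells$area) | cells$area <= 0)) {
    stop("cell areas must be strictly positive")
  }
  cells$sampled <- as.integer(cells$sampled)
  obs <- lapply(cells$observers, function(s) {
    if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ";")[[1L]]
  })
  names(obs) <- as.character(cells$cell)
  n_obs <- lengths(obs)
  if (any(cells$sampled == 1 & n_obs == 0)) {
    stop("sampled cells must have assigned observers")
  }
  if (any(n_obs > 2)) {
    stop("at most two observers per transect are supported")
  }
  attr(cells, "observers") <- obs
  attr(cells, "J") <- sum(cells$sampled == 1)
  attr(cells, "L") <- nrow(cells)
  class(cells) <- c("rjds_cells", "data.frame")
  cells
}

#' Scale cell areas to their mean
#'
#' Divides every area by the mean area, so the areas of the returned table
#' average 1 and the intensity intercept is interpretable on the
#' mean-cell scale. Idempotent up to floating-point tolerance.
#'
#' @param cells a cell table (\code{\link{read_cell_table}}).
#' @return the cell table with scaled areas.
#' @export
scale_areas <- function(cells) {
  stopifnot(all(cells$area > 0))
  cells$area <- cells$area / mean(cells$area)
  cells
}

#' Write / read posterior draws
#'
#' Delimited text, one row per retained iteration, with a \code{chain}
#' column and one labeled column per scalar (parameters, per-cell group
#' counts, predicted totals). Round-trippable via \code{read_posterior}.
#'
#' @param draws an \code{rjds_draws} object (from \code{\link{fit_hds}} or a
#'   fit's \code{$draws}).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_posterior <- function(draws, path) {
  stopifnot(inherits(draws, "rjds_draws"), nrow(draws$samples) >= 1)
  out <- data.frame(chain = draws$chain, draws$samples, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.csv(path, check.names = FALSE)
  chain <- as.integer(tab$chain)
  samples <- as.matrix(tab[, setdiff(names(tab), "chain"), drop = FALSE])
  structure(list(samples = samples, chain = chain,
                 n_chains = length(unique(chain))),
            class = "rjds_draws")
}

#' Write detection / cell tables
#'
#' Inverse of the readers: \code{write_detection_table} expands each group
#' back to one row per observer (ordered by the cell table's assignment);
#' \code{write_cell_table} serializes observer lists with \code{;}.
#'
#' @param det an \code{rjds_detections} table.
#' @param cells an \code{rjds_cells} table.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_detection_table <- function(det, cells, path) {
  obs <- attr(cells, "observers")
  covs <- setdiff(names(det), c("transect", "group", "y1", "y2"))
  rows <- lapply(seq_len(nrow(det)), function(i) {
    o <- obs[[as.character(det$transect[i])]]
    k <- length(o)
    cbind(data.frame(transect = rep(det$transect[i], k),
                     group = rep(det$group[i], k), observer = o,
                     seen = c(det$y1[i], if (k > 1L) det$y2[i]),
                     stringsAsFactors = FALSE),
          det[rep(i, k), covs, drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detection_table
#' @export
write_cell_table <- function(cells, path) {
  out <- as.data.frame(cells)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a structured configuration file
#'
#' YAML with sections \code{model}, \code{priors}, \code{sampler} and
#' (optionally) \code{simulation}; formulas are strings, covariate models
#' are maps with a \code{family} field and the corresponding
#' \code{\link{covariate_model}} arguments.
#'
#' @param path configuration file path.
#' @return list with \code{model} (\code{rjds_model}), \code{priors}
#'   (\code{rjds_priors}), \code{sampler} (\code{rjds_sampler}) and the raw
#'   \code{simulation} section, if present.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  covm <- list()
  for (nm in names(cfg$model$covariate_models)) {
    covm[[nm]] <- do.call(covariate_model, cfg$model$covariate_models[[nm]])
  }
  model <- model_spec(
    detection_formula = stats::as.formula(cfg$model$detection_formula),
    habitat_formula = stats::as.formula(cfg$model$habitat_formula),
    covariate_models = covm,
    distance_mode = cfg$model$distance_mode %||% "continuous",
    n_bins = cfg$model$n_bins,
    species_mode = cfg$model$species_mode %||% "partitioned",
    species_levels = cfg$model$species_levels)
  priors <- do.call(prior_spec, cfg$priors %||% list())
  sampler <- do.call(sampler_config, cfg$sampler %||% list())
  list(model = model, priors = priors, sampler = sampler,
       simulation = cfg$simulation)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
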