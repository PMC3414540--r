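# Bivariate-probit observation model: detection design matrices, the
# distance-dependent observer correlation, detection probabilities, latent
# Albert-Chib Gibbs updates, and derived detection-function diagnostics.

# Compile a detection formula into a fast design builder.
#
# var_info is a named list describing each variable in the formula:
#   list(type = "numeric") or list(type = "factor", levels = c(...)).
# The returned closure takes a list/data.frame of per-row values (factors as
# integer codes or labels) and returns the design matrix. Factors are
# dummy-coded against their first declared level (treatment coding);
# interaction columns are products of main-effect columns.
make_design_builder <- function(formula, var_info) {
  tt <- stats::terms(stats::as.formula(formula))
  fac <- attr(tt, "factors")
  term_labels <- attr(tt, "term.labels")
  has_int <- attr(tt, "intercept") == 1
  vars <- rownames(fac)
  unknown <- setdiff(vars, names(var_info))
  if (length(unknown)) {
    stop("detection formula term(s) not resolvable: ",
         paste(unknown, collapse = ", "))
  }
  # precompute, per term, the expansion into dummy/numeric column products
  term_plan <- lapply(term_labels, function(lab) {
    comps <- vars[fac[, lab] > 0]
    pieces <- lapply(comps, function(v) {
      vi <- var_info[[v]]
      if (identical(vi$type, "factor")) {
        lv <- vi$levels
        list(var = v, factor = TRUE, levels = lv[-1])
      } else list(var = v, factor = FALSE)
    })
    # expand.grid over factor levels; numerics contribute one column each
    fpieces <- Filter(function(p) p$factor, pieces)
    if (length(fpieces)) {
      grid <- expand.grid(lapply(fpieces, function(p) p$levels),
                          stringsAsFactors = FALSE)
      names(grid) <- vapply(fpieces, function(p) p$var, "")
    } else grid <- NULL
    list(label = lab, pieces = pieces, grid = grid)
  })
  # column names mirror model.matrix conventions
  colnames_out <- c(if (has_int) "(Intercept)",
    unlist(lapply(term_plan, function(tp) {
      if (is.null(tp$grid)) return(tp$label)
      apply(tp$grid, 1, function(row) {
        nm <- vapply(tp$pieces, function(p) {
          if (p$factor) paste0(p$var, row[[p$var]]) else p$var
        }, "")
        paste(nm, collapse = ":")
      })
    })))

  builder <- function(data) {
    n <- length(data[[1L]])
    cols <- vector("list", length(colnames_out))
    j <- 0L
    if (has_int) { j <- 1L; cols[[1L]] <- rep(1, n) }
    for (tp in term_plan) {
      if (is.null(tp$grid)) {
        v <- rep(1, n)
        for (p in tp$pieces) v <- v * as.numeric(data[[p$var]])
        j <- j + 1L; cols[[j]] <- v
      } else {
        for (g in seq_len(nrow(tp$grid))) {
          v <- rep(1, n)
          for (p in tp$pieces) {
            if (p$factor) {
              lv <- var_info[[p$var]]$levels
              x <- data[[p$var]]
              code <- if (is.character(x) || is.factor(x)) {
                match(as.character(x), lv)
              } else as.integer(x)
              v <- v * as.numeric(code == match(tp$grid[g, p$var], lv))
            } else v <- v * as.numeric(data[[p$var]])
          }
          j <- j + 1L; cols[[j]] <- v
        }
      }
    }
    out <- do.call(cbind, cols)
    colnames(out) <- colnames_out
    out
  }
  attr(builder, "colnames") <- colnames_out
  attr(builder, "vars") <- vars
  builder
}

#' Build detection design rows for groups
#'
#' One design row per observer slot per group, with categorical terms
#' dummy-coded against the first declared level and interaction columns as
#' products of main-effect columns.
#'
#' @param groups data.frame (or list) of per-group covariate values.
#' @param observers character/integer vector or 2-column matrix of observer
#'   identities; one row of design per group per observer.
#' @param formula detection model formula (e.g.
#'   \code{~ observer + distance + size + exposure + species +
#'   distance:exposure}).
#' @param var_info named list describing each formula variable:
#'   \code{list(type = "numeric")} or \code{list(type = "factor",
#'   levels = ...)}. Must include \code{observer} when it appears in the
#'   formula.
#' @return design matrix with rows blocked by observer slot (all groups for
#'   observer 1, then all groups for observer 2).
#' @export
build_detection_design <- function(groups, observers, formula, var_info) {
  builder <- make_design_builder(formula, var_info)
  groups <- as.list(groups)
  obs <- if (is.matrix(observers)) observers else
    matrix(observers, nrow = length(groups[[1L]]), ncol = length(observers),
           byrow = TRUE)
  out <- lapply(seq_len(ncol(obs)), function(k) {
    builder(c(groups, list(observer = obs[, k])))
  })
  do.call(rbind, out)
}

# Compile a detection formula into the flattened representation used by the
# compiled sweep: per design column, a static multiplier per slot and
# observer side (observer, species, and other unit-level terms) times a
# product of dynamic factors referencing modeled slot covariates. Kinds:
# -1 = numeric value, l >= 1 = indicator(value == l) for a factor level.
.compile_design <- function(formula, var_info, dynamic_vars,
                            static1, static2) {
  tt <- stats::terms(stats::as.formula(formula))
  fac <- attr(tt, "factors")
  term_labels <- attr(tt, "term.labels")
  has_int <- attr(tt, "intercept") == 1
  vars <- rownames(fac)
  n <- length(static1[[1L]])
  cols <- list()   # per column: list(static1, static2, dyn_cov, dyn_kind)
  add_col <- function(pieces) {
    s1 <- rep(1, n); s2 <- rep(1, n)
    dcov <- integer(0); dkind <- integer(0)
    for (p in pieces) {
      if (p$var %in% dynamic_vars) {
        dcov <- c(dcov, match(p$var, dynamic_vars) - 1L)
        dkind <- c(dkind, if (p$factor) p$level_idx else -1L)
      } else {
        val1 <- static1[[p$var]]; val2 <- static2[[p$var]]
        if (p$factor) {
          s1 <- s1 * as.numeric(val1 == p$level_idx)
          s2 <- s2 * as.numeric(val2 == p$level_idx)
        } else {
          s1 <- s1 * as.numeric(val1); s2 <- s2 * as.numeric(val2)
        }
      }
    }
    cols[[length(cols) + 1L]] <<- list(s1 = s1, s2 = s2, dcov = dcov,
                                       dkind = dkind)
  }
  if (has_int) add_col(list())
  for (lab in term_labels) {
    comps <- vars[fac[, lab] > 0]
    fvars <- comps[vapply(comps, function(v)
      identical(var_info[[v]]$type, "factor"), TRUE)]
    nvars <- setdiff(comps, fvars)
    if (length(fvars)) {
      grid <- expand.grid(lapply(fvars, function(v)
        seq_along(var_info[[v]]$levels)[-1L]))
      names(grid) <- fvars
      for (g in seq_len(nrow(grid))) {
        pieces <- c(
          lapply(fvars, function(v) list(var = v, factor = TRUE,
                                         level_idx = grid[g, v])),
          lapply(nvars, function(v) list(var = v, factor = FALSE)))
        add_col(pieces)
      }
    } else {
      add_col(lapply(nvars, function(v) list(var = v, factor = FALSE)))
    }
  }
  S1 <- do.call(cbind, lapply(cols, `[[`, "s1"))
  S2 <- do.call(cbind, lapply(cols, `[[`, "s2"))
  dyn_cov <- lapply(cols, `[[`, "dcov")
  dyn_kind <- lapply(cols, `[[`, "dkind")
  affected <- lapply(seq_along(dynamic_vars), function(ci) {
    which(vapply(dyn_cov, function(d) (ci - 1L) %in% d, TRUE)) - 1L
  })
  list(S1 = S1, S2 = S2, dyn_cov = dyn_cov, dyn_kind = dyn_kind,
       affected = affected,
       in_design = dynamic_vars %in% vars)
}

#' Observer correlation as a function of distance
#'
#' Under point independence the latent-scale correlation between the two
#' observers is zero on the transect line (continuous distance 0, or the
#' first distance bin) and grows linearly to \code{rho} at the farthest
#' observable distance: \eqn{\rho d} for continuous \eqn{d \in [0,1]} and
#' \eqn{\rho (b-1)/(B-1)} for bins \eqn{b = 1, \ldots, B}.
#'
#' @param rho dependence parameter (correlation at the maximum distance).
#' @param distance distance value(s): continuous in \eqn{[0,1]} or integer
#'   bin index.
#' @param mode \code{"continuous"} or \code{"binned"}.
#' @param n_bins number of distance bins (binned mode).
#' @return correlation(s) in \eqn{(-1, 1)}.
#' @export
correlation_at <- function(rho, distance, mode = c("continuous", "binned"),
                           n_bins = NULL) {
  mode <- match.arg(mode)
  r <- if (mode == "continuous") {
    stopifnot(all(distance >= 0 & distance <= 1))
    rho * distance
  } else {
    stopifnot(!is.null(n_bins), n_bins >= 1,
              all(distance >= 1 & distance <= n_bins))
    if (n_bins == 1L) rep(0, length(distance))
    else rho * (distance - 1) / (n_bins - 1)
  }
  if (any(abs(r) >= 1)) stop("implied correlation outside (-1, 1)")
  r
}

#' Probability of detection by at least one observer
#'
#' With one observer this is the inverse probit link \eqn{\Phi(\mu)}; with
#' two observers it is one minus the bivariate-normal orthant mass with both
#' latent variables below their negated linear predictors, computed with a
#' deterministic routine accurate to well below 1e-10.
#'
#' @param mu linear predictor(s): a vector of length 1 or 2 for a single
#'   group, or an n x 2 matrix for n groups.
#' @param corr latent correlation(s); recycled.
#' @return detection probabilities.
#' @export
prob_detect_any <- function(mu, corr = 0) {
  if (is.matrix(mu)) {
    stopifnot(ncol(mu) %in% 1:2)
    if (ncol(mu) == 1L) return(stats::pnorm(mu[, 1L]))
    stopifnot(all(abs(corr) < 1))
    return(1 - pbvnorm(-mu[, 1L], -mu[, 2L], corr))
  }
  stopifnot(length(mu) %in% 1:2)
  if (length(mu) == 1L) return(stats::pnorm(mu))
  stopifnot(all(abs(corr) < 1))
  1 - pbvnorm(-mu[1L], -mu[2L], corr)
}

#' Gibbs update of latent probit variables
#'
#' Albert-Chib data augmentation: each latent \eqn{y^*_k} is drawn from its
#' full conditional, a univariate normal with mean \eqn{\mu_k + r (y^*_{-k} -
#' \mu_{-k})} and variance \eqn{1 - r^2}, truncated to \eqn{(0, \infty)} if
#' the corresponding detection is 1 and \eqn{(-\infty, 0]} otherwise.
#' Components are updated in sequence (observer 1 given 2, then 2 given 1).
#'
#' @param y detections: n x 2 0/1 matrix (or n x 1 for single observer).
#' @param mu linear predictors, same shape as \code{y}.
#' @param corr latent correlation(s), recycled over rows.
#' @param ystar current latent values (same shape); if \code{NULL},
#'   initialized from independent truncated normals.
#' @return matrix of latent values, sign-consistent with \code{y}.
#' @export
gibbs_update_latent <- function(y, mu, corr = 0, ystar = NULL) {
  y <- as.matrix(y); mu <- as.matrix(mu)
  n <- nrow(y)
  lo <- ifelse(y == 1, 0, -Inf)
  hi <- ifelse(y == 1, Inf, 0)
  if (ncol(y) == 1L) {
    return(matrix(rtnorm(n, mu[, 1L], 1, lo[, 1L], hi[, 1L]), ncol = 1L))
  }
  corr <- rep_len(corr, n)
  s <- sqrt(1 - corr^2)
  if (is.null(ystar)) {
    ystar <- cbind(rtnorm(n, mu[, 1L], 1, lo[, 1L], hi[, 1L]),
                   rtnorm(n, mu[, 2L], 1, lo[, 2L], hi[, 2L]))
  }
  m1 <- mu[, 1L] + corr * (ystar[, 2L] - mu[, 2L])
  ystar[, 1L] <- rtnorm(n, m1, s, lo[, 1L], hi[, 1L])
  m2 <- mu[, 2L] + corr * (ystar[, 1L] - mu[, 1L])
  ystar[, 2L] <- rtnorm(n, m2, s, lo[, 2L], hi[, 2L])
  ystar
}

# Full conditional (normal) for beta_det given latent pairs. Whitens each
# two-observer pair with its 2x2 correlation (single-observer rows enter with
# unit variance) and combines with the N(prior_mean, prior_sd^2 I) prior.
# Returns mean and upper-Cholesky of the precision.
beta_det_fullcond <- function(ystar, X1, X2, corr, prior_sd = 10,
                              prior_mean = 0, two_obs = NULL) {
  p <- ncol(X1)
  n <- nrow(X1)
  if (is.null(two_obs)) two_obs <- rep(!is.null(X2), n)
  corr <- rep_len(corr, n)
  if (any(two_obs)) {
    i <- which(two_obs)
    s <- sqrt(1 - corr[i]^2)
    Xw <- rbind(X1[i, , drop = FALSE],
                (X2[i, , drop = FALSE] - corr[i] * X1[i, , drop = FALSE]) / s,
                X1[!two_obs, , drop = FALSE])
    yw <- c(ystar[i, 1L], (ystar[i, 2L] - corr[i] * ystar[i, 1L]) / s,
            ystar[!two_obs, 1L])
  } else {
    Xw <- X1; yw <- ystar[, 1L]
  }
  if (any(colSums(abs(Xw)) == 0)) {
    stop("detection design has an all-zero column")
  }
  prec <- crossprod(Xw) + diag(1 / prior_sd^2, p)
  b <- crossprod(Xw, yw) + prior_mean / prior_sd^2
  R <- tryCatch(chol(prec), error = function(e)
    stop("singular detection precision (collinear design)"))
  m <- backsolve(R, backsolve(R, b, transpose = TRUE))
  list(mean = drop(m), chol_prec = R)
}

#' Gibbs update of detection coefficients
#'
#' Draws \eqn{\beta^{det}} from its exact multivariate-normal full
#' conditional, combining the normal prior with the generalized-least-squares
#' likelihood of the latent pairs (per-group covariance
#' \eqn{[[1, r], [r, 1]]}).
#'
#' @param ystar latent matrix (n x 2, or n x 1 single observer).
#' @param X1,X2 design rows for observer slots 1 and 2 (\code{X2 = NULL} for
#'   single observer).
#' @param corr latent correlation per group.
#' @param prior_sd,prior_mean normal prior on each coefficient.
#' @param two_obs optional logical mask: rows with \code{FALSE} contribute a
#'   single observer-1 row (their \code{X2}/second latent are ignored).
#' @return sampled coefficient vector.
#' @export
gibbs_update_beta_det <- function(ystar, X1, X2 = NULL, corr = 0,
                                  prior_sd = 10, prior_mean = 0,
                                  two_obs = NULL) {
  fc <- beta_det_fullcond(as.matrix(ystar), X1, X2, corr, prior_sd,
                          prior_mean, two_obs)
  z <- stats::rnorm(length(fc$mean))
  drop(fc$mean + backsolve(fc$chol_prec, z))
}

# log-likelihood of latent pairs under correlations r (vectorized)
.bvn_pair_loglik <- function(z1, z2, r) {
  q <- z1^2 - 2 * r * z1 * z2 + z2^2
  sum(-0.5 * log(1 - r^2) - q / (2 * (1 - r^2))) - length(z1) * log(2 * pi)
}

#' Metropolis-Hastings update of the observer dependence parameter
#'
#' Targets the full conditional of \eqn{\rho} given all latent pairs, with a
#' symmetric uniform random-walk proposal. Proposals implying any correlation
#' outside \eqn{(-1, 1)}, or outside the prior interval, are rejected.
#'
#' @param rho current value.
#' @param ystar latent n x 2 matrix (active groups).
#' @param mu linear predictors, n x 2.
#' @param corr_scale per-group multiplier mapping \code{rho} to correlation
#'   (distance for continuous data, \eqn{(b-1)/(B-1)} for bins).
#' @param prior support of the uniform prior on \code{rho}.
#' @param width half-width of the uniform proposal.
#' @return list with \code{rho} and logical \code{accepted}.
#' @export
mh_update_rho <- function(rho, ystar, mu, corr_scale,
                          prior = c(-0.99, 0.99), width = 0.1) {
  cand <- rho + stats::runif(1, -width, width)
  if (cand < prior[1L] || cand > prior[2L] ||
      any(abs(cand * corr_scale) >= 1)) {
    return(list(rho = rho, accepted = FALSE))
  }
  z1 <- ystar[, 1L] - mu[, 1L]; z2 <- ystar[, 2L] - mu[, 2L]
  lr <- .bvn_pair_loglik(z1, z2, cand * corr_scale) -
    .bvn_pair_loglik(z1, z2, rho * corr_scale)
  if (is.finite(lr) && log(stats::runif(1)) < lr) {
    list(rho = cand, accepted = TRUE)
  } else list(rho = rho, accepted = FALSE)
}

#' Detection-function diagnostics over a distance grid
#'
#' For a fixed covariate profile and two observers, computes the individual
#' detection functions \eqn{p_1(y), p_2(y)}, the duplicate function
#' \eqn{p_{dup}(y)} (both observers), the pooled function (at least one
#' observer), the conditional function \eqn{p_{dup}/p_1} (observer 2 given
#' observer 1), and the dependence ratio \eqn{\delta(y) =
#' p_{dup}/(p_1 p_2)}, which equals 1 under full independence.
#'
#' @param beta detection coefficients, aligned with the design columns.
#' @param rho dependence parameter.
#' @param formula,var_info detection model description (see
#'   \code{\link{build_detection_design}}).
#' @param observers length-2 vector of observer identities.
#' @param fixed_covariates named list of covariate values held fixed.
#' @param distance grid of distances.
#' @param mode,n_bins distance convention (see \code{\link{correlation_at}}).
#' @return data.frame with columns \code{distance, p1, p2, cond, dup,
#'   pooled, delta}; \code{cond}/\code{delta} are \code{NA} where an
#'   individual probability underflows.
#' @export
detection_curves <- function(beta, rho, formula, var_info, observers,
                             fixed_covariates = list(),
                             distance = seq(0, 1, length.out = 51),
                             mode = "continuous", n_bins = NULL) {
  stopifnot(length(observers) == 2L)
  builder <- make_design_builder(formula, var_info)
  n <- length(distance)
  base <- lapply(fixed_covariates, rep_len, n)
  base$distance <- distance
  X1 <- builder(c(base, list(observer = rep(observers[1L], n))))
  X2 <- builder(c(base, list(observer = rep(observers[2L], n))))
  stopifnot(length(beta) == ncol(X1))
  mu1 <- drop(X1 %*% beta); mu2 <- drop(X2 %*% beta)
  r <- correlation_at(rho, distance, mode, n_bins)
  p1 <- stats::pnorm(mu1); p2 <- stats::pnorm(mu2)
  dup <- pbvnorm(mu1, mu2, r)          # P(y1* > 0, y2* > 0) by symmetry
  pooled <- 1 - pbvnorm(-mu1, -mu2, r)
  tol <- 1e-300
  cond <- ifelse(p1 > tol, dup / p1, NA_real_)
  delta <- ifelse(p1 > tol & p2 > tol, dup / (p1 * p2), NA_real_)
  data.frame(distance = distance, p1 = p1, p2 = p2, cond = cond,
             dup = dup, pooled = pooled, delta = delta)
}
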