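# Reversible-jump sampler over per-transect group counts and latent
# covariates, and the orchestrating MCMC loop (adaptation, burn-in, thinning,
# multiple chains).
#
# State layout: each sampled unit (cell, or cell x species in partitioned
# mode) owns a fixed array of G_max slots. Slots 1..c hold observed groups
# (immutable detections and covariates), c+1..G are active latent groups
# (all-zero detections, sampled covariates and latent probit variables), and
# G+1..G_max are inactive pseudo-groups whose covariates are refreshed from
# the current covariate model each sweep. Multi-step jumps activate or
# deactivate the lowest/highest-indexed slots (stack discipline), which is
# valid because slot labels are non-identifiable.

#' Propose a new group count
#'
#' Uniform proposal on the integers \eqn{\{G-\psi, ..., G+\psi\} \setminus
#' \{G\}}. Values below the observed count or above the slot bound are
#' invalid and should be rejected outright by the caller (they count as
#' rejections).
#'
#' @param G current total group count.
#' @param psi jump window half-width (integer >= 1).
#' @param c observed group count (informational; bounds are enforced by the
#'   acceptance step).
#' @param g_max slot bound.
#' @return proposed integer count (possibly outside \code{[c, g_max]}).
#' @export
propose_group_count <- function(G, psi, c = 0, g_max = Inf) {
  d <- sample.int(2L * psi, 1L)
  G + if (d <= psi) d - psi - 1L else d - psi
}

# log Metropolis ratio for G -> Gp.
# sum_log1mp: sum of log(1 - p*) over slots min(G,Gp)+1 .. max(G,Gp).
.log_accept_ratio <- function(G, Gp, log_lamA, sum_log1mp, c = 0) {
  dG <- Gp - G
  dG * log_lamA + sign(dG) * sum_log1mp -
    (lgamma(Gp - c + 1) - lgamma(G - c + 1))
}

#' Reversible-jump acceptance ratio for a group-count move
#'
#' The complete-data target is \eqn{\pi(G, z) \propto Poisson(G \mid \lambda
#' A) \, \binom{G}{c} \prod_{latent} (1 - p^*(z_i))} times factors that do
#' not involve \eqn{G}; with pseudo-group covariates proposed from their
#' population model \eqn{g(\cdot \mid \theta)}, the \eqn{g} terms cancel and
#' the one-step addition ratio reduces to \eqn{\lambda A (1 - p^*_{new}) /
#' (G + 1 - c)}; deletions are the reciprocal, and multi-step jumps multiply
#' the one-step factors.
#'
#' @param G,G_new current and proposed counts.
#' @param lambda_area Poisson mean \eqn{\lambda_j A_j} for the unit.
#' @param pstar detection-by-anyone probabilities of the slots activated (if
#'   \code{G_new > G}) or deactivated (if \code{G_new < G}).
#' @param c observed group count.
#' @return the Metropolis ratio \eqn{r}.
#' @export
accept_ratio <- function(G, G_new, lambda_area, pstar, c = 0) {
  stopifnot(G_new >= c, G >= c, length(pstar) == abs(G_new - G))
  if (any(pstar >= 1)) {
    # a slot certain to be detected can never be an undetected group
    if (G_new > G) return(0)
  }
  exp(.log_accept_ratio(G, G_new, log(lambda_area), sum(log1p(-pstar)), c))
}

#' Sample latent probit pairs for newly added groups
#'
#' Draws \eqn{(y^*_1, y^*_2)} from the bivariate normal with means \code{mu}
#' and correlation \code{corr}, conditioned on both components being
#' \eqn{\le 0} (an added group was detected by nobody). Exact rejection
#' sampling with a Gibbs fallback for near-certain-detection cases.
#'
#' @param mu m x 2 matrix of linear predictors.
#' @param corr correlation(s), recycled over rows.
#' @return m x 2 matrix with all entries \eqn{\le 0}.
#' @export
sample_latents_for_additions <- function(mu, corr = 0) {
  mu <- as.matrix(mu)
  m <- nrow(mu)
  if (m == 0L) return(mu)
  corr <- rep_len(corr, m)
  s <- sqrt(1 - corr^2)
  out <- matrix(NA_real_, m, 2L)
  todo <- seq_len(m)
  for (tries in 1:50) {
    z1 <- stats::rnorm(length(todo))
    z2 <- corr[todo] * z1 + s[todo] * stats::rnorm(length(todo))
    y1 <- mu[todo, 1L] + z1
    y2 <- mu[todo, 2L] + z2
    ok <- y1 <= 0 & y2 <= 0
    out[todo[ok], ] <- cbind(y1[ok], y2[ok])
    todo <- todo[!ok]
    if (!length(todo)) break
  }
  if (length(todo)) {
    # rare high-p* slots: truncated-normal Gibbs scans
    ys <- cbind(rtnorm(length(todo), mu[todo, 1L], 1, upper = 0),
                rtnorm(length(todo), mu[todo, 2L], 1, upper = 0))
    zero <- matrix(0L, length(todo), 2L)
    for (sweep in 1:10) {
      ys <- gibbs_update_latent(zero, mu[todo, , drop = FALSE], corr[todo], ys)
    }
    out[todo, ] <- ys
  }
  out
}

# -------------------------------------------------------------------------
# preprocessing

# Build static fit structures shared by all chains.
.prep_fit <- function(det, cells, model, priors, sampler) {
  stopifnot(inherits(model, "rjds_model"), inherits(priors, "rjds_priors"),
            inherits(sampler, "rjds_sampler"))
  cells <- scale_areas(cells)
  obs_by_cell <- attr(cells, "observers")
  if (is.null(obs_by_cell)) stop("cells must come from read_cell_table()")
  cell_lab <- as.character(cells$cell)

  partitioned <- model$species_mode == "partitioned" &&
    ("species" %in% names(det) || !is.null(model$species_levels))
  sp_levels <- if (partitioned) {
    model$species_levels %||% sort(unique(as.character(det$species)))
  } else "all"
  n_sp <- length(sp_levels)

  # units: cells x species (partitioned) or cells
  n_units <- nrow(cells) * n_sp
  U <- list(
    cell = rep(cell_lab, each = n_sp),
    species = rep(sp_levels, times = nrow(cells)),
    species_idx = rep(seq_len(n_sp), times = nrow(cells)),
    area = rep(cells$area, each = n_sp),
    sampled = rep(cells$sampled == 1, each = n_sp))
  U$label <- if (partitioned) paste(U$cell, U$species, sep = ".") else U$cell
  pool <- sort(unique(unlist(obs_by_cell)))
  obs_codes <- lapply(obs_by_cell, function(o) match(o, pool))
  U$obs1 <- vapply(U$cell, function(cl) {
    o <- obs_codes[[cl]]; if (length(o)) o[1L] else NA_integer_ }, 0L)
  U$obs2 <- vapply(U$cell, function(cl) {
    o <- obs_codes[[cl]]; if (length(o) > 1L) o[2L] else NA_integer_ }, 0L)
  U$n_obs <- ifelse(is.na(U$obs1), 0L, ifelse(is.na(U$obs2), 1L, 2L))

  # observed groups -> units
  ucell <- match(as.character(det$transect), cell_lab)
  if (anyNA(ucell)) stop("detection transect labels not found in cell table")
  usp <- if (partitioned) match(as.character(det$species), sp_levels) else
    rep(1L, nrow(det))
  if (anyNA(usp)) stop("species label outside declared levels")
  unit_of_group <- (ucell - 1L) * n_sp + usp
  U$c <- tabulate(unit_of_group, nbins = n_units)
  if (any(U$c > 0 & !U$sampled)) stop("detections reported on unsampled cells")
  U$G_max <- ifelse(U$sampled,
                    pmax(sampler$g_max_min,
                         sampler$g_max_mult * U$c + sampler$g_max_add), 0L)
  U$offset <- c(0L, cumsum(U$G_max))[seq_len(n_units)]
  n_slots <- sum(U$G_max)

  # slot-level static structure
  unit_of_slot <- rep.int(seq_len(n_units), U$G_max)
  obs1_slot <- U$obs1[unit_of_slot]
  obs2_slot <- U$obs2[unit_of_slot]
  two_obs <- !is.na(obs2_slot)

  # modeled slot covariates (species is unit-level in partitioned mode)
  covmods <- model$covariate_models
  if (partitioned) covmods$species <- NULL
  modeled <- names(covmods)

  # per-species clones of each non-fixed covariate model, with moment inits
  covmodels0 <- lapply(modeled, function(cv) {
    base <- covmods[[cv]]
    lapply(seq_len(n_sp), function(sidx) {
      m <- base
      if (!m$fixed && cv %in% names(det)) {
        vals <- det[[cv]][usp == sidx | n_sp == 1L]
        if (m$family == "categorical") {
          cnt <- tabulate(.cat_code(vals, m), nbins = length(m$levels))
          m$probs <- (cnt + 1) / sum(cnt + 1)
        } else if (length(vals)) {
          m$theta <- log(max(mean(vals), 0.5))
        }
      }
      m
    })
  })
  names(covmodels0) <- modeled

  # slot covariate seeds: observed groups fill slots offset + 1..c
  slot_of_group <- integer(nrow(det))
  cnt <- integer(n_units)
  for (i in seq_len(nrow(det))) {
    u <- unit_of_group[i]
    cnt[u] <- cnt[u] + 1L
    slot_of_group[i] <- U$offset[u] + cnt[u]
  }
  Z0 <- lapply(modeled, function(cv) {
    z <- rep(NA_real_, n_slots)
    if (cv %in% names(det)) {
      v <- det[[cv]]
      if (covmods[[cv]]$family == "categorical") {
        v <- .cat_code(v, covmods[[cv]])
        if (anyNA(v)) stop("covariate '", cv, "' outside declared levels")
      }
      z[slot_of_group] <- as.numeric(v)
    } else if (U_total_c <- sum(U$c)) {
      stop("modeled covariate '", cv, "' missing from the detection table")
    }
    z
  })
  names(Z0) <- modeled
  y1 <- integer(n_slots); y2 <- integer(n_slots)
  y1[slot_of_group] <- det$y1
  y2[slot_of_group] <- ifelse(is.na(det$y2), 0L, det$y2)

  # detection design builder
  det_vars <- all.vars(model$detection_formula)
  var_info <- list(observer = list(type = "factor", levels = pool))
  for (cv in modeled) {
    var_info[[cv]] <- if (covmods[[cv]]$family == "categorical") {
      list(type = "factor", levels = covmods[[cv]]$levels)
    } else list(type = "numeric")
  }
  unit_level_det <- list()
  if (partitioned && "species" %in% det_vars) {
    var_info$species <- list(type = "factor", levels = sp_levels)
    unit_level_det$species <- U$species_idx[unit_of_slot]
  }
  for (v in setdiff(det_vars, c(names(var_info)))) {
    if (!v %in% names(cells)) {
      stop("detection formula term not resolvable: ", v)
    }
    col <- cells[[v]][match(U$cell, cell_lab)]
    if (is.numeric(col)) {
      var_info[[v]] <- list(type = "numeric")
      unit_level_det[[v]] <- col[unit_of_slot]
    } else {
      lv <- sort(unique(as.character(col)))
      var_info[[v]] <- list(type = "factor", levels = lv)
      unit_level_det[[v]] <- match(as.character(col), lv)[unit_of_slot]
    }
  }
  builder <- make_design_builder(model$detection_formula, var_info)

  # flattened design for the compiled sweep
  static1 <- c(list(observer = obs1_slot), unit_level_det)
  static2 <- c(list(observer = obs2_slot), unit_level_det)
  cd <- .compile_design(model$detection_formula, var_info, modeled,
                        static1, static2)
  stopifnot(ncol(cd$S1) == length(attr(builder, "colnames")))
  cd$dyn_cov <- lapply(cd$dyn_cov, as.integer)
  cd$dyn_kind <- lapply(cd$dyn_kind, as.integer)
  cd$affected <- lapply(cd$affected, as.integer)
  cd$S2[is.na(cd$S2)] <- 0   # single-observer slots never use side 2

  # habitat design over units
  hab_df <- as.data.frame(cells[match(U$cell, cell_lab),
                                setdiff(names(cells),
                                        c("area", "sampled", "observers")),
                                drop = FALSE])
  hab_df$species <- factor(U$species, levels = sp_levels)
  Xhab <- stats::model.matrix(model$habitat_formula, hab_df)
  if (qr(Xhab)$rank < ncol(Xhab)) stop("habitat design is rank deficient")

  list(U = U, n_units = n_units, n_slots = n_slots,
       unit_of_slot = unit_of_slot, obs1_slot = obs1_slot,
       obs2_slot = obs2_slot, two_obs = two_obs,
       slot_of_group = slot_of_group, y1 = y1, y2 = y2, Z0 = Z0,
       modeled = modeled, covmodels0 = covmodels0,
       builder = builder, det_vars = det_vars, var_info = var_info,
       unit_level_det = unit_level_det, cd = cd,
       distance_cov = match("distance", modeled) - 1L,
       bin_denom = if (model$distance_mode == "continuous") 0 else
         if (model$n_bins > 1L) model$n_bins - 1 else Inf,
       Xhab = Xhab, partitioned = partitioned, sp_levels = sp_levels,
       n_sp = n_sp, has_size = "size" %in% modeled)
}

# -------------------------------------------------------------------------
# single chain

.run_chain <- function(prep, model, priors, sampler, init, chain_id, track) {
  set.seed(sampler$seed + chain_id - 1L)
  U <- prep$U
  n_units <- prep$n_units; n_slots <- prep$n_slots
  us <- prep$unit_of_slot
  two <- prep$two_obs
  upd <- sampler$update
  sampled_units <- which(U$sampled)
  unsampled_units <- which(!U$sampled)
  any_two <- any(two)

  # ---- parameter state
  p_det <- length(attr(prep$builder, "colnames"))
  beta_det <- init$beta_det %||% c(0.5, numeric(p_det - 1L))
  stopifnot(length(beta_det) == p_det)
  rho <- init$rho %||% 0
  covm <- prep$covmodels0
  G <- as.integer(ifelse(U$sampled,
                         pmin(pmax(rep_len(init$G %||% U$c, n_units), U$c),
                              U$G_max),
                         0L))
  v <- init$v %||% ifelse(U$sampled, log(pmax(U$c, 0.5) / U$area), 0)
  q_hab <- ncol(prep$Xhab)
  beta_hab <- init$beta_hab %||% {
    if (length(sampled_units) >= q_hab) {
      drop(beta_hab_fullcond(v[sampled_units],
                             prep$Xhab[sampled_units, , drop = FALSE],
                             1, priors$beta_sd)$mean)
    } else numeric(q_hab)
  }
  tau_v <- init$tau_v %||% 1
  if (!upd$process && is.null(init$v)) {
    v[] <- drop(prep$Xhab %*% beta_hab)
  }

  # ---- slot state (deep copies: the compiled sweep mutates in place)
  Z <- lapply(prep$Z0, `+`, 0)
  G <- G + 0L
  eps <- lapply(prep$modeled, function(cv) numeric(n_slots))
  names(eps) <- prep$modeled
  sp_of_slot <- U$species_idx[us]
  for (cv in prep$modeled) {
    fill <- which(is.na(Z[[cv]]))
    if (length(fill)) {
      for (sidx in seq_len(prep$n_sp)) {
        ii <- fill[sp_of_slot[fill] == sidx]
        if (!length(ii)) next
        d <- covariate_sample(length(ii), covm[[cv]][[sidx]])
        Z[[cv]][ii] <- d$value
        eps[[cv]][ii] <- d$eps
      }
    }
  }
  ys1 <- numeric(n_slots); ys2 <- numeric(n_slots)
  mu1 <- numeric(n_slots); mu2 <- numeric(n_slots)
  corr <- numeric(n_slots); pstar <- numeric(n_slots)

  # ---- proposal widths
  psi <- rep(as.integer(sampler$psi), n_units)
  w_rho <- 0.1
  w_v <- 0.5
  w_theta <- lapply(prep$modeled, function(cv) 0.2)
  names(w_theta) <- prep$modeled
  w_eps <- 0.5
  tgt <- sampler$target_accept

  # ---- recording layout
  cn_det <- paste0("det.", attr(prep$builder, "colnames"))
  cn_hab <- paste0("hab.", colnames(prep$Xhab))
  cov_par_names <- character(0)
  for (cv in prep$modeled) for (sidx in seq_len(prep$n_sp)) {
    m <- covm[[cv]][[sidx]]
    if (m$fixed || m$family == "uniform") next
    sfx <- if (prep$n_sp > 1L) paste0(".", prep$sp_levels[sidx]) else ""
    cov_par_names <- c(cov_par_names, switch(m$family,
      categorical = paste0("cov.", cv, sfx, ".p", seq_along(m$levels)),
      {
        nm <- paste0("cov.", cv, sfx, ".theta")
        if (.is_od(m)) nm <- c(nm, paste0("cov.", cv, sfx, ".sigma"))
        nm
      }))
  }
  track <- track %||% character(0)
  track_info <- NULL
  if (length(track)) {
    getters <- list(); lvls <- list()
    for (tv in track) {
      if (prep$partitioned && tv == "species") {
        getters[[tv]] <- "unit_species"; lvls[[tv]] <- prep$sp_levels
      } else if (tv %in% prep$modeled &&
                 covm[[tv]][[1L]]$family == "categorical") {
        getters[[tv]] <- "slot"; lvls[[tv]] <- covm[[tv]][[1L]]$levels
      } else stop("track covariate must be categorical: ", tv)
    }
    grid <- expand.grid(lvls, stringsAsFactors = FALSE)
    labs <- apply(grid, 1, paste, collapse = ".")
    track_info <- list(getters = getters, lvls = lvls,
                       names = paste0("Gclass.", labs),
                       k = vapply(lvls, length, 0L))
  }
  col_names <- c(cn_det, if (any_two) "rho", cov_par_names, cn_hab, "tau_v",
                 paste0("G.", U$label), paste0("N.", U$label),
                 if (prep$n_sp > 1L) paste0("G.total.", prep$sp_levels),
                 if (prep$n_sp > 1L) paste0("N.total.", prep$sp_levels),
                 "G.total", "N.total",
                 if (!is.null(track_info)) track_info$names)
  keep_at <- .retained_iters(sampler$n_iter, sampler$burn_in, sampler$thin)
  keep_flag <- logical(sampler$n_iter)
  keep_flag[keep_at] <- TRUE
  samples <- matrix(NA_real_, length(keep_at), length(col_names),
                    dimnames = list(NULL, col_names))

  # ---- acceptance bookkeeping
  acc <- c(G = 0, G_n = 0, rho = 0, rho_n = 0, v = 0, v_n = 0,
           latent = 0, latent_n = 0)
  acc_theta <- lapply(prep$modeled, function(cv) c(0, 0))
  names(acc_theta) <- prep$modeled
  saturated <- 0L
  pilot <- if (sampler$adapt) sampler$pilot_iters else 0L
  adapt_every <- 100L
  a_cnt <- c(G = 0, G_n = 0, rho = 0, rho_n = 0, v = 0, v_n = 0)
  a_theta <- lapply(acc_theta, function(x) c(0, 0))

  size_model_of <- function(sidx) {
    if (prep$has_size) covm[["size"]][[sidx]] else NULL
  }
  keep_row <- 0L
  total_iters <- pilot + sampler$n_iter

  # flattened covariate-model parameters for the compiled sweep
  fam_code <- c(uniform = 0L, categorical = 1L, poisson = 2L,
                poisson_zt = 3L, poisson_od = 4L, poisson_zt_od = 5L)
  covpar_of <- function() {
    lapply(prep$modeled, function(cv) {
      ms <- covm[[cv]]
      par <- switch(ms[[1L]]$family,
        uniform = t(vapply(ms, function(m) c(m$min, m$max), numeric(2))),
        categorical = t(vapply(ms, function(m) m$probs,
                               numeric(length(ms[[1L]]$levels)))),
        t(vapply(ms, function(m) c(m$theta, if (.is_od(m)) m$sigma else 0),
                 numeric(2))))
      list(fam_code[[ms[[1L]]$family]], par)
    })
  }
  sp0 <- sp_of_slot - 1L
  X1 <- matrix(0, n_slots, p_det)
  X2 <- matrix(0, n_slots, p_det)

  for (t in seq_len(total_iters)) {
    in_pilot <- t <= pilot

    # (0)-(4) compiled sweep: pseudo-group refresh from the current
    # covariate models, detection linear predictors and p* over the
    # reachable slots, reversible-jump count moves (with exact latent pairs
    # for additions), latent-covariate resampling targeting
    # (1 - p*(z)) g(z | theta), and the truncated-normal probit Gibbs
    # update. State vectors are updated in place.
    sw <- .cpp_sweep(two, U$offset, U$c, U$G_max, U$sampled, sp0,
                     prep$cd$S1, prep$cd$S2, prep$cd$dyn_cov,
                     prep$cd$dyn_kind, prep$cd$affected, prep$cd$in_design,
                     prep$distance_cov, prep$bin_denom,
                     Z, eps, prep$y1, prep$y2, ys1, ys2, mu1, mu2,
                     pstar, corr, X1, X2, G, beta_det, rho, covpar_of(),
                     psi, log(U$area) + v,
                     upd$G, upd$latent_covariates, any_two)
    a_cnt["G"] <- a_cnt["G"] + sw$acc_G
    a_cnt["G_n"] <- a_cnt["G_n"] + sw$n_G
    acc["latent"] <- acc["latent"] + sw$acc_lat
    acc["latent_n"] <- acc["latent_n"] + sw$n_lat
    saturated <- saturated + sw$saturated

    active <- sequence(G, from = U$offset + 1L)
    a2 <- active[two[active]]
    a1 <- active[!two[active]]

    # (5) detection coefficients: exact GLS full conditional (whitened
    # cross-products accumulated by the sweep; same math as
    # gibbs_update_beta_det)
    if (upd$beta_det && length(active)) {
      prec <- sw$xtx + diag(1 / priors$beta_sd^2, p_det)
      R <- tryCatch(chol(prec), error = function(e)
        stop("singular detection precision (collinear design)"))
      m <- backsolve(R, backsolve(R, sw$xty, transpose = TRUE))
      beta_det <- drop(m + backsolve(R, stats::rnorm(p_det)))
    }

    # (6) observer dependence, at the post-update coefficients
    if (upd$rho && length(a2)) {
      m1 <- drop(X1[a2, , drop = FALSE] %*% beta_det)
      m2 <- drop(X2[a2, , drop = FALSE] %*% beta_det)
      cs2 <- if (prep$bin_denom > 0) {
        (Z$distance[a2] - 1) / prep$bin_denom
      } else if (is.infinite(prep$bin_denom)) {
        numeric(length(a2))
      } else Z$distance[a2]
      st <- mh_update_rho(rho, cbind(ys1[a2], ys2[a2]), cbind(m1, m2), cs2,
                          prior = priors$rho_bounds, width = w_rho)
      rho <- st$rho
      a_cnt["rho"] <- a_cnt["rho"] + st$accepted
      a_cnt["rho_n"] <- a_cnt["rho_n"] + 1
    }

    # (7) covariate-model hyperparameters over groups in the population
    if (upd$theta) {
      sp_a <- sp_of_slot[active]
      for (cv in prep$modeled) {
        if (covm[[cv]][[1L]]$fixed) next
        for (sidx in seq_len(prep$n_sp)) {
          ii <- active[sp_a == sidx]
          m <- covm[[cv]][[sidx]]
          if (.is_od(m) && length(ii)) {
            st <- update_covariate_eps(m, Z[[cv]][ii], eps[[cv]][ii],
                                       width = w_eps)
            eps[[cv]][ii] <- st$eps
          }
          st <- update_covariate_theta(m, Z[[cv]][ii],
                                       eps = eps[[cv]][ii],
                                       width = w_theta[[cv]])
          covm[[cv]][[sidx]] <- st$model
          if (length(st$accept)) {
            a_theta[[cv]] <- a_theta[[cv]] + c(st$accept[[1L]], 1)
          }
        }
      }
    }

    # (8) process model: v, beta_hab, tau_v
    if (upd$process) {
      eta <- drop(prep$Xhab %*% beta_hab)
      st <- update_v(v, G, eta, tau_v, U$area, U$sampled, width = w_v)
      v <- st$v
      if (is.finite(st$accept)) {
        a_cnt["v"] <- a_cnt["v"] + st$accept
        a_cnt["v_n"] <- a_cnt["v_n"] + 1
      }
      beta_hab <- gibbs_update_beta_hab(
        v[sampled_units], prep$Xhab[sampled_units, , drop = FALSE], tau_v,
        prior_sd = priors$beta_sd)
      tau_v <- gibbs_update_tau_v(
        v[sampled_units], prep$Xhab[sampled_units, , drop = FALSE], beta_hab,
        a = priors$tau_a, b = priors$tau_b)
    } else if (length(unsampled_units)) {
      eta <- drop(prep$Xhab %*% beta_hab)
      v[unsampled_units] <- stats::rnorm(length(unsampled_units),
                                         eta[unsampled_units],
                                         1 / sqrt(tau_v))
    }

    # ---- pilot adaptation (frozen afterwards)
    if (in_pilot && t %% adapt_every == 0L) {
      rt <- function(a, n) if (n > 0) a / n else NA
      r <- rt(a_cnt["G"], a_cnt["G_n"])
      if (!is.na(r)) {
        if (r > tgt[2L]) psi <- psi + 1L
        else if (r < tgt[1L]) psi <- pmax(1L, psi - 1L)
      }
      r <- rt(a_cnt["rho"], a_cnt["rho_n"])
      if (!is.na(r)) {
        if (r > tgt[2L]) w_rho <- w_rho * 1.5
        else if (r < tgt[1L]) w_rho <- w_rho * 0.7
      }
      r <- rt(a_cnt["v"], a_cnt["v_n"])
      if (!is.na(r)) {
        if (r > tgt[2L]) w_v <- w_v * 1.5
        else if (r < tgt[1L]) w_v <- w_v * 0.7
      }
      for (cv in prep$modeled) {
        n <- a_theta[[cv]][2L]
        if (n > 0) {
          r <- a_theta[[cv]][1L] / n
          if (r > tgt[2L]) w_theta[[cv]] <- w_theta[[cv]] * 1.5
          else if (r < tgt[1L]) w_theta[[cv]] <- w_theta[[cv]] * 0.7
        }
        a_theta[[cv]] <- c(0, 0)
      }
      a_cnt[] <- 0
    }
    if (!in_pilot) {
      acc["G"] <- acc["G"] + a_cnt["G"]; acc["G_n"] <- acc["G_n"] + a_cnt["G_n"]
      acc["rho"] <- acc["rho"] + a_cnt["rho"]
      acc["rho_n"] <- acc["rho_n"] + a_cnt["rho_n"]
      acc["v"] <- acc["v"] + a_cnt["v"]; acc["v_n"] <- acc["v_n"] + a_cnt["v_n"]
      a_cnt[] <- 0
    }

    # (9) posterior predictions and recording
    if (!in_pilot && keep_flag[t - pilot]) {
      keep_row <- keep_row + 1L
      Gj <- G
      Nj <- numeric(n_units)
      if (prep$has_size) {
        sz <- Z$size
        Nj_active <- vapply(seq_len(n_units), function(u) {
          if (G[u] == 0L) 0 else
            sum(sz[(U$offset[u] + 1L):(U$offset[u] + G[u])])
        }, 0)
      } else Nj_active <- as.numeric(G)
      Nj <- Nj_active
      if (length(unsampled_units)) {
        for (u in unsampled_units) {
          pr <- predict_unsampled_cell(U$area[u] * exp(v[u]),
                                       size_model_of(U$species_idx[u]))
          Gj[u] <- pr[1L]; Nj[u] <- pr[2L]
        }
      }
      row <- c(beta_det, if (any_two) rho)
      for (cv in prep$modeled) for (sidx in seq_len(prep$n_sp)) {
        m <- covm[[cv]][[sidx]]
        if (m$fixed || m$family == "uniform") next
        row <- c(row, switch(m$family,
          categorical = m$probs,
          { x <- m$theta; if (.is_od(m)) x <- c(x, m$sigma); x }))
      }
      row <- c(row, beta_hab, tau_v, Gj, Nj)
      if (prep$n_sp > 1L) {
        gsp <- vapply(seq_len(prep$n_sp), function(s)
          sum(Gj[U$species_idx == s]), 0)
        nsp <- vapply(seq_len(prep$n_sp), function(s)
          sum(Nj[U$species_idx == s]), 0)
        row <- c(row, gsp, nsp)
      }
      row <- c(row, sum(Gj), sum(Nj))
      if (!is.null(track_info)) {
        code <- rep(1L, length(active))
        mult <- 1L
        for (tv in names(track_info$getters)) {
          val <- if (track_info$getters[[tv]] == "unit_species") {
            sp_of_slot[active]
          } else as.integer(Z[[tv]][active])
          code <- code + (val - 1L) * mult
          mult <- mult * track_info$k[[tv]]
        }
        row <- c(row, tabulate(code, nbins = mult))
      }
      samples[keep_row, ] <- row
    }
  }

  rates <- c(G = unname(acc["G"] / max(acc["G_n"], 1)),
             rho = unname(acc["rho"] / max(acc["rho_n"], 1)),
             v = unname(acc["v"] / max(acc["v_n"], 1)),
             latent_covariates = unname(acc["latent"] /
                                          max(acc["latent_n"], 1)))
  list(samples = samples, accept = rates,
       saturation = saturated / max(total_iters, 1),
       widths = list(psi = psi, rho = w_rho, v = w_v, theta = w_theta))
}

# -------------------------------------------------------------------------

#' Fit the hierarchical double-observer model
#'
#' Runs the reversible-jump MCMC sampler: per sweep, each sampled unit's
#' group count is updated by add/delete moves, latent covariates of
#' never-detected groups are resampled, pseudo-groups are refreshed from the
#' covariate models, latent probit variables are Gibbs-updated, and the
#' detection, covariate, and process parameters are updated from their full
#' conditionals (Gibbs) or by tuned Metropolis-Hastings. Posterior
#' predictions of group and individual abundance are drawn each retained
#' iteration.
#'
#' @param detections an \code{rjds_detections} table
#'   (\code{\link{read_detection_table}} or \code{\link{simulate_survey}}).
#' @param cells an \code{rjds_cells} table; areas are scaled to their mean
#'   internally.
#' @param model a \code{\link{model_spec}}.
#' @param priors a \code{\link{prior_spec}}.
#' @param sampler a \code{\link{sampler_config}}.
#' @param init optional named list of starting values (\code{beta_det},
#'   \code{rho}, \code{v}, \code{beta_hab}, \code{tau_v}, and \code{G},
#'   recycled over units and clamped to \code{[c, G_max]}); combined with
#'   frozen blocks in \code{sampler$update}, this supports fixed-parameter
#'   validation runs.
#' @param track optional character vector of categorical covariates whose
#'   group counts are cross-tabulated over the population each retained
#'   iteration (columns \code{Gclass.*}).
#' @return an object of class \code{rjds_fit} with elements \code{draws}
#'   (class \code{rjds_draws}: \code{samples} matrix, \code{chain} index),
#'   \code{accept}, \code{saturation}, \code{units}, and the specification
#'   objects.
#' @export
fit_hds <- function(detections, cells, model, priors = prior_spec(),
                    sampler = sampler_config(), init = list(),
                    track = NULL) {
  if (is.null(sampler$seed)) sampler$seed <- 1L
  prep <- .prep_fit(detections, cells, model, priors, sampler)
  res <- lapply(seq_len(sampler$n_chains), function(ch) {
    .run_chain(prep, model, priors, sampler, init, ch, track)
  })
  samples <- do.call(rbind, lapply(res, `[[`, "samples"))
  chain <- rep(seq_len(sampler$n_chains),
               each = nrow(res[[1L]]$samples))
  draws <- structure(list(samples = samples, chain = chain,
                          n_chains = sampler$n_chains),
                     class = "rjds_draws")
  accept <- Reduce(`+`, lapply(res, `[[`, "accept")) / length(res)
  saturation <- mean(vapply(res, `[[`, 0, "saturation"))
  if (saturation > sampler$saturation_warn) {
    warning(sprintf(paste("group count hit its slot bound in %.1f%% of",
                          "iterations; increase g_max_* settings"),
                    100 * saturation))
  }
  structure(list(draws = draws, accept = accept, saturation = saturation,
                 fixture_id = attr(detections, "fixture_id"),
                 units = data.frame(label = prep$U$label, cell = prep$U$cell,
                                    species = prep$U$species,
                                    area = prep$U$area,
                                    sampled = prep$U$sampled, c = prep$U$c,
                                    G_max = prep$U$G_max),
                 model = model, priors = priors, sampler = sampler,
                 design = list(det_colnames = attr(prep$builder, "colnames"),
                               hab_colnames = colnames(prep$Xhab),
                               var_info = prep$var_info),
                 widths = lapply(res, `[[`, "widths")),
            class = "rjds_fit")
}

#' @export
print.rjds_fit <- function(x, ...) {
  cat("Hierarchical double-observer distance-sampling fit\n")
  cat(sprintf("  units: %d (%d sampled), chains: %d, retained draws: %d\n",
              nrow(x$units), sum(x$units$sampled), x$draws$n_chains,
              nrow(x$draws$samples)))
  cat(sprintf("  acceptance: G %.2f, rho %.2f, v %.2f, latent cov %.2f\n",
              x$accept["G"], x$accept["rho"], x$accept["v"],
              x$accept["latent_covariates"]))
  gt <- x$draws$samples[, "G.total"]
  cat(sprintf("  posterior total groups: mean %.1f (95%% CI %.0f-%.0f)\n",
              mean(gt), stats::quantile(gt, 0.025),
              stats::quantile(gt, 0.975)))
  invisible(x)
}
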