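# Posterior predictions of group and individual abundance, and posterior
# summaries of the retained draws.

#' Abundance in a sampled cell
#'
#' For surveyed cells the current augmented state already enumerates every
#' group (observed and latent), so group abundance is the active count and
#' individual abundance is the sum of the group-size covariate over active
#' slots.
#'
#' @param G current group count.
#' @param sizes group sizes of the \code{G} active slots (omit or \code{NULL}
#'   if group size is not modeled; every group then counts 1).
#' @return numeric vector \code{c(G, N)}.
#' @export
predict_sampled_cell <- function(G, sizes = NULL) {
  if (is.null(sizes)) return(c(G = G, N = G))
  stopifnot(length(sizes) == G, all(sizes >= 1))
  c(G = G, N = sum(sizes))
}

#' Abundance in an unsampled cell
#'
#' Draws the group count from its Poisson law \eqn{G_j \sim Poisson(\lambda_j
#' A_j)} and individual abundance as the sum of \eqn{G_j} independent draws
#' from the group-size model (a fresh overdispersion random effect per
#' predicted group).
#'
#' @param lambda_area Poisson mean \eqn{\lambda_j A_j}.
#' @param size_model group-size \code{\link{covariate_model}} (or \code{NULL}
#'   for unit group sizes).
#' @return numeric vector \code{c(G, N)}.
#' @export
predict_unsampled_cell <- function(lambda_area, size_model = NULL) {
  stopifnot(lambda_area >= 0)
  G <- stats::rpois(1L, lambda_area)
  N <- if (G == 0L) 0 else if (is.null(size_model)) G else
    sum(covariate_sample(G, size_model)$value)
  c(G = G, N = N)
}

#' Summarize posterior draws
#'
#' Posterior mean, SD, and equal-tailed credible intervals (linear
#' interpolation sample quantiles, the default quantile rule) for each
#' requested scalar.
#'
#' @param x an \code{rjds_fit} or \code{rjds_draws} object.
#' @param quantities column names to summarize; default all.
#' @param level credible level(s), e.g. \code{0.95}.
#' @return data.frame with columns \code{quantity, mean, sd} and
#'   \code{lo<level>, hi<level>} per requested level.
#' @export
summarize_draws <- function(x, quantities = NULL, level = 0.95) {
  draws <- if (inherits(x, "rjds_fit")) x$draws else x
  stopifnot(inherits(draws, "rjds_draws"), nrow(draws$samples) >= 1)
  if (is.null(quantities)) quantities <- colnames(draws$samples)
  miss <- setdiff(quantities, colnames(draws$samples))
  if (length(miss)) stop("unknown quantities: ", paste(miss, collapse = ", "))
  m <- draws$samples[, quantities, drop = FALSE]
  out <- data.frame(quantity = quantities,
                    mean = colMeans(m),
                    sd = apply(m, 2, stats::sd))
  for (lv in sort(level)) {
    a <- (1 - lv) / 2
    q <- apply(m, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
    out[[sprintf("lo%g", 100 * lv)]] <- q[1L, ]
    out[[sprintf("hi%g", 100 * lv)]] <- q[2L, ]
  }
  rownames(out) <- NULL
  out
}

#' Posterior predictive mass function of group size
#'
#' Averages the group-size pmf over the retained posterior draws of its
#' parameters; overdispersed families integrate the random effect by Monte
#' Carlo.
#'
#' @param fit an \code{rjds_fit} whose model includes a \code{size}
#'   covariate model.
#' @param species species level (partitioned mode); default the first.
#' @param max_size largest size tabulated.
#' @param n_mc Monte Carlo size for the random-effect integral per draw.
#' @param max_draws cap on the number of posterior draws used (thinned
#'   evenly).
#' @return data.frame with columns \code{size, probability}.
#' @export
size_pmf <- function(fit, species = NULL, max_size = 20, n_mc = 30,
                     max_draws = 500) {
  stopifnot(inherits(fit, "rjds_fit"))
  base <- fit$model$covariate_models[["size"]]
  if (is.null(base)) stop("fit has no group-size model")
  sp <- unique(fit$units$species)
  sfx <- if (length(sp) > 1L) {
    paste0(".", species %||% sp[1L])
  } else ""
  cn <- colnames(fit$draws$samples)
  th_col <- paste0("cov.size", sfx, ".theta")
  sg_col <- paste0("cov.size", sfx, ".sigma")
  sizes <- seq_len(max_size)
  if (base$fixed || !th_col %in% cn) {
    # fixed parameters: single pmf evaluation
    pm <- .size_pmf_at(base, sizes, n_mc)
    return(data.frame(size = sizes, probability = pm))
  }
  th <- fit$draws$samples[, th_col]
  use <- unique(round(seq(1, length(th), length.out = min(max_draws,
                                                          length(th)))))
  pm <- rowMeans(vapply(use, function(i) {
    m <- base
    m$theta <- th[i]
    if (.is_od(m)) m$sigma <- fit$draws$samples[i, sg_col]
    .size_pmf_at(m, sizes, n_mc)
  }, numeric(length(sizes))))
  data.frame(size = sizes, probability = pm)
}

.size_pmf_at <- function(model, sizes, n_mc) {
  if (!.is_od(model)) return(covariate_density(sizes, model))
  e <- stats::qnorm((seq_len(n_mc) - 0.5) / n_mc) * model$sigma
  rowMeans(vapply(e, function(ei) covariate_density(sizes, model, eps = ei),
                  numeric(length(sizes))))
}
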