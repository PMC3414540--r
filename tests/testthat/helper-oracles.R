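# Independent oracles and small fixture builders used across the suite.

# Bivariate-normal CDF oracle, independent of the package's quadrature:
# Phi2(h, k, r) = Phi(h) Phi(k) +
#   (1 / 2pi) int_0^r exp(-(h^2 - 2 t h k + k^2) / (2 (1 - t^2))) /
#   sqrt(1 - t^2) dt   (Drezner-Wesolowsky identity, adaptive quadrature)
pbvn_oracle <- function(h, k, r) {
  base <- pnorm(h) * pnorm(k)
  if (r == 0) return(base)
  f <- function(t) exp(-(h^2 - 2 * t * h * k + k^2) / (2 * (1 - t^2))) /
    sqrt(1 - t^2)
  base + integrate(f, 0, r, rel.tol = 1e-12, abs.tol = 1e-14)$value / (2 * pi)
}

# total-variation distance between an empirical sample of nonnegative
# integers and a probability mass function evaluated on 0..(length(pmf)-1)
tv_dist <- function(x, pmf) {
  emp <- tabulate(x + 1L, nbins = length(pmf)) / length(x)
  0.5 * sum(abs(emp - pmf)) + 0.5 * (1 - sum(pmf))
}

# one-cell survey with two observers and a handful of observed groups
toy_cells <- function(n_obs = 2) {
  obs <- if (n_obs == 2) list(c("o1", "o2")) else list("o1")
  rjds:::.make_cells(
    data.frame(cell = "t1", area = 1, sampled = 1L,
               observers = paste(obs[[1]], collapse = ";"),
               stringsAsFactors = FALSE), obs)
}

toy_detections <- function(n = 3, two_obs = TRUE) {
  rjds:::.make_detections(data.frame(
    transect = "t1", group = seq_len(n),
    y1 = rep_len(c(1L, 1L, 0L), n),
    y2 = if (two_obs) rep_len(c(0L, 1L, 1L), n) else NA_integer_,
    distance = seq(0.1, 0.9, length.out = n)))
}

# write a small detection/cell CSV pair and return the paths
write_toy_tables <- function(dir = tempfile()) {
  dir.create(dir)
  cells <- data.frame(cell = c("t1", "t2", "t3"),
                      area = c(2, 4, 6), sampled = c(1L, 1L, 0L),
                      observers = c("a;b", "b;c", ""),
                      habx = c(0.1, 0.5, 0.9))
  det <- data.frame(
    transect = c("t1", "t1", "t1", "t1", "t2", "t2"),
    group = c(1L, 1L, 2L, 2L, 1L, 1L),
    observer = c("a", "b", "a", "b", "b", "c"),
    seen = c(1L, 0L, 1L, 1L, 0L, 1L),
    distance = c(0.2, 0.2, 0.7, 0.7, 0.4, 0.4),
    size = c(3L, 3L, 1L, 1L, 2L, 2L))
  cp <- file.path(dir, "cells.csv"); dp <- file.path(dir, "det.csv")
  write.csv(cells, cp, row.names = FALSE)
  write.csv(det, dp, row.names = FALSE)
  list(cells = cp, det = dp, dir = dir)
}
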