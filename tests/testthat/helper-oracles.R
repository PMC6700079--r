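# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: circular statistics are recomputed from first
# principles, geodesic bearings via a 3-D vector construction, and the
# assignment chain by explicit pixel enumeration.

# circular mean of bearings in degrees
circ_mean_deg <- function(deg) {
  th <- deg * pi / 180
  (atan2(mean(sin(th)), mean(cos(th))) * 180 / pi) %% 360
}

# smallest absolute angular difference in degrees
ang_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# Rayleigh test p-value (large-sample) for circular uniformity
rayleigh_p <- function(deg) {
  th <- deg * pi / 180
  n <- length(th)
  R <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  Z <- n * R^2
  exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n))
}

# initial bearing via 3-D unit vectors: independent of the package's
# spherical-trig formula
bearing_vec_oracle <- function(origin, dest) {
  to_xyz <- function(p) {
    phi <- p[1] * pi / 180; lam <- p[2] * pi / 180
    c(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
  }
  a <- to_xyz(origin); b <- to_xyz(dest)
  north <- c(0, 0, 1)
  # east and north unit vectors in the tangent plane at a
  e <- c(-a[2], a[1], 0); e <- e / sqrt(sum(e^2))
  nvec <- north - sum(north * a) * a; nvec <- nvec / sqrt(sum(nvec^2))
  # direction of the great circle towards b, projected to the tangent plane
  d <- b - sum(b * a) * a
  (atan2(sum(d * e), sum(d * nvec)) * 180 / pi) %% 360
}

# brute-force assignment chain on a tiny grid: explicit loops over pixels,
# no shared code with the package implementation
brute_force_assignment <- function(lik_list, prior_vals, q, thresholds) {
  n <- length(lik_list)
  nr <- nrow(prior_vals); nc <- ncol(prior_vals)
  bins <- vector("list", n)
  for (i in seq_len(n)) {
    post <- lik_list[[i]] * prior_vals
    post <- post / sum(post)
    # flatten row-major, sort descending with row-major tie-break
    vals <- as.vector(t(post))
    ord <- order(-vals, seq_along(vals))
    cum <- cumsum(vals[ord])
    keep <- ord[seq_len(which(cum >= q - 1e-12)[1])]
    b <- matrix(0L, nr, nc)
    for (k in keep) {
      r <- (k - 1) %/% nc + 1; c <- (k - 1) %% nc + 1
      b[r, c] <- 1L
    }
    bins[[i]] <- b
  }
  counts <- Reduce(`+`, bins)
  masks <- lapply(thresholds, function(p) counts / n > p)
  list(bins = bins, counts = counts, masks = masks)
}

# winter NDVI covariate series used by several SEM tests
ndvi_years <- function(years, seed) {
  set.seed(seed)
  stats::setNames(pmin(0.675, pmax(0.6, stats::rnorm(length(years),
                                                     0.6375, 0.02))), years)
}
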