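#' Initial great-circle bearing between two points
#'
#' Bearing at `origin` of the great circle through `origin` and `dest`, in
#' degrees clockwise from geographic north, in [0, 360). A spherical Earth is
#' assumed; at the grid resolutions used for origin assignment (~0.83 deg) the
#' difference from ellipsoidal geodesics is negligible.
#'
#' @param origin,dest Numeric length-2 vectors `c(lat, lon)` in degrees.
#' @return Bearing in degrees in [0, 360).
#' @examples
#' initial_bearing(c(0, 0), c(0, 10))   # due east: 90
#' initial_bearing(c(10, 0), c(-10, 0)) # due south: 180
#' @export
initial_bearing <- function(origin, dest) {
  stopifnot(length(origin) == 2L, length(dest) == 2L)
  if (isTRUE(all.equal(origin, dest, tolerance = 0)) ||
      (origin[1] == dest[1] && origin[2] == dest[2]))
    stop("bearing undefined for coincident points")
  phi1 <- origin[1] * pi / 180; phi2 <- dest[1] * pi / 180
  dl <- (dest[2] - origin[2]) * pi / 180
  y <- sin(dl) * cos(phi2)
  x <- cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dl)
  (atan2(y, x) * 180 / pi) %% 360
}

# vectorized form used on raster grids: origin fixed, many destinations
bearing_many <- function(origin, lat, lon) {
  phi1 <- origin[1] * pi / 180; phi2 <- lat * pi / 180
  dl <- (lon - origin[2]) * pi / 180
  y <- sin(dl) * cos(phi2)
  x <- cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dl)
  (atan2(y, x) * 180 / pi) %% 360
}

#' Fit a von Mises distribution to circular bearings
#'
#' Mean direction is the circular mean; the concentration kappa is the maximum
#' likelihood estimate, obtained by inverting A1(kappa) = Rbar (the ratio of
#' modified Bessel functions I1/I0 equated to the mean resultant length) with
#' Fisher's series approximation refined by Newton steps. As Rbar approaches 1
#' the MLE diverges, so kappa is capped at `kappa_max`.
#'
#' @param bearings Bearings in degrees (any real values; reduced modulo 360).
#' @param kappa_max Cap on the fitted concentration (default 500).
#' @return An object of class `von_mises_fit`: list with `mu` (degrees in
#'   [0, 360)), `kappa`, `Rbar`, `n`.
#' @examples
#' fit_von_mises(c(160, 170, 180))
#' @export
fit_von_mises <- function(bearings, kappa_max = 500) {
  n <- length(bearings)
  if (n < 2L) stop("need at least 2 bearings")
  th <- bearings * pi / 180
  C <- mean(cos(th)); S <- mean(sin(th))
  Rbar <- sqrt(C^2 + S^2)
  mu <- (atan2(S, C) * 180 / pi) %% 360
  if (Rbar < 1e-12) {
    kappa <- 0
  } else {
    kappa <- a1inv(Rbar)
    if (!is.finite(kappa) || kappa > kappa_max) {
      warning("bearings nearly identical: kappa capped at ", kappa_max)
      kappa <- kappa_max
    }
  }
  structure(list(mu = mu, kappa = kappa, Rbar = Rbar, n = n),
            class = "von_mises_fit")
}

#' @export
print.von_mises_fit <- function(x, ...) {
  cat(sprintf("von Mises fit: mu = %.2f deg, kappa = %.3f (Rbar = %.4f, n = %d)\n",
              x$mu, x$kappa, x$Rbar, x$n))
  invisible(x)
}

# A1(k) = I1(k)/I0(k), computed with scaled Bessel functions for stability
besselA1 <- function(k) {
  ifelse(k == 0, 0,
         besselI(k, 1, expon.scaled = TRUE) / besselI(k, 0, expon.scaled = TRUE))
}

# invert A1(k) = r: Fisher (1993) start, then Newton refinement.
# A1'(k) = 1 - A1(k)/k - A1(k)^2
a1inv <- function(r) {
  if (r >= 1 - 1e-12) return(Inf)
  k <- if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
       else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
       else 1 / (r^3 - 4 * r^2 + 3 * r)
  for (i in 1:25) {
    a <- besselA1(k)
    dk <- (a - r) / (1 - a / k - a^2)
    k <- k - dk
    if (k <= 0) k <- 1e-8
    if (abs(dk) < 1e-10 * (1 + k)) break
  }
  k
}

# von Mises density on degrees (normalized on the circle)
dvonmises_deg <- function(theta_deg, mu_deg, kappa) {
  t <- (theta_deg - mu_deg) * pi / 180
  exp(kappa * cos(t)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE) *
                           exp(kappa))
}

#' Draw random bearings from a von Mises distribution
#'
#' Best & Fisher (1979) wrapped-Cauchy envelope rejection sampler; exact for
#' kappa > 0, uniform on the circle for kappa = 0.
#'
#' @param n Number of draws.
#' @param mu Mean direction in degrees.
#' @param kappa Concentration (>= 0).
#' @return Bearings in degrees in [0, 360).
#' @export
rvonmises_deg <- function(n, mu, kappa) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(stats::runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      theta <- sign(u3 - 0.5) * acos(f)
      out[i] <- (mu + theta * 180 / pi) %% 360
      i <- i + 1L
    }
  }
  out
}

#' Movement-direction prior surface from a von Mises fit
#'
#' For every valid pixel the initial bearing from the breeding centroid to the
#' pixel center is computed, snapped to the nearest node of a discrete
#' direction grid (odd degrees 1, 3, ..., 359 by default), the von Mises
#' density is evaluated there, and the resulting field is normalized over
#' pixels to sum to one. Snapping can be disabled for continuous evaluation;
#' the difference is bounded by the density's modulus of continuity over half
#' the node spacing.
#'
#' @param fit A `von_mises_fit`.
#' @param centroid Breeding centroid `c(lat, lon)` in degrees.
#' @param grid A `grid_spec`.
#' @param direction_step Spacing of direction nodes in degrees (default 2,
#'   giving nodes 1, 3, ..., 359).
#' @param snap If `FALSE`, evaluate the density at the exact bearing.
#' @param mask Optional logical matrix of valid pixels (default all valid).
#' @return An object of class `prior_surface`: list with `grid`, `values`
#'   (matrix summing to 1 over valid pixels, NA outside `mask`), `centroid`,
#'   `fit`.
#' @export
build_prior_surface <- function(fit, centroid, grid, direction_step = 2,
                                snap = TRUE, mask = NULL) {
  stopifnot(inherits(fit, "von_mises_fit"))
  ctr <- grid_centers(grid)
  if (is.null(mask)) mask <- matrix(TRUE, grid$nrow, grid$ncol)
  stopifnot(all(dim(mask) == dim_grid(grid)))
  b <- bearing_many(centroid, ctr$lat_mat, ctr$lon_mat)
  coincident <- abs(ctr$lat_mat - centroid[1]) < 1e-12 &
    abs(ctr$lon_mat - centroid[2]) < 1e-12
  if (snap) {
    nodes <- seq(1, 359, by = direction_step)
    idx <- round((b - 1) / direction_step)
    idx <- ((idx %% length(nodes)) + length(nodes)) %% length(nodes) + 1
    b <- matrix(nodes[idx], grid$nrow, grid$ncol)
  }
  dens <- dvonmises_deg(b, fit$mu, fit$kappa)
  if (any(coincident & mask)) {
    # a pixel sitting exactly on the centroid has no defined bearing:
    # give it the mean density of its valid neighbors
    for (k in which(coincident & mask)) {
      i <- (k - 1) %% grid$nrow + 1; j <- (k - 1) %/% grid$nrow + 1
      ni <- max(1, i - 1):min(grid$nrow, i + 1)
      nj <- max(1, j - 1):min(grid$ncol, j + 1)
      nb <- dens[ni, nj, drop = FALSE]
      ok <- mask[ni, nj, drop = FALSE] & !(coincident[ni, nj, drop = FALSE])
      dens[i, j] <- mean(nb[ok])
    }
  }
  dens[!mask] <- NA_real_
  tot <- sum(dens[mask])
  if (!is.finite(tot) || tot <= 0) stop("prior surface has zero total mass")
  vals <- dens / tot
  structure(list(grid = grid, values = vals, centroid = centroid, fit = fit),
            class = "prior_surface")
}

#' @export
print.prior_surface <- function(x, ...) {
  cat(sprintf("prior_surface on %d x %d grid (mu = %.1f deg, kappa = %.2f)\n",
              x$grid$nrow, x$grid$ncol, x$fit$mu, x$fit$kappa))
  invisible(x)
}
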