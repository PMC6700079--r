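#' Residual isotope covariance from calibration samples
#'
#' Computes the maximum-likelihood mean and covariance of the residuals
#' (feather value minus isoscape value at the known or assumed origin) over
#' the three isotopes. With complete data this is the closed-form n-denominator
#' sample covariance; with missing cells the ML estimate is obtained by EM for
#' the multivariate normal, iterated until the log-likelihood improves by less
#' than `tol`.
#'
#' @param samples Data frame with columns `d2H`, `d13C`, `d15N` (NA allowed)
#'   and origin columns `true_lat`/`true_lon` (or `lat`/`lon`).
#' @param isoscapes An `isoscape_set`.
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param max_iter EM iteration cap.
#' @param ridge If `TRUE`, add `1e-6 * mean(diag)` to the diagonal when the
#'   estimate is numerically singular (off by default; degenerate estimates
#'   are otherwise an error).
#' @return An object of class `residual_covariance`: list with `mean`
#'   (length-3), `cov` (3x3), `method` (`"ML-complete"` or `"ML-EM-missing"`
#'   or `"user-supplied"`), `n`, `n_missing_cells`.
#' @export
estimate_residual_covariance <- function(samples, isoscapes, tol = 1e-8,
                                         max_iter = 500, ridge = FALSE) {
  iso_names <- c("d2H", "d13C", "d15N")
  latc <- if ("true_lat" %in% names(samples)) "true_lat" else "lat"
  lonc <- if ("true_lon" %in% names(samples)) "true_lon" else "lon"
  X <- as.matrix(samples[, iso_names]) -
    isoscape_at(isoscapes, samples[[latc]], samples[[lonc]])
  keep_rows <- rowSums(!is.na(X)) >= 1L
  X <- X[keep_rows, , drop = FALSE]
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 samples with at least one isotope each")
  all_missing <- colSums(!is.na(X)) == 0L
  if (any(all_missing)) {
    warning("isotope(s) ", paste(iso_names[all_missing], collapse = ", "),
            " missing in every sample: dropped from the covariance")
    X <- X[, !all_missing, drop = FALSE]
  }
  if (!anyNA(X)) {
    mu <- colMeans(X)
    S <- crossprod(sweep(X, 2, mu)) / n
    method <- "ML-complete"
  } else {
    fit <- mvn_em(X, tol = tol, max_iter = max_iter)
    mu <- fit$mean; S <- fit$cov
    method <- "ML-EM-missing"
  }
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("estimated covariance is not positive semi-definite")
  if (min(ev) < 1e-10 * max(ev, 1)) {
    if (ridge) {
      eps <- 1e-6 * mean(diag(S))
      if (eps <= 0) eps <- 1e-6  # fully degenerate: absolute floor
      S <- S + diag(eps, nrow(S))
      warning("near-singular residual covariance: ridge added to the diagonal")
    } else {
      warning("residual covariance is numerically singular (e.g. duplicated ",
              "samples); consider ridge = TRUE")
    }
  }
  structure(list(mean = mu, cov = S, method = method, n = n,
                 n_missing_cells = sum(is.na(X))),
            class = "residual_covariance")
}

#' @export
print.residual_covariance <- function(x, ...) {
  cat(sprintf("residual_covariance (%s, n = %d, %d missing cells)\n",
              x$method, x$n, x$n_missing_cells))
  print(round(x$cov, 4))
  invisible(x)
}

# EM for the MVN mean/covariance with missing-at-random cells
mvn_em <- function(X, tol = 1e-8, max_iter = 500) {
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X, na.rm = TRUE)
  S <- diag(apply(X, 2, stats::var, na.rm = TRUE), p)
  obs_pat <- apply(!is.na(X), 1, paste, collapse = "")
  pats <- split(seq_len(n), obs_pat)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    sum_x <- numeric(p)
    sum_xx <- matrix(0, p, p)
    ll <- 0
    for (rows in pats) {
      o <- !is.na(X[rows[1], ])
      m <- !o
      Xo <- X[rows, o, drop = FALSE]
      if (!any(m)) {
        sum_x <- sum_x + colSums_at(Xo, o, p)
        sum_xx <- sum_xx + crossprod_at(Xo, o, p)
        ll <- ll + sum(dmvnorm_log(Xo, mu[o], S[o, o, drop = FALSE]))
        next
      }
      Soo <- S[o, o, drop = FALSE]
      Smo <- S[m, o, drop = FALSE]
      Smm <- S[m, m, drop = FALSE]
      B <- Smo %*% solve(Soo)
      cond_cov <- Smm - B %*% t(Smo)
      dev <- sweep(Xo, 2, mu[o])
      Xm_hat <- matrix(mu[m], nrow(Xo), sum(m), byrow = TRUE) + dev %*% t(B)
      Xfull <- matrix(0, nrow(Xo), p)
      Xfull[, o] <- Xo; Xfull[, m] <- Xm_hat
      sum_x <- sum_x + colSums(Xfull)
      cp <- crossprod(Xfull)
      cp[m, m] <- cp[m, m] + nrow(Xo) * cond_cov
      sum_xx <- sum_xx + cp
      ll <- ll + sum(dmvnorm_log(Xo, mu[o], Soo))
    }
    mu <- sum_x / n
    S <- sum_xx / n - tcrossprod(mu)
    S <- (S + t(S)) / 2
    if (is.finite(ll_old) && ll - ll_old < tol && ll - ll_old > -1e-6) break
    ll_old <- ll
  }
  list(mean = mu, cov = S, loglik = ll, iterations = iter)
}

colSums_at <- function(Xo, o, p) { v <- numeric(p); v[o] <- colSums(Xo); v }
crossprod_at <- function(Xo, o, p) {
  m <- matrix(0, p, p); m[o, o] <- crossprod(Xo); m
}

dmvnorm_log <- function(X, mu, S) {
  X <- as.matrix(X)
  k <- ncol(X)
  ch <- chol(S)
  z <- forwardsolve(t(ch), t(sweep(X, 2, mu)))
  -0.5 * k * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

#' Multivariate normal likelihood-of-origin surface
#'
#' Evaluates, for one feather sample, the multivariate normal density of its
#' observed isotope values at every valid pixel, with the pixel's isoscape
#' values as the mean vector and the residual covariance (restricted to the
#' observed isotopes) as the covariance. Missing isotopes are handled by
#' marginalization — the density of the observed subvector under the
#' corresponding sub-covariance — which is exact under multivariate normality.
#'
#' @param sample One-row data frame (or list) with `d2H`, `d13C`, `d15N`,
#'   NA where unmeasured, and optionally `individual_id`.
#' @param isoscapes An `isoscape_set`.
#' @param cov A `residual_covariance`, or a 3x3 matrix (taken as
#'   user-supplied, mean zero).
#' @return An `origin_surface` of type `"likelihood"`: list with `grid`,
#'   `values` (densities, NA outside the mask), `individual_id`.
#' @export
likelihood_surface <- function(sample, isoscapes, cov) {
  iso_names <- c("d2H", "d13C", "d15N")
  x <- unlist(sample[iso_names])
  obs <- !is.na(x)
  if (!any(obs)) stop("sample has no observed isotope values")
  S <- if (inherits(cov, "residual_covariance")) cov$cov else as.matrix(cov)
  idx <- match(iso_names[obs], colnames(S) %||% iso_names)
  So <- S[idx, idx, drop = FALSE]
  ch <- tryCatch(chol(So), error = function(e)
    stop("singular sub-covariance for observed isotopes; ",
         "consider a ridge on the residual covariance"))
  g <- isoscapes$grid
  mask <- isoscapes$mask
  M <- do.call(cbind, lapply(iso_names[obs], function(nm)
    as.vector(isoscapes$layers[[nm]])))
  dev <- sweep(M, 2, x[obs], "-")
  k <- sum(obs)
  q <- rep(NA_real_, nrow(dev))
  okpix <- as.vector(mask)
  z <- backsolve(ch, t(dev[okpix, , drop = FALSE]), transpose = TRUE)
  q[okpix] <- colSums(z^2)
  dens <- exp(-0.5 * q) / ((2 * pi)^(k / 2) * prod(diag(ch)))
  vals <- matrix(dens, g$nrow, g$ncol)
  structure(list(grid = g, values = vals,
                 individual_id = sample[["individual_id"]] %||% NA_character_,
                 type = "likelihood"),
            class = "origin_surface")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Posterior origin surface by Bayes' rule
#'
#' Multiplies an individual's likelihood surface by the movement-direction
#' prior pixelwise and renormalizes to a probability surface summing to one.
#'
#' @param likelihood An `origin_surface` (type `"likelihood"`).
#' @param prior A `prior_surface` on the identical grid, or `NULL` for a flat
#'   prior (debug use: the posterior is then the normalized likelihood).
#' @return An `origin_surface` of type `"posterior"` whose values sum to 1.
#' @export
posterior_surface <- function(likelihood, prior = NULL) {
  v <- likelihood$values
  if (!is.null(prior)) {
    if (!grids_identical(likelihood$grid, prior$grid))
      stop("likelihood and prior grids differ")
    v <- v * prior$values
  }
  tot <- sum(v, na.rm = TRUE)
  if (!is.finite(tot) || tot <= 0)
    stop("prior and likelihood have disjoint support for individual ",
         likelihood$individual_id)
  structure(list(grid = likelihood$grid, values = v / tot,
                 individual_id = likelihood$individual_id,
                 type = "posterior"),
            class = "origin_surface")
}

#' @export
print.origin_surface <- function(x, ...) {
  cat(sprintf("origin_surface (%s) for %s on %d x %d grid\n",
              x$type, x$individual_id, x$grid$nrow, x$grid$ncol))
  invisible(x)
}

#' Odds-based binarization of a posterior surface
#'
#' Codes as 1 the smallest set of highest-posterior pixels whose cumulative
#' probability mass first reaches `q` (default 0.67, the upper 67% of the
#' probability density map); all other pixels are coded 0. Ties in posterior
#' value are broken by row-major pixel index.
#'
#' @param posterior An `origin_surface` of type `"posterior"`.
#' @param q Cumulative mass to capture, in (0, 1).
#' @return A `binary_origin_map`: list with `grid`, `values` (0/1 integer
#'   matrix, NA outside the valid mask), `q`, `individual_id`.
#' @export
binarize_odds <- function(posterior, q = 0.67) {
  stopifnot(q > 0, q < 1)
  v <- posterior$values
  g <- posterior$grid
  ok <- which(!is.na(v))
  # row-major index for the documented tie-break
  rm_idx <- ((ok - 1) %% g$nrow) * g$ncol + ((ok - 1) %/% g$nrow) + 1
  ord <- ok[order(-v[ok], rm_idx)]
  cum <- cumsum(v[ord])
  n_in <- which(cum >= q - 1e-12)[1]
  if (is.na(n_in)) n_in <- length(ord)  # q exceeds total mass (numerical)
  bin <- matrix(NA_integer_, g$nrow, g$ncol)
  bin[ok] <- 0L
  bin[ord[seq_len(n_in)]] <- 1L
  structure(list(grid = g, values = bin, q = q,
                 individual_id = posterior$individual_id),
            class = "binary_origin_map")
}

#' Population origin surface
#'
#' Per-pixel count of individuals whose binary origin map includes the pixel.
#'
#' @param maps List of `binary_origin_map`s on one common grid.
#' @return A `population_origin_surface`: list with `grid`, `counts`
#'   (integer matrix), `n_individuals`.
#' @export
population_surface <- function(maps) {
  stopifnot(length(maps) >= 1L)
  g <- maps[[1]]$grid
  for (m in maps)
    if (!grids_identical(g, m$grid)) stop("binary maps are on different grids")
  counts <- matrix(0L, g$nrow, g$ncol)
  for (m in maps) {
    v <- m$values
    v[is.na(v)] <- 0L
    counts <- counts + v
  }
  structure(list(grid = g, counts = counts, n_individuals = length(maps)),
            class = "population_origin_surface")
}

#' @export
print.population_origin_surface <- function(x, ...) {
  cat(sprintf("population_origin_surface: %d individuals, max count %d\n",
              x$n_individuals, max(x$counts)))
  invisible(x)
}

#' Threshold a population surface into a winter-area mask
#'
#' Keeps pixels assigned as origin for strictly more than a proportion `p` of
#' individuals, and reports the spherical area of the retained pixels.
#'
#' @param pop A `population_origin_surface`.
#' @param p Proportion threshold in (0, 1); inclusion is `count/n > p`
#'   (strict).
#' @return A `winter_mask`: list with `grid`, `mask` (logical matrix), `p`,
#'   `area_km2`, `n_individuals`.
#' @export
threshold_origin <- function(pop, p) {
  stopifnot(p > 0, p < 1)
  mask <- pop$counts / pop$n_individuals > p
  area <- sum(pixel_area_km2(pop$grid)[mask])
  structure(list(grid = pop$grid, mask = mask, p = p, area_km2 = area,
                 n_individuals = pop$n_individuals),
            class = "winter_mask")
}

#' @export
print.winter_mask <- function(x, ...) {
  cat(sprintf("winter_mask (> %d%% of %d individuals): %d pixels, %.0f km^2\n",
              round(100 * x$p), x$n_individuals, sum(x$mask), x$area_km2))
  invisible(x)
}

#' Full per-individual assignment pipeline
#'
#' Convenience wrapper running likelihood, posterior, binarization, population
#' summation and thresholding for a table of feather samples.
#'
#' @param samples Data frame of feather samples (`individual_id`, `d2H`,
#'   `d13C`, `d15N`).
#' @param isoscapes An `isoscape_set`.
#' @param cov A `residual_covariance` or 3x3 matrix.
#' @param prior A `prior_surface` or `NULL` (flat).
#' @param q Binarization mass (default 0.67).
#' @param thresholds Population proportions for winter-area masks
#'   (default `c(0.5, 0.6, 0.7)`).
#' @param keep_posteriors Keep the per-individual posterior surfaces
#'   (default `FALSE` to save memory).
#' @return An `origin_assignment`: list with `population`
#'   (`population_origin_surface`), `masks` (named list of `winter_mask`s),
#'   `areas` (data frame threshold/pixels/area_km2), and optionally
#'   `posteriors`.
#' @export
assign_origins <- function(samples, isoscapes, cov, prior = NULL, q = 0.67,
                           thresholds = c(0.5, 0.6, 0.7),
                           keep_posteriors = FALSE) {
  maps <- vector("list", nrow(samples))
  posts <- if (keep_posteriors) vector("list", nrow(samples)) else NULL
  for (i in seq_len(nrow(samples))) {
    lik <- likelihood_surface(samples[i, , drop = FALSE], isoscapes, cov)
    post <- posterior_surface(lik, prior)
    if (keep_posteriors) posts[[i]] <- post
    maps[[i]] <- binarize_odds(post, q)
  }
  pop <- population_surface(maps)
  masks <- lapply(thresholds, function(p) threshold_origin(pop, p))
  names(masks) <- sprintf("gt%d", round(100 * thresholds))
  areas <- data.frame(threshold = thresholds,
                      pixels = vapply(masks, function(m) sum(m$mask), 1L),
                      area_km2 = vapply(masks, function(m) m$area_km2, 1.0))
  structure(list(population = pop, masks = masks, areas = areas,
                 posteriors = posts, q = q),
            class = "origin_assignment")
}

#' @export
print.origin_assignment <- function(x, ...) {
  cat(sprintf("origin_assignment of %d individuals (q = %.2f)\n",
              x$population$n_individuals, x$q))
  print(x$areas, row.names = FALSE)
  invisible(x)
}
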