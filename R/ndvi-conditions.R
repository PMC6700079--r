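#' Fill missing cells in an NDVI stack
#'
#' Per-pixel linear interpolation in time, with boundary gaps filled by the
#' nearest observed composite; any cell still missing afterwards (possible
#' only when a whole composite is missing for that pixel's neighborhood in
#' time) is filled by the mean of its valid 8-neighbors within the same
#' composite. This is a deliberately simple, documented substitute for
#' space-time quantile-regression gap fillers: the downstream covariate is a
#' mask-wide mean over ~150 composites and is insensitive to the filler at
#' realistic gap rates.
#'
#' @param stack An `ndvi_stack`.
#' @return An `ndvi_stack` with no missing cells and an attribute
#'   `gap_filler = "linear-time+neighbor"` recording the method. A stack with
#'   no gaps is returned unchanged (bit-exact, no attribute added).
#' @export
gap_fill <- function(stack) {
  v <- stack$values
  if (!anyNA(v)) return(stack)
  nr <- dim(v)[1]; nc <- dim(v)[2]; nt <- dim(v)[3]
  tnum <- as.numeric(stack$dates)
  flat <- matrix(v, nr * nc, nt)  # one row per pixel, columns = time
  nobs <- rowSums(!is.na(flat))
  if (any(nobs == 0L))
    stop("pixel(s) missing in all composites: ",
         paste(head(which(nobs == 0L)), collapse = ", "))
  need <- which(nobs < nt)
  for (px in need[nobs[need] >= 2L]) {
    y <- flat[px, ]
    ok <- !is.na(y)
    flat[px, !ok] <- stats::approx(tnum[ok], y[ok], xout = tnum[!ok],
                                   rule = 2)$y
  }
  # pixels with a single observation: constant in time
  for (px in need[nobs[need] == 1L])
    flat[px, ] <- flat[px, which(!is.na(flat[px, ]))[1]]
  v <- array(flat, c(nr, nc, nt))
  # safety net for composite-wide holes: same-composite 8-neighbor mean
  if (anyNA(v)) {
    for (k in seq_len(nt)) {
      sl <- v[, , k]
      holes <- which(is.na(sl), arr.ind = TRUE)
      for (h in seq_len(nrow(holes))) {
        i <- holes[h, 1]; j <- holes[h, 2]
        nb <- sl[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
        v[i, j, k] <- mean(nb, na.rm = TRUE)
      }
    }
  }
  out <- stack
  out$values <- v
  attr(out, "gap_filler") <- "linear-time+neighbor"
  out
}

#' Winter mean NDVI over a delineated wintering area
#'
#' The winter-condition covariate of year `i`: the unweighted mean of every
#' masked pixel over every composite dated 1 November of year `i - 1` through
#' 31 March of year `i` (the period the population spends on the wintering
#' grounds). Winters are labeled by their ending (January) year.
#'
#' @param stack An `ndvi_stack` (gap-filled or not; NA cells are excluded
#'   from the mean with a count of the cells used).
#' @param mask A `winter_mask`, or a logical matrix on the stack's grid.
#' @param year Winter label `i` (integer): the window is Nov (i-1) - Mar (i).
#' @return One-row data frame: `year`, `ndvi`, `n_pixels`, `n_composites`.
#' @export
winter_mean <- function(stack, mask, year) {
  m <- if (inherits(mask, "winter_mask")) mask$mask else mask
  stopifnot(all(dim(m) == dim_grid(stack$grid)))
  if (!any(m)) stop("empty winter mask")
  from <- as.Date(sprintf("%d-11-01", year - 1))
  to <- as.Date(sprintf("%d-03-31", year))
  kk <- which(stack$dates >= from & stack$dates <= to)
  if (!length(kk)) stop("no composites dated within Nov-Mar window of ", year)
  cells <- stack$values[, , kk, drop = FALSE][rep(m, length(kk))]
  data.frame(year = year, ndvi = mean(cells, na.rm = TRUE),
             n_pixels = sum(m), n_composites = length(kk))
}

#' Winter NDVI series over several years
#'
#' @param stack An `ndvi_stack`.
#' @param mask A `winter_mask` or logical matrix.
#' @param years Integer vector of winter labels.
#' @return Data frame with one [winter_mean()] row per year.
#' @export
winter_series <- function(stack, mask, years) {
  do.call(rbind, lapply(years, function(y) winter_mean(stack, mask, y)))
}

#' Temporal trend in winter NDVI
#'
#' Ordinary least squares of NDVI on calendar year, optionally with a
#' quadratic year term. Both terms are entered raw (uncentered), matching the
#' coefficient scale conventionally reported for such trends; the fit itself
#' is computed on centered years for conditioning and the coefficients are
#' back-transformed exactly. A Durbin-Watson statistic is reported as a
#' temporal-autocorrelation diagnostic but plays no role in the p-values,
#' which are plain two-sided OLS t-tests.
#'
#' @param series Data frame with columns `year` and `ndvi`.
#' @param quadratic Include a `year^2` term.
#' @return A `trend_fit`: data frame of terms (`estimate`, `se`, `p`) with
#'   attributes `r_squared`, `durbin_watson`, `n`.
#' @export
fit_trend <- function(series, quadratic = FALSE) {
  yr <- series$year
  y <- series$ndvi
  n <- length(y)
  if (length(unique(yr)) < 2L) stop("year is constant: trend undefined")
  if (n < (if (quadratic) 4L else 3L)) stop("too few years for this model")
  yc <- yr - mean(yr)
  fit <- if (quadratic) stats::lm(y ~ yc + I(yc^2)) else stats::lm(y ~ yc)
  cf <- stats::coef(fit)
  # covariance computed directly (stats::vcov warns on perfect fits)
  X <- stats::model.matrix(fit)
  s2 <- sum(stats::residuals(fit)^2) / fit$df.residual
  V <- chol2inv(chol(crossprod(X))) * s2
  m <- mean(yr)
  if (quadratic) {
    # back-transform (b0 + b1*yc + b2*yc^2) to raw-year coefficients
    A <- rbind(c(1, -m, m^2), c(0, 1, -2 * m), c(0, 0, 1))
    est <- as.vector(A %*% cf)
    se <- sqrt(diag(A %*% V %*% t(A)))
    terms <- c("(Intercept)", "year", "year^2")
  } else {
    A <- rbind(c(1, -m), c(0, 1))
    est <- as.vector(A %*% cf)
    se <- sqrt(diag(A %*% V %*% t(A)))
    terms <- c("(Intercept)", "year")
  }
  df <- fit$df.residual
  p <- 2 * stats::pt(abs(est / se), df, lower.tail = FALSE)
  res <- stats::residuals(fit)
  dw <- sum(diff(res)^2) / sum(res^2)
  out <- data.frame(term = terms, estimate = est, se = se, p = p)
  # a constant series has zero total sum of squares: define R^2 = 0
  tss <- sum((y - mean(y))^2)
  attr(out, "r_squared") <- if (tss == 0) 0 else 1 - sum(res^2) / tss
  attr(out, "durbin_watson") <- dw
  attr(out, "n") <- n
  class(out) <- c("trend_fit", "data.frame")
  out
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("OLS trend in winter NDVI\n")
  print.data.frame(cbind(x[1], round(x[-1], 5)), row.names = FALSE)
  cat(sprintf("R^2 = %.3f, Durbin-Watson = %.2f, n = %d\n",
              attr(x, "r_squared"), attr(x, "durbin_watson"), attr(x, "n")))
  invisible(x)
}

#' Partition a wintering area by biome
#'
#' Splits a winter mask by the classes of a co-registered land-cover raster.
#' Unknown class codes (NA or not in `class_names`) are collected under
#' `"other"`. The per-biome masks partition the input mask exactly.
#'
#' @param mask A `winter_mask` or logical matrix.
#' @param landcover Integer/numeric matrix of class codes on the same grid,
#'   or a list with `grid` and `values`.
#' @param class_names Optional named character vector mapping codes to biome
#'   names (e.g. `c("2" = "evergreen_broadleaf", "8" = "woody_savanna")`).
#' @param grid The `grid_spec` (required when `mask` is a bare matrix and
#'   `landcover` carries no grid).
#' @return Named list of `winter_mask`s, one per biome present in the mask.
#' @export
stratify_by_biome <- function(mask, landcover, class_names = NULL,
                              grid = NULL) {
  if (inherits(mask, "winter_mask")) {
    g <- mask$grid; m <- mask$mask
    p <- mask$p; nind <- mask$n_individuals
  } else {
    g <- grid; m <- mask; p <- NA_real_; nind <- NA_integer_
  }
  lc <- if (is.list(landcover)) landcover$values else landcover
  stopifnot(!is.null(g), all(dim(lc) == dim(m)))
  codes <- lc[m]
  labels <- as.character(codes)
  if (!is.null(class_names)) {
    labels <- unname(class_names[labels])
  }
  labels[is.na(labels)] <- "other"
  area <- pixel_area_km2(g)
  out <- list()
  for (b in unique(labels)) {
    mb <- matrix(FALSE, g$nrow, g$ncol)
    mb[m][labels == b] <- TRUE
    out[[b]] <- structure(list(grid = g, mask = mb, p = p,
                               area_km2 = sum(area[mb]),
                               n_individuals = nind, biome = b),
                          class = "winter_mask")
  }
  out
}
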