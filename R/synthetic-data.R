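#' Synthetic feather isoscapes
#'
#' Generates three co-registered rasters of expected feather isotope values
#' (d2H in permil VSMOW, d13C in permil VPDB, d15N in permil air) as a planar
#' gradient plus a smooth Gaussian random field. These are stand-ins for
#' published feather isoscapes: they reproduce the *structure* the assignment
#' machinery needs (broad spatial gradients, spatially correlated residual
#' texture), not the geography of any real isoscape.
#'
#' @param grid A [grid_spec()].
#' @param gradients Named list with one entry per layer (`d2H`, `d13C`,
#'   `d15N`), each `c(intercept, per_deg_lat, per_deg_lon)` evaluated at the
#'   pixel-center coordinates.
#' @param noise_sd Named numeric: SD of the smooth random field added to each
#'   layer (same names). The field is rescaled so its sample SD over the grid
#'   equals `noise_sd` exactly.
#' @param smooth_px Gaussian smoothing length of the noise field, in pixels.
#' @param mask Optional logical validity matrix (default: all pixels valid).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @return An `isoscape_set`: list with `grid`, `layers` (named list of three
#'   matrices), `mask`.
#' @export
generate_isoscapes <- function(grid,
                               gradients = list(d2H = c(-30, -1.0, 0.2),
                                                d13C = c(-22, 0.15, -0.05),
                                                d15N = c(8, -0.1, 0.1)),
                               noise_sd = c(d2H = 8, d13C = 1.5, d15N = 1.5),
                               smooth_px = 5, mask = NULL, seed = 1) {
  stopifnot(all(c("d2H", "d13C", "d15N") %in% names(gradients)),
            all(noise_sd >= 0))
  if (is.null(mask)) mask <- matrix(TRUE, grid$nrow, grid$ncol)
  ctr <- grid_centers(grid)
  set.seed(seed)
  layers <- list()
  for (nm in c("d2H", "d13C", "d15N")) {
    g <- gradients[[nm]]
    base <- g[1] + g[2] * ctr$lat_mat + g[3] * ctr$lon_mat
    sdv <- noise_sd[[nm]]
    if (sdv > 0) {
      z <- matrix(stats::rnorm(grid$nrow * grid$ncol), grid$nrow, grid$ncol)
      z <- gaussian_smooth(z, smooth_px)
      z <- z - mean(z)
      s <- stats::sd(as.vector(z))
      if (s > 0) z <- z * (sdv / s)
      base <- base + z
    }
    base[!mask] <- NA_real_
    layers[[nm]] <- base
  }
  structure(list(grid = grid, layers = layers, mask = mask),
            class = "isoscape_set")
}

# separable Gaussian blur with reflecting edges
gaussian_smooth <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  smooth1 <- function(v) {
    n <- length(v)
    vv <- v[pmin(pmax(seq(-r + 1, n + r), 1), n)]  # clamp-pad the ends
    as.numeric(stats::filter(vv, k, sides = 2))[(r + 1):(r + n)]
  }
  m2 <- apply(m, 2, smooth1)
  t(apply(m2, 1, smooth1))
}

#' @export
print.isoscape_set <- function(x, ...) {
  cat(sprintf("isoscape_set: layers %s on %d x %d grid (%d valid pixels)\n",
              paste(names(x$layers), collapse = "/"),
              x$grid$nrow, x$grid$ncol, sum(x$mask)))
  invisible(x)
}

# look up the three isoscape values at point locations (lat, lon vectors);
# errors if any point falls outside the grid or on a masked pixel
isoscape_at <- function(iso, lat, lon) {
  g <- iso$grid
  i <- ceiling((g$lat_max - lat) / g$resolution - 1e-9)
  j <- ceiling((lon - g$lon_min) / g$resolution - 1e-9)
  bad <- i < 1 | i > g$nrow | j < 1 | j > g$ncol
  if (any(bad)) stop("origin outside the isoscape extent")
  k <- cbind(i, j)
  if (any(!iso$mask[k])) stop("origin on a masked isoscape pixel")
  cbind(d2H = iso$layers$d2H[k], d13C = iso$layers$d13C[k],
        d15N = iso$layers$d15N[k])
}

#' Synthetic ringing recoveries
#'
#' Simulates ring-recovery pairs for a migratory population: a breeding
#' location uniform in a European breeding box, a migration bearing drawn from
#' a von Mises distribution, a migration distance drawn uniformly, and the
#' winter location obtained by projecting along the great circle. Draws whose
#' winter point falls outside the winter box are rejected and redrawn.
#'
#' @param n Number of recoveries.
#' @param breeding_box,winter_box Named numeric vectors
#'   `c(lat_min, lat_max, lon_min, lon_max)` in degrees. Defaults: breeding
#'   36-66N, 5-15E (a longitude buffer around Denmark); winter 35S-15N,
#'   17W-42E (the sub-Saharan winter range).
#' @param mu,kappa von Mises mean bearing (degrees) and concentration of the
#'   migration direction.
#' @param range_km Length-2 vector: uniform bounds of migration distance.
#' @param max_tries Retry bound per recovery before erroring (guards against
#'   box/bearing combinations under which rejection never terminates).
#' @param seed Integer seed.
#' @return Data frame with columns `breeding_lat`, `breeding_lon`,
#'   `winter_lat`, `winter_lon`, `direction_known`.
#' @export
generate_ringing_recoveries <- function(n,
                                        breeding_box = c(lat_min = 36, lat_max = 66,
                                                         lon_min = 5, lon_max = 15),
                                        winter_box = c(lat_min = -35, lat_max = 15,
                                                       lon_min = -17, lon_max = 42),
                                        mu = 170, kappa = 4,
                                        range_km = c(4000, 10000),
                                        max_tries = 1000, seed = 1) {
  stopifnot(n >= 1, kappa >= 0)
  check_box <- function(b) {
    if (b["lat_min"] >= b["lat_max"] || b["lon_min"] >= b["lon_max"])
      stop("empty box")
  }
  check_box(breeding_box); check_box(winter_box)
  set.seed(seed)
  out <- matrix(NA_real_, n, 4)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      blat <- stats::runif(1, breeding_box["lat_min"], breeding_box["lat_max"])
      blon <- stats::runif(1, breeding_box["lon_min"], breeding_box["lon_max"])
      brg <- rvonmises_deg(1, mu, kappa)
      dist <- stats::runif(1, range_km[1], range_km[2])
      w <- destination_point(c(blat, blon), brg, dist)
      if (w[1] >= winter_box["lat_min"] && w[1] <= winter_box["lat_max"] &&
          w[2] >= winter_box["lon_min"] && w[2] <= winter_box["lon_max"]) {
        out[i, ] <- c(blat, blon, w[1], w[2])
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("rejection sampling did not terminate within max_tries; ",
                  "check that bearings from the breeding box can reach the winter box")
  }
  data.frame(breeding_lat = out[, 1], breeding_lon = out[, 2],
             winter_lat = out[, 3], winter_lon = out[, 4],
             direction_known = TRUE)
}

# spherical direct problem: destination from start point, initial bearing
# (degrees) and distance (km) on a 6371 km sphere
destination_point <- function(origin, bearing_deg, dist_km, R = 6371) {
  phi1 <- origin[1] * pi / 180; lam1 <- origin[2] * pi / 180
  th <- bearing_deg * pi / 180; d <- dist_km / R
  phi2 <- asin(sin(phi1) * cos(d) + cos(phi1) * sin(d) * cos(th))
  lam2 <- lam1 + atan2(sin(th) * sin(d) * cos(phi1),
                       cos(d) - sin(phi1) * sin(phi2))
  lon <- ((lam2 * 180 / pi + 180) %% 360) - 180
  c(lat = phi2 * 180 / pi, lon = lon)
}

#' Synthetic feather isotope samples
#'
#' Draws individuals with known true moult origins, reads the expected isotope
#' triplet off the isoscapes at each origin, and adds correlated multivariate
#' normal residual noise. Cells are then censored independently per isotope at
#' rate `missing_rate`; a sample that would lose all three values has its
#' missingness pattern redrawn, since a feather with no measurement at all
#' would never enter an assignment data set.
#'
#' @param n Number of samples.
#' @param origin_sampler Function `n -> matrix/data.frame` with columns
#'   `lat`, `lon` giving true origins, or a named box
#'   `c(lat_min, lat_max, lon_min, lon_max)` sampled uniformly.
#' @param isoscapes An `isoscape_set`.
#' @param residual_cov 3x3 symmetric PSD covariance of the residuals, in
#'   permil^2, ordered (d2H, d13C, d15N).
#' @param missing_rate Probability each isotope cell is missing (in [0, 1)).
#' @param seed Integer seed.
#' @return Data frame with `individual_id`, `d2H`, `d13C`, `d15N` (NA where
#'   missing), `true_lat`, `true_lon`.
#' @export
generate_feather_samples <- function(n, origin_sampler, isoscapes,
                                     residual_cov = diag(c(64, 2.25, 2.25)),
                                     missing_rate = 0, seed = 1) {
  stopifnot(missing_rate >= 0, missing_rate < 1)
  residual_cov <- as.matrix(residual_cov)
  if (!isTRUE(all.equal(residual_cov, t(residual_cov))))
    stop("residual_cov must be symmetric")
  ev <- eigen(residual_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) stop("residual_cov must be PSD")
  set.seed(seed)
  if (is.numeric(origin_sampler)) {
    box <- origin_sampler
    origin_sampler <- function(m)
      cbind(lat = stats::runif(m, box["lat_min"], box["lat_max"]),
            lon = stats::runif(m, box["lon_min"], box["lon_max"]))
  }
  org <- as.matrix(as.data.frame(origin_sampler(n))[, c("lat", "lon")])
  mu <- isoscape_at(isoscapes, org[, "lat"], org[, "lon"])
  noise <- mvrnorm_psd(n, residual_cov)
  vals <- mu + noise
  if (missing_rate > 0) {
    miss <- matrix(stats::runif(n * 3) < missing_rate, n, 3)
    allm <- rowSums(miss) == 3L
    while (any(allm)) {
      miss[allm, ] <- stats::runif(sum(allm) * 3) < missing_rate
      allm <- rowSums(miss) == 3L
    }
    vals[miss] <- NA_real_
  }
  data.frame(individual_id = sprintf("bird_%04d", seq_len(n)),
             d2H = vals[, 1], d13C = vals[, 2], d15N = vals[, 3],
             true_lat = org[, "lat"], true_lon = org[, "lon"])
}

# MVN draws allowing singular (PSD) covariance, via eigendecomposition
mvrnorm_psd <- function(n, sigma) {
  p <- nrow(sigma)
  e <- eigen(sigma, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  z <- matrix(stats::rnorm(n * p), n, p)
  z %*% (t(e$vectors) * sqrt(lam))
}

#' Synthetic twice-monthly NDVI stack
#'
#' Per-pixel NDVI composites on the 1st and 15th of every month, following
#' base + linear trend + a 12-month sinusoid + white noise, clipped to
#' [-1, 1], with a fraction of cells censored as missing. The sinusoid peaks
#' mid-January by default, mimicking the southern-hemisphere wet season that
#' makes the November-March winter window non-trivial.
#'
#' @param grid A [grid_spec()].
#' @param years Integer vector of calendar years to generate.
#' @param trend_per_year Linear NDVI trend per year.
#' @param base NDVI level at the first composite.
#' @param seasonal_amp Amplitude of the annual sinusoid.
#' @param peak_doy Day of year at which the sinusoid peaks (default 15).
#' @param noise_sd SD of white noise added per cell.
#' @param annual_sd SD of a mean-zero year-level offset shared by all
#'   composites and pixels of a calendar year (default 0), emulating
#'   interannual rainfall-driven variability; without it, spatial averages
#'   over many pixels are nearly identical across years.
#' @param gap_fraction Probability each cell is missing.
#' @param seed Integer seed.
#' @return An `ndvi_stack`: list with `grid`, `dates` (class `Date`, length
#'   T), `values` (array nrow x ncol x T, NA where missing).
#' @export
generate_ndvi_series <- function(grid, years, trend_per_year = 0.001,
                                 base = 0.5, seasonal_amp = 0.1,
                                 peak_doy = 15, noise_sd = 0.02,
                                 annual_sd = 0, gap_fraction = 0, seed = 1) {
  stopifnot(gap_fraction >= 0, gap_fraction < 1, noise_sd >= 0,
            annual_sd >= 0)
  set.seed(seed)
  dates <- as.Date(unlist(lapply(years, function(y)
    sprintf("%d-%02d-%02d", y, rep(1:12, each = 2), c(1, 15)))))
  t0 <- dates[1]
  tyr <- as.numeric(dates - t0) / 365.25
  doy <- as.numeric(format(dates, "%j"))
  seas <- seasonal_amp * cos(2 * pi * (doy - peak_doy) / 365.25)
  yr_of <- as.integer(format(dates, "%Y"))
  annual <- stats::setNames(stats::rnorm(length(years), 0, annual_sd),
                            years)
  np <- grid$nrow * grid$ncol
  vals <- array(NA_real_, c(grid$nrow, grid$ncol, length(dates)))
  for (k in seq_along(dates)) {
    mu <- base + trend_per_year * tyr[k] + seas[k] +
      annual[as.character(yr_of[k])]
    x <- mu + if (noise_sd > 0) stats::rnorm(np, 0, noise_sd) else 0
    x <- pmin(1, pmax(-1, x))
    if (gap_fraction > 0) x[stats::runif(np) < gap_fraction] <- NA_real_
    vals[, , k] <- x
  }
  structure(list(grid = grid, dates = dates, values = vals),
            class = "ndvi_stack")
}

#' @export
print.ndvi_stack <- function(x, ...) {
  cat(sprintf("ndvi_stack: %d composites (%s .. %s) on %d x %d grid, %.1f%% missing\n",
              length(x$dates), min(x$dates), max(x$dates),
              x$grid$nrow, x$grid$ncol, 100 * mean(is.na(x$values))))
  invisible(x)
}

#' Ground-truth coefficients of the breeding carry-over generative model
#'
#' Bundles every parameter of the synthetic breeding-record generator: the
#' raw-scale structural coefficients of the sex-specific causal diagrams
#' (winter NDVI, age and their interaction plus tail length acting on breeding
#' date; breeding date acting on clutch size for females and on fledgling
#' number for males; clutch size acting on fledgling number for females),
#' random-intercept SDs for ring, colony and year, residual SDs, and the
#' residual correlation of body mass with each reproductive variable.
#'
#' Defaults encode the direction and rough magnitude of the effects reported
#' for Danish barn swallows: breeding date responds to winter NDVI much more
#' strongly in old birds than in yearlings (positive age x NDVI interaction
#' against a negative age main effect), later breeding lowers reproductive
#' output, and longer-tailed birds breed earlier. On these defaults a shift
#' from poor (NDVI 0.6) to good (NDVI 0.675) winters moves a yearling male's
#' expected date by about -1 day but a five-year-old's by about +10 days.
#'
#' @param sex `"male"` or `"female"`; selects the default coefficient set.
#' @param beta_date Named coefficients on breeding date:
#'   `intercept`, `ndvi`, `age`, `age_ndvi`, `tail`.
#' @param gamma_clutch Female-only coefficients on clutch size:
#'   `intercept`, `date`, `age`, `tail`.
#' @param gamma_fledge Coefficients on fledgling number: females
#'   `intercept`, `clutch`, `age`, `tail`; males `intercept`, `date`, `age`,
#'   `tail`.
#' @param re_sd Named list of length-3 vectors `c(ring, colony, year)` of
#'   random-intercept SDs per response (`date`, `clutch`, `fledge`).
#' @param resid_sd Named residual SDs per response.
#' @param mass_cor Residual correlation of body mass with each reproductive
#'   variable (`date`, `clutch`, `fledge`); squared values must sum to <= 1.
#' @param tail_mean,tail_sd,mass_mean,mass_sd Morphology distribution (mm, g).
#' @return An object of class `causal_truth` (a named list of the above).
#' @export
causal_truth <- function(sex = c("male", "female"),
                         beta_date = NULL, gamma_clutch = NULL,
                         gamma_fledge = NULL,
                         re_sd = list(date = c(ring = 3, colony = 2, year = 3),
                                      clutch = c(ring = 0.25, colony = 0.15, year = 0.2),
                                      fledge = c(ring = 0.25, colony = 0.15, year = 0.2)),
                         resid_sd = c(date = 6, clutch = 0.7, fledge = 0.8),
                         mass_cor = c(date = 0.05, clutch = 0, fledge = 0),
                         tail_mean = NULL, tail_sd = 5,
                         mass_mean = 20, mass_sd = 1.5) {
  sex <- match.arg(sex)
  if (is.null(beta_date))
    beta_date <- if (sex == "male")
      c(intercept = 89.5, ndvi = -50, age = -25.5, age_ndvi = 36.667, tail = -0.2)
    else
      c(intercept = 70.8, ndvi = -33, age = -17, age_ndvi = 24, tail = -0.2)
  if (is.null(gamma_clutch))
    gamma_clutch <- c(intercept = 5.515, date = -0.03, age = 0.005, tail = 0.002)
  if (is.null(gamma_fledge))
    gamma_fledge <- if (sex == "male")
      c(intercept = 4.88, date = -0.0371, age = 0.02, tail = 0.004)
    else
      c(intercept = 0.92, clutch = 0.6, age = 0.02, tail = 0.002)
  if (is.null(tail_mean)) tail_mean <- if (sex == "male") 105 else 90
  stopifnot(all(unlist(re_sd) >= 0), all(resid_sd >= 0),
            all(abs(mass_cor) <= 1), sum(mass_cor^2) <= 1)
  structure(list(sex = sex, beta_date = beta_date,
                 gamma_clutch = gamma_clutch, gamma_fledge = gamma_fledge,
                 re_sd = re_sd, resid_sd = resid_sd, mass_cor = mass_cor,
                 tail_mean = tail_mean, tail_sd = tail_sd,
                 mass_mean = mass_mean, mass_sd = mass_sd),
            class = "causal_truth")
}

#' Synthetic longitudinal breeding records
#'
#' Simulates a ringed breeding population followed over years. Individuals
#' recruit at age 1 in a random study year, return to the same colony every
#' year, and survive from one year to the next with probability
#' `age_survival` (up to age 8), producing the declining age distribution of
#' long-term swallow data sets. Each bird-year record carries the year's
#' winter NDVI and responses generated from the causal model in `truth`:
#' breeding date from NDVI, age, their interaction and tail length; then, per
#' the sex-specific diagram, clutch size (females) and fledgling number, all
#' with crossed ring/colony/year random intercepts. Clutch and fledgling
#' counts are generated as Gaussians, rounded, floored at zero, and
#' fledglings are capped at clutch size for females. Body mass is generated
#' with the stated residual correlation to each reproductive variable.
#'
#' @param truth A [causal_truth()].
#' @param n_individuals Number of recruits to simulate (one sex per call;
#'   `truth$sex` fixes the sex).
#' @param years Integer vector of study years.
#' @param ndvi_by_year Named numeric: winter NDVI covariate per year (names =
#'   years; must cover `years`).
#' @param age_survival Annual survival probability (default 0.52, matching a
#'   roughly halving of records from age 1 to age 2).
#' @param n_colonies Number of breeding colonies (default 40).
#' @param seed Integer seed.
#' @return Data frame of class `breeding_records` with columns `ring_id`,
#'   `colony_id`, `year`, `sex`, `age`, `tail_length`, `body_mass`,
#'   `breeding_date`, `clutch_size` (NA for males), `fledglings`,
#'   `winter_ndvi`.
#' @export
generate_breeding_records <- function(truth, n_individuals, years,
                                      ndvi_by_year, age_survival = 0.52,
                                      n_colonies = 40, seed = 1) {
  stopifnot(inherits(truth, "causal_truth"),
            age_survival >= 0, age_survival <= 1)
  if (!all(as.character(years) %in% names(ndvi_by_year)))
    stop("ndvi_by_year must cover every simulated year")
  set.seed(seed)
  max_age <- 8L
  recruit_year <- sample(years, n_individuals, replace = TRUE)
  colony <- sample.int(n_colonies, n_individuals, replace = TRUE)
  tail_i <- stats::rnorm(n_individuals, truth$tail_mean, truth$tail_sd)
  # lifespan: geometric number of survivals, capped at max_age
  n_surv <- if (age_survival == 0) rep(0L, n_individuals)
            else if (age_survival == 1) rep(max_age - 1L, n_individuals)
            else pmin(stats::rgeom(n_individuals, 1 - age_survival), max_age - 1L)
  rows <- list()
  for (i in seq_len(n_individuals)) {
    ages <- 1:(1 + n_surv[i])
    yrs <- recruit_year[i] + ages - 1L
    keep <- yrs <= max(years)
    if (!any(keep)) next
    rows[[i]] <- data.frame(ring = i, age = ages[keep], year = yrs[keep])
  }
  d <- do.call(rbind, rows)
  n <- nrow(d)
  u_ring <- lapply(truth$re_sd, function(s) stats::rnorm(n_individuals, 0, s["ring"]))
  u_col <- lapply(truth$re_sd, function(s) stats::rnorm(n_colonies, 0, s["colony"]))
  yr_levels <- sort(unique(d$year))
  u_year <- lapply(truth$re_sd, function(s)
    stats::setNames(stats::rnorm(length(yr_levels), 0, s["year"]), yr_levels))
  ndvi <- unname(ndvi_by_year[as.character(d$year)])
  tail <- tail_i[d$ring]
  col <- colony[d$ring]
  b <- truth$beta_date
  eps_date <- stats::rnorm(n, 0, truth$resid_sd["date"])
  date_raw <- b["intercept"] + b["ndvi"] * ndvi + b["age"] * d$age +
    b["age_ndvi"] * d$age * ndvi + b["tail"] * tail +
    u_ring$date[d$ring] + u_col$date[col] + u_year$date[as.character(d$year)] +
    eps_date
  date <- round(date_raw)
  female <- truth$sex == "female"
  if (female) {
    gc <- truth$gamma_clutch
    eps_clutch <- stats::rnorm(n, 0, truth$resid_sd["clutch"])
    clutch_raw <- gc["intercept"] + gc["date"] * date + gc["age"] * d$age +
      gc["tail"] * tail + u_ring$clutch[d$ring] + u_col$clutch[col] +
      u_year$clutch[as.character(d$year)] + eps_clutch
    clutch <- pmax(0, round(clutch_raw))
    gf <- truth$gamma_fledge
    eps_fledge <- stats::rnorm(n, 0, truth$resid_sd["fledge"])
    fled_raw <- gf["intercept"] + gf["clutch"] * clutch + gf["age"] * d$age +
      gf["tail"] * tail + u_ring$fledge[d$ring] + u_col$fledge[col] +
      u_year$fledge[as.character(d$year)] + eps_fledge
    fledge <- pmin(clutch, pmax(0, round(fled_raw)))
  } else {
    clutch <- rep(NA_real_, n)
    eps_clutch <- NULL
    gf <- truth$gamma_fledge
    eps_fledge <- stats::rnorm(n, 0, truth$resid_sd["fledge"])
    fled_raw <- gf["intercept"] + gf["date"] * date + gf["age"] * d$age +
      gf["tail"] * tail + u_ring$fledge[d$ring] + u_col$fledge[col] +
      u_year$fledge[as.character(d$year)] + eps_fledge
    fledge <- pmax(0, round(fled_raw))
  }
  # body mass: shared-driver construction giving the stated residual
  # correlation with each reproductive variable's structural residual
  rho <- truth$mass_cor
  z_date <- eps_date / max(truth$resid_sd["date"], 1e-12)
  z_clutch <- if (female) eps_clutch / max(truth$resid_sd["clutch"], 1e-12) else 0
  z_fledge <- eps_fledge / max(truth$resid_sd["fledge"], 1e-12)
  lin <- rho["date"] * z_date + (if (female) rho["clutch"] * z_clutch else 0) +
    rho["fledge"] * z_fledge
  resvar <- 1 - rho["date"]^2 - (if (female) rho["clutch"]^2 else 0) -
    rho["fledge"]^2
  mass <- truth$mass_mean + truth$mass_sd *
    (lin + sqrt(max(resvar, 0)) * stats::rnorm(n))
  out <- data.frame(
    ring_id = sprintf("%s_%04d", substr(truth$sex, 1, 1), d$ring),
    colony_id = sprintf("col_%02d", col),
    year = d$year,
    sex = truth$sex,
    age = d$age,
    tail_length = tail,
    body_mass = mass,
    breeding_date = date,
    clutch_size = clutch,
    fledglings = fledge,
    winter_ndvi = ndvi)
  class(out) <- c("breeding_records", "data.frame")
  out
}
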