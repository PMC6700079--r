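years <- 1984:2013

test_that("standardization z-scores on the listwise-complete set", {
  d <- data.frame(x = c(1, 2, 3), y = c(10, 20, 40))
  s <- standardize(d, c("x", "y"))
  expect_equal(s$x, c(-1, 0, 1))  # SD with denominator n - 1
  expect_equal(mean(s$y), 0, tolerance = 1e-12)
  expect_equal(sd(s$y), 1, tolerance = 1e-12)
  # an already-standardized column is unchanged
  s2 <- standardize(s, c("x", "y"))
  expect_equal(s2$x, s$x, tolerance = 1e-12)
  # interaction: product of raw columns, then z-scored
  d3 <- data.frame(a = c(1, 2, 3, 4), b = c(2, 1, 3, 5))
  s3 <- standardize(d3, c("a", "b"), interactions = list(ab = c("a", "b")))
  expect_equal(s3$ab, as.vector(scale(d3$a * d3$b)))
  # listwise deletion
  d4 <- data.frame(x = c(1, NA, 3, 4), y = c(1, 2, NA, 4))
  expect_equal(nrow(standardize(d4, c("x", "y"))), 2L)
  expect_error(standardize(data.frame(x = rep(1, 5)), "x"), "zero variance")
})

test_that("degenerate mixed models reduce to OLS", {
  tr <- causal_truth("male",
                     re_sd = list(date = c(ring = 0, colony = 0, year = 0),
                                  clutch = c(ring = 0, colony = 0, year = 0),
                                  fledge = c(ring = 0, colony = 0, year = 0)),
                     resid_sd = c(date = 0, clutch = 0, fledge = 0))
  recs <- generate_breeding_records(tr, 400, years, ndvi_years(years, 3),
                                    seed = 5)
  model <- swallow_path_model("male")
  std <- standardize(recs, setdiff(model$variables,
                                   names(model$interactions)),
                     model$interactions)
  f <- suppressWarnings(fit_submodel(model, "breeding_date", std))
  ols <- lm(breeding_date ~ winter_ndvi + age_ndvi + age + tail_length, std)
  got <- setNames(f$coefficients$estimate, f$coefficients$term)
  expect_equal(got[names(coef(ols))], coef(ols), tolerance = 1e-6)
})

test_that("standardized path coefficients are recovered without bias", {
  # direct simulation of one structural equation with known standardized
  # coefficients; closed-form truth divides by the response's implied SD
  beta <- c(x1 = -0.075, x2 = 0.2, x3 = -0.2, x4 = -0.06)
  re_sd <- c(ring = 0.3, colony = 0.2, year = 0.3)
  sig <- 0.85
  sd_y <- sqrt(sum(beta^2) + sum(re_sd^2) + sig^2)
  truth_std <- beta / sd_y
  model <- path_model(list(y = c("x1", "x2", "x3", "x4")),
                      random = c("ring_id", "colony_id", "year"))
  set.seed(14)
  est <- matrix(NA_real_, 200, 4)
  for (r in 1:200) {
    n <- 2000
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                    x4 = rnorm(n),
                    ring_id = sample(700, n, TRUE),
                    colony_id = sample(40, n, TRUE),
                    year = sample(30, n, TRUE))
    d$y <- as.matrix(d[, 1:4]) %*% beta +
      rnorm(700, 0, re_sd["ring"])[d$ring_id] +
      rnorm(40, 0, re_sd["colony"])[d$colony_id] +
      rnorm(30, 0, re_sd["year"])[d$year] + rnorm(n, 0, sig)
    std <- standardize(d, c("y", "x1", "x2", "x3", "x4"))
    f <- suppressWarnings(fit_submodel(model, "y", std))
    est[r, ] <- f$coefficients$estimate[match(names(beta),
                                              f$coefficients$term)]
  }
  expect_true(all(abs(colMeans(est) - truth_std) < 0.01))
})

test_that("Wald p-values are calibrated under the null", {
  model <- path_model(list(y = "x"), random = c("ring_id", "colony_id",
                                                "year"))
  set.seed(15)
  rej <- logical(500)
  for (r in 1:500) {
    n <- 600
    d <- data.frame(x = rnorm(n),
                    ring_id = sample(200, n, TRUE),
                    colony_id = sample(40, n, TRUE),
                    year = sample(30, n, TRUE))
    d$y <- rnorm(200, 0, 0.4)[d$ring_id] + rnorm(40, 0, 0.3)[d$colony_id] +
      rnorm(30, 0, 0.4)[d$year] + rnorm(n)
    std <- standardize(d, c("y", "x"))
    f <- suppressWarnings(fit_submodel(model, "y", std))
    rej[r] <- f$coefficients$p[f$coefficients$term == "x"] < 0.05
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("basis sets enumerate the DAG's independence claims", {
  # saturated DAG: no claims, df 0
  sat <- path_model(list(y = "x", z = c("x", "y")))
  expect_length(basis_set(sat), 0L)

  # chain x -> y -> z: the single textbook claim z independent of x given y
  chain <- path_model(list(y = "x", z = "y"))
  bs <- basis_set(chain)
  expect_length(bs, 1L)
  expect_equal(bs[[1]]$later, "z")
  expect_equal(bs[[1]]$earlier, "x")
  expect_equal(bs[[1]]$conditioning, "y")

  # the sex-specific carry-over diagrams: 5 female claims (df 10) and
  # 2 male claims (df 4), with body-mass correlated pairs excluded
  expect_length(basis_set(swallow_path_model("female")), 5L)
  expect_length(basis_set(swallow_path_model("male")), 2L)

  expect_error(path_model(list(y = "x", x = "y")), "cycle")
  expect_error(path_model(list(y = character(0))), "at least one predictor")
  expect_error(path_model(list(y = "x"), correlated = list(c("x", "y"))),
               "also a directed edge")
})

test_that("the d-separation test combines claim p-values into Fisher's C", {
  truth <- causal_truth("female")
  recs <- generate_breeding_records(truth, 600, years,
                                    ndvi_years(years, 8), seed = 21)
  model <- swallow_path_model("female")
  std <- standardize(recs, setdiff(model$variables,
                                   names(model$interactions)),
                     model$interactions)
  ds <- suppressWarnings(dsep_test(model, std))
  expect_equal(nrow(ds$claims), 5L)
  expect_equal(ds$df, 10L)
  expect_equal(ds$fisher_c, -2 * sum(log(ds$claims$p)), tolerance = 1e-12)
  expect_equal(ds$p_value, chi_square_upper_tail(ds$fisher_c, 10L),
               tolerance = 1e-12)
  expect_true(all(ds$claims$p >= 0 & ds$claims$p <= 1))
})

test_that("a strong missing edge drives d-separation rejection", {
  model <- swallow_path_model("male")
  truth <- causal_truth("male")
  set.seed(23)
  rej <- logical(25)
  for (r in 1:25) {
    nd <- ndvi_years(years, 3000 + r)
    recs <- generate_breeding_records(truth, 1450, years, nd,
                                      seed = 4000 + r)
    recs <- recs[seq_len(min(2000, nrow(recs))), ]
    # inject an NDVI -> fledglings edge absent from the fitted DAG
    recs$fledglings <- recs$fledglings + 40 * (recs$winter_ndvi - 0.6375)
    std <- standardize(recs, setdiff(model$variables,
                                     names(model$interactions)),
                       model$interactions)
    ds <- suppressWarnings(dsep_test(model, std))
    rej[r] <- ds$p_value < 0.05
  }
  expect_gt(mean(rej), 0.8)
})

test_that("indirect effects multiply standardized path coefficients", {
  truth <- causal_truth("male")
  nd <- ndvi_years(years, 31)
  recs <- generate_breeding_records(truth, 5000, years, nd, seed = 99)
  fit <- suppressWarnings(carryover_sem(swallow_path_model("male"), recs,
                                        dsep = FALSE))
  ie <- indirect_effect(fit$fits,
                        c("age_ndvi", "breeding_date", "fledglings"))
  # internal consistency: product of the two fitted coefficients
  b1 <- with(fit$fits$breeding_date$coefficients,
             estimate[term == "age_ndvi"])
  b2 <- with(fit$fits$fledglings$coefficients,
             estimate[term == "breeding_date"])
  expect_equal(ie$value, b1 * b2, tolerance = 1e-12)
  expect_true(ie$reportable)

  # path-tracing oracle: closed-form standardized product of the generative
  # system, using the realized SDs of the analysis set
  raw <- attr(fit$data, "raw")
  exp1 <- truth$beta_date["age_ndvi"] * sd(raw$age_ndvi) /
    sd(raw$breeding_date)
  exp2 <- truth$gamma_fledge["date"] * sd(raw$breeding_date) /
    sd(raw$fledglings)
  expect_equal(ie$value, unname(exp1 * exp2), tolerance = 0.1)

  expect_error(indirect_effect(fit$fits,
                               c("winter_ndvi", "fledglings")),
               "not present")
})

test_that("prediction surfaces propagate the age x NDVI interaction", {
  # interaction present: age-related spread of breeding date is larger in
  # poor winters than good winters, and the response to NDVI at old ages is
  # monotonically increasing
  truth <- causal_truth("male")
  recs <- generate_breeding_records(truth, 3000, years,
                                    ndvi_years(years, 41), seed = 43)
  fit <- suppressWarnings(carryover_sem(swallow_path_model("male"), recs,
                                        dsep = FALSE))
  sf <- predict_surface(fit, "breeding_date", age = c(1, 5),
                        ndvi = c(0.6, 0.675))
  spread <- function(nd) {
    v <- sf$breeding_date[sf$winter_ndvi == nd]
    abs(diff(v))
  }
  expect_gt(spread(0.6), spread(0.675))
  nd_grid <- predict_surface(fit, "breeding_date", age = 5,
                             ndvi = seq(0.6, 0.675, length.out = 8))
  expect_true(all(diff(nd_grid$breeding_date) > 0))
  # fledgling predictions inherit the pattern through the date path
  sff <- predict_surface(fit, "fledglings", age = c(1, 5),
                         ndvi = c(0.6, 0.675))
  fspread <- function(nd) abs(diff(sff$fledglings[sff$winter_ndvi == nd]))
  expect_gt(fspread(0.6), fspread(0.675))

  # additivity: with the interaction coefficient exactly zero, the
  # predicted age slope is identical at every NDVI
  fit0 <- fit
  cf0 <- fit0$fits$breeding_date$coefficients
  cf0$estimate[cf0$term == "age_ndvi"] <- 0
  fit0$fits$breeding_date$coefficients <- cf0
  sf0 <- predict_surface(fit0, "breeding_date", age = c(1, 5),
                         ndvi = c(0.6, 0.675))
  s_lo <- diff(sf0$breeding_date[sf0$winter_ndvi == 0.6])
  s_hi <- diff(sf0$breeding_date[sf0$winter_ndvi == 0.675])
  expect_equal(s_lo, s_hi, tolerance = 1e-9)

  # extrapolation is flagged, not refused
  sx <- predict_surface(fit, "breeding_date", age = 30, ndvi = 0.64)
  expect_true(any(attr(sx, "extrapolated")))
})

test_that("correlated errors recover the generative residual correlation", {
  slim <- path_model(list(breeding_date = c("winter_ndvi", "age_ndvi",
                                            "age", "tail_length")),
                     correlated = list(c("body_mass", "breeding_date")),
                     interactions = list(age_ndvi = c("age", "winter_ndvi")),
                     sex = "female")
  truth <- causal_truth("female", mass_cor = c(date = 0.3, clutch = 0,
                                               fledge = 0))
  null_truth <- causal_truth("female", mass_cor = c(date = 0, clutch = 0,
                                                    fledge = 0))
  set.seed(51)
  est <- nullest <- numeric(100)
  for (r in 1:100) {
    recs <- generate_breeding_records(truth, 1450, years,
                                      ndvi_years(years, 5000 + r),
                                      seed = 6000 + r)
    recs <- recs[seq_len(min(2000, nrow(recs))), ]
    f <- suppressWarnings(carryover_sem(slim, recs, dsep = FALSE))
    est[r] <- f$correlated[[1]]$estimate
    recs0 <- generate_breeding_records(null_truth, 1450, years,
                                       ndvi_years(years, 7000 + r),
                                       seed = 8000 + r)
    recs0 <- recs0[seq_len(min(2000, nrow(recs0))), ]
    f0 <- suppressWarnings(carryover_sem(slim, recs0, dsep = FALSE))
    nullest[r] <- f0$correlated[[1]]$estimate
  }
  # attenuation from response rounding is below the stated bound
  expect_lt(abs(mean(est) - 0.3), 0.05)
  # null sampling bound: |r| < 0.07 in at least 95% of replicates
  expect_gte(mean(abs(nullest) < 0.07), 0.95)
})

test_that("the male pipeline equals the female pipeline with the clutch node removed", {
  female <- swallow_path_model("female")
  noclutch <- path_model(
    responses = list(
      breeding_date = female$responses$breeding_date,
      fledglings = c("breeding_date", "age", "tail_length")),
    correlated = list(c("body_mass", "breeding_date"),
                      c("body_mass", "fledglings")),
    interactions = female$interactions,
    random = female$random, sex = "male")
  truth <- causal_truth("male")
  recs <- generate_breeding_records(truth, 800, years,
                                    ndvi_years(years, 61), seed = 62)
  f1 <- suppressWarnings(carryover_sem(swallow_path_model("male"), recs))
  f2 <- suppressWarnings(carryover_sem(noclutch, recs))
  expect_equal(summary(f1)$table, summary(f2)$table, tolerance = 1e-12)
  expect_equal(f1$dsep$fisher_c, f2$dsep$fisher_c, tolerance = 1e-12)
})

test_that("simulate() and residuals() methods are coherent with the fit", {
  truth <- causal_truth("male")
  recs <- generate_breeding_records(truth, 500, 2000:2009,
                                    ndvi_years(2000:2009, 71), seed = 72)
  fit <- suppressWarnings(carryover_sem(swallow_path_model("male"), recs,
                                        dsep = FALSE))
  r <- residuals(fit)
  expect_named(r, c("breeding_date", "fledglings"))
  expect_length(r$breeding_date, fit$n)
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2L)
  expect_equal(nrow(sims[[1]]), fit$n)
  # simulated responses have roughly unit scale (inputs are standardized)
  expect_lt(abs(sd(sims[[1]]$breeding_date) - 1), 0.35)
})
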