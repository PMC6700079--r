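#' Specify a causal path model
#'
#' A path model is a DAG over observed variables, given as one predictor list
#' per endogenous (response) variable, plus bidirectional correlated-error
#' pairs, interaction-node definitions, and the crossed random factors under
#' which every sub-model and every d-separation claim is fitted.
#'
#' @param responses Named list: for each endogenous variable, the character
#'   vector of its parents.
#' @param correlated List of length-2 character vectors: variable pairs joined
#'   by a bidirectional (correlated-error) arc. Such pairs count as adjacent
#'   and are excluded from the d-separation basis set; a correlated pair may
#'   not also be a directed edge.
#' @param interactions Named list: for each interaction node, the two raw
#'   variables whose product defines it (the node is z-scored after the
#'   product is formed).
#' @param random Character vector of grouping factors fitted as crossed
#'   random intercepts in every sub-model (all are mandatory).
#' @param sex Optional tag carried through outputs.
#' @return An object of class `path_model`.
#' @seealso [swallow_path_model()] for the barn-swallow carry-over diagrams.
#' @export
path_model <- function(responses, correlated = list(),
                       interactions = list(),
                       random = c("ring_id", "colony_id", "year"),
                       sex = NULL) {
  stopifnot(is.list(responses), length(responses) >= 1L,
            !is.null(names(responses)))
  if (any(vapply(responses, length, 1L) == 0L))
    stop("every endogenous variable needs at least one predictor")
  vars <- unique(c(names(responses), unlist(responses),
                   unlist(correlated)))
  edges <- do.call(rbind, lapply(names(responses), function(r)
    data.frame(from = responses[[r]], to = r)))
  for (pair in correlated) {
    stopifnot(length(pair) == 2L)
    hit <- (edges$from == pair[1] & edges$to == pair[2]) |
      (edges$from == pair[2] & edges$to == pair[1])
    if (any(hit))
      stop("correlated-error pair (", paste(pair, collapse = ", "),
           ") is also a directed edge")
  }
  ord <- topo_order(vars, edges)  # errors on cycles
  structure(list(responses = responses, correlated = correlated,
                 interactions = interactions, random = random,
                 variables = vars, edges = edges, order = ord, sex = sex),
            class = "path_model")
}

# Kahn topological sort; exogenous variables first, stable by input order
topo_order <- function(vars, edges) {
  indeg <- stats::setNames(integer(length(vars)), vars)
  tab <- table(edges$to)
  indeg[names(tab)] <- as.integer(tab)
  out <- character(0)
  active <- edges
  repeat {
    free <- setdiff(vars[indeg == 0L], out)
    if (!length(free)) break
    out <- c(out, free)
    drop <- active$from %in% free
    for (v in active$to[drop]) indeg[v] <- indeg[v] - 1L
    active <- active[!drop, , drop = FALSE]
  }
  if (length(out) != length(vars)) stop("the path diagram contains a cycle")
  out
}

#' @export
print.path_model <- function(x, ...) {
  cat("path_model", if (!is.null(x$sex)) sprintf("(%s)", x$sex), "\n")
  for (r in names(x$responses))
    cat(" ", r, "~", paste(x$responses[[r]], collapse = " + "), "\n")
  for (p in x$correlated)
    cat("  ", p[1], "<->", p[2], "\n")
  cat("  random intercepts:", paste(x$random, collapse = ", "), "\n")
  invisible(x)
}

#' Barn-swallow carry-over path diagrams
#'
#' The sex-specific causal diagrams linking winter NDVI to first-brood
#' reproductive output. For females: NDVI, age, their interaction and tail
#' length act on breeding date; breeding date (with age and tail) on clutch
#' size; clutch size (with age and tail) on fledgling number. For males the
#' clutch-size node is removed (clutch size is determined by the female) and
#' breeding date acts on fledglings directly. Body mass is joined to every
#' reproductive variable by a correlated-error arc, since the direction of
#' causality between mass and reproduction is not identified in field data.
#' Ring, colony and year enter every sub-model as crossed random intercepts.
#'
#' @param sex `"female"` or `"male"`.
#' @return A [path_model()].
#' @export
swallow_path_model <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  date_preds <- c("winter_ndvi", "age_ndvi", "age", "tail_length")
  if (sex == "female") {
    responses <- list(
      breeding_date = date_preds,
      clutch_size = c("breeding_date", "age", "tail_length"),
      fledglings = c("clutch_size", "age", "tail_length"))
    correlated <- list(c("body_mass", "breeding_date"),
                       c("body_mass", "clutch_size"),
                       c("body_mass", "fledglings"))
  } else {
    responses <- list(
      breeding_date = date_preds,
      fledglings = c("breeding_date", "age", "tail_length"))
    correlated <- list(c("body_mass", "breeding_date"),
                       c("body_mass", "fledglings"))
  }
  path_model(responses, correlated,
             interactions = list(age_ndvi = c("age", "winter_ndvi")),
             random = c("ring_id", "colony_id", "year"),
             sex = sex)
}

#' Z-score model variables on the listwise-complete analysis set
#'
#' Standardizes each variable to mean 0, SD 1 (denominator n - 1) over the
#' rows complete on all requested variables. Interaction nodes are formed as
#' the product of the *raw* component variables and then z-scored themselves.
#'
#' @param data Data frame.
#' @param variables Character vector of columns to standardize.
#' @param interactions Named list as in [path_model()].
#' @return The listwise-complete data frame with standardized columns, plus
#'   attributes `centers` and `scales` (named vectors) and `raw` (the raw
#'   complete-case values of the standardized columns).
#' @export
standardize <- function(data, variables, interactions = list()) {
  for (nm in names(interactions)) {
    comp <- interactions[[nm]]
    data[[nm]] <- data[[comp[1]]] * data[[comp[2]]]
    if (!(nm %in% variables)) variables <- c(variables, nm)
  }
  keep <- stats::complete.cases(data[, variables, drop = FALSE])
  out <- data[keep, , drop = FALSE]
  raw <- out[, variables, drop = FALSE]
  centers <- scales <- stats::setNames(numeric(length(variables)), variables)
  for (v in variables) {
    x <- out[[v]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) stop("variable '", v, "' has zero variance")
    centers[v] <- mean(x)
    scales[v] <- s
    out[[v]] <- (x - mean(x)) / s
  }
  attr(out, "centers") <- centers
  attr(out, "scales") <- scales
  attr(out, "raw") <- raw
  out
}

# shared mixed-model machinery -------------------------------------------

lmer_ctrl <- function() lme4::lmerControl(calc.derivs = FALSE,
                                          check.conv.singular = "ignore")

fit_lmm <- function(response, predictors, data, random) {
  miss <- setdiff(random, names(data))
  if (length(miss))
    stop("random factor(s) ", paste(miss, collapse = ", "),
         " absent from data: crossed intercepts for ",
         paste(random, collapse = "/"), " are mandatory")
  for (r in random) data[[r]] <- factor(data[[r]])
  fml <- stats::as.formula(paste(
    response, "~", paste(predictors, collapse = " + "), "+",
    paste(sprintf("(1 | %s)", random), collapse = " + ")))
  fit <- lme4::lmer(fml, data = data, REML = TRUE, control = lmer_ctrl())
  if (lme4::isSingular(fit, tol = 1e-5))
    warning("singular fit for '", response,
            "': at least one random-intercept variance estimated at 0")
  fit
}

# Satterthwaite df for every fixed effect of an lmer REML fit, computed
# from the non-profiled REML criterion
#   h(theta, sigma) = ldL2 + ldRX2 + (n - p) log(2 pi sigma^2) + pwrss/sigma^2
# whose pieces live in the deviance-function environment; for coefficient i
# the df is 2 f_i^2 / (g_i' A g_i) with f_i = V(theta, sigma)[i, i], g_i its
# gradient in (theta, sigma) and A = 2 H^{-1} the asymptotic covariance of
# (theta, sigma). One Hessian and one set of perturbed V matrices serve all
# coefficients. Returns NA per coefficient when the fit sits on the boundary
# or the Hessian is not positive definite.
satterthwaite_df <- function(fit) {
  p <- length(lme4::fixef(fit))
  th <- lme4::getME(fit, "theta")
  if (any(th < 1e-6)) return(rep(NA_real_, p))
  sig <- stats::sigma(fit)
  n <- stats::nobs(fit)
  devfun <- lme4::lFormula(stats::formula(fit),
                           data = stats::model.frame(fit), REML = TRUE,
                           control = lmer_ctrl())
  devfun <- do.call(lme4::mkLmerDevfun, devfun)
  rho <- environment(devfun)
  Vdiag <- function(vp) {
    devfun(vp[-length(vp)])
    vp[length(vp)]^2 * diag(rho$pp$unsc())
  }
  hfun <- function(vp) {
    devfun(vp[-length(vp)])
    s2 <- vp[length(vp)]^2
    pwrss <- rho$resp$wrss() + rho$pp$sqrL(1)
    rho$pp$ldL2() + rho$pp$ldRX2() + (n - p) * log(2 * pi * s2) + pwrss / s2
  }
  vp <- c(th, sig)
  k <- length(vp)
  hstep <- pmax(abs(vp), 0.05) * 1e-3
  G <- matrix(NA_real_, k, p)  # gradient of each V[i, i] in (theta, sigma)
  for (j in seq_len(k)) {
    e <- numeric(k); e[j] <- hstep[j]
    G[j, ] <- (Vdiag(vp + e) - Vdiag(vp - e)) / (2 * hstep[j])
  }
  H <- matrix(NA_real_, k, k)
  h0 <- hfun(vp)
  for (j in seq_len(k)) for (l in j:k) {
    ej <- numeric(k); ej[j] <- hstep[j]
    el <- numeric(k); el[l] <- hstep[l]
    if (j == l) {
      H[j, j] <- (hfun(vp + ej) - 2 * h0 + hfun(vp - ej)) / hstep[j]^2
    } else {
      H[j, l] <- H[l, j] <-
        (hfun(vp + ej + el) - hfun(vp + ej - el) -
           hfun(vp - ej + el) + hfun(vp - ej - el)) /
        (4 * hstep[j] * hstep[l])
    }
  }
  A <- tryCatch(2 * solve(H), error = function(e) NULL)
  if (is.null(A)) return(rep(NA_real_, p))
  f0 <- Vdiag(vp)
  denom <- colSums((A %*% G) * G)
  ifelse(is.finite(denom) & denom > 0, 2 * f0^2 / denom, NA_real_)
}

# Wald t table with Satterthwaite degrees of freedom. Residual df (n - p)
# would be badly anti-conservative for covariates whose variation lives at
# the level of a random factor (a yearly environmental covariate under a
# year intercept, or a cross-level interaction driven by it), so every
# coefficient gets a Satterthwaite df, capped at the residual df; when the
# Satterthwaite machinery is undefined (boundary fits, non-PD Hessian) the
# fallback is the containment df (levels of the coarsest factor the
# covariate is constant within, minus the fixed-effect count).
wald_table <- function(fit) {
  cf <- summary(fit)$coefficients
  n <- stats::nobs(fit)
  p <- nrow(cf)
  X <- lme4::getME(fit, "X")
  flist <- lme4::getME(fit, "flist")
  df_s <- satterthwaite_df(fit)
  df <- numeric(p)
  for (i in seq_len(p)) {
    eff_n <- n
    if (rownames(cf)[i] != "(Intercept)") {
      for (g in flist) {
        within_var <- stats::ave(X[, i], g, FUN = stats::var)
        if (all(within_var < 1e-12, na.rm = TRUE))
          eff_n <- min(eff_n, nlevels(g))
      }
    }
    # Satterthwaite, never exceeding the containment df (levels of the
    # coarsest factor the covariate is constant within, minus p)
    df[i] <- if (is.finite(df_s[i])) min(df_s[i], eff_n - p) else
      max(eff_n - p, 3)
    df[i] <- max(df[i], 3)
  }
  data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
             se = cf[, "Std. Error"],
             df = df,
             p = 2 * stats::pt(abs(cf[, "t value"]), df, lower.tail = FALSE),
             row.names = NULL)
}

# Nakagawa-style conditional R2: (fixed + random variance) / total
conditional_r2 <- function(fit) {
  var_f <- stats::var(as.vector(lme4::getME(fit, "X") %*% lme4::fixef(fit)))
  vc <- lme4::VarCorr(fit)
  var_r <- sum(vapply(vc, function(m) m[1, 1], 1.0))
  var_e <- attr(vc, "sc")^2
  (var_f + var_r) / (var_f + var_r + var_e)
}

#' Fit one structural sub-model
#'
#' Gaussian linear mixed model of one endogenous variable on its parents,
#' estimated by maximum likelihood with the model's crossed random
#' intercepts. Intended to be called on the standardized analysis set, in
#' which case the fixed-effect estimates are standardized path coefficients.
#' P-values are two-sided Wald t tests with Satterthwaite degrees of
#' freedom (capped at the residual df, with a containment-df fallback at
#' variance boundaries); this matters for covariates whose variation lives
#' at the level of a random factor, such as a yearly environmental covariate
#' under a year intercept. The convention is recorded in the output.
#'
#' @param model A `path_model`.
#' @param response Name of the endogenous variable.
#' @param data Standardized, listwise-complete data (see [standardize()]).
#' @return A `submodel_fit`: list with `response`, `coefficients` (term,
#'   estimate, se, p), `re_variance` (named, incl. `residual`),
#'   `conditional_r2`, `n`, `df_method`, and the underlying `lmerMod` as
#'   `fit`.
#' @export
fit_submodel <- function(model, response, data) {
  stopifnot(inherits(model, "path_model"),
            response %in% names(model$responses))
  preds <- model$responses[[response]]
  fit <- fit_lmm(response, preds, data, model$random)
  vc <- lme4::VarCorr(fit)
  rev <- c(vapply(vc, function(m) m[1, 1], 1.0), residual = attr(vc, "sc")^2)
  structure(list(response = response, coefficients = wald_table(fit),
                 re_variance = rev, conditional_r2 = conditional_r2(fit),
                 n = stats::nobs(fit),
                 df_method = "Satterthwaite (containment fallback)", fit = fit),
            class = "submodel_fit")
}

#' @export
print.submodel_fit <- function(x, ...) {
  cat(sprintf("submodel: %s (n = %d, conditional R2 = %.3f)\n",
              x$response, x$n, x$conditional_r2))
  print(cbind(x$coefficients[1], round(x$coefficients[-1], 4)),
        row.names = FALSE)
  invisible(x)
}

#' d-separation basis set of a path model
#'
#' Enumerates the conditional-independence claims implied by the DAG: one
#' claim per unordered pair of non-adjacent variables that is not joined by a
#' correlated-error arc and is not exogenous-exogenous. Each claim regresses
#' the topologically later variable on the earlier one, conditioning on the
#' union of both variables' parents.
#'
#' @param model A `path_model`.
#' @return List of claims: each a list with `later`, `earlier`,
#'   `conditioning` (character vector).
#' @export
basis_set <- function(model) {
  stopifnot(inherits(model, "path_model"))
  vars <- model$order
  parents <- function(v) model$edges$from[model$edges$to == v]
  adjacent <- function(a, b) {
    any((model$edges$from == a & model$edges$to == b) |
          (model$edges$from == b & model$edges$to == a)) ||
      any(vapply(model$correlated,
                 function(p) setequal(p, c(a, b)), TRUE))
  }
  exo <- setdiff(vars, names(model$responses))
  claims <- list()
  nv <- length(vars)
  for (i in seq_len(nv - 1)) for (j in (i + 1):nv) {
    a <- vars[i]; b <- vars[j]  # a earlier in topological order
    if (a %in% exo && b %in% exo) next
    if (adjacent(a, b)) next
    claims[[length(claims) + 1L]] <- list(
      later = b, earlier = a,
      conditioning = setdiff(union(parents(a), parents(b)), c(a, b)))
  }
  claims
}

#' Test the d-separation claims of a path model
#'
#' Each claim is evaluated by adding the claimed-independent (earlier)
#' variable to a mixed model of the later variable on the conditioning set,
#' with the model's crossed random intercepts, and taking the two-sided Wald
#' p-value of the added term. The claim p-values are combined into Fisher's
#' C = -2 * sum(log p), referred to a chi-square distribution with 2k degrees
#' of freedom (k claims).
#'
#' @param model A `path_model`.
#' @param data Standardized, listwise-complete data.
#' @return A `dsep_result`: list with `claims` (data frame: later, earlier,
#'   conditioning, p), `fisher_c`, `df`, `p_value`.
#' @export
dsep_test <- function(model, data) {
  claims <- basis_set(model)
  k <- length(claims)
  if (k == 0L)
    return(structure(list(claims = data.frame(), fisher_c = 0, df = 0L,
                          p_value = 1), class = "dsep_result"))
  ps <- numeric(k)
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    cl <- claims[[i]]
    preds <- c(cl$earlier, cl$conditioning)
    fit <- fit_lmm(cl$later, preds, data, model$random)
    tab <- wald_table(fit)
    p <- tab$p[tab$term == cl$earlier]
    if (p == 0) {
      warning("claim p-value underflow: floored at 1e-300")
      p <- 1e-300
    }
    ps[i] <- p
    rows[[i]] <- data.frame(
      later = cl$later, earlier = cl$earlier,
      conditioning = paste(cl$conditioning, collapse = "+"), p = p)
  }
  C <- -2 * sum(log(ps))
  df <- 2L * k
  structure(list(claims = do.call(rbind, rows), fisher_c = C, df = df,
                 p_value = chi_square_upper_tail(C, df)),
            class = "dsep_result")
}

#' @export
print.dsep_result <- function(x, ...) {
  cat(sprintf("d-separation test: Fisher's C = %.1f, df = %d, p = %.3f\n",
              x$fisher_c, x$df, x$p_value))
  invisible(x)
}

#' Upper tail of the chi-square distribution
#'
#' Survival function used to refer Fisher's C to its chi-square reference
#' distribution with 2k degrees of freedom.
#'
#' @param C Test statistic (>= 0).
#' @param df Degrees of freedom (positive integer; 0 allowed, giving p = 1
#'   for C = 0).
#' @return Upper-tail probability.
#' @examples
#' chi_square_upper_tail(15.3, 10) # 0.121
#' chi_square_upper_tail(2.2, 4)   # 0.699
#' @export
chi_square_upper_tail <- function(C, df) {
  stopifnot(C >= 0, df >= 0)
  if (df == 0) return(1)
  stats::pchisq(C, df, lower.tail = FALSE)
}

#' Indirect effect along a causal chain
#'
#' The product of the standardized path coefficients along an ordered chain
#' of directed edges. Following common reporting practice, the product is
#' flagged as reportable only when every component path is individually
#' significant at `alpha` (two-sided, no multiplicity correction).
#'
#' @param fits Named list of `submodel_fit`s (names = responses), e.g. from
#'   [carryover_sem()].
#' @param chain Character vector of variables, e.g.
#'   `c("age_ndvi", "breeding_date", "fledglings")`.
#' @param alpha Significance gate for reporting (default 0.05).
#' @return An `indirect_effect`: list with `chain`, `value`, `components`
#'   (data frame edge/estimate/p), `reportable`.
#' @export
indirect_effect <- function(fits, chain, alpha = 0.05) {
  stopifnot(length(chain) >= 2L)
  comps <- vector("list", length(chain) - 1L)
  for (i in seq_len(length(chain) - 1L)) {
    from <- chain[i]; to <- chain[i + 1]
    f <- fits[[to]]
    if (is.null(f)) stop("no sub-model for response '", to, "'")
    row <- f$coefficients[f$coefficients$term == from, ]
    if (nrow(row) == 0L)
      stop("edge ", from, " -> ", to, " not present in its sub-model")
    comps[[i]] <- data.frame(from = from, to = to,
                             estimate = row$estimate, p = row$p)
  }
  comps <- do.call(rbind, comps)
  structure(list(chain = chain, value = prod(comps$estimate),
                 components = comps,
                 reportable = all(comps$p < alpha)),
            class = "indirect_effect")
}

#' @export
print.indirect_effect <- function(x, ...) {
  cat(sprintf("indirect effect %s = %.4f%s\n",
              paste(x$chain, collapse = " -> "), x$value,
              if (x$reportable) "" else " (component path(s) not significant)"))
  invisible(x)
}

#' Correlated-error estimate for a variable pair
#'
#' Pearson correlation of the two variables' model residuals on the shared
#' analysis set, with a two-sided t test. Endogenous variables contribute
#' their sub-model residuals; a variable without a sub-model (body mass) is
#' first residualized on the exogenous covariates under the same random
#' structure.
#'
#' @param object A `carryover_sem` fit.
#' @param pair Length-2 character vector.
#' @return List with `pair`, `estimate`, `p`, `n`.
#' @export
correlated_error <- function(object, pair) {
  stopifnot(inherits(object, "carryover_sem"), length(pair) == 2L)
  r1 <- sem_residuals_of(object, pair[1])
  r2 <- sem_residuals_of(object, pair[2])
  n <- length(r1)
  if (n < 4L) stop("need at least 4 shared residuals")
  r <- stats::cor(r1, r2)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(pair = pair, estimate = r,
       p = 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE), n = n)
}

sem_residuals_of <- function(object, var) {
  if (var %in% names(object$fits))
    return(stats::residuals(object$fits[[var]]$fit))
  exo <- setdiff(object$model$order, names(object$model$responses))
  covars <- setdiff(exo, var)
  fit <- fit_lmm(var, covars, object$data, object$model$random)
  stats::residuals(fit)
}

# carryover_sem: the user-facing fitted-model object ----------------------

#' Fit a carry-over path analysis (piecewise SEM)
#'
#' Fits a confirmatory path analysis: the data are restricted to rows
#' complete on every model variable (listwise deletion), all variables are
#' z-scored (interaction nodes as products of raw variables, then z-scored),
#' each endogenous variable is fitted by a Gaussian linear mixed model on its
#' parents with crossed random intercepts, the DAG's conditional-independence
#' claims are tested and combined into Fisher's C, and every declared
#' correlated-error pair is estimated from model residuals. Raw-scale
#' coefficients (standardized estimate times SD ratio) are reported alongside
#' the standardized ones.
#'
#' @param model A [path_model()], e.g. [swallow_path_model()].
#' @param data Data frame with the model's variables and random factors.
#' @param dsep Run the d-separation test (default `TRUE`).
#' @return An object of class `carryover_sem` with components `model`,
#'   `fits` (named list of `submodel_fit`s), `dsep` (`dsep_result`),
#'   `correlated` (list of correlated-error estimates), `centers`, `scales`,
#'   `ranges` (raw covariate ranges), `data` (the standardized analysis set),
#'   `n`.
#' @examples
#' \donttest{
#' truth <- causal_truth("male")
#' ndvi <- setNames(runif(10, 0.6, 0.675), 2001:2010)
#' recs <- generate_breeding_records(truth, 400, 2001:2010, ndvi, seed = 7)
#' fit <- carryover_sem(swallow_path_model("male"), recs)
#' summary(fit)
#' }
#' @export
carryover_sem <- function(model, data, dsep = TRUE) {
  stopifnot(inherits(model, "path_model"))
  vars <- setdiff(model$variables, names(model$interactions))
  miss <- setdiff(c(vars, model$random), names(data))
  if (length(miss))
    stop("data lacks column(s): ", paste(miss, collapse = ", "))
  std <- standardize(data[, c(vars, model$random), drop = FALSE],
                     variables = vars, interactions = model$interactions)
  fits <- lapply(names(model$responses), function(r)
    fit_submodel(model, r, std))
  names(fits) <- names(model$responses)
  ds <- if (dsep) dsep_test(model, std) else NULL
  raw <- attr(std, "raw")
  obj <- structure(list(model = model, fits = fits, dsep = ds,
                        centers = attr(std, "centers"),
                        scales = attr(std, "scales"),
                        ranges = lapply(raw, range),
                        data = std, n = nrow(std)),
                   class = "carryover_sem")
  obj$correlated <- lapply(model$correlated, function(p)
    correlated_error(obj, p))
  obj
}

#' @export
print.carryover_sem <- function(x, ...) {
  cat(sprintf("Carry-over path analysis%s: %d records, %d sub-models\n",
              if (!is.null(x$model$sex)) paste0(" (", x$model$sex, ")") else "",
              x$n, length(x$fits)))
  if (!is.null(x$dsep))
    cat(sprintf("  Fisher's C = %.1f, df = %d, p = %.3f\n",
                x$dsep$fisher_c, x$dsep$df, x$dsep$p_value))
  invisible(x)
}

#' @export
summary.carryover_sem <- function(object, ...) {
  tabs <- lapply(object$fits, function(f) {
    tab <- f$coefficients[f$coefficients$term != "(Intercept)", ]
    tab$raw_estimate <- tab$estimate * object$scales[f$response] /
      object$scales[tab$term]
    data.frame(response = f$response, tab,
               conditional_r2 = f$conditional_r2, row.names = NULL)
  })
  out <- list(table = do.call(rbind, tabs), dsep = object$dsep,
              correlated = object$correlated, sex = object$model$sex,
              n = object$n)
  class(out) <- "summary.carryover_sem"
  out
}

#' @export
print.summary.carryover_sem <- function(x, ...) {
  cat(sprintf("Carry-over path analysis%s, n = %d\n",
              if (!is.null(x$sex)) paste0(" (", x$sex, ")") else "", x$n))
  tab <- x$table
  tab[-(1:2)] <- round(tab[-(1:2)], 4)
  print(tab, row.names = FALSE)
  if (!is.null(x$dsep))
    cat(sprintf("d-separation: Fisher's C = %.1f, df = %d, p = %.3f\n",
                x$dsep$fisher_c, x$dsep$df, x$dsep$p_value))
  for (ce in x$correlated)
    cat(sprintf("correlated errors %s <-> %s: r = %.3f, p = %.3f\n",
                ce$pair[1], ce$pair[2], ce$estimate, ce$p))
  invisible(x)
}

#' @export
coef.carryover_sem <- function(object, standardized = TRUE, ...) {
  out <- lapply(object$fits, function(f) {
    cf <- stats::setNames(f$coefficients$estimate, f$coefficients$term)
    if (!standardized) {
      terms <- setdiff(names(cf), "(Intercept)")
      cf[terms] <- cf[terms] * object$scales[f$response] /
        object$scales[terms]
      cf <- cf[terms]
    }
    cf
  })
  out
}

#' @export
residuals.carryover_sem <- function(object, ...) {
  lapply(object$fits, function(f) stats::residuals(f$fit))
}

#' Fixed-effects predictions from a fitted path analysis
#'
#' Predicts every endogenous variable in raw units for new covariate values,
#' using fixed effects only. Endogenous variables are computed in topological
#' order, so downstream responses use the *predicted* values of their
#' endogenous parents: the prediction propagates effects along the diagram's
#' chains (the prediction-surface analogue of an indirect effect).
#' Interaction nodes are recomputed from the raw covariates. Covariate values
#' outside the range observed in the analysis set are flagged in the
#' `"extrapolated"` attribute, not refused.
#'
#' @param object A `carryover_sem`.
#' @param newdata Data frame of raw exogenous covariates.
#' @param ... Unused.
#' @return `newdata` with one added column per endogenous variable, plus a
#'   logical attribute `extrapolated` (one value per row).
#' @export
predict.carryover_sem <- function(object, newdata, ...) {
  model <- object$model
  for (nm in names(model$interactions)) {
    comp <- model$interactions[[nm]]
    newdata[[nm]] <- newdata[[comp[1]]] * newdata[[comp[2]]]
  }
  exo <- setdiff(model$order, names(model$responses))
  used_exo <- intersect(exo, unlist(model$responses))
  extrap <- rep(FALSE, nrow(newdata))
  for (v in used_exo) {
    rng <- object$ranges[[v]]
    extrap <- extrap | newdata[[v]] < rng[1] | newdata[[v]] > rng[2]
  }
  z <- function(v, x) (x - object$centers[v]) / object$scales[v]
  for (r in intersect(model$order, names(model$responses))) {
    f <- object$fits[[r]]
    cf <- stats::setNames(f$coefficients$estimate, f$coefficients$term)
    pred_std <- cf[["(Intercept)"]]
    for (tm in setdiff(names(cf), "(Intercept)"))
      pred_std <- pred_std + cf[[tm]] * z(tm, newdata[[tm]])
    newdata[[r]] <- object$centers[r] + object$scales[r] * pred_std
  }
  attr(newdata, "extrapolated") <- extrap
  newdata
}

#' Predicted response over an age x NDVI grid
#'
#' Evaluates [predict.carryover_sem()] on the cross of an age grid and an
#' NDVI grid, holding the remaining covariates at stated reference values
#' (defaults: their analysis-set means).
#'
#' @param object A `carryover_sem`.
#' @param response Endogenous variable to extract.
#' @param age,ndvi Numeric grids.
#' @param fixed Named list of reference values for other exogenous
#'   covariates.
#' @return Data frame `age`, `winter_ndvi`, and the predicted response.
#' @export
predict_surface <- function(object, response, age, ndvi, fixed = list()) {
  stopifnot(response %in% names(object$fits))
  nd <- expand.grid(age = age, winter_ndvi = ndvi)
  exo <- setdiff(object$model$order, names(object$model$responses))
  others <- setdiff(intersect(exo, unlist(object$model$responses)),
                    c("age", "winter_ndvi", names(object$model$interactions)))
  for (v in others)
    nd[[v]] <- if (!is.null(fixed[[v]])) fixed[[v]] else object$centers[[v]]
  pr <- predict(object, nd)
  out <- pr[, c("age", "winter_ndvi", response)]
  attr(out, "extrapolated") <- attr(pr, "extrapolated")
  out
}

#' @export
plot.carryover_sem <- function(x, response = NULL,
                               age = NULL, ndvi = NULL, ...) {
  if (is.null(response))
    response <- utils::tail(names(x$fits), 1)
  if (is.null(age))
    age <- seq(x$ranges$age[1], x$ranges$age[2], length.out = 25)
  if (is.null(ndvi))
    ndvi <- seq(x$ranges$winter_ndvi[1], x$ranges$winter_ndvi[2],
                length.out = 25)
  sf <- predict_surface(x, response, age, ndvi)
  z <- matrix(sf[[response]], length(age), length(ndvi))
  graphics::persp(age, ndvi, z, xlab = "age (years)", ylab = "winter NDVI",
                  zlab = response, theta = 35, phi = 25,
                  ticktype = "detailed", ...)
  invisible(sf)
}

#' @export
simulate.carryover_sem <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  model <- object$model
  std <- object$data
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    sim <- std
    for (r in intersect(model$order, names(model$responses))) {
      f <- object$fits[[r]]
      cf <- stats::setNames(f$coefficients$estimate, f$coefficients$term)
      mu <- cf[["(Intercept)"]]
      for (tm in setdiff(names(cf), "(Intercept)"))
        mu <- mu + cf[[tm]] * sim[[tm]]
      rv <- f$re_variance
      for (g in model$random) {
        lev <- factor(sim[[g]])
        mu <- mu + stats::rnorm(nlevels(lev), 0,
                                sqrt(rv[[g]]))[as.integer(lev)]
      }
      sim[[r]] <- mu + stats::rnorm(nrow(sim), 0, sqrt(rv[["residual"]]))
    }
    out[[s]] <- sim
  }
  out
}
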