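curve_id <- function(df) {
  paste(df$metabolite, df$position, df$pattern, sep = "|")
}

# predictor closure: fluxes -> model fe vector aligned with dataset rows
make_predictor <- function(dataset, rtol = 1e-8) {
  net <- dataset$net
  spec <- dataset$spec
  curves <- dataset$curves
  times <- sort(unique(curves$time_min))
  inp <- input_function(spec)
  positional <- identical(dataset$variant, "positional")
  sys <- build_cumomer_system(net, if (positional) 1L else 3L,
                              spec$natural_abundance)
  want <- unique(curves[, c("metabolite", "position", "pattern")])
  row_key <- paste(curve_id(curves), curves$time_min)

  function(f) {
    traj <- integrate_system(sys, f, inp, times, rtol = rtol,
                             atol = rtol * 1e-2)
    if (positional) {
      pred <- do.call(rbind, lapply(seq_len(nrow(want)), function(i) {
        pools <- net$observables[[want$metabolite[i]]]
        w <- vapply(pools, function(p) net$pools[[p]]$concentration,
                    numeric(1))
        w <- w / sum(w)
        fe <- 0
        for (j in seq_along(pools))
          fe <- fe + w[j] * get_fe(traj, pools[j], want$position[i])
        data.frame(time_min = times, metabolite = want$metabolite[i],
                   position = want$position[i], pattern = want$pattern[i],
                   fe = fe, stringsAsFactors = FALSE)
      }))
    } else {
      pred <- multiplet_curves(traj, net)
    }
    m <- match(row_key, paste(curve_id(pred), pred$time_min))
    if (anyNA(m)) stop("forward model did not produce all observed curves")
    pred$fe[m]
  }
}

# Levenberg-Marquardt core shared by fit_fluxes, monte_carlo and the
# sensitivity scan; `fixed` overrides selected fluxes.
lm_core <- function(predict_fe, obs, w, init, lower, upper, fixed,
                    control) {
  free_names <- setdiff(free_flux_names, names(fixed))
  if (length(free_names) == 0) stop("no free parameters left to fit")
  par0 <- pmin(pmax(init$free[free_names], lower), upper)
  assemble <- function(par) {
    full <- init$free
    full[free_names] <- par
    if (!is.null(fixed)) full[names(fixed)] <- fixed
    as_flux_set(full)
  }
  n_eval <- 0L
  resid_fn <- function(par) {
    n_eval <<- n_eval + 1L
    fe <- tryCatch(predict_fe(assemble(par)),
                   error = function(e) rep(NA_real_, length(obs)))
    r <- (fe - obs) * w
    r[!is.finite(r)] <- 1e6
    r
  }
  lm <- minpack.lm::nls.lm(par = par0, lower = rep(lower, length(par0)),
                           upper = rep(upper, length(par0)),
                           fn = resid_fn, control = control)
  est <- assemble(lm$par)
  fitted <- predict_fe(est)
  list(estimates = derived_fluxes(est),
       fitted = fitted,
       residual = sum(((fitted - obs) * w)^2),
       converged = lm$info %in% 1:4,
       info = lm$info, message = lm$message,
       niter = lm$niter, n_eval = n_eval)
}

default_lm_control <- function() {
  minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10, ptol = 1e-8)
}

weights_from_sd <- function(sdv) {
  if (all(sdv == 0)) return(rep(1, length(sdv)))
  if (any(sdv <= 0)) stop("curve SDs must be positive (or all zero)")
  1 / sdv
}

#' Fit the metabolic fluxes to labeling curves
#'
#' Weighted nonlinear least squares with the Levenberg-Marquardt
#' algorithm: minimises `sum(((model - data) / sd)^2)` over the free
#' fluxes, integrating the cumomer ODEs at every evaluation. Residuals
#' (not squared residuals) are weighted by the reciprocal standard
#' deviation, so noisy curves do not dominate the joint regression. The
#' positional variant fits the order-1 (positional) reduction of the
#' model to the 6 total-enrichment curves; the bonded and multiplet-only
#' variants fit the full order-3 system to their curve sets.
#'
#' @param dataset a `labeling_dataset`
#' @param init initial `flux_set` (default [default_truth_fluxes()])
#' @param lower,upper box bounds on every free flux, micromol/g/min
#'   (defaults 0 and 5; nonnegativity is physical)
#' @param fixed optional named numeric vector of fluxes held constant
#'   (used by [sensitivity_scan()])
#' @param rtol ODE tolerance used inside the fit
#' @param control a [minpack.lm::nls.lm.control()] list
#' @return An object of class `flux_fit`: estimates (with derived
#'   fluxes), weighted residual sum of squares, fitted curves,
#'   convergence diagnostics.
#' @export
fit_fluxes <- function(dataset, init = default_truth_fluxes(),
                       lower = 0, upper = 5, fixed = NULL,
                       rtol = 1e-8, control = default_lm_control()) {
  stopifnot(inherits(dataset, "labeling_dataset"))
  init <- as_flux_set(init)
  predict_fe <- make_predictor(dataset, rtol = rtol)
  w <- weights_from_sd(dataset$curves$sd)
  res <- lm_core(predict_fe, dataset$curves$fe, w, init, lower, upper,
                 fixed, control)
  if (!res$converged)
    warning("Levenberg-Marquardt did not report convergence: ",
            res$message)
  structure(list(
    estimates = res$estimates,
    residual = res$residual,
    fitted = res$fitted,
    n_curves = nrow(unique(dataset$curves[, c("metabolite", "position",
                                              "pattern")])),
    variant = dataset$variant,
    convergence = res[c("converged", "info", "message", "niter",
                        "n_eval")],
    fixed = fixed,
    dataset = dataset,
    predictor = predict_fe,
    control = list(lower = lower, upper = upper, rtol = rtol,
                   lm = control)
  ), class = "flux_fit")
}

#' @export
print.flux_fit <- function(x, ...) {
  cat("Flux fit (", x$variant, " variant, ", x$n_curves, " curves)\n",
      sep = "")
  print(round(x$estimates$free, 4))
  cat("weighted RSS:", signif(x$residual, 5),
      if (x$convergence$converged) "(converged)\n" else
        "(NOT converged)\n")
  invisible(x)
}

#' Monte-Carlo uncertainty analysis of a flux fit
#'
#' Generates `n_mc` artificial data sets by adding Gaussian noise with
#' the experimental variance to the best-fit model curves, refits each
#' one starting from the base estimates, and summarises the resulting
#' flux samples: mean, SD, a gamma-distribution fit with its full width
#' at half maximum, and the Pearson correlation matrix between fluxes.
#'
#' @param fit a `flux_fit`
#' @param n_mc number of artificial data sets (default 500)
#' @param seed integer seed
#' @param max_fail_frac maximal tolerated fraction of non-converged
#'   replicates (default 0.1); exceeding it is an error
#' @return An object of class `mc_result`: `samples` (n_mc x 7), `mean`,
#'   `sd`, `gamma` (per-flux shape/rate/FWHM), `correlation`.
#' @export
monte_carlo <- function(fit, n_mc = 500, seed = 1L,
                        max_fail_frac = 0.1) {
  stopifnot(inherits(fit, "flux_fit"))
  base <- fit$fitted
  sdv <- fit$dataset$curves$sd
  if (all(sdv == 0))
    stop("dataset has zero noise SD; Monte Carlo is degenerate")
  w <- weights_from_sd(sdv)
  set.seed(seed)
  samples <- matrix(NA_real_, nrow = n_mc,
                    ncol = length(free_flux_names),
                    dimnames = list(NULL, free_flux_names))
  failed <- 0L
  for (i in seq_len(n_mc)) {
    obs <- base + rnorm(length(base), 0, sdv)
    res <- tryCatch(
      lm_core(fit$predictor, obs, w, fit$estimates,
              fit$control$lower, fit$control$upper, fit$fixed,
              fit$control$lm),
      error = function(e) NULL)
    if (is.null(res) || !res$converged) { failed <- failed + 1L; next }
    samples[i, ] <- res$estimates$free
  }
  if (failed > max_fail_frac * n_mc)
    stop(failed, " of ", n_mc, " Monte-Carlo refits failed to converge")
  samples <- samples[stats::complete.cases(samples), , drop = FALSE]
  gam <- lapply(colnames(samples), function(fl) {
    tryCatch(summarize_distribution(samples[, fl]),
             error = function(e)
               list(shape = NA_real_, rate = NA_real_, fwhm = NA_real_))
  })
  names(gam) <- colnames(samples)
  structure(list(
    samples = samples,
    n_mc = n_mc, n_failed = failed, seed = seed,
    mean = colMeans(samples),
    sd = apply(samples, 2, sd),
    gamma = gam,
    correlation = if (nrow(samples) >= 50) correlation_matrix(samples),
    base_estimates = fit$estimates,
    variant = fit$variant
  ), class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat("Monte-Carlo flux uncertainty (", x$variant, " variant, ",
      nrow(x$samples), " replicates)\n", sep = "")
  fwhm <- vapply(x$gamma, function(g) g$fwhm, numeric(1))
  print(round(rbind(mean = x$mean, sd = x$sd, fwhm = fwhm), 4))
  invisible(x)
}

#' Gamma-distribution summary of Monte-Carlo samples
#'
#' Maximum-likelihood gamma fit to a positive sample, plus the full width
#' at half maximum of the fitted density (located by root bisection on
#' the half-maximum crossings around the mode).
#'
#' @param samples numeric vector, at least 50 positive values
#' @return List with `shape`, `rate`, `mean`, `sd`, `fwhm`.
#' @export
summarize_distribution <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) < 50) stop("need at least 50 samples")
  if (any(samples <= 0)) stop("gamma fit requires positive samples")
  if (sd(samples) == 0) stop("degenerate (constant) samples")
  m <- mean(samples); v <- var(samples)
  fit <- suppressWarnings(
    MASS::fitdistr(samples, "gamma",
                   start = list(shape = m^2 / v, rate = m / v),
                   lower = c(1e-8, 1e-8)))
  shape <- unname(fit$estimate["shape"])
  rate <- unname(fit$estimate["rate"])
  if (shape <= 1)
    stop("fitted gamma density has no interior mode; FWHM undefined")
  mode <- (shape - 1) / rate
  half <- dgamma(mode, shape, rate) / 2
  g <- function(x) dgamma(x, shape, rate) - half
  left <- uniroot(g, c(mode * 1e-9, mode))$root
  ub <- mode * 2
  while (g(ub) > 0) ub <- ub * 2
  right <- uniroot(g, c(mode, ub))$root
  list(shape = shape, rate = rate, mean = m, sd = sd(samples),
       fwhm = right - left)
}

#' Pearson correlation matrix of Monte-Carlo flux samples
#'
#' @param samples matrix with one column per flux
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(samples) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 50) stop("need at least 50 samples")
  if (any(apply(samples, 2, sd) == 0))
    stop("zero-variance flux sample; correlation undefined")
  cor(samples)
}

#' Default sensitivity-scan grids
#'
#' @param flux_name `"Vnt"` or `"Vdil"`
#' @return The constrained values scanned by default: Vnt over
#'   0.07, 0.10, 0.20 and Vdil over 0.20, 0.30, 0.60 micromol/g/min.
#' @export
default_scan_grid <- function(flux_name) {
  switch(flux_name,
         Vnt = c(0.07, 0.10, 0.20),
         Vdil = c(0.20, 0.30, 0.60),
         stop("no default grid for flux ", flux_name))
}

#' Sensitivity scan of one flux
#'
#' Constrains one flux to each value of a grid, refits all remaining free
#' fluxes, and records, next to the constrained estimates, the implied
#' GluC4 and GlnC4 total and multiplet time courses. For the positional
#' variant the multiplets are not part of the cost function but are still
#' simulated at each constrained optimum, exposing the isotopomer
#' information the positional fit ignores.
#'
#' @param dataset a `labeling_dataset`
#' @param flux_name one of [free_flux_names]
#' @param grid strictly increasing constrained values (default
#'   [default_scan_grid()])
#' @param init initial fluxes for each refit
#' @param rtol ODE tolerance
#' @return An object of class `scan_result`: `flux_name`, `grid`,
#'   `estimates` (one row per grid value), `curves` (GluC4/GlnC4 pattern
#'   time courses per grid value), `residuals`, `converged`.
#' @export
sensitivity_scan <- function(dataset, flux_name,
                             grid = default_scan_grid(flux_name),
                             init = default_truth_fluxes(),
                             rtol = 1e-8) {
  if (!flux_name %in% free_flux_names)
    stop("unknown flux ", flux_name)
  if (any(diff(grid) <= 0)) stop("grid values must be strictly increasing")
  net <- dataset$net
  spec <- dataset$spec
  predict_fe <- make_predictor(dataset, rtol = rtol)
  w <- weights_from_sd(dataset$curves$sd)
  sys3 <- build_cumomer_system(net, 3, spec$natural_abundance)
  times <- sort(unique(dataset$curves$time_min))
  est_rows <- list(); curve_rows <- list()
  residuals <- numeric(length(grid)); conv <- logical(length(grid))
  for (i in seq_along(grid)) {
    fx <- setNames(grid[i], flux_name)
    res <- lm_core(predict_fe, dataset$curves$fe, w, as_flux_set(init),
                   0, 5, fx, default_lm_control())
    residuals[i] <- res$residual
    conv[i] <- res$converged
    est_rows[[i]] <- res$estimates$free
    traj <- integrate_system(sys3, res$estimates, input_function(spec),
                             times, rtol = rtol, atol = rtol * 1e-2)
    mc <- multiplet_curves(traj, net)
    mc <- mc[mc$position == 4L, , drop = FALSE]
    mc$constrained_value <- grid[i]
    curve_rows[[i]] <- mc
  }
  est <- do.call(rbind, lapply(est_rows, function(r)
    as.data.frame(as.list(r))))
  structure(list(flux_name = flux_name, grid = grid,
                 estimates = est,
                 curves = do.call(rbind, curve_rows),
                 residuals = residuals, converged = conv,
                 variant = dataset$variant),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("Sensitivity scan of", x$flux_name, "over",
      paste(x$grid, collapse = ", "), "\n")
  print(cbind(round(x$estimates, 4), wRSS = signif(x$residuals, 4)))
  invisible(x)
}
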