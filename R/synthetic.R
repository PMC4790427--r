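#' Acquisition specification for synthetic experiments
#'
#' Describes the acquisition emulated by the synthetic-data generator: a
#' roughly three-hour [1,6-13C2]glucose infusion sampled at the temporal
#' resolution of the averaged dynamic spectra, with plasma glucose
#' enrichment brought to its plateau by a 5-min bolus of 99%-enriched
#' glucose, and curve-class noise calibrated to the spectral-fitting
#' uncertainty at steady state (Cramer-Rao bounds around 15% for
#' individual multiplets, better for totals).
#'
#' @param t_end end of acquisition, min (default 180)
#' @param dt sampling interval, min (default 10.6)
#' @param bolus_duration duration of the enrichment rise, min (default 5)
#' @param plateau_fe plasma glucose fractional enrichment maintained after
#'   the bolus (default 0.70)
#' @param bolus_fe enrichment of the bolus infusate (default 0.99); upper
#'   bound for the plateau
#' @param noise_total relative standard deviation of total-enrichment
#'   curves at steady state (default 0.05)
#' @param noise_multiplet relative standard deviation of individual
#'   multiplet curves at steady state (default 0.15)
#' @param natural_abundance baseline 13C enrichment (default 0.011)
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(t_end = 180, dt = 10.6, bolus_duration = 5,
                             plateau_fe = 0.70, bolus_fe = 0.99,
                             noise_total = 0.05, noise_multiplet = 0.15,
                             natural_abundance = 0.011) {
  if (dt <= 0) stop("dt must be positive")
  if (!(plateau_fe > 0 && plateau_fe <= bolus_fe && bolus_fe <= 1))
    stop("need 0 < plateau_fe <= bolus_fe <= 1")
  if (t_end <= bolus_duration) stop("t_end must exceed the bolus")
  structure(list(t_end = t_end, dt = dt, bolus_duration = bolus_duration,
                 plateau_fe = plateau_fe, bolus_fe = bolus_fe,
                 noise_total = noise_total,
                 noise_multiplet = noise_multiplet,
                 natural_abundance = natural_abundance),
            class = "acquisition_spec")
}

#' Plasma glucose input function
#'
#' Fractional enrichment of plasma glucose C1/C6 versus time: a linear
#' rise from natural abundance to the plateau over the bolus, constant
#' thereafter (the adapted bolus is designed to put plasma enrichment at
#' the plateau by the end of the 5 minutes; the enrichment consumed by
#' the model, not the infusate volume profile, is what matters here).
#'
#' @param spec an `acquisition_spec`
#' @return A function `FE(t)`; its `breakpoints` attribute lists the
#'   kink positions for exact piecewise-linear handling by the
#'   integrator.
#' @export
input_function <- function(spec = acquisition_spec()) {
  na <- spec$natural_abundance
  tb <- spec$bolus_duration
  fe <- spec$plateau_fe
  f <- function(t) {
    ifelse(t <= 0, na,
           ifelse(t >= tb, fe, na + (fe - na) * t / tb))
  }
  attr(f, "breakpoints") <- c(0, tb)
  f
}

#' Observable curve set of a model variant
#'
#' The quantifiable curve sets, fixed by the 15% steady-state
#' Cramer-Rao-bound inclusion rule of the spectral analysis:
#' \itemize{
#'   \item `positional`: the 6 total-enrichment curves of Glu and Gln
#'     C4, C3, C2;
#'   \item `bonded`: those 6 plus the quantifiable multiplets -- GluC4
#'     S, D43; GluC3 S+T, D; GluC2 S, D23; GlnC4 S, D43; GlnC3 S+T, D;
#'     GlnC2 S -- 17 curves in all;
#'   \item `multiplet_only`: the 11 multiplet curves without the totals.
#' }
#'
#' @param variant `"positional"`, `"bonded"` or `"multiplet_only"`
#' @return Data frame with columns `metabolite`, `position`, `pattern`.
#' @export
observable_set <- function(variant = c("bonded", "positional",
                                       "multiplet_only")) {
  variant <- match.arg(variant)
  totals <- expand.grid(metabolite = c("glu", "gln"),
                        position = c(4L, 3L, 2L),
                        pattern = "total", stringsAsFactors = FALSE)
  mult <- rbind(
    data.frame(metabolite = "glu", position = c(4L, 4L, 3L, 3L, 2L, 2L),
               pattern = c("S", "D43", "S+T", "D", "S", "D23")),
    data.frame(metabolite = "gln", position = c(4L, 4L, 3L, 3L, 2L),
               pattern = c("S", "D43", "S+T", "D", "S")))
  out <- switch(variant,
                positional = totals,
                bonded = rbind(totals, mult),
                multiplet_only = mult)
  out[order(out$metabolite, -out$position, out$pattern), , drop = FALSE]
}

#' Forward-model labeling curves
#'
#' Integrates the cumomer system at the given fluxes and returns the
#' observable curves of the requested variant at the acquisition's
#' sampling times.
#'
#' @param fluxes a `flux_set`
#' @param spec an `acquisition_spec`
#' @param variant observable set, see [observable_set()]
#' @param net network (default [build_default_network()])
#' @param sys optional prebuilt `cumomer_system` for `net` (order 3),
#'   reused across calls for speed
#' @param times optional explicit sampling times; default
#'   `seq(0, t_end, dt)`
#' @param rtol integration tolerance
#' @return Tidy data frame `time_min`, `metabolite`, `position`,
#'   `pattern`, `fe`.
#' @export
forward_curves <- function(fluxes, spec = acquisition_spec(),
                           variant = "bonded",
                           net = build_default_network(), sys = NULL,
                           times = NULL, rtol = 1e-8) {
  if (is.null(sys))
    sys <- build_cumomer_system(net, 3, spec$natural_abundance)
  if (is.null(times))
    times <- seq(0, spec$t_end, by = spec$dt)
  traj <- integrate_system(sys, fluxes, input_function(spec), times,
                           rtol = rtol, atol = rtol * 1e-2)
  all_curves <- multiplet_curves(traj, net)
  want <- observable_set(variant)
  out <- merge(want, all_curves, by = c("metabolite", "position",
                                        "pattern"), sort = FALSE)
  out <- out[order(out$metabolite, -out$position, out$pattern,
                   out$time_min), c("time_min", "metabolite", "position",
                                    "pattern", "fe")]
  rownames(out) <- NULL
  out
}

curve_sd_model <- function(curves, spec) {
  # constant absolute SD per curve: relative SD at steady state times the
  # steady-state (last time point) value, mimicking Cramer-Rao behaviour
  key <- interaction(curves$metabolite, curves$position, curves$pattern,
                     drop = TRUE)
  sd <- numeric(nrow(curves))
  for (k in levels(key)) {
    id <- which(key == k)
    ss <- curves$fe[id[which.max(curves$time_min[id])]]
    rel <- if (unique(curves$pattern[id]) == "total") spec$noise_total
           else spec$noise_multiplet
    sd[id] <- rel * ss
  }
  sd
}

#' Generate a synthetic labeling dataset
#'
#' Runs the forward model at the ground-truth fluxes, samples it at the
#' acquisition times, attaches the per-curve noise model (constant
#' absolute SD equal to the relative steady-state SD times the
#' steady-state value) and, optionally, adds one realisation of
#' independent Gaussian noise.
#'
#' @param truth `flux_set` used as ground truth
#' @param spec an `acquisition_spec`
#' @param variant `"positional"`, `"bonded"` or `"multiplet_only"`
#' @param seed integer seed for the noise realisation
#' @param noise add Gaussian noise (`TRUE`) or return noiseless curves
#'   with the same SD model (`FALSE`)
#' @param net,sys as in [forward_curves()]
#' @return An object of class `labeling_dataset`: `curves` (with `fe` and
#'   `sd` columns), `truth`, `spec`, `variant`, `seed`.
#' @export
generate_dataset <- function(truth = default_truth_fluxes(),
                             spec = acquisition_spec(),
                             variant = c("bonded", "positional",
                                         "multiplet_only"),
                             seed = 1L, noise = TRUE,
                             net = build_default_network(), sys = NULL) {
  variant <- match.arg(variant)
  curves <- forward_curves(truth, spec, variant, net = net, sys = sys)
  curves$sd <- curve_sd_model(curves, spec)
  if (noise) {
    set.seed(seed)
    curves$fe <- curves$fe + rnorm(nrow(curves), 0, curves$sd)
  }
  structure(list(curves = curves, truth = truth, spec = spec,
                 variant = variant, seed = seed, net = net),
            class = "labeling_dataset")
}

#' Restrict a dataset to another model variant
#'
#' Subsets a bonded-variant dataset to the curves of a smaller variant,
#' preserving the noise realisation -- useful for comparing model
#' variants on matched data.
#'
#' @param dataset a `labeling_dataset`
#' @param variant target variant, a subset of the dataset's curves
#' @return A `labeling_dataset` of the target variant.
#' @export
subset_variant <- function(dataset, variant) {
  want <- observable_set(variant)
  keep <- interaction(dataset$curves$metabolite, dataset$curves$position,
                      dataset$curves$pattern) %in%
          interaction(want$metabolite, want$position, want$pattern)
  if (sum(keep) < nrow(want) * length(unique(dataset$curves$time_min)))
    stop("dataset does not contain all curves of variant ", variant)
  out <- dataset
  out$curves <- dataset$curves[keep, , drop = FALSE]
  out$variant <- variant
  out
}

#' @export
print.labeling_dataset <- function(x, ...) {
  ng <- nrow(unique(x$curves[, c("metabolite", "position", "pattern")]))
  cat("Labeling dataset (", x$variant, " variant): ", ng, " curves, ",
      length(unique(x$curves$time_min)), " time points\n", sep = "")
  invisible(x)
}
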