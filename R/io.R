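curve_columns <- c("time_min", "metabolite", "position", "pattern",
                   "fe", "sd")

#' Write labeling curves to CSV
#'
#' Tidy schema: one row per (time, metabolite, position, pattern) with
#' columns `time_min`, `metabolite`, `position`, `pattern`, `fe`, `sd`.
#' A JSON sidecar (`<path>.json`) records the generating fluxes,
#' acquisition spec, variant and seed when the input is a
#' `labeling_dataset`.
#'
#' @param dataset a `labeling_dataset` or a bare curve data frame
#' @param path output CSV path
#' @param sidecar write the JSON sidecar (default `TRUE` for datasets)
#' @return `path`, invisibly.
#' @export
write_curves <- function(dataset, path, sidecar = TRUE) {
  curves <- if (inherits(dataset, "labeling_dataset")) dataset$curves
            else dataset
  missing <- setdiff(curve_columns, names(curves))
  if (length(missing) > 0)
    stop("curve table lacks columns: ", paste(missing, collapse = ", "))
  write.csv(curves[, curve_columns], path, row.names = FALSE)
  if (sidecar && inherits(dataset, "labeling_dataset")) {
    meta <- list(
      truth = as.list(derived_fluxes(dataset$truth)$free),
      spec = unclass(dataset$spec),
      variant = dataset$variant,
      seed = dataset$seed)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read labeling curves from CSV
#'
#' Validates the tidy schema, rejects duplicate
#' (time, metabolite, position, pattern) rows, and warns about
#' enrichment values outside the physical range.
#'
#' @param path CSV path written by [write_curves()]
#' @param spec optional `acquisition_spec` to attach; defaults to the
#'   sidecar's spec when present, else [acquisition_spec()]
#' @param net network to attach (default [build_default_network()])
#' @return A `labeling_dataset` (with `truth = NULL` unless the sidecar
#'   provides it).
#' @export
read_curves <- function(path, spec = NULL,
                        net = build_default_network()) {
  curves <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(curve_columns, names(curves))
  if (length(missing) > 0)
    stop("curve file lacks columns: ", paste(missing, collapse = ", "))
  key <- paste(curves$time_min, curves$metabolite, curves$position,
               curves$pattern)
  if (anyDuplicated(key))
    stop("duplicate (time, metabolite, position, pattern) rows in ", path)
  if (nrow(curves) > 0 && any(curves$fe < 0 | curves$fe > 1.05))
    warning("fe values outside [0, 1.05] in ", path)

  truth <- NULL; variant <- NA_character_; seed <- NA_integer_
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$truth)) truth <- as_flux_set(unlist(meta$truth))
    if (!is.null(meta$variant)) variant <- meta$variant
    if (!is.null(meta$seed)) seed <- meta$seed
    if (is.null(spec) && !is.null(meta$spec))
      spec <- do.call(acquisition_spec, meta$spec)
  }
  if (is.null(spec)) spec <- acquisition_spec()
  if (is.na(variant)) {
    n_mult <- sum(curves$pattern != "total")
    variant <- if (n_mult == 0) "positional"
               else if (any(curves$pattern == "total")) "bonded"
               else "multiplet_only"
  }
  structure(list(curves = curves, truth = truth, spec = spec,
                 variant = variant, seed = seed, net = net),
            class = "labeling_dataset")
}

#' Serialize a network to JSON
#'
#' Pools (name, compartment, carbons, concentration, input flag, labeled
#' positions) and reactions (flux label, substrate stoichiometries, per
#' product the orientation atom maps as "pool.carbon" strings).
#'
#' @param net a `network`
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_network_json <- function(net, path) {
  doc <- list(
    pools = lapply(unname(net$pools), function(p)
      c(list(name = p$name, compartment = p$compartment,
             n_carbons = p$n_carbons),
        if (!p$is_input) list(concentration = p$concentration),
        list(is_input = p$is_input,
             hot_positions = I(p$hot_positions)))),
    reactions = lapply(unname(net$reactions), function(r)
      list(name = r$name, flux = r$flux,
           substrates = as.list(r$substrates),
           products = lapply(r$products, function(ol)
             lapply(ol, function(o)
               list(weight = o$weight, map = I(o$map)))))),
    measured_pools = I(net$measured_pools),
    observables = lapply(net$observables, I),
    constants = as.list(net$constants))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a network from JSON
#'
#' @param path file written by [write_network_json()]
#' @return A `network`.
#' @export
read_network_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  pools <- lapply(doc$pools, function(p)
    pool(p$name, p$compartment, p$n_carbons,
         if (is.null(p$concentration)) NA_real_ else p$concentration,
         isTRUE(p$is_input), unlist(p$hot_positions)))
  names(pools) <- vapply(pools, `[[`, character(1), "name")
  rx <- lapply(doc$reactions, function(r)
    reaction(r$name, r$flux,
             substrates = unlist(r$substrates),
             products = lapply(r$products, function(ol)
               lapply(ol, function(o)
                 list(weight = o$weight, map = unlist(o$map))))))
  names(rx) <- vapply(rx, `[[`, character(1), "name")
  net <- structure(list(
    pools = pools, reactions = rx,
    measured_pools = unlist(doc$measured_pools),
    observables = lapply(doc$observables, unlist),
    constants = unlist(doc$constants)), class = "network")
  validate_network(net)
  net
}

#' Write fit / Monte-Carlo / scan results to JSON
#'
#' @param x a `flux_fit`, `mc_result` or `scan_result`
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_results_json <- function(x, path) {
  doc <- if (inherits(x, "flux_fit")) {
    list(type = "fit", variant = x$variant,
         estimates = as.list(x$estimates$free),
         derived = as.list(x$estimates$derived),
         residual = x$residual, n_curves = x$n_curves,
         convergence = x$convergence)
  } else if (inherits(x, "mc_result")) {
    list(type = "monte_carlo", variant = x$variant,
         n_mc = x$n_mc, n_failed = x$n_failed, seed = x$seed,
         mean = as.list(x$mean), sd = as.list(x$sd),
         gamma = x$gamma,
         correlation = list(fluxes = I(colnames(x$correlation)),
                            matrix = x$correlation))
  } else if (inherits(x, "scan_result")) {
    list(type = "sensitivity_scan", flux = x$flux_name,
         grid = x$grid, estimates = x$estimates,
         residuals = x$residuals, converged = x$converged)
  } else stop("cannot serialize objects of class ", class(x)[1])
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
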