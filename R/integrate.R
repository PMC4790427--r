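resolve_rates <- function(sys, f) {
  v <- if (inherits(f, "flux_set") || (is.list(f) && !is.null(f$free))) {
    flux_values(as_flux_set(f), constants = sys$net$constants)
  } else {
    unlist(f)
  }
  need <- unique(c(sys$terms$flux,
                   unlist(lapply(sys$outflow, names))))
  missing <- setdiff(need, names(v))
  if (length(missing) > 0)
    stop("rates absent from flux vector: ", paste(missing, collapse = ", "))
  if (any(v[need] < -1e-12))
    stop("negative reaction rate encountered")
  v
}

input_table <- function(input_fn, t0, t1) {
  bp <- attr(input_fn, "breakpoints")
  tt <- if (!is.null(bp)) {
    sort(unique(c(t0, bp[bp > t0 & bp < t1], t1)))
  } else {
    # unknown shape: sample densely and treat as piecewise linear
    seq(t0, t1, length.out = 1001L)
  }
  list(t = tt, fe = vapply(tt, input_fn, numeric(1)))
}

#' Integrate a cumomer system
#'
#' Solves the labeling ODEs with an adaptive Dormand-Prince Runge-Kutta
#' 5(4) method (explicit, for nonstiff systems; compiled) or, as an
#' independent cross-check, with `deSolve` on the identical term table
#' (`engine = "r"`).
#'
#' @param sys a `cumomer_system` with the right-hand side attached
#' @param f a `flux_set` (or named rate vector)
#' @param input_fn plasma input function: enrichment versus time (min),
#'   e.g. from [input_function()]
#' @param times increasing vector of output times (min); the first entry
#'   is the initial time
#' @param rtol,atol relative and absolute integration tolerances
#' @param engine `"cpp"` (default) or `"r"` (deSolve `lsoda`)
#' @param init_natural start every cumomer at natural abundance raised to
#'   its order (default); `FALSE` starts at exactly zero
#' @return A `cumomer_traj`: times, a states-by-time matrix of cumomer
#'   fractions, and the state table.
#' @export
integrate_system <- function(sys, f, input_fn, times, rtol = 1e-8,
                             atol = 1e-10, engine = c("cpp", "r"),
                             init_natural = TRUE) {
  engine <- match.arg(engine)
  if (is.null(sys$terms))
    stop("cumomer system has no right-hand side; call build_rhs() first")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (rtol <= 0 || atol <= 0) stop("tolerances must be positive")

  states <- sys$states
  n <- nrow(states)
  v <- resolve_rates(sys, f)

  k <- sys$terms$weight * as.numeric(v[sys$terms$flux])
  pool_out <- vapply(names(sys$outflow), function(pn) {
    o <- sys$outflow[[pn]]
    sum(as.numeric(v[names(o)]) * o)
  }, numeric(1))
  outrate <- ifelse(states$pool %in% names(pool_out),
                    pool_out[states$pool], 0)

  y0 <- if (init_natural) sys$na^states$order else rep(0, n)
  m <- nrow(sys$driven)
  const_slot <- n + m + 1L
  s1 <- ifelse(sys$terms$s1 == 0L, const_slot, sys$terms$s1)
  s2 <- ifelse(sys$terms$s2 == 0L, const_slot, sys$terms$s2)

  if (engine == "cpp") {
    tab <- input_table(input_fn, times[1], times[length(times)])
    vals <- rk45_integrate(
      y0, as.numeric(times),
      as.integer(sys$terms$tgt - 1L), k,
      as.integer(s1 - 1L), as.integer(s2 - 1L),
      as.numeric(outrate), as.numeric(states$conc),
      as.integer(sys$driven$a), as.integer(sys$driven$b),
      tab$t, tab$fe, sys$na, rtol, atol, 2000000L)
  } else {
    na <- sys$na
    a <- sys$driven$a; b <- sys$driven$b
    tgt <- sys$terms$tgt
    conc <- states$conc
    rhs <- function(t, y, parms) {
      fe <- input_fn(t)
      x <- c(y, fe^a * na^b, 1)
      infl <- k * x[s1] * x[s2]
      d <- numeric(n)
      agg <- rowsum(infl, tgt)
      d[as.integer(rownames(agg))] <- agg[, 1]
      list((d - outrate * y) / conc)
    }
    sol <- deSolve::ode(y0, as.numeric(times), rhs, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol)
    vals <- unname(sol[, -1, drop = FALSE])
  }
  colnames(vals) <- states$key
  structure(list(times = as.numeric(times), values = vals,
                 states = states),
            class = "cumomer_traj")
}

#' Extract one cumomer trajectory
#'
#' @param traj a `cumomer_traj`
#' @param pool pool name
#' @param positions carbon position(s) of the cumomer
#' @return Numeric vector of fractional enrichments over `traj$times`.
#' @export
get_fe <- function(traj, pool, positions) {
  key <- state_key(pool, sort(as.integer(positions)))
  if (!key %in% colnames(traj$values))
    stop("no tracked state ", key)
  traj$values[, key]
}

#' @export
print.cumomer_traj <- function(x, ...) {
  cat("Cumomer trajectories:", ncol(x$values), "states,",
      length(x$times), "time points on [",
      min(x$times), ",", max(x$times), "] min\n")
  invisible(x)
}

#' Export trajectories as a tidy data frame
#'
#' @param traj a `cumomer_traj`
#' @return Data frame with columns `time_min`, `pool`, `positions`, `fe`.
#' @export
trajectories_to_df <- function(traj) {
  st <- traj$states
  pos <- vapply(seq_len(nrow(st)), function(i)
    paste(st$first[i] + seq_len(st$order[i]) - 1L, collapse = ","),
    character(1))
  data.frame(
    time_min = rep(traj$times, times = nrow(st)),
    pool = rep(st$pool, each = length(traj$times)),
    positions = rep(pos, each = length(traj$times)),
    fe = as.vector(traj$values),
    stringsAsFactors = FALSE)
}
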