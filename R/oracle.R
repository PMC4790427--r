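bit_set <- function(iso, pos) bitwAnd(bitwShiftR(iso, pos - 1L), 1L) == 1L

#' Brute-force isotopomer simulation (test oracle)
#'
#' Simulates every isotopomer fraction of every non-input pool explicitly
#' (2^n states per n-carbon pool) and aggregates the solution into the
#' bonded cumomer states tracked by [enumerate_bonded_cumomers()]. By
#' cumomer theory the aggregate must coincide with the cumomer engine;
#' this function is deliberately implemented independently (dense
#' isotopomer balance equations integrated with `deSolve::lsoda`) so it
#' can serve as an oracle for the engine on small networks.
#'
#' @param net a `network`, small enough that the total isotopomer count
#'   stays below `cap`
#' @param f a `flux_set` or named rate vector
#' @param input_fn plasma input function (enrichment versus time)
#' @param times increasing output times (min)
#' @param cap maximum total number of isotopomer states (default 4096)
#' @param natural_abundance unlabeled-carbon enrichment (default 0.011)
#' @param rtol,atol integration tolerances
#' @return A `cumomer_traj` on the same state set as the cumomer engine.
#' @export
oracle_isotopomer_simulation <- function(net, f, input_fn, times,
                                         cap = 4096,
                                         natural_abundance = 0.011,
                                         rtol = 1e-10, atol = 1e-12) {
  na <- natural_abundance
  ode_pools <- Filter(function(p) !p$is_input, net$pools)
  sizes <- vapply(ode_pools, function(p) as.integer(2^p$n_carbons),
                  integer(1))
  if (sum(sizes) > cap)
    stop("isotopomer state count ", sum(sizes), " exceeds cap ", cap)
  offset <- setNames(cumsum(c(0L, sizes[-length(sizes)])), names(sizes))

  sysref <- enumerate_bonded_cumomers(net)
  v <- resolve_rates(build_rhs(net, sysref, na), f)

  # prebuild inflow descriptors: per reaction x product x orientation
  jobs <- list()
  for (r in net$reactions) {
    rate <- as.numeric(v[[r$flux]])
    for (q in names(r$products)) {
      cq <- net$pools[[q]]$n_carbons
      nq <- 2L^cq
      for (o in r$products[[q]]) {
        src <- strsplit(o$map, ".", fixed = TRUE)
        by_pool <- list()
        unl <- integer(0)
        for (j in seq_len(cq)) {
          if (identical(o$map[j], "*")) { unl <- c(unl, j); next }
          pn <- src[[j]][1]
          by_pool[[pn]] <- rbind(by_pool[[pn]],
                                 c(prod_pos = j,
                                   sub_pos = as.integer(src[[j]][2])))
        }
        naf <- vapply(0:(nq - 1L), function(p) {
          prod(vapply(unl, function(u)
            if (bit_set(p, u)) na else 1 - na, numeric(1)))
        }, numeric(1))
        groups <- lapply(names(by_pool), function(pn) {
          mp <- by_pool[[pn]]
          kk <- nrow(mp)
          # pattern id of product iso restricted to the mapped positions
          pid <- vapply(0:(nq - 1L), function(p) {
            s <- 0L
            for (r2 in seq_len(kk))
              if (bit_set(p, mp[r2, "prod_pos"])) s <- s + bitwShiftL(1L, r2 - 1L)
            s + 1L
          }, integer(1))
          if (net$pools[[pn]]$is_input) {
            hot <- mp[, "sub_pos"] %in% net$pools[[pn]]$hot_positions
            list(type = "input", pid = pid, hot = hot, k = kk)
          } else {
            cs <- net$pools[[pn]]$n_carbons
            gid <- vapply(0:(2L^cs - 1L), function(iso) {
              s <- 0L
              for (r2 in seq_len(kk))
                if (bit_set(iso, mp[r2, "sub_pos"])) s <- s + bitwShiftL(1L, r2 - 1L)
              s + 1L
            }, integer(1))
            list(type = "pool", pool = pn, pid = pid, gid = gid, k = kk)
          }
        })
        jobs[[length(jobs) + 1L]] <- list(
          q = q, nq = nq, rate = rate * o$weight, naf = naf,
          groups = groups)
      }
    }
  }

  # total consumption rate per pool
  cons <- setNames(numeric(length(ode_pools)), names(ode_pools))
  for (r in net$reactions)
    for (pn in names(r$substrates))
      if (pn %in% names(cons))
        cons[pn] <- cons[pn] + as.numeric(v[[r$flux]]) * r$substrates[[pn]]

  conc <- vapply(ode_pools, `[[`, numeric(1), "concentration")

  rhs <- function(t, x, parms) {
    fe <- input_fn(t)
    dx <- numeric(length(x))
    for (jb in jobs) {
      infl <- rep(jb$rate, jb$nq) * jb$naf
      for (g in jb$groups) {
        marg <- if (g$type == "input") {
          fev <- ifelse(g$hot, fe, na)
          vapply(seq_len(2L^g$k), function(pat) {
            prod(ifelse(bit_set(pat - 1L, seq_len(g$k)), fev, 1 - fev))
          }, numeric(1))
        } else {
          xs <- x[offset[[g$pool]] + seq_len(2L^net$pools[[g$pool]]$n_carbons)]
          as.numeric(rowsum(xs, g$gid)[, 1])
        }
        infl <- infl * marg[g$pid]
      }
      io <- offset[[jb$q]]
      dx[io + seq_len(jb$nq)] <- dx[io + seq_len(jb$nq)] + infl
    }
    for (pn in names(ode_pools)) {
      id <- offset[[pn]] + seq_len(sizes[[pn]])
      dx[id] <- (dx[id] - cons[[pn]] * x[id]) / conc[[pn]]
    }
    list(dx)
  }

  x0 <- unlist(lapply(ode_pools, function(p) {
    vapply(0:(2L^p$n_carbons - 1L), function(iso) {
      nb <- sum(vapply(seq_len(p$n_carbons), function(j)
        bit_set(iso, j), logical(1)))
      na^nb * (1 - na)^(p$n_carbons - nb)
    }, numeric(1))
  }))

  sol <- deSolve::ode(unname(x0), as.numeric(times), rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  xs <- unname(sol[, -1, drop = FALSE])

  # aggregate isotopomers into the tracked bonded cumomers
  st <- sysref$states
  vals <- matrix(0, nrow = length(times), ncol = nrow(st))
  for (i in seq_len(nrow(st))) {
    p <- net$pools[[st$pool[i]]]
    positions <- st$first[i] + seq_len(st$order[i]) - 1L
    sel <- vapply(0:(2L^p$n_carbons - 1L), function(iso)
      all(vapply(positions, function(j) bit_set(iso, j), logical(1))),
      logical(1))
    id <- offset[[st$pool[i]]] + which(sel)
    vals[, i] <- rowSums(xs[, id, drop = FALSE])
  }
  colnames(vals) <- st$key
  structure(list(times = as.numeric(times), values = vals, states = st),
            class = "cumomer_traj")
}
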