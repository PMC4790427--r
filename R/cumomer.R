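state_key <- function(pool, positions) {
  paste0(pool, ":", paste(positions, collapse = ","))
}

# does any consuming reaction of `pname` pass the fragment `positions`
# on intact (onto adjacent carbons of some product)?
fragment_transferred <- function(net, pname, positions) {
  tags <- paste0(pname, ".", positions)
  for (r in net$reactions) {
    if (!pname %in% names(r$substrates)) next
    for (q in names(r$products)) {
      for (o in r$products[[q]]) {
        hit <- which(o$map %in% tags)
        if (length(hit) == length(positions) &&
            all(diff(sort(hit)) == 1L) &&
            setequal(o$map[hit], tags))
          return(TRUE)
      }
    }
  }
  FALSE
}

has_consumer <- function(net, pname) {
  any(vapply(net$reactions,
             function(r) pname %in% names(r$substrates), logical(1)))
}

#' Enumerate the bonded cumomer states of a network
#'
#' Every non-input pool contributes all its order-1 (positional) cumomers
#' and its bonded cumomers of order 2..`max_order` (sets of carbons that
#' are pairwise adjacent in the carbon chain). An intact-fragment filter
#' removes bonded states that can never influence any other pool or
#' observable: a multi-carbon fragment is dropped when the pool is
#' consumed by at least one reaction but every consuming reaction cleaves
#' the fragment, and the pool is not itself NMR-measured. In the canonical
#' network this removes only the glucose fragments spanning the
#' aldolase-cleaved C3-C4 bond; the resulting state count is 133.
#'
#' @param net a `network`
#' @param max_order highest cumomer order tracked (default 3, the order
#'   needed to predict all one-bond multiplet patterns)
#' @return A `cumomer_system` (states enumerated, right-hand side not yet
#'   attached); its `states` element is a data frame with one row per ODE.
#' @export
enumerate_bonded_cumomers <- function(net, max_order = 3) {
  stopifnot(max_order >= 1, max_order <= 3)
  rows <- list()
  for (p in net$pools) {
    if (p$is_input) next
    consumed <- has_consumer(net, p$name)
    measured <- p$name %in% net$measured_pools
    for (ord in seq_len(min(max_order, p$n_carbons))) {
      for (first in seq_len(p$n_carbons - ord + 1L)) {
        positions <- first:(first + ord - 1L)
        if (ord > 1L && consumed && !measured &&
            !fragment_transferred(net, p$name, positions)) next
        rows[[length(rows) + 1L]] <- data.frame(
          pool = p$name, first = first, order = ord,
          key = state_key(p$name, positions),
          conc = p$concentration, stringsAsFactors = FALSE)
      }
    }
  }
  states <- do.call(rbind, rows)
  # order states by pool (network order), then order, then position
  structure(list(net = net, states = states, terms = NULL, driven = NULL,
                 outflow = NULL, na = 0.011),
            class = "cumomer_system")
}

#' @export
print.cumomer_system <- function(x, ...) {
  cat("Bonded cumomer system:", nrow(x$states), "state equations")
  cat(if (is.null(x$terms)) " (rhs not built)\n" else " (rhs built)\n")
  tab <- table(x$states$pool)
  cat(paste0("  ", names(tab), ": ", as.integer(tab), collapse = "\n"), "\n")
  invisible(x)
}

#' Attach the labeling right-hand side to a cumomer system
#'
#' Builds the term table of the cumomer balance equations. For a cumomer
#' S of pool M with concentration P,
#' `P * dpi_S/dt = sum_inflows V * prod(source cumomer fractions covering
#' the mapped positions) - (sum_outflows V) * pi_S`.
#' Condensation reactions contribute the product of the cumomer fractions
#' of the substrates supplying the fragment; unlabeled sources contribute
#' a factor equal to the natural-abundance enrichment; orientation
#' variants of symmetric reactions enter with their weights.
#'
#' @param net a `network`
#' @param sys a `cumomer_system` from [enumerate_bonded_cumomers()]
#' @param natural_abundance fractional enrichment of unlabeled carbon
#'   (default 0.011)
#' @return The `cumomer_system` with `terms`, `driven` and `outflow`
#'   attached, ready for [integrate_system()].
#' @export
build_rhs <- function(net, sys, natural_abundance = 0.011) {
  states <- sys$states
  idx <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(states))) assign(states$key[i], i, envir = idx)

  driven_keys <- new.env(parent = emptyenv())
  driven_rows <- list()
  get_driven <- function(pool, positions) {
    key <- state_key(pool, positions)
    if (!is.null(driven_keys[[key]])) return(driven_keys[[key]])
    hot <- net$pools[[pool]]$hot_positions
    a <- sum(positions %in% hot)
    j <- length(driven_rows) + 1L
    driven_rows[[j]] <<- data.frame(key = key, a = a,
                                    b = length(positions) - a)
    driven_keys[[key]] <- j
    j
  }

  tgt <- integer(0); wgt <- numeric(0); flx <- character(0)
  src1 <- integer(0); src2 <- integer(0)
  n <- nrow(states)

  for (r in net$reactions) {
    for (q in names(r$products)) {
      q_states <- which(states$pool == q)
      for (o in r$products[[q]]) {
        src_split <- strsplit(o$map, ".", fixed = TRUE)
        for (i in q_states) {
          positions <- states$first[i] + seq_len(states$order[i]) - 1L
          unl <- 0L
          by_pool <- list()
          for (j in positions) {
            s <- src_split[[j]]
            if (identical(o$map[j], "*")) { unl <- unl + 1L; next }
            by_pool[[s[1]]] <- c(by_pool[[s[1]]], as.integer(s[2]))
          }
          factors <- integer(0)
          for (pn in names(by_pool)) {
            ps <- sort(by_pool[[pn]])
            if (net$pools[[pn]]$is_input) {
              factors <- c(factors, n + get_driven(pn, ps))
            } else {
              if (length(ps) > 1L && any(diff(ps) != 1L))
                stop("state ", states$key[i], " in reaction ", r$name,
                     " needs non-adjacent source carbons ",
                     state_key(pn, ps))
              k <- idx[[state_key(pn, ps)]]
              if (is.null(k))
                stop("state ", states$key[i], " in reaction ", r$name,
                     " requires untracked source cumomer ",
                     state_key(pn, ps))
              factors <- c(factors, k)
            }
          }
          if (length(factors) > 2L)
            stop("more than two labeled substrates feed ", states$key[i],
                 " in reaction ", r$name)
          tgt <- c(tgt, i)
          wgt <- c(wgt, o$weight * natural_abundance^unl)
          flx <- c(flx, r$flux)
          src1 <- c(src1, if (length(factors) >= 1L) factors[1] else 0L)
          src2 <- c(src2, if (length(factors) >= 2L) factors[2] else 0L)
        }
      }
    }
  }

  # molecular outflow rates per pool: named list of flux -> stoichiometry
  outflow <- list()
  for (r in net$reactions) {
    for (pn in names(r$substrates)) {
      cur <- outflow[[pn]]
      if (is.null(cur)) cur <- numeric(0)
      cur[r$flux] <- (if (r$flux %in% names(cur)) cur[[r$flux]] else 0) +
        r$substrates[[pn]]
      outflow[[pn]] <- cur
    }
  }

  sys$terms <- data.frame(tgt = tgt, flux = flx, weight = wgt,
                          s1 = src1, s2 = src2, stringsAsFactors = FALSE)
  sys$driven <- if (length(driven_rows) > 0) do.call(rbind, driven_rows)
                else data.frame(key = character(0), a = integer(0),
                                b = integer(0))
  sys$outflow <- outflow
  sys$na <- natural_abundance
  sys
}

#' Build a ready-to-integrate cumomer system
#'
#' Convenience wrapper: [enumerate_bonded_cumomers()] followed by
#' [build_rhs()]. `max_order = 1` gives the positional model (total
#' enrichment per carbon only), the first-order reduction of the bonded
#' cumomer model.
#'
#' @inheritParams enumerate_bonded_cumomers
#' @inheritParams build_rhs
#' @return A `cumomer_system` with the right-hand side attached.
#' @export
build_cumomer_system <- function(net, max_order = 3,
                                 natural_abundance = 0.011) {
  build_rhs(net, enumerate_bonded_cumomers(net, max_order),
            natural_abundance)
}
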