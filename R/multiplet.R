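check_containment <- function(pc, p_left, p_right, p_triple, tol) {
  bad <- p_left > pc + tol | p_right > pc + tol |
    p_triple > p_left + tol | p_triple > p_right + tol |
    pc > 1 + tol | p_triple < -tol | p_left < -tol | p_right < -tol
  if (any(bad))
    stop("cumomer containment violated beyond tolerance ", tol)
}

#' Multiplet decomposition for a carbon with two distinct couplings
#'
#' Converts the bonded cumomer fractions around a carbon position into the
#' observable multiplet intensities when the two one-bond couplings
#' differ (e.g. C4 of glutamate, coupled to C3 and C5): a doublet of
#' doublets (quartet) Q when both neighbours are labeled, doublets toward
#' either neighbour, and a singlet. All intensities are fractions of the
#' pool and sum to the positional enrichment `pc`.
#'
#' @param pc order-1 cumomer of the observed position
#' @param p_left bonded pair cumomer with the lower-numbered neighbour
#' @param p_right bonded pair cumomer with the higher-numbered neighbour
#' @param p_triple bonded triple covering both neighbours
#' @param tol containment tolerance (default 1e-8)
#' @return List with components `Q`, `D_left`, `D_right`, `S` (vectors if
#'   the inputs are vectors).
#' @export
c4_type_transform <- function(pc, p_left, p_right, p_triple, tol = 1e-8) {
  check_containment(pc, p_left, p_right, p_triple, tol)
  list(Q = p_triple,
       D_left = p_left - p_triple,
       D_right = p_right - p_triple,
       S = pc - p_left - p_right + p_triple)
}

#' Multiplet decomposition for a carbon with two equal couplings
#'
#' As [c4_type_transform()], but for a position whose couplings to the two
#' neighbours are identical (e.g. C3 of glutamate): both-neighbour
#' labeling gives a triplet T, single-neighbour labeling a doublet D
#' (both doublets coincide), no labeled neighbour a singlet S.
#'
#' @inheritParams c4_type_transform
#' @return List with components `T`, `D`, `S`.
#' @export
c3_type_transform <- function(pc, p_left, p_right, p_triple, tol = 1e-8) {
  check_containment(pc, p_left, p_right, p_triple, tol)
  list(T = p_triple,
       D = p_left + p_right - 2 * p_triple,
       S = pc - p_left - p_right + p_triple)
}

#' Positional enrichment of C3 from the C4 multiplets
#'
#' The doublet D34 of the C4 resonance arises from molecules doubly
#' labeled at C4 and C3, the C4 singlet from molecules labeled at C4
#' only; their ratio gives the fractional enrichment of C3 among
#' C4-labeled molecules: `FE(C3) = D34 / (S + D34)`. Used to put
#' dynamically measured spectra on an absolute enrichment scale.
#'
#' @param c4_d34 area of the C4 doublet toward C3
#' @param c4_s area of the C4 singlet
#' @return The enrichment ratio in `[0, 1]`.
#' @export
fe_c3_from_c4_multiplets <- function(c4_d34, c4_s) {
  if (any(c4_d34 < 0) || any(c4_s < 0))
    stop("multiplet areas must be nonnegative")
  tot <- c4_s + c4_d34
  if (any(tot == 0)) stop("C4 singlet and D34 areas are both zero")
  c4_d34 / tot
}

#' Sum of singlet and triplet intensities
#'
#' The central line of the C3 triplet overlaps the C3 singlet, so the two
#' cannot be quantified separately at low enrichment; their sum is the
#' reliably quantified observable, computed here per time point.
#'
#' @param s singlet intensities
#' @param t triplet intensities
#' @return Elementwise sum.
#' @export
merge_singlet_triplet <- function(s, t) {
  if (any(s < 0) || any(t < 0)) stop("intensities must be nonnegative")
  s + t
}

# positions of the bonded cumomers entering the multiplet transform of
# carbon `pos` of a 5-carbon amino acid: centre, left pair, right pair,
# triple
multiplet_inputs <- function(pos) {
  list(centre = pos, left = c(pos - 1L, pos), right = c(pos, pos + 1L),
       triple = c(pos - 1L, pos, pos + 1L))
}

#' Multiplet time courses of the measured amino acids
#'
#' Applies the cumomer-to-multiplet transforms to simulated trajectories
#' and returns the full pattern set for glutamate and glutamine carbons
#' C4, C3 and C2. The measured glutamate signal mixes the neuronal and
#' glial pools weighted by concentration; glutamine is purely glial.
#' C4 uses the distinct-coupling transform (patterns S, D43, D45, Q), C3
#' the equal-coupling transform (S, D, T, and the merged S+T), and C2 the
#' distinct-coupling transform with the pair toward C1 folded into the
#' reported patterns S and D23.
#'
#' @param traj a `cumomer_traj` from [integrate_system()] on the full
#'   (order-3) system
#' @param net the `network` the trajectories came from
#' @return Tidy data frame: `time_min`, `metabolite` (`"glu"`, `"gln"`),
#'   `position` (4, 3, 2), `pattern`, `fe`.
#' @export
multiplet_curves <- function(traj, net) {
  mix <- function(pools, positions) {
    w <- vapply(pools, function(p) net$pools[[p]]$concentration,
                numeric(1))
    w <- w / sum(w)
    out <- 0
    for (i in seq_along(pools))
      out <- out + w[i] * get_fe(traj, pools[i], positions)
    out
  }
  rows <- list()
  add <- function(met, pos, pattern, fe)
    rows[[length(rows) + 1L]] <<- data.frame(
      time_min = traj$times, metabolite = met, position = pos,
      pattern = pattern, fe = fe, stringsAsFactors = FALSE)

  for (met in names(net$observables)) {
    pools <- net$observables[[met]]
    for (pos in c(4L, 3L, 2L)) {
      mi <- multiplet_inputs(pos)
      pc <- mix(pools, mi$centre)
      pl <- mix(pools, mi$left)
      pr <- mix(pools, mi$right)
      pt <- mix(pools, mi$triple)
      add(met, pos, "total", pc)
      if (pos == 3L) {
        m <- c3_type_transform(pc, pl, pr, pt, tol = 1e-6)
        add(met, pos, "S", m$S)
        add(met, pos, "D", m$D)
        add(met, pos, "T", m$T)
        add(met, pos, "S+T", merge_singlet_triplet(m$S, m$T))
      } else {
        m <- c4_type_transform(pc, pl, pr, pt, tol = 1e-6)
        add(met, pos, "S", m$S)
        if (pos == 4L) {
          add(met, pos, "D43", m$D_left)
          add(met, pos, "D45", m$D_right)
          add(met, pos, "Q", m$Q)
        } else {
          add(met, pos, "D21", m$D_left)
          add(met, pos, "D23", m$D_right)
          add(met, pos, "Q", m$Q)
        }
      }
    }
  }
  do.call(rbind, rows)
}
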