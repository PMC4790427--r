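#' Names of the free fluxes
#'
#' The seven independently estimated fluxes of the two-compartment
#' neuronal-glial model, in micromol/g/min:
#' \describe{
#'   \item{Vpdh_n}{neuronal pyruvate dehydrogenase = neuronal TCA cycle rate}
#'   \item{Vg}{glial oxidative (PDH-driven) TCA component}
#'   \item{Vpc}{pyruvate carboxylase (glial anaplerosis)}
#'   \item{Vx}{exchange between cytosolic amino acids (Glu, Asp) and
#'     mitochondrial TCA intermediates (2-oxoglutarate, oxaloacetate),
#'     reflecting malate-aspartate shuttle activity}
#'   \item{Vnt}{apparent glutamate-glutamine neurotransmission cycle flux}
#'   \item{Vdil}{exchange of glial acetyl-CoA with unlabeled alternative
#'     substrates (glial dilution)}
#'   \item{Vout}{efflux of brain lactate, balanced by an equal unlabeled
#'     inflow Vin from extracerebral lactate}
#' }
#' @export
free_flux_names <- c("Vpdh_n", "Vg", "Vpc", "Vx", "Vnt", "Vdil", "Vout")

#' Create a flux set
#'
#' A flux set holds the seven free fluxes of the two-compartment model.
#' Derived fluxes (glial TCA rate, glutamine synthesis, oxidative glucose
#' consumption, ...) are filled in by [derived_fluxes()].
#'
#' Defaults are the reference condition used by the synthetic-data
#' generator: Vnt and Vdil sit at the middle of the sensitivity-scan grids
#' (0.10 and 0.30) and the TCA fluxes are chosen so that the derived
#' oxidative glucose consumption CMRglc_ox equals 0.28 micromol/g/min.
#'
#' @param Vpdh_n,Vg,Vpc,Vx,Vnt,Vdil,Vout free fluxes, micromol/g/min; see
#'   [free_flux_names] for meanings. All must be nonnegative.
#' @return An object of class `flux_set`.
#' @examples
#' f <- flux_set(Vg = 0.10, Vpc = 0.06)
#' derived_fluxes(f)
#' @export
flux_set <- function(Vpdh_n = 0.40, Vg = 0.10, Vpc = 0.06, Vx = 0.45,
                     Vnt = 0.10, Vdil = 0.30, Vout = 0.30) {
  free <- c(Vpdh_n = Vpdh_n, Vg = Vg, Vpc = Vpc, Vx = Vx, Vnt = Vnt,
            Vdil = Vdil, Vout = Vout)
  if (any(!is.finite(free))) stop("all free fluxes must be finite numbers")
  if (any(free < 0)) stop("all free fluxes must be nonnegative")
  structure(list(free = free, derived = NULL), class = "flux_set")
}

#' Build a flux set from a named vector
#'
#' @param x named numeric vector containing at least the entries of
#'   [free_flux_names].
#' @return A `flux_set`.
#' @export
as_flux_set <- function(x) {
  if (inherits(x, "flux_set")) return(x)
  x <- unlist(x)
  missing <- setdiff(free_flux_names, names(x))
  if (length(missing) > 0)
    stop("missing free fluxes: ", paste(missing, collapse = ", "))
  do.call(flux_set, as.list(x[free_flux_names]))
}

#' Fill in the derived fluxes of a flux set
#'
#' At metabolic steady state the remaining fluxes of the network follow
#' from the free fluxes by mass balance:
#' \itemize{
#'   \item `VTCA_g = Vg + Vpc` (total glial TCA cycle rate),
#'   \item `Vefflux = Vpc` (glutamine efflux balancing anaplerosis),
#'   \item `Vsyn = Vnt + Vefflux` (glutamine synthetase rate),
#'   \item `CMRglc_ox = (Vpdh_n + Vg + Vpc) / 2` (oxidative glucose
#'     consumption, i.e. half the summed TCA rates),
#'   \item `Vin = Vout` (unlabeled lactate inflow balancing lactate loss).
#' }
#'
#' @param f a `flux_set`
#' @return The same `flux_set` with the `derived` element filled.
#' @export
derived_fluxes <- function(f) {
  f <- as_flux_set(f)
  fr <- as.list(f$free)
  f$derived <- c(
    VTCA_n    = fr$Vpdh_n,
    VTCA_g    = fr$Vg + fr$Vpc,
    Vefflux   = fr$Vpc,
    Vsyn      = fr$Vnt + fr$Vpc,
    CMRglc_ox = (fr$Vpdh_n + fr$Vg + fr$Vpc) / 2,
    Vin       = fr$Vout
  )
  f
}

# All named rates that scale individual reactions of the canonical network.
# `constants` carries model constants that are not estimated (currently the
# lactate dehydrogenase exchange rate).
flux_values <- function(f, constants = c(Vex_lac = 0.5)) {
  f <- derived_fluxes(f)
  fr <- as.list(f$free)
  v <- c(
    f$free,
    f$derived,
    # glycolysis in pyruvate units feeding each compartment
    Vgly_n   = fr$Vpdh_n,
    Vgly_g   = fr$Vg + 2 * fr$Vpc,
    # glial PDH supplies all glial acetyl-CoA consumed by citrate synthase
    Vpdh_g   = fr$Vg + fr$Vpc,
    # glucose transport, glucose units: oxidised plus anaplerotic carbon
    CMRglc   = (fr$Vpdh_n + fr$Vg + 2 * fr$Vpc) / 2,
    # glial oxidative branch past 2-oxoglutarate (anaplerotic carbon has
    # left the cycle as glutamine by then)
    Vogdh_g  = fr$Vg,
    # net 2-oxoglutarate -> glutamate flow in the glia carries Vpc de novo
    Vglu_g_in = fr$Vx + fr$Vpc,
    # CO2 efflux balancing decarboxylations minus pyruvate carboxylase
    Vco2_out = 3 * fr$Vpdh_n + 3 * fr$Vg + fr$Vpc
  )
  c(v, constants)
}

#' @export
print.flux_set <- function(x, ...) {
  cat("Flux set (micromol/g/min)\n")
  print(round(x$free, 4))
  if (!is.null(x$derived)) {
    cat("derived:\n")
    print(round(x$derived, 4))
  }
  invisible(x)
}

#' Reference fluxes of the synthetic-data generator
#'
#' Returns the flux set used as ground truth when generating synthetic
#' experiments: Vnt = 0.10 and Vdil = 0.30 (the middle values of the
#' sensitivity-scan grids), Vpdh_n = 0.40, Vg = 0.10, Vpc = 0.06 so that
#' CMRglc_ox = 0.28 micromol/g/min, Vx = 0.45 (slightly above Vpdh_n, as
#' expected when the malate-aspartate shuttle maintains the cytosolic
#' redox state), and Vout = 0.30.
#'
#' @return A `flux_set` with derived fluxes filled.
#' @export
default_truth_fluxes <- function() {
  derived_fluxes(flux_set())
}
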