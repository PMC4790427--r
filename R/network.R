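#' Define a metabolite pool
#'
#' @param name pool identifier, e.g. `"Glu_n"`
#' @param compartment one of `"neuronal"`, `"glial"`, `"shared"`, `"input"`
#' @param n_carbons number of carbon positions (1..6)
#' @param concentration pool size in micromol/g, fixed over the experiment
#'   (metabolic steady state). Ignored for input pools.
#' @param is_input `TRUE` for driven pools whose enrichment is imposed from
#'   outside (plasma glucose)
#' @param hot_positions for input pools, the carbon positions carrying the
#'   infused label; the remaining positions stay at natural abundance
#' @return A list of class `pool`.
#' @export
pool <- function(name, compartment, n_carbons, concentration = NA_real_,
                 is_input = FALSE, hot_positions = integer(0)) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!compartment %in% c("neuronal", "glial", "shared", "input"))
    stop("unknown compartment: ", compartment)
  n_carbons <- as.integer(n_carbons)
  if (n_carbons < 1L || n_carbons > 6L)
    stop("n_carbons must be in 1..6 for pool ", name)
  if (!is_input) {
    if (!is.finite(concentration) || concentration <= 0)
      stop("concentration must be positive for pool ", name)
  }
  structure(list(name = name, compartment = compartment,
                 n_carbons = n_carbons, concentration = concentration,
                 is_input = is_input,
                 hot_positions = as.integer(hot_positions)),
            class = "pool")
}

#' Define an atom-mapped reaction
#'
#' Atom maps are given per product as character vectors with one entry per
#' product carbon, `"pool.position"` naming the source carbon or `"*"` for
#' an unlabeled source (CO2 entering via carboxylation, dilution inflows).
#' A reaction passing through a symmetric intermediate (fumarate-type
#' scrambling, or the two triose halves of glucose) lists two orientation
#' maps applied with weight 1/2 each.
#'
#' @param name reaction identifier
#' @param flux name of the rate (free, derived or constant) that scales the
#'   reaction; resolved against [flux_values()]
#' @param substrates named numeric vector: consumed pools and the number of
#'   substrate molecules consumed per product molecule formed (1 except for
#'   glycolysis, where half a glucose is consumed per pyruvate)
#' @param products list: one element per product pool, each a list of
#'   orientations `list(weight =, map =)`
#' @return A list of class `reaction`.
#' @export
reaction <- function(name, flux, substrates = numeric(0), products = list()) {
  for (p in names(products)) {
    w <- vapply(products[[p]], function(o) o$weight, numeric(1))
    if (abs(sum(w) - 1) > 1e-12)
      stop("orientation weights for product ", p, " of ", name,
           " must sum to 1")
  }
  structure(list(name = name, flux = flux, substrates = substrates,
                 products = products), class = "reaction")
}

# single-orientation helper
orient1 <- function(map) list(list(weight = 1, map = map))

# identity atom map: product carbon i <- source carbon i
idmap <- function(src, n) paste0(src, ".", seq_len(n))

#' Build the canonical two-compartment neuronal-glial network
#'
#' Constructs the atom-mapped metabolic network used throughout the
#' package: plasma glucose (driven input, labeled at C1 and C6) feeding
#' brain glucose, glycolysis to compartment-specific pyruvate pools, a
#' shared lactate pool exchanging with both pyruvate pools and with an
#' unlabeled extracerebral lactate pool (Vin/Vout), pyruvate
#' dehydrogenase, a full TCA span per compartment (acetyl-CoA,
#' 2-oxoglutarate, oxaloacetate) with fumarate-type scrambling between
#' 2-oxoglutarate and oxaloacetate, exchange of the TCA intermediates with
#' the amino-acid pools (Glu, Asp in both compartments) at rate Vx,
#' pyruvate carboxylase fixing CO2 into glial oxaloacetate, an unlabeled
#' dilution exchange at glial acetyl-CoA (Vdil), the
#' glutamate-glutamine neurotransmission cycle (Vnt), glutamine synthesis
#' (Vsyn) and glutamine efflux balancing anaplerosis (Vefflux = Vpc), and
#' a brain CO2/bicarbonate pool closing the decarboxylation balance.
#'
#' Atom mappings follow standard TCA-cycle biochemistry. Citrate synthase
#' places the acetyl methyl carbon on 2-oxoglutarate C4 and the acetyl
#' carboxyl on C5, and transfers the oxaloacetate arm in reversed order
#' (OAA C4, C3, C2 onto OG C1, C2, C3) while OAA C1 is lost as CO2; this
#' is what routes pyruvate-carboxylase carbon (pyruvate C3) to glutamate
#' and glutamine C2 and dilutes their C3 in the glia.
#'
#' @param config optional named list of concentration overrides
#'   (micromol/g). Recognised names: `Glu`, `Gln`, `Asp` (totals, split
#'   across compartments as 90/10 for Glu, 100% glial for Gln, 60/40 for
#'   Asp), and per-pool names such as `Glc_b`, `Lac`, `Pyr_n`, `Pyr_g`,
#'   `AcCoA_n`, `AcCoA_g`, `OG_n`, `OG_g`, `OAA_n`, `OAA_g`, `CO2`.
#' @return A list of class `network` with elements `pools`, `reactions`,
#'   `measured_pools`, `observables` (measured-signal composition) and
#'   `constants`.
#' @examples
#' net <- build_default_network()
#' names(net$pools)
#' @export
build_default_network <- function(config = list()) {
  conc <- list(
    Glu = 8.4, Gln = 4.3, Asp = 2.5,
    Glc_b = 1.2, Lac = 1.0,
    Pyr_n = 0.15, Pyr_g = 0.15,
    AcCoA_n = 0.1, AcCoA_g = 0.1,
    OG_n = 0.2, OG_g = 0.1,
    OAA_n = 0.1, OAA_g = 0.1,
    CO2 = 1.0
  )
  bad <- setdiff(names(config), names(conc))
  if (length(bad) > 0) stop("unknown config entries: ", paste(bad, collapse = ", "))
  conc <- modifyList(conc, config)
  num <- unlist(conc)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all configured concentrations must be positive")

  pools <- list(
    pool("Glc_p", "input", 6, is_input = TRUE, hot_positions = c(1L, 6L)),
    pool("Glc_b", "shared", 6, conc$Glc_b),
    pool("Lac",   "shared", 3, conc$Lac),
    pool("Pyr_n", "neuronal", 3, conc$Pyr_n),
    pool("Pyr_g", "glial",    3, conc$Pyr_g),
    pool("AcCoA_n", "neuronal", 2, conc$AcCoA_n),
    pool("AcCoA_g", "glial",    2, conc$AcCoA_g),
    pool("OG_n",  "neuronal", 5, conc$OG_n),
    pool("OG_g",  "glial",    5, conc$OG_g),
    pool("Glu_n", "neuronal", 5, 0.9 * conc$Glu),
    pool("Glu_g", "glial",    5, 0.1 * conc$Glu),
    pool("Gln",   "glial",    5, conc$Gln),
    pool("OAA_n", "neuronal", 4, conc$OAA_n),
    pool("OAA_g", "glial",    4, conc$OAA_g),
    pool("Asp_n", "neuronal", 4, 0.6 * conc$Asp),
    pool("Asp_g", "glial",    4, 0.4 * conc$Asp),
    pool("CO2",   "shared",   1, conc$CO2)
  )
  names(pools) <- vapply(pools, `[[`, character(1), "name")

  # glycolysis orientation maps: each triose half of glucose yields one
  # pyruvate, C1/C6 -> pyruvate C3 (methyl), C3/C4 -> pyruvate C1
  gly <- function(target) list(
    list(weight = 0.5, map = c("Glc_b.3", "Glc_b.2", "Glc_b.1")),
    list(weight = 0.5, map = c("Glc_b.4", "Glc_b.5", "Glc_b.6"))
  )
  # citrate synthase + isocitrate dehydrogenase, compartment cc
  cs <- function(cc) {
    oaa <- paste0("OAA_", cc); ac <- paste0("AcCoA_", cc)
    list(
      OG = orient1(c(paste0(oaa, ".4"), paste0(oaa, ".3"), paste0(oaa, ".2"),
                     paste0(ac, ".2"), paste0(ac, ".1"))),
      CO2 = orient1(paste0(oaa, ".1"))
    )
  }
  # 2-oxoglutarate -> oxaloacetate through symmetric succinate/fumarate
  ogdh <- function(cc) {
    og <- paste0("OG_", cc)
    list(
      OAA = list(
        list(weight = 0.5, map = paste0(og, ".", 2:5)),
        list(weight = 0.5, map = paste0(og, ".", 5:2))
      ),
      CO2 = orient1(paste0(og, ".1"))
    )
  }

  rx <- list(
    reaction("glc_transport", "CMRglc", c(Glc_p = 1),
             list(Glc_b = orient1(idmap("Glc_p", 6)))),
    reaction("glycolysis_n", "Vgly_n", c(Glc_b = 0.5), list(Pyr_n = gly())),
    reaction("glycolysis_g", "Vgly_g", c(Glc_b = 0.5), list(Pyr_g = gly())),
    reaction("ldh_n_fwd", "Vex_lac", c(Pyr_n = 1),
             list(Lac = orient1(idmap("Pyr_n", 3)))),
    reaction("ldh_n_rev", "Vex_lac", c(Lac = 1),
             list(Pyr_n = orient1(idmap("Lac", 3)))),
    reaction("ldh_g_fwd", "Vex_lac", c(Pyr_g = 1),
             list(Lac = orient1(idmap("Pyr_g", 3)))),
    reaction("ldh_g_rev", "Vex_lac", c(Lac = 1),
             list(Pyr_g = orient1(idmap("Lac", 3)))),
    reaction("lac_inflow", "Vin", numeric(0),
             list(Lac = orient1(rep("*", 3)))),
    reaction("lac_efflux", "Vout", c(Lac = 1)),
    reaction("pdh_n", "Vpdh_n", c(Pyr_n = 1),
             list(AcCoA_n = orient1(c("Pyr_n.2", "Pyr_n.3")),
                  CO2 = orient1("Pyr_n.1"))),
    reaction("pdh_g", "Vpdh_g", c(Pyr_g = 1),
             list(AcCoA_g = orient1(c("Pyr_g.2", "Pyr_g.3")),
                  CO2 = orient1("Pyr_g.1"))),
    reaction("acdil_in", "Vdil", numeric(0),
             list(AcCoA_g = orient1(rep("*", 2)))),
    reaction("acdil_out", "Vdil", c(AcCoA_g = 1)),
    reaction("cs_n", "VTCA_n", c(OAA_n = 1, AcCoA_n = 1),
             setNames(cs("n"), c("OG_n", "CO2"))),
    reaction("cs_g", "VTCA_g", c(OAA_g = 1, AcCoA_g = 1),
             setNames(cs("g"), c("OG_g", "CO2"))),
    reaction("ogdh_n", "VTCA_n", c(OG_n = 1),
             setNames(ogdh("n"), c("OAA_n", "CO2"))),
    reaction("ogdh_g", "Vogdh_g", c(OG_g = 1),
             setNames(ogdh("g"), c("OAA_g", "CO2"))),
    reaction("pc", "Vpc", c(Pyr_g = 1, CO2 = 1),
             list(OAA_g = orient1(c("Pyr_g.1", "Pyr_g.2", "Pyr_g.3", "CO2.1")))),
    reaction("vx_og_glu_n_f", "Vx", c(OG_n = 1),
             list(Glu_n = orient1(idmap("OG_n", 5)))),
    reaction("vx_og_glu_n_r", "Vx", c(Glu_n = 1),
             list(OG_n = orient1(idmap("Glu_n", 5)))),
    reaction("vx_oaa_asp_n_f", "Vx", c(OAA_n = 1),
             list(Asp_n = orient1(idmap("OAA_n", 4)))),
    reaction("vx_oaa_asp_n_r", "Vx", c(Asp_n = 1),
             list(OAA_n = orient1(idmap("Asp_n", 4)))),
    reaction("vx_og_glu_g_f", "Vglu_g_in", c(OG_g = 1),
             list(Glu_g = orient1(idmap("OG_g", 5)))),
    reaction("vx_og_glu_g_r", "Vx", c(Glu_g = 1),
             list(OG_g = orient1(idmap("Glu_g", 5)))),
    reaction("vx_oaa_asp_g_f", "Vx", c(OAA_g = 1),
             list(Asp_g = orient1(idmap("OAA_g", 4)))),
    reaction("vx_oaa_asp_g_r", "Vx", c(Asp_g = 1),
             list(OAA_g = orient1(idmap("Asp_g", 4)))),
    reaction("gln_synthetase", "Vsyn", c(Glu_g = 1),
             list(Gln = orient1(idmap("Glu_g", 5)))),
    reaction("glu_release", "Vnt", c(Glu_n = 1),
             list(Glu_g = orient1(idmap("Glu_n", 5)))),
    reaction("glnase_n", "Vnt", c(Gln = 1),
             list(Glu_n = orient1(idmap("Gln", 5)))),
    reaction("gln_efflux", "Vefflux", c(Gln = 1)),
    reaction("co2_efflux", "Vco2_out", c(CO2 = 1))
  )
  names(rx) <- vapply(rx, `[[`, character(1), "name")

  net <- structure(list(
    pools = pools,
    reactions = rx,
    measured_pools = c("Glu_n", "Glu_g", "Gln"),
    observables = list(glu = c("Glu_n", "Glu_g"), gln = "Gln"),
    constants = c(Vex_lac = 0.5)
  ), class = "network")
  validate_network(net)
  net
}

# structural checks: references resolve, atom maps complete
validate_network <- function(net) {
  pn <- names(net$pools)
  for (r in net$reactions) {
    subs <- names(r$substrates)
    if (!all(subs %in% pn))
      stop("reaction ", r$name, " references unknown substrate pool")
    for (pname in names(r$products)) {
      if (!pname %in% pn)
        stop("reaction ", r$name, " references unknown product pool ", pname)
      nc <- net$pools[[pname]]$n_carbons
      for (o in r$products[[pname]]) {
        if (length(o$map) != nc)
          stop("atom map for ", pname, " in ", r$name,
               " must list one source per product carbon")
        for (src in o$map) {
          if (src == "*") next
          parts <- strsplit(src, ".", fixed = TRUE)[[1]]
          if (length(parts) != 2L || !parts[1] %in% pn)
            stop("bad atom-map source '", src, "' in ", r$name)
          if (as.integer(parts[2]) > net$pools[[parts[1]]]$n_carbons)
            stop("atom-map source '", src, "' in ", r$name,
                 " exceeds carbon count")
        }
      }
    }
  }
  invisible(net)
}

#' @export
print.network <- function(x, ...) {
  cat("Metabolic network:", length(x$pools), "pools,",
      length(x$reactions), "reactions\n")
  cat("measured pools:", paste(x$measured_pools, collapse = ", "), "\n")
  invisible(x)
}

#' Check steady-state mass balance of a network
#'
#' For every non-input pool, computes total molecular inflow minus total
#' outflow under the given fluxes. A valid flux set (free fluxes plus the
#' derived fluxes they imply) gives a zero residual everywhere; passing a
#' manually overridden named rate vector exposes the imbalance it creates.
#'
#' @param net a `network`
#' @param f a `flux_set`, or a named numeric vector of reaction rates as
#'   produced by [flux_values()] (possibly with manual overrides)
#' @return Named numeric vector of per-pool residuals (micromol/g/min).
#' @export
validate_mass_balance <- function(net, f) {
  v <- if (inherits(f, "flux_set") || (is.list(f) && !is.null(f$free))) {
    flux_values(as_flux_set(f), constants = net$constants)
  } else {
    unlist(f)
  }
  ode_pools <- Filter(function(p) !p$is_input, net$pools)
  res <- setNames(numeric(length(ode_pools)), names(ode_pools))
  for (r in net$reactions) {
    if (!r$flux %in% names(v))
      stop("flux '", r$flux, "' used by reaction ", r$name,
           " is absent from the flux vector")
    rate <- v[[r$flux]]
    for (pname in names(r$products))
      if (pname %in% names(res)) res[pname] <- res[pname] + rate
    for (pname in names(r$substrates))
      if (pname %in% names(res))
        res[pname] <- res[pname] - rate * r$substrates[[pname]]
  }
  res
}
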