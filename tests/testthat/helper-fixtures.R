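# shared fixtures, built lazily and cached across test files
.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.cache[[name]])) .cache[[name]] <- force(expr)
  .cache[[name]]
}

default_net <- function() cached("net", build_default_network())

# small single-input TCA-style loop exercising condensation, symmetric
# scrambling, decarboxylation and an unlabeled dilution inflow; tractable
# for the full-isotopomer oracle
toy_network <- function(V = 0.5, Vd = 0.1) {
  pools <- list(
    pool("Glc_t", "input", 1, is_input = TRUE, hot_positions = 1L),
    pool("Pyr", "shared", 3, 0.2),
    pool("AcCoA", "shared", 2, 0.1),
    pool("OG", "shared", 5, 0.3),
    pool("OAA", "shared", 4, 0.15))
  names(pools) <- vapply(pools, `[[`, character(1), "name")
  rx <- list(
    reaction("feed", "V", c(Glc_t = 1),
             list(Pyr = list(list(weight = 1,
                                  map = c("*", "*", "Glc_t.1"))))),
    reaction("pdh", "V", c(Pyr = 1),
             list(AcCoA = list(list(weight = 1,
                                    map = c("Pyr.2", "Pyr.3"))))),
    reaction("dil_in", "Vd", numeric(0),
             list(AcCoA = list(list(weight = 1, map = c("*", "*"))))),
    reaction("cs", "Vloop", c(OAA = 1, AcCoA = 1),
             list(OG = list(list(weight = 1,
               map = c("OAA.4", "OAA.3", "OAA.2",
                       "AcCoA.2", "AcCoA.1"))))),
    reaction("ogdh", "Vloop", c(OG = 1),
             list(OAA = list(
               list(weight = 0.5, map = paste0("OG.", 2:5)),
               list(weight = 0.5, map = paste0("OG.", 5:2))))))
  names(rx) <- vapply(rx, `[[`, character(1), "name")
  structure(list(pools = pools, reactions = rx,
                 measured_pools = character(0), observables = list(),
                 constants = c(V = V, Vd = Vd, Vloop = V + Vd)),
            class = "network")
}

# a bare pool with no reactions (combinatorial state-count checks)
isolated_pool_network <- function(n_carbons) {
  p <- pool("M", "shared", n_carbons, 1)
  structure(list(pools = setNames(list(p), "M"),
                 reactions = list(), measured_pools = character(0),
                 observables = list(), constants = numeric(0)),
            class = "network")
}

# noiseless datasets at the reference truth, shared across files
zero_noise_bonded <- function()
  cached("ds_bonded",
         generate_dataset(default_truth_fluxes(), variant = "bonded",
                          noise = FALSE, net = default_net()))
zero_noise_positional <- function()
  cached("ds_positional", subset_variant(zero_noise_bonded(), "positional"))

base_fit_bonded <- function()
  cached("fit_bonded", fit_fluxes(zero_noise_bonded()))
base_fit_positional <- function()
  cached("fit_positional", fit_fluxes(zero_noise_positional()))

# Monte-Carlo at the study noise level, 50 replicates per variant; the
# heavy shared computation behind the recovery and variant-comparison
# checks
mc_bonded <- function()
  cached("mc_bonded", monte_carlo(base_fit_bonded(), n_mc = 50, seed = 11))
mc_positional <- function()
  cached("mc_positional",
         monte_carlo(base_fit_positional(), n_mc = 50, seed = 12))
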