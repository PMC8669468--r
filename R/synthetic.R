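# Synthetic-data generation: feasible flux truths, noisy parallel-tracer MID
# sets with optional unlabeled carry-over, growth/consumption time series,
# two-condition proteomes and adenylate pools. Every generator is
# deterministic under its seed, and defaults reproduce the study conditions
# the chain is meant to operate under: two positionally labeled succinate
# tracers with three replicates each (six isotopomer sets), Gaussian MID
# noise, carry-over influx below 7% of uptake, exponential growth with lag.

#' Path to a bundled species model file
#'
#' @param species `"pputida"` or `"ctestosteroni"`
#' @return file path
#' @export
species_model_path <- function(species = c("pputida", "ctestosteroni")) {
  species <- match.arg(species)
  file <- switch(species,
                 pputida = "pputida_kt2440_succinate.tsv",
                 ctestosteroni = "ctestosteroni_kf1_succinate.tsv")
  p <- system.file("extdata", file, package = "emumfa")
  if (p == "") p <- file.path("inst", "extdata", file)
  p
}

#' Metabolite fragments measured in the tracer experiments
#' @export
MEASURED_FRAGMENTS <- c("G6P", "F6P", "X5P", "R5P", "S7P", "MAL", "FUM",
                        "ASP", "CIT", "AKG", "PEP", "PG3", "DHAP")

#' Default parallel succinate tracers
#'
#' `[1,4-13C4]`- and `[2,3-13C4]`-succinate at the given enrichment.
#' @param purity per-position isotopic enrichment
#' @return named list of `tracer_spec`
#' @export
succinate_tracers <- function(purity = 0.99) {
  list(suc_14 = tracer_spec("SUC_ext", "1001", purity = purity),
       suc_23 = tracer_spec("SUC_ext", "0110", purity = purity))
}

#' Scenario configuration for the synthetic benchmark
#'
#' Defaults encode the study conditions: growth rate 0.55 h^-1 with a 3 h
#' lag, succinate uptake 9.5 mmol gCDW^-1 h^-1, two tracers x 3 replicates,
#' MID noise SD 0.005, no carry-over (set `carryover` up to 0.07 of uptake
#' for the unwashed-cell condition).
#'
#' @param species species tag
#' @param mu growth rate (h^-1)
#' @param lag lag time (h)
#' @param q_uptake substrate uptake (mmol gCDW^-1 h^-1)
#' @param replicates replicates per tracer
#' @param mid_noise_sd additive (truncated-Gaussian) MID noise SD
#' @param carryover unlabeled carry-over influx as a fraction of uptake
#' @param purity tracer positional enrichment
#' @param od_noise multiplicative OD noise (lognormal sdlog)
#' @param od_to_cdw g CDW per OD unit per liter
#' @param proteome_size,frac_differential,effect_units two-condition proteome
#'   shape: protein count, differential fraction, and true shift expressed in
#'   units of the summed between-condition uncertainty
#' @param seed master seed
#' @return `scenario_config` list
#' @export
scenario_config <- function(species = "pputida", mu = 0.55, lag = 3,
                            q_uptake = 9.5, replicates = 3,
                            mid_noise_sd = 0.005, carryover = 0,
                            purity = 0.99, od_noise = 0.02, od_to_cdw = 0.4,
                            asp_drain = 1.0, glu_drain = 1.5,
                            proteome_size = 1000, frac_differential = 0.1,
                            effect_units = 4, seed = 1) {
  stopifnot(mid_noise_sd >= 0, carryover >= 0, carryover <= 0.5)
  structure(as.list(environment()), class = "scenario_config")
}

# Carry-over influx weights (fraction of total scavenged carbon per entry
# point); the entry metabolites mirror the unwashed-cell observations.
CARRYOVER_WEIGHTS <- c(MAL_IN = 5, PYR_IN = 5, G6P_IN = 2, DHAP_IN = 3,
                       ACCOA_IN = 2) / 17

#' Paper-shaped true flux distribution for the succinate benchmark
#'
#' Fixes uptake at 100, biomass drains at the composition-derived efflux,
#' shuts the glyoxylate shunt, oxidative PP and ED routes, and lets the
#' steady-state constraints determine the remaining TCA/gluconeogenesis
#' pattern (high reductive-TCA flux > 100% of uptake, PEP-to-EMP flux near
#' 20%). With `carryover > 0` the influx reactions carry the configured
#' fraction of uptake, split across entry metabolites by
#' `CARRYOVER_WEIGHTS`.
#'
#' @param model bundled succinate `flux_model`
#' @param config `scenario_config`
#' @return list(net, exch, fixed, demand): truth fluxes, the equality
#'   constraints that generated them, and the biomass demand used
#' @export
demo_true_fluxes <- function(model, config) {
  comp <- default_biomass_composition(config$species)
  dem <- biomass_efflux(config$mu, comp)
  pct <- dem$rates / config$q_uptake * 100
  infl <- config$carryover * 100 * CARRYOVER_WEIGHTS
  fixed <- c(SUC_UPT = 100,
             stats::setNames(as.numeric(pct), paste0("BM_", names(pct))),
             BM_ASP = config$asp_drain, BM_GLU = config$glu_drain,
             GLUDH = config$glu_drain, ASPTA = config$asp_drain,
             ICL = 0, PYK = 0, ZWF = 0, THD = 0,
             infl[names(infl) %in% names(model$reactions)])
  # species-specific routes absent from the C. testosteroni reconstruction
  for (id in c("PYC", "PPC", "PPS", "EDD", "ACK", "PYR_EX", "ODX"))
    if (id %in% names(model$reactions) && !(id %in% names(fixed)))
      fixed[id] <- if (id == "ODX") 2 else 0
  fixed <- fixed[names(fixed) %in% names(model$reactions)]
  b <- flux_basis(model, fixed)
  if (b$n_free > 0)
    stop("demo flux pattern under-determined; free: ",
         paste(b$free_reaction_ids, collapse = ", "))
  v <- complete_fluxes(b, stats::setNames(numeric(0), character(0)))
  if (!is_feasible(model, v))
    stop("demo flux pattern infeasible for this configuration")
  exch <- c(FUMH = 40, MDH = 25)
  list(net = v, exch = exch, fixed = fixed, demand = dem)
}

#' Sample a random feasible flux distribution
#'
#' Free fluxes are drawn uniformly in boxes and completed; draws violating
#' irreversibility are rejected.
#'
#' @param model `flux_model`
#' @param fixed equality constraints (e.g. uptake)
#' @param box sampling box for free net fluxes
#' @param max_tries rejection cap
#' @return named feasible net flux vector
#' @export
sample_true_fluxes <- function(model, fixed, box = c(0, 150),
                               max_tries = 1000) {
  b <- flux_basis(model, fixed)
  for (i in seq_len(max_tries)) {
    u <- stats::setNames(stats::runif(b$n_free, box[1], box[2]),
                         b$free_reaction_ids)
    v <- complete_fluxes(b, u)
    if (is_feasible(model, v)) return(v)
  }
  stop("no feasible flux distribution found in ", max_tries, " draws")
}

#' Generate a noisy parallel-tracer MID measurement set
#'
#' Simulates each tracer at the true fluxes, adds truncated-Gaussian noise
#' per replicate, renormalizes each fragment, and attaches the noise SD as
#' the measurement SD.
#'
#' @param model `flux_model`
#' @param fluxes truth list(net, exch)
#' @param tracers named list of `tracer_spec`
#' @param targets measured fragments (default [MEASURED_FRAGMENTS] filtered
#'   to the model)
#' @param replicates replicates per tracer
#' @param noise_sd additive MID noise SD (0 = clean)
#' @param seed RNG seed
#' @return `measurement_set` (mids only)
#' @export
make_mid_dataset <- function(model, fluxes, tracers,
                             targets = intersect(MEASURED_FRAGMENTS,
                                                 model$balanced),
                             replicates = 3, noise_sd = 0.005, seed = 1) {
  net <- emu_network(model, targets)
  set.seed(seed)
  rows <- list()
  for (tid in names(tracers)) {
    sim <- emu_simulate(net, model, fluxes, tracers[[tid]])
    for (rep in seq_len(replicates)) {
      for (met in targets) {
        mid <- sim[[met]]
        if (noise_sd > 0) {
          mid <- pmax(mid + stats::rnorm(length(mid), 0, noise_sd), 0)
          s <- sum(mid)
          if (s < 0.5) stop("noise level degenerates the MID of ", met)
          mid <- mid / s
        }
        rows[[length(rows) + 1]] <- data.frame(
          tracer = tid, replicate = rep, metabolite = met,
          mass = seq_along(mid) - 1, value = mid,
          sd = max(noise_sd, 1e-4))
      }
    }
  }
  measurement_set(do.call(rbind, rows))
}

#' Generate growth and exchange-concentration time series
#'
#' OD follows lagged exponential growth with multiplicative lognormal noise;
#' substrate and product concentrations are tied to biomass through the
#' configured uptake rate and yield (balanced-growth kinetics).
#'
#' @param config `scenario_config`
#' @param t_end,dt sampling grid (h)
#' @param od0 initial OD
#' @param s0 initial substrate concentration (mM)
#' @param q_secretion secreted-product rate (mmol gCDW^-1 h^-1), may be 0
#' @return list(od, substrate, product, cdw_per_od, truth)
#' @export
make_physiology_dataset <- function(config, t_end = 10, dt = 0.5, od0 = 0.05,
                                    s0 = 25, q_secretion = 0) {
  set.seed(config$seed + 7)
  t <- seq(0, t_end, by = dt)
  od_true <- ifelse(t < config$lag, od0, od0 * exp(config$mu * (t - config$lag)))
  od <- od_true * exp(stats::rnorm(length(t), 0, config$od_noise))
  x <- od_true * config$od_to_cdw            # g CDW / L
  dx <- x - x[1]
  subs <- pmax(s0 - (config$q_uptake / config$mu) * dx, 0)
  prod <- (q_secretion / config$mu) * dx
  conc_noise <- function(v) pmax(v * exp(stats::rnorm(length(v), 0, config$od_noise)), 0)
  list(od = data.frame(time = t, od = od),
       substrate = data.frame(time = t, conc = conc_noise(subs)),
       product = data.frame(time = t, conc = conc_noise(prod)),
       cdw = data.frame(time = t, cdw = x),
       cdw_per_od = config$od_to_cdw,
       truth = list(mu = config$mu, lag = config$lag,
                    q_uptake = config$q_uptake, q_secretion = q_secretion))
}

#' Generate a two-condition proteome with known differential proteins
#'
#' Null proteins share their condition means; differential proteins are
#' shifted by `effect_units` times the expected summed uncertainty
#' (u1 + u2), half up and half down. Per-replicate within-SEs are drawn from
#' `within_se_range`.
#'
#' @param config `scenario_config`
#' @param replicates biological replicates per condition (default 4)
#' @param rep_sd between-replicate SD of log2 abundance
#' @param within_se_range range of within-replicate standard errors
#' @return list(table, truth) where `truth` flags the differential proteins
#' @export
make_proteome <- function(config, replicates = 4, rep_sd = 0.25,
                          within_se_range = c(0.05, 0.2)) {
  set.seed(config$seed + 13)
  n <- config$proteome_size
  n_diff <- round(config$frac_differential * n)
  base <- stats::runif(n, 18, 30)
  u_nom <- sqrt(rep_sd^2 + mean(within_se_range)^2)
  shift <- config$effect_units * 2 * u_nom
  truth <- rep(FALSE, n); truth[seq_len(n_diff)] <- TRUE
  sign <- rep(c(1, -1), length.out = n_diff)
  rows <- list()
  for (i in seq_len(n)) {
    for (cond in c("succinate", "gluconate")) {
      m <- base[i] + if (cond == "succinate" && truth[i]) sign[i] * shift else 0
      for (r in seq_len(replicates)) {
        rows[[length(rows) + 1]] <- data.frame(
          protein = sprintf("P%04d", i), condition = cond, replicate = r,
          log2_abundance = stats::rnorm(1, m, rep_sd),
          within_se = stats::runif(1, within_se_range[1], within_se_range[2]))
      }
    }
  }
  list(table = do.call(rbind, rows),
       truth = data.frame(protein = sprintf("P%04d", seq_len(n)),
                          differential = truth))
}

#' Construct adenylate pools with a target energy charge
#'
#' Closed-form inversion of the energy charge with the ADP share of the pool
#' as the free parameter: ATP = (EC - d/2) * total, ADP = d * total,
#' AMP = remainder.
#'
#' @param target_ec energy charge in [0, 1]
#' @param total total adenylate pool (umol/g)
#' @param adp_share ADP fraction of the pool; default `min(EC, 1 - EC)`
#'   (keeps all pools non-negative across the full EC range)
#' @return named vector c(atp, adp, amp)
#' @export
make_adenylate_pools <- function(target_ec, total = 10, adp_share = NULL) {
  if (target_ec < 0 || target_ec > 1) stop("energy charge must lie in [0, 1]")
  if (is.null(adp_share)) adp_share <- min(target_ec, 1 - target_ec)
  atp <- target_ec - adp_share / 2
  amp <- 1 - atp - adp_share
  if (atp < -1e-12 || amp < -1e-12)
    stop("adp_share incompatible with the target energy charge")
  c(atp = max(atp, 0), adp = adp_share, amp = max(amp, 0)) * total
}

#' Full synthetic succinate benchmark scenario
#'
#' Builds the bundled model, the paper-shaped truth, tracer specs, a noisy
#' MID set, biomass-drain rate measurements, physiology series, a proteome
#' and adenylate pools -- everything the pipeline consumes.
#'
#' @param seed master seed (sub-seeds are derived per stage)
#' @param ... overrides passed to [scenario_config()]
#' @return list with model, config, truth, tracers, measurements, rates,
#'   physiology, proteome, pools
#' @export
pputida_succinate_demo <- function(seed = 1, ...) {
  config <- scenario_config(seed = seed, ...)
  model <- read_flux_model(species_model_path(config$species))
  truth <- demo_true_fluxes(model, config)
  tracers <- succinate_tracers(config$purity)
  mids <- make_mid_dataset(model, truth[c("net", "exch")], tracers,
                           replicates = config$replicates,
                           noise_sd = config$mid_noise_sd, seed = seed)
  rates <- biomass_rate_measurements(model, truth$demand, config$q_uptake)
  meas <- measurement_set(mids$mids, rates)
  # fully labeled tracer experiment used for carry-over gating: with
  # [U-13C4]-succinate every skeleton carbon is labeled, so unlabeled
  # fractions above the purity floor can only come from scavenged carbon
  gating_tracer <- list(suc_U = tracer_spec("SUC_ext", "1111",
                                            purity = config$purity))
  gating <- make_mid_dataset(model, truth[c("net", "exch")], gating_tracer,
                             replicates = config$replicates,
                             noise_sd = config$mid_noise_sd, seed = seed + 101)
  list(model = model, config = config, truth = truth, tracers = tracers,
       measurements = meas, gating = gating, gating_tracer = gating_tracer,
       physiology = make_physiology_dataset(config),
       proteome = make_proteome(config),
       pools = make_adenylate_pools(0.68))
}
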