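# Biomass demand: precursor efflux rates from growth rate x macromolecular
# composition, pathway partitioning of biosynthetic carbon, and anabolic
# cofactor/ATP demand (including polymerization ATP).

#' Precursor carbon counts used for carbon-weighted partitioning
#' @export
PRECURSOR_CARBONS <- c(G6P = 6, F6P = 6, GAP = 3, PG3 = 3, PEP = 3, PYR = 3,
                       ACCOA = 2, R5P = 5, E4P = 4, OAA = 4, AKG = 5)

#' Default pathway assignment of biosynthetic precursors
#' @export
PRECURSOR_PATHWAYS <- c(G6P = "EMP", F6P = "EMP", GAP = "EMP", PG3 = "EMP",
                        PEP = "EMP", PYR = "EMP", ACCOA = "EMP",
                        R5P = "PP", E4P = "PP", OAA = "TCA", AKG = "TCA")

#' Construct a biomass composition
#'
#' @param mass_fractions named vector over components (RNA, DNA, protein,
#'   lipid, polysaccharide), g per g dry biomass; must sum to <= 1
#' @param precursors data.frame(component, precursor, mmol_per_g): mmol of
#'   each precursor needed per g of component
#' @param polymerization data.frame(component, monomer_mmol_per_g,
#'   atp_per_mmol): polymerization ATP bookkeeping
#' @param cofactor_coefs data.frame(precursor, nadph, atp, nadh_uqh2): mmol of
#'   cofactor consumed per mmol precursor pulled into biosynthesis
#' @return a `biomass_composition`
#' @export
biomass_composition <- function(mass_fractions, precursors, polymerization,
                                cofactor_coefs) {
  if (any(mass_fractions < 0)) stop("mass fractions must be >= 0")
  if (sum(mass_fractions) > 1 + 1e-9)
    stop("mass fractions sum to more than 1")
  if (any(precursors$mmol_per_g < 0)) stop("precursor stoichiometries must be >= 0")
  structure(list(mass_fractions = mass_fractions, precursors = precursors,
                 polymerization = polymerization,
                 cofactor_coefs = cofactor_coefs),
            class = "biomass_composition")
}

#' Bundled synthetic biomass composition
#'
#' A literature-shaped but synthetic default (per-precursor totals on the
#' order of classic Gram-negative measurements); the acceptance benchmarks
#' use these values throughout. Species tags select mildly different
#' protein/lipid fractions.
#'
#' @param species_tag `"pputida"` or `"ctestosteroni"`
#' @return `biomass_composition`
#' @export
default_biomass_composition <- function(species_tag = "pputida") {
  fr <- switch(species_tag,
               pputida = c(protein = 0.55, RNA = 0.16, DNA = 0.03,
                           lipid = 0.09, polysaccharide = 0.07),
               ctestosteroni = c(protein = 0.58, RNA = 0.14, DNA = 0.03,
                                 lipid = 0.10, polysaccharide = 0.06),
               stop("unknown species_tag: ", species_tag))
  pre <- rbind(
    data.frame(component = "protein",
               precursor = c("PYR", "OAA", "AKG", "PEP", "PG3", "R5P", "E4P"),
               mmol_per_g = c(3.2, 2.6, 1.9, 0.7, 1.0, 0.3, 0.6)),
    data.frame(component = "RNA",
               precursor = c("R5P", "OAA", "PG3"),
               mmol_per_g = c(3.7, 1.2, 0.4)),
    data.frame(component = "DNA",
               precursor = c("R5P", "OAA", "PG3"),
               mmol_per_g = c(3.2, 1.0, 0.3)),
    data.frame(component = "lipid",
               precursor = c("ACCOA", "GAP"),
               mmol_per_g = c(26.0, 1.2)),
    data.frame(component = "polysaccharide",
               precursor = c("G6P", "F6P"),
               mmol_per_g = c(5.6, 0.6)))
  poly <- data.frame(
    component = c("protein", "RNA", "DNA", "lipid", "polysaccharide"),
    monomer_mmol_per_g = c(9.1, 3.1, 3.1, 1.3, 6.2),
    atp_per_mmol = c(4.3, 2.4, 3.4, 1.0, 2.0))
  cof <- data.frame(
    precursor = c("PYR", "OAA", "AKG", "PEP", "PG3", "R5P", "E4P", "ACCOA",
                  "GAP", "G6P", "F6P"),
    nadph = c(1.6, 1.4, 2.2, 1.0, 1.5, 0.8, 2.0, 2.8, 0.3, 0.0, 0.0),
    atp = c(0.9, 0.8, 1.0, 0.5, 0.7, 1.6, 0.8, 0.9, 0.3, 0.3, 0.3),
    nadh_uqh2 = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0))
  biomass_composition(fr, pre, poly, cof)
}

#' Biomass precursor efflux rates
#'
#' Each precursor's efflux is `mu * sum_c(mass_fraction_c * mmol_per_g_{c,p})`
#' in mmol gCDW^-1 h^-1; strictly linear in the growth rate.
#'
#' @param growth_rate specific growth rate mu (h^-1), >= 0
#' @param composition `biomass_composition`
#' @param pathways named pathway assignment per precursor (defaults to
#'   [PRECURSOR_PATHWAYS])
#' @return a `precursor_demand`: list(rates, pathways, growth_rate)
#' @export
biomass_efflux <- function(growth_rate, composition,
                           pathways = PRECURSOR_PATHWAYS) {
  if (growth_rate < 0) stop("growth rate must be >= 0")
  pre <- composition$precursors
  fr <- composition$mass_fractions
  pre$fc <- fr[pre$component]
  per_g <- tapply(pre$mmol_per_g * pre$fc, pre$precursor, sum)
  rates <- growth_rate * per_g
  structure(list(rates = rates, pathways = pathways,
                 growth_rate = growth_rate, composition = composition),
            class = "precursor_demand")
}

#' Partition biosynthetic carbon demand across pathways
#'
#' Carbon-weighted: each precursor contributes `rate * carbon_count`; the
#' returned fractions over {TCA, PP, EMP} sum to 1.
#'
#' @param demand `precursor_demand`
#' @param carbons named carbon counts per precursor (default
#'   [PRECURSOR_CARBONS])
#' @return named numeric vector of fractions
#' @export
pathway_partition <- function(demand, carbons = PRECURSOR_CARBONS) {
  pr <- names(demand$rates)
  if (!all(pr %in% names(demand$pathways)))
    stop("precursor(s) without pathway assignment: ",
         paste(setdiff(pr, names(demand$pathways)), collapse = ", "))
  if (!all(pr %in% names(carbons)))
    stop("precursor(s) without carbon count: ",
         paste(setdiff(pr, names(carbons)), collapse = ", "))
  cw <- demand$rates * carbons[pr]
  tot <- sum(cw)
  if (tot == 0) {
    f <- tapply(cw, demand$pathways[pr], sum)
    return(f * 0)
  }
  out <- tapply(cw, demand$pathways[pr], sum) / tot
  out[sort(names(out))]
}

#' Anabolic cofactor and ATP demand
#'
#' Per-precursor cofactor coefficients times the precursor efflux rates, plus
#' a polymerization ATP term
#' `mu * sum_c(mass_fraction_c * monomer_mmol_per_g_c * atp_per_mmol_c)`.
#'
#' @param demand `precursor_demand` from [biomass_efflux()]
#' @return named vector (nadph, atp, nadh_uqh2) of consumption rates in
#'   mmol gCDW^-1 h^-1
#' @export
anabolic_cofactor_demand <- function(demand) {
  comp <- demand$composition
  cof <- comp$cofactor_coefs
  pr <- names(demand$rates)
  miss <- setdiff(pr, cof$precursor)
  if (length(miss) > 0)
    stop("missing cofactor coefficients for precursor(s): ",
         paste(miss, collapse = ", "))
  idx <- match(pr, cof$precursor)
  out <- c(
    nadph = sum(demand$rates * cof$nadph[idx]),
    atp = sum(demand$rates * cof$atp[idx]),
    nadh_uqh2 = sum(demand$rates * cof$nadh_uqh2[idx]))
  poly <- comp$polymerization
  fr <- comp$mass_fractions[poly$component]
  out["atp"] <- out["atp"] +
    demand$growth_rate * sum(fr * poly$monomer_mmol_per_g * poly$atp_per_mmol)
  out
}

#' Turn precursor demand into drain-rate measurements for the fitter
#'
#' Maps each precursor to the model's biomass-drain reaction consuming it and
#' expresses the efflux on the uptake-=-100 flux scale.
#'
#' @param model `flux_model`
#' @param demand `precursor_demand`
#' @param q_uptake substrate uptake rate (mmol gCDW^-1 h^-1)
#' @param sd_rel relative SD attached to each rate (default 0.1)
#' @return data.frame(reaction, value, sd, type = "biomass")
#' @export
biomass_rate_measurements <- function(model, demand, q_uptake, sd_rel = 0.1) {
  drains <- Filter(function(r) r$kind == "biomass_drain", model$reactions)
  rows <- list()
  for (p in names(demand$rates)) {
    hit <- Filter(function(r) p %in% names(r$reactants), drains)
    if (length(hit) == 0) next
    val <- demand$rates[[p]] / q_uptake * 100
    rows[[length(rows) + 1]] <- data.frame(
      reaction = hit[[1]]$id, value = val,
      sd = max(val * sd_rel, 1e-3), type = "biomass")
  }
  do.call(rbind, rows)
}
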