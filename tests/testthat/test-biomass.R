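single_component_comp <- function(fraction = 0.5, stoich = 4, atp_poly = 0,
                                  monomer = 1) {
  biomass_composition(
    c(protein = fraction),
    data.frame(component = "protein", precursor = "OAA", mmol_per_g = stoich),
    data.frame(component = "protein", monomer_mmol_per_g = monomer,
               atp_per_mmol = atp_poly),
    data.frame(precursor = "OAA", nadph = 0, atp = 0, nadh_uqh2 = 0))
}

test_that("biomass efflux is the growth rate times the weighted stoichiometry", {
  comp <- single_component_comp(0.5, 4)
  expect_equal(unname(biomass_efflux(0, comp)$rates[["OAA"]]), 0)
  d <- biomass_efflux(0.2, comp)
  expect_equal(unname(d$rates[["OAA"]]), 0.2 * 0.5 * 4)
  d2 <- biomass_efflux(0.4, comp)
  expect_equal(unname(d2$rates), unname(2 * d$rates))
  expect_error(biomass_efflux(-0.1, comp), ">= 0")
})

test_that("pathway partition is a carbon-weighted probability vector", {
  comp <- biomass_composition(
    c(protein = 1),
    data.frame(component = rep("protein", 2), precursor = c("OAA", "AKG"),
               mmol_per_g = c(2, 3)),
    data.frame(component = "protein", monomer_mmol_per_g = 1, atp_per_mmol = 0),
    data.frame(precursor = c("OAA", "AKG"), nadph = 0, atp = 0, nadh_uqh2 = 0))
  f <- pathway_partition(biomass_efflux(0.3, comp))
  expect_equal(unname(f[["TCA"]]), 1)

  # constructed symmetry: TCA carbon equals EMP carbon
  comp2 <- biomass_composition(
    c(protein = 1),
    data.frame(component = rep("protein", 2), precursor = c("OAA", "PYR"),
               mmol_per_g = c(3, 4)),  # 3*4 = 4*3 carbons
    data.frame(component = "protein", monomer_mmol_per_g = 1, atp_per_mmol = 0),
    data.frame(precursor = c("OAA", "PYR"), nadph = 0, atp = 0, nadh_uqh2 = 0))
  f2 <- pathway_partition(biomass_efflux(0.3, comp2))
  expect_equal(unname(f2[["TCA"]]), 0.5)
  expect_equal(sum(f2), 1)
})

test_that("bundled composition matches a brute-force per-precursor summation", {
  comp <- default_biomass_composition("pputida")
  mu <- 0.42
  d <- biomass_efflux(mu, comp)
  # independent recomputation straight off the tables
  manual <- numeric(0)
  for (i in seq_len(nrow(comp$precursors))) {
    row <- comp$precursors[i, ]
    add <- mu * comp$mass_fractions[[row$component]] * row$mmol_per_g
    manual[row$precursor] <- (if (is.na(manual[row$precursor])) 0
                              else manual[row$precursor]) + add
  }
  ord <- sort(names(d$rates))
  expect_identical(sort(names(manual)), ord)
  expect_equal(as.numeric(d$rates[ord]), as.numeric(manual[ord]),
               tolerance = 1e-12)

  f <- pathway_partition(d)
  cw <- manual * PRECURSOR_CARBONS[names(manual)]
  expect_equal(unname(f[["TCA"]]),
               unname(sum(cw[c("OAA", "AKG")]) / sum(cw)), tolerance = 1e-12)
  expect_equal(sum(f), 1)
})

test_that("anabolic cofactor demand includes the polymerization ATP term", {
  comp <- single_component_comp(1, 1, atp_poly = 2, monomer = 1)
  d <- biomass_efflux(1, comp)
  out <- anabolic_cofactor_demand(d)
  expect_equal(unname(out[["atp"]]), 2)  # mu * 1 g/g * 1 mmol/g * 2 ATP
  expect_equal(unname(anabolic_cofactor_demand(biomass_efflux(0, comp))[["atp"]]), 0)

  comp2 <- default_biomass_composition("pputida")
  d2 <- biomass_efflux(0.55, comp2)
  out2 <- anabolic_cofactor_demand(d2)
  # brute-force oracle
  idx <- match(names(d2$rates), comp2$cofactor_coefs$precursor)
  nadph <- sum(d2$rates * comp2$cofactor_coefs$nadph[idx])
  expect_equal(unname(out2[["nadph"]]), nadph, tolerance = 1e-12)
  poly <- comp2$polymerization
  atp_poly <- 0.55 * sum(comp2$mass_fractions[poly$component] *
                         poly$monomer_mmol_per_g * poly$atp_per_mmol)
  atp_pre <- sum(d2$rates * comp2$cofactor_coefs$atp[idx])
  expect_equal(unname(out2[["atp"]]), atp_pre + atp_poly, tolerance = 1e-12)
})

test_that("missing configuration surfaces as errors, not silent zeros", {
  comp <- single_component_comp()
  d <- biomass_efflux(0.2, comp)
  d$pathways <- c()  # strip the pathway assignment
  expect_error(pathway_partition(d), "pathway")
  comp2 <- comp; comp2$cofactor_coefs <- comp2$cofactor_coefs[0, ]
  d2 <- biomass_efflux(0.2, comp2)
  expect_error(anabolic_cofactor_demand(d2), "coefficients")
})

test_that("drain-rate measurements map precursors onto model drains on the uptake scale", {
  model <- read_flux_model(species_model_path("pputida"))
  comp <- default_biomass_composition("pputida")
  d <- biomass_efflux(0.55, comp)
  rt <- biomass_rate_measurements(model, d, q_uptake = 9.5)
  expect_true(all(rt$type == "biomass"))
  expect_true(all(startsWith(rt$reaction, "BM_")))
  oaa <- rt$value[rt$reaction == "BM_OAA"]
  expect_equal(oaa, unname(d$rates[["OAA"]]) / 9.5 * 100, tolerance = 1e-12)
})
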