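toy_cof_model <- function() {
  build_flux_model(list(
    make_reaction("u", "1 A_ext -> 1 A", "A_ext:ab -> A:ab", kind = "uptake",
                  pathway = "transport"),
    make_reaction("r1", "1 A -> 1 B", "A:ab -> B:ab", pathway = "TCA",
                  cofactors = c(nadh_uqh2 = 1)),
    make_reaction("r2", "1 B -> 1 C", "B:ab -> C:ab", pathway = "PP",
                  cofactors = c(nadph = 1, atp = -0.5)),
    make_reaction("d", "1 C ->", kind = "biomass_drain", pathway = "biomass")))
}

abs_flux <- function(v) { attr(v, "units") <- "mmol_gcdw_h"; v }

test_that("normalized fluxes are rejected; scaled fluxes carry units", {
  m <- toy_cof_model()
  v <- c(u = 100, r1 = 100, r2 = 100, d = 100)
  expect_error(ledger_from_fluxes(v, m), "unit")
  va <- scale_fluxes(v, q_uptake = 10)
  expect_identical(attr(va, "units"), "mmol_gcdw_h")
  expect_equal(unname(va[["r1"]]), 10)
})

test_that("ledger sums production and consumption with the reaction deltas", {
  m <- toy_cof_model()
  lg0 <- ledger_from_fluxes(abs_flux(c(u = 0, r1 = 0, r2 = 0, d = 0)), m)
  expect_true(all(lg0$production == 0) && all(lg0$consumption == 0))

  lg <- ledger_from_fluxes(abs_flux(c(u = 10, r1 = 10, r2 = 10, d = 10)), m)
  expect_equal(unname(lg$production[["nadh_uqh2"]]), 10)
  expect_equal(unname(lg$production[["nadph"]]), 10)
  expect_equal(unname(lg$consumption[["atp"]]), 5)

  # linearity: scaling fluxes scales every rate
  lg2 <- ledger_from_fluxes(abs_flux(2 * c(u = 10, r1 = 10, r2 = 10, d = 10)), m)
  expect_equal(unname(lg2$production), unname(2 * lg$production))
})

test_that("ledger on the benchmark fluxes equals a naive per-reaction tally", {
  sc <- pputida_succinate_demo(seed = 2, mid_noise_sd = 0)
  v <- scale_fluxes(sc$truth$net, sc$config$q_uptake)
  anab <- anabolic_cofactor_demand(sc$truth$demand)
  lg <- ledger_from_fluxes(v, sc$model, anab)
  for (cf in c("nadh_uqh2", "nadph", "atp")) {
    prod <- cons <- 0
    for (r in sc$model$reactions) {
      rate <- v[[r$id]] * r$cofactors[[cf]]
      if (rate > 0) prod <- prod + rate else cons <- cons - rate
    }
    expect_equal(unname(lg$production[[cf]]), prod, tolerance = 1e-10)
    expect_equal(unname(lg$consumption[[cf]]), cons + unname(anab[[cf]]),
                 tolerance = 1e-10)
  }
})

test_that("transhydrogenase closure balances NADPH exactly", {
  lg <- structure(list(
    production = c(nadh_uqh2 = 40, nadph = 4.76, atp = 10),
    consumption = c(nadh_uqh2 = 2, nadph = 14.01, atp = 8),
    reaction_consumption = c(nadh_uqh2 = 2, nadph = 0, atp = 8),
    anabolic_demand = c(nadh_uqh2 = 0, nadph = 14.01, atp = 0),
    production_sd = c(nadh_uqh2 = 0, nadph = 0, atp = 0),
    consumption_sd = c(nadh_uqh2 = 0, nadph = 0, atp = 0),
    prod_by_pathway = list(), transhydrogenase_flux = NA_real_,
    closed = FALSE), class = "cofactor_ledger")
  cl <- close_nadph(lg)
  expect_equal(cl$transhydrogenase_flux, 14.01 - 4.76)
  expect_equal(unname(cl$production[["nadph"]]), unname(cl$consumption[["nadph"]]))
  expect_equal(cl$thd_fraction, 9.25 / 14.01, tolerance = 1e-12)

  # production >= consumption: no transhydrogenase needed
  lg$production["nadph"] <- 20
  cl2 <- close_nadph(lg)
  expect_equal(cl2$transhydrogenase_flux, 0)
})

test_that("ATP accounting follows the P/O ratio and exact surplus identity", {
  m <- toy_cof_model()
  v <- abs_flux(c(u = 10, r1 = 10, r2 = 10, d = 10))
  lg <- cofactor_ledger(v, m, c(nadph = 0, atp = 3, nadh_uqh2 = 0), po_ratio = 1.5)
  expect_error(atp_accounting(ledger_from_fluxes(v, m)), "close_nadph")
  # r1 makes 10 NADH; nothing consumes it; no NADPH deficit (r2 covers it)
  expect_equal(lg$respirable_nadh, 10)
  expect_equal(lg$oxphos_atp, 15)
  expect_equal(lg$atp_production_total,
               lg$atp_surplus + unname(lg$consumption[["atp"]]))
  # P/O scaling is linear
  lg2 <- cofactor_ledger(v, m, c(nadph = 0, atp = 3, nadh_uqh2 = 0), po_ratio = 3)
  expect_equal(lg2$oxphos_atp, 30)
})

test_that("pathway attribution sums to one and routes transhydrogenase NADPH to its NADH source", {
  m <- toy_cof_model()
  v <- abs_flux(c(u = 10, r1 = 10, r2 = 10, d = 10))
  # force an NADPH deficit so the transhydrogenase runs
  lg <- cofactor_ledger(v, m, c(nadph = 25, atp = 0, nadh_uqh2 = 0))
  at <- attribute_pathways(lg)
  expect_equal(sum(at$nadph), 1, tolerance = 1e-12)
  # NADPH: 10 from PP (r2) + 15 transhydrogenase attributed to TCA NADH
  expect_equal(unname(at$nadph[["TCA"]]), 15 / 25, tolerance = 1e-12)
  expect_equal(unname(at$nadh_uqh2[["TCA"]]), 1)
})

test_that("energy charge closed forms, bounds and scale invariance", {
  expect_equal(energy_charge(1, 0, 0), 1)
  expect_equal(energy_charge(0, 1, 0), 0.5)
  expect_equal(energy_charge(0, 0, 1), 0)
  expect_equal(energy_charge(1, 1, 1), 0.5)
  expect_error(energy_charge(0, 0, 0), "all-zero")
  expect_error(energy_charge(-1, 0, 2), ">= 0")
  set.seed(3)
  for (k in 1:25) {
    pools <- stats::runif(3, 0, 5)
    ec <- energy_charge(pools[1], pools[2], pools[3])
    expect_gte(ec, 0); expect_lte(ec, 1)
    expect_equal(ec, energy_charge(7 * pools[1], 7 * pools[2], 7 * pools[3]))
  }
})
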