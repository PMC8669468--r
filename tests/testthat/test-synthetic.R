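test_that("generators are deterministic under their seeds", {
  m <- read_flux_model(species_model_path("pputida"))
  cfg <- scenario_config(seed = 4)
  tr <- succinate_tracers()
  truth <- demo_true_fluxes(m, cfg)
  d1 <- make_mid_dataset(m, truth[c("net", "exch")], tr, seed = 4)
  d2 <- make_mid_dataset(m, truth[c("net", "exch")], tr, seed = 4)
  expect_identical(d1$mids, d2$mids)
  p1 <- make_physiology_dataset(cfg); p2 <- make_physiology_dataset(cfg)
  expect_identical(p1$od, p2$od)
  q1 <- make_proteome(scenario_config(seed = 4, proteome_size = 50))
  q2 <- make_proteome(scenario_config(seed = 4, proteome_size = 50))
  expect_identical(q1$table, q2$table)
  set.seed(1); s1 <- sample_true_fluxes(toy_model_branch(), c(upt = 100))
  set.seed(1); s2 <- sample_true_fluxes(toy_model_branch(), c(upt = 100))
  expect_identical(s1, s2)
})

test_that("sampled flux distributions satisfy steady state and sign constraints", {
  set.seed(33)
  for (m in list(toy_model_branch(), toy_model_cycle())) {
    up <- names(Filter(function(r) r$kind == "uptake", m$reactions))[1]
    for (k in 1:100) {
      v <- sample_true_fluxes(m, stats::setNames(100, up))
      expect_lt(max(abs(m$S %*% v)), 1e-8 * max(1, max(abs(v))))
      expect_true(is_feasible(m, v))
    }
  }
  chain <- toy_model_linear()
  v <- sample_true_fluxes(chain, c(upt = 100))
  expect_true(all(abs(v - 100) < 1e-9))  # linear chain forces uptake everywhere
})

test_that("the demo truth is paper-shaped: high TCA flux, ~20% gluconeogenesis, shut shunts", {
  m <- read_flux_model(species_model_path("pputida"))
  truth <- demo_true_fluxes(m, scenario_config())
  v <- truth$net
  expect_gt(v[["SDH"]], 100)            # reductive TCA above uptake
  expect_gt(v[["ENO"]], 15); expect_lt(v[["ENO"]], 25)
  expect_equal(unname(v[["ICL"]]), 0)   # glyoxylate shunt inactive
  expect_equal(unname(v[["ZWF"]]), 0)   # oxidative PP inactive
  expect_true(is_feasible(m, v))
  expect_lt(max(abs(m$S %*% v)), 1e-8)
})

test_that("noise-free MID sets equal the clean simulation; noise stays attached as SD", {
  m <- read_flux_model(species_model_path("pputida"))
  cfg <- scenario_config(seed = 6)
  truth <- demo_true_fluxes(m, cfg)
  tr <- succinate_tracers()
  clean <- make_mid_dataset(m, truth[c("net", "exch")], tr, replicates = 1,
                            noise_sd = 0, seed = 6)
  net <- emu_network(m, intersect(MEASURED_FRAGMENTS, m$balanced))
  sim <- emu_simulate(net, m, truth[c("net", "exch")], tr$suc_14)
  rows <- clean$mids[clean$mids$tracer == "suc_14" &
                     clean$mids$metabolite == "MAL", ]
  expect_equal(rows$value, sim$MAL, tolerance = 1e-12)
  noisy <- make_mid_dataset(m, truth[c("net", "exch")], tr, noise_sd = 0.005,
                            seed = 6)
  expect_true(all(noisy$mids$sd == 0.005))
  sums <- tapply(noisy$mids$value,
                 paste(noisy$mids$tracer, noisy$mids$replicate,
                       noisy$mids$metabolite), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("carry-over influx raises unlabeled fractions at its entry points", {
  m <- read_flux_model(species_model_path("pputida"))
  tr <- succinate_tracers()
  t0 <- demo_true_fluxes(m, scenario_config(carryover = 0))
  t5 <- demo_true_fluxes(m, scenario_config(carryover = 0.05))
  expect_equal(sum(t5$net[names(CARRYOVER_WEIGHTS)]), 5, tolerance = 1e-9)
  d0 <- make_mid_dataset(m, t0[c("net", "exch")], tr, noise_sd = 0, replicates = 1)
  d5 <- make_mid_dataset(m, t5[c("net", "exch")], tr, noise_sd = 0, replicates = 1)
  m0_clean <- mean_m0(d0$mids)
  m0_dirty <- mean_m0(d5$mids)
  for (met in c("MAL", "G6P", "DHAP", "PEP", "PG3"))
    expect_gt(m0_dirty[[met]], m0_clean[[met]])
})

test_that("adenylate pool construction inverts the energy charge exactly", {
  p <- make_adenylate_pools(1)
  expect_equal(unname(p), c(10, 0, 0))
  p68 <- make_adenylate_pools(0.68, total = 12)
  expect_equal(energy_charge(p68["atp"], p68["adp"], p68["amp"]),
               c(atp = 0.68), tolerance = 1e-12)
  expect_equal(sum(p68), 12)
  pure_adp <- make_adenylate_pools(0.5, adp_share = 1)
  expect_equal(unname(pure_adp), c(0, 10, 0))
  p0 <- make_adenylate_pools(0)
  expect_equal(energy_charge(p0["atp"], p0["adp"], p0["amp"]),
               c(atp = 0), tolerance = 1e-12)
  expect_error(make_adenylate_pools(1.2), "\\[0, 1\\]")
  expect_error(make_adenylate_pools(0.9, adp_share = 0.9), "incompatible")
})

test_that("extreme proteome effects are fully detected; zero effects are not generated", {
  pr <- make_proteome(scenario_config(seed = 3, proteome_size = 60,
                                      frac_differential = 0.2,
                                      effect_units = 10))
  expect_identical(sum(pr$truth$differential), 12L)
  res <- differential_proteins(pr$table, "succinate", "gluconate")
  truth <- pr$truth$differential[match(res$protein, pr$truth$protein)]
  expect_true(all(res$significant[truth]))
})
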