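test_that("the objective is zero at truth on clean data and scales with the SDs", {
  ex <- toy_branch_experiment(noise_sd = 0, seed = 2)
  b <- flux_basis(ex$model, ex$fixed)
  free_truth <- ex$truth[b$free_reaction_ids]
  # clean data, rates at truth: SSR vanishes
  ex$measurements$rates$value <- ex$truth[["vP"]]
  s0 <- mfa_objective(ex$model, ex$measurements, ex$tracers, free_truth,
                      fixed = ex$fixed, options = list(sd_floor = 1e-4))
  expect_lt(s0, 1e-12)
  # perturbed fluxes misfit; doubling every SD divides the SSR by 4
  off <- free_truth + 5
  s1 <- mfa_objective(ex$model, ex$measurements, ex$tracers, off,
                      fixed = ex$fixed, options = list(sd_floor = 1e-4))
  meas2 <- ex$measurements
  meas2$mids$sd <- meas2$mids$sd * 2
  meas2$rates$sd <- meas2$rates$sd * 2
  s2 <- mfa_objective(ex$model, meas2, ex$tracers, off,
                      fixed = ex$fixed, options = list(sd_floor = 2e-4))
  expect_gt(s1, 1)
  expect_equal(s2, s1 / 4, tolerance = 1e-9)
  # row order of the measurement table is irrelevant
  meas3 <- ex$measurements
  meas3$mids <- meas3$mids[rev(seq_len(nrow(meas3$mids))), ]
  s3 <- mfa_objective(ex$model, meas3, ex$tracers, off,
                      fixed = ex$fixed, options = list(sd_floor = 1e-4))
  expect_equal(s3, s1, tolerance = 1e-12)
})

test_that("a single residual contributes ((sim - meas)/sd)^2", {
  m <- toy_model_split()
  tr <- list(t1 = tracer_spec("A_ext", "110", purity = 1))
  truth <- c(upt = 10, cut = 10, outB = 10, outC = 10)
  clean <- make_mid_dataset(m, list(net = truth), tr, targets = "C",
                            replicates = 1, noise_sd = 0)
  mids <- clean$mids[clean$mids$mass == 0, ]   # C is unlabeled here: M+0 = 1
  mids$value <- mids$value - 0.1
  mids$sd <- 0.05
  s <- mfa_objective(m, measurement_set(mids), tr,
                     stats::setNames(numeric(0), character(0)),
                     fixed = c(upt = 10), options = list(sd_floor = 0.05))
  expect_equal(s, 4, tolerance = 1e-9)
})

test_that("the biomass-imprecision option widens exactly the biomass rate SDs by 2x", {
  ex <- toy_branch_experiment(noise_sd = 0.01, seed = 3)
  ex$measurements$rates$type <- "biomass"
  p1 <- emumfa:::mfa_prepare(ex$model, ex$measurements, ex$tracers, ex$fixed,
                             list())
  p2 <- emumfa:::mfa_prepare(ex$model, ex$measurements, ex$tracers, ex$fixed,
                             list(biomass_sd_factor = 2))
  expect_equal(p2$rates$sd, 2 * p1$rates$sd)
})

test_that("multi-start fitting recovers the branch toy and is bit-deterministic", {
  ex <- toy_branch_experiment(noise_sd = 0, seed = 4, rate_sd = 0.01)
  ex$measurements$rates$value <- ex$truth[["vP"]]
  fit <- fit_fluxes(ex$model, ex$measurements, ex$tracers, ex$fixed,
                    n_starts = 5, seed = 9, options = list(sd_floor = 1e-4))
  expect_lt(fit$ssr, 1e-6)
  for (rx in names(ex$truth))
    expect_lt(abs(fit$fluxes$net[[rx]] - ex$truth[[rx]]),
              1e-3 * max(1, abs(ex$truth[[rx]])))
  fit2 <- fit_fluxes(ex$model, ex$measurements, ex$tracers, ex$fixed,
                     n_starts = 5, seed = 9, options = list(sd_floor = 1e-4))
  expect_identical(fit$par, fit2$par)
  expect_identical(fit$ssr, fit2$ssr)
  expect_identical(fit$per_start, fit2$per_start)
})

test_that("chi-square acceptance flags a misspecified topology", {
  # data generated with the recombination route active, fitted with it shut
  ex <- toy_branch_experiment(noise_sd = 0.005, seed = 5, vB = 40, vC = 30)
  good <- fit_fluxes(ex$model, ex$measurements, ex$tracers, ex$fixed,
                     n_starts = 5, seed = 1)
  expect_true(good$accepted)
  bad <- fit_fluxes(ex$model, ex$measurements, ex$tracers,
                    c(ex$fixed, vC = 0), n_starts = 5, seed = 1)
  expect_false(bad$accepted)
  expect_gt(bad$ssr, good$chi2_cutoff_95)
})

test_that("profile confidence intervals bracket the estimate and nest across levels", {
  ex <- toy_branch_experiment(noise_sd = 0.01, seed = 6)
  fit <- fit_fluxes(ex$model, ex$measurements, ex$tracers, ex$fixed,
                    n_starts = 5, seed = 2)
  ci05 <- flux_confidence_interval(fit, "vC", alpha = 0.05, tol = 0.05)
  ci01 <- flux_confidence_interval(fit, "vC", alpha = 0.01, tol = 0.05)
  expect_lte(ci05$lb95, ci05$estimate); expect_gte(ci05$ub95, ci05$estimate)
  expect_lte(ci01$lb95, ci05$lb95 + 0.05)
  expect_gte(ci01$ub95, ci05$ub95 - 0.05)
  expect_equal(ci05$sd, (ci05$ub95 - ci05$lb95) / (2 * stats::qnorm(0.975)))
})

test_that("a structurally unidentifiable flux profiles out to the box limit", {
  # two indistinguishable parallel routes A -> B (identical atom maps)
  m <- build_flux_model(list(
    make_reaction("u", "1 A_ext -> 1 A", "A_ext:ab -> A:ab", kind = "uptake"),
    make_reaction("r1", "1 A -> 1 B", "A:ab -> B:ab"),
    make_reaction("r2", "1 A -> 1 B", "A:ab -> B:ab"),
    make_reaction("d", "1 B ->", kind = "biomass_drain")))
  tr <- list(t1 = tracer_spec("A_ext", "10", 0.99))
  truth <- c(u = 100, r1 = 60, r2 = 40, d = 100)
  mids <- make_mid_dataset(m, list(net = truth), tr, targets = "B",
                           replicates = 1, noise_sd = 0.005, seed = 3)
  fit <- fit_fluxes(m, mids, tr, c(u = 100), n_starts = 4, seed = 5)
  ci <- flux_confidence_interval(fit, "r1", tol = 0.5)
  expect_true(ci$lb_at_box || ci$lb95 <= 1)
  expect_true(ci$ub_at_box || ci$ub95 >= 99)
})

test_that("precision scores follow the squared width ratio", {
  mk <- function(lb, ub) list(lb95 = lb, ub95 = ub)
  expect_equal(precision_score(mk(0, 4), mk(0, 4)), 1)
  expect_equal(precision_score(mk(0, 4), mk(1, 3)), 4)
  expect_identical(precision_score(mk(0, 4), mk(2, 2)), Inf)
})

test_that("influx gating follows the strict 1% rule on unlabeled fractions", {
  model <- read_flux_model(species_model_path("pputida"))
  m0 <- c(MAL = 0.05, PYR = 0.05, G6P = 0.02, DHAP = 0.03, ACCOA = 0.02,
          FUM = 0.004, CIT = 0.002)
  expect_setequal(gate_unlabeled_influx(m0, model),
                  c("MAL_IN", "PYR_IN", "G6P_IN", "DHAP_IN", "ACCOA_IN"))
  expect_length(gate_unlabeled_influx(c(MAL = 0.01, PYR = 0.005), model), 0)
  expect_identical(gate_unlabeled_influx(c(MAL = 0.01)), character(0))
  expect_identical(gate_unlabeled_influx(c(MAL = 0.010001)), "MAL")
})
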