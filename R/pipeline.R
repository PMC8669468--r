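# End-to-end orchestration: influx gating -> parallel-tracer flux fit ->
# confidence intervals -> cofactor ledger -> physiology and proteome
# summaries -> JSON/markdown reports. Deterministic under config + seed.

#' Run the full analysis pipeline on a scenario
#'
#' @param scenario a scenario list as returned by [pputida_succinate_demo()],
#'   or NULL to build one from `seed` and `...`
#' @param out_dir output directory for `fit.json`, `ledger.json` and
#'   `report.md`; NULL skips writing
#' @param n_starts random restarts for the flux fit
#' @param seed master seed (also used for the scenario when generated here)
#' @param ci_reactions reactions to profile for 95% confidence intervals
#' @param po_ratio P/O ratio for ATP accounting
#' @param fit_options options forwarded to [fit_fluxes()]
#' @param ... scenario overrides when `scenario` is NULL
#' @return a `pipeline_run` list with fit, estimates, ledger, attribution,
#'   physiology, proteomics and energy-charge results
#' @export
run_pipeline <- function(scenario = NULL, out_dir = NULL, n_starts = 100,
                         seed = 1, ci_reactions = c("SDH", "CS", "ENO", "MAE", "PCK"),
                         po_ratio = 1.5, fit_options = list(), ...) {
  if (is.null(scenario)) scenario <- pputida_succinate_demo(seed = seed, ...)
  model <- scenario$model
  cfg <- scenario$config

  message("[gate] computing unlabeled fractions ([U-13C] experiment)")
  m0 <- mean_m0(scenario$gating$mids)
  gated <- gate_unlabeled_influx(m0, model)
  influx_ids <- vapply(Filter(function(r) r$kind == "unlabeled_influx",
                              model$reactions), `[[`, "", "id")
  off <- setdiff(influx_ids, gated)
  # biomass drains are constrained at the calculated efflux (the rates in
  # the measurement set); the free parameters are the labeling-informed
  # fluxes
  drain_fixed <- stats::setNames(scenario$measurements$rates$value,
                                 scenario$measurements$rates$reaction)
  fixed <- c(stats::setNames(100, uptake_reaction(model)),
             stats::setNames(rep(0, length(off)), off),
             drain_fixed)
  if ("THD" %in% names(model$reactions)) fixed["THD"] <- 0
  if ("BM_ASP" %in% names(model$reactions)) fixed["BM_ASP"] <- cfg$asp_drain
  if ("BM_GLU" %in% names(model$reactions)) fixed["BM_GLU"] <- cfg$glu_drain
  message("[gate] influxes enabled: ",
          if (length(gated) > 0) paste(gated, collapse = ", ") else "none")

  message("[fit] ", n_starts, " starts, seed ", seed)
  fit <- fit_fluxes(model, measurement_set(scenario$measurements$mids),
                    scenario$tracers, fixed,
                    n_starts = n_starts, seed = seed, options = fit_options)
  message(sprintf("[fit] SSR %.3f (dof %d, cutoff %.1f) %s", fit$ssr, fit$dof,
                  fit$chi2_cutoff_95,
                  if (isTRUE(fit$accepted)) "accepted" else "REJECTED"))

  estimates <- list()
  prep_ci <- mfa_prepare(model, fit$measurements, fit$tracers, fit$fixed,
                         fit$options)
  for (rx in intersect(ci_reactions, names(model$reactions))) {
    estimates[[rx]] <- flux_confidence_interval(fit, rx, prep = prep_ci)
    message(sprintf("[ci] %s: [%.2f, %.2f]", rx, estimates[[rx]]$lb95,
                    estimates[[rx]]$ub95))
  }

  message("[ledger] cofactor accounting at P/O ", po_ratio)
  demand <- biomass_efflux(cfg$mu, default_biomass_composition(cfg$species))
  anab <- anabolic_cofactor_demand(demand)
  sds <- stats::setNames(rep(0, length(fit$fluxes$net)), names(fit$fluxes$net))
  for (rx in names(estimates)) sds[rx] <- estimates[[rx]]$sd
  ledger <- cofactor_ledger(scale_fluxes(fit$fluxes$net, cfg$q_uptake), model,
                            anab, po_ratio = po_ratio,
                            flux_sds = sds * cfg$q_uptake / 100)
  attribution <- attribute_pathways(ledger)

  message("[physiology] growth and exchange rates")
  phys <- scenario$physiology
  growth <- fit_growth(phys$od, window = c(cfg$lag + 0.5, max(phys$od$time)))
  upt <- exchange_rates(phys$substrate, phys$cdw, growth$mu)

  message("[proteomics] differential abundance")
  prot <- differential_proteins(scenario$proteome$table, "succinate", "gluconate")

  ec <- energy_charge(scenario$pools["atp"], scenario$pools["adp"],
                      scenario$pools["amp"])

  run <- structure(list(
    scenario = scenario, fixed = fixed, gated_influxes = gated,
    fit = fit, estimates = estimates, ledger = ledger,
    attribution = attribution, growth = growth, uptake = upt,
    proteomics = prot, energy_charge = unname(ec), seed = seed,
    n_starts = n_starts, po_ratio = po_ratio), class = "pipeline_run")

  if (!is.null(out_dir)) write_pipeline_run(run, out_dir)
  run
}

uptake_reaction <- function(model) {
  up <- Filter(function(r) r$kind == "uptake", model$reactions)
  if (length(up) == 0) stop("model has no uptake reaction")
  up[[1]]$id
}

#' Write pipeline outputs (fit.json, ledger.json, report.md)
#' @param run `pipeline_run`
#' @param out_dir directory (created if missing)
#' @return `out_dir`, invisibly
#' @export
write_pipeline_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- run$fit
  fit_json <- list(
    seed = run$seed, n_starts = run$n_starts,
    ssr = fit$ssr, dof = fit$dof, chi2_cutoff_95 = fit$chi2_cutoff_95,
    accepted = fit$accepted,
    net_fluxes = as.list(round(fit$fluxes$net, 6)),
    exchange_fluxes = as.list(round(fit$fluxes$exch, 6)),
    confidence_intervals = lapply(run$estimates, function(e)
      list(estimate = e$estimate, lb95 = e$lb95, ub95 = e$ub95, sd = e$sd)))
  jsonlite::write_json(fit_json, file.path(out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  lg <- run$ledger
  ledger_json <- list(
    production = as.list(lg$production),
    consumption = as.list(lg$consumption),
    transhydrogenase_flux = lg$transhydrogenase_flux,
    thd_fraction = lg$thd_fraction,
    oxphos_atp = lg$oxphos_atp, substrate_level_atp = lg$substrate_level_atp,
    atp_production_total = lg$atp_production_total,
    atp_surplus = lg$atp_surplus, oxphos_fraction = lg$oxphos_fraction,
    po_ratio = lg$po_ratio,
    attribution = lapply(run$attribution, as.list))
  jsonlite::write_json(ledger_json, file.path(out_dir, "ledger.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  rpt <- c(
    "# Pipeline run report", "",
    sprintf("- seed %d, %d starts", run$seed, run$n_starts),
    sprintf("- chi2: SSR %.3f vs cutoff %.2f (dof %d): %s", fit$ssr,
            fit$chi2_cutoff_95, fit$dof,
            if (isTRUE(fit$accepted)) "accepted" else "rejected"),
    sprintf("- gated influxes: %s",
            if (length(run$gated_influxes) > 0)
              paste(run$gated_influxes, collapse = ", ") else "none"),
    sprintf("- transhydrogenase: %.2f mmol/gCDW/h (%.0f%% of NADPH production)",
            lg$transhydrogenase_flux, 100 * lg$thd_fraction),
    sprintf("- ATP: %.1f total, %.0f%% oxidative phosphorylation, surplus %.1f",
            lg$atp_production_total, 100 * lg$oxphos_fraction, lg$atp_surplus),
    sprintf("- growth: mu %.3f h^-1 (R2 %.3f); uptake q %.2f mmol/gCDW/h",
            run$growth$mu, run$growth$r2, run$uptake$q),
    sprintf("- energy charge %.3f", run$energy_charge),
    "", "## Net fluxes (% of uptake)", "",
    sprintf("| %s | %.2f |", names(fit$fluxes$net), fit$fluxes$net))
  writeLines(rpt, file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' Flux precision scores between two runs
#'
#' Computes P per requested reaction with `run_a` as the unwashed condition
#' and `run_b` as the washed reference; missing intervals give NA with a
#' warning.
#'
#' @param run_a,run_b `pipeline_run` objects (or lists with `$estimates`)
#' @param flux_ids reactions to score
#' @return data.frame(reaction, P)
#' @export
compare_runs <- function(run_a, run_b, flux_ids) {
  P <- vapply(flux_ids, function(rx) {
    a <- run_a$estimates[[rx]]; b <- run_b$estimates[[rx]]
    if (is.null(a) || is.null(b)) {
      warning("no confidence interval for ", rx, " in one of the runs")
      return(NA_real_)
    }
    precision_score(a, b)
  }, 0)
  data.frame(reaction = flux_ids, P = unname(P))
}
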