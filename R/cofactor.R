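# Cofactor and ATP accounting from an optimized flux distribution.
#
# Reactions carry signed per-flux cofactor stoichiometries for the lumped
# NADH/UQH2 pool (FADH2/ubiquinol are reported jointly), NADPH, and ATP.
# The ledger sums production and consumption separately, closes the anabolic
# NADPH deficit via a net NADH -> NADPH transhydrogenase flux, converts the
# remaining (respirable) NADH/UQH2 to ATP at a fixed P/O ratio, and reports
# the ATP surplus left after anabolism. SDs propagate as root-sum-of-squares
# of the contributing flux SDs (flux-flux correlations ignored).

#' Scale a normalized flux vector to absolute units
#'
#' @param v named net flux vector on the uptake-=-100 scale
#' @param q_uptake measured substrate uptake rate (mmol gCDW^-1 h^-1)
#' @return flux vector in mmol gCDW^-1 h^-1 with a `units` attribute
#' @export
scale_fluxes <- function(v, q_uptake) {
  out <- v * q_uptake / 100
  attr(out, "units") <- "mmol_gcdw_h"
  out
}

#' Build a cofactor ledger from absolute fluxes
#'
#' Production of cofactor c is `sum_r max(0, v_r * delta_rc)`; consumption is
#' the symmetric negative part plus the anabolic demand. Does not yet close
#' NADPH or account ATP; see [close_nadph()] and [atp_accounting()], or use
#' [cofactor_ledger()] for the full chain.
#'
#' @param fluxes named net flux vector in mmol gCDW^-1 h^-1 (from
#'   [scale_fluxes()]); passing normalized fluxes without the units attribute
#'   is an error
#' @param model `flux_model` carrying the cofactor stoichiometries
#' @param anabolic_demand named vector (nadph, atp, nadh_uqh2) of anabolic
#'   consumption rates (from [anabolic_cofactor_demand()]), or NULL
#' @param flux_sds optional named SD vector (same units) for propagation
#' @return a `cofactor_ledger`
#' @export
ledger_from_fluxes <- function(fluxes, model, anabolic_demand = NULL,
                               flux_sds = NULL) {
  if (is.null(attr(fluxes, "units")) || attr(fluxes, "units") != "mmol_gcdw_h")
    stop("unit error: fluxes must be absolute (mmol gCDW^-1 h^-1); ",
         "use scale_fluxes() on normalized fluxes")
  if (is.null(anabolic_demand))
    anabolic_demand <- c(nadph = 0, atp = 0, nadh_uqh2 = 0)
  cofs <- COFACTOR_KEYS
  prod <- cons <- stats::setNames(rep(0, 3), cofs)
  prod_var <- cons_var <- stats::setNames(rep(0, 3), cofs)
  prod_by_pathway <- list()
  for (r in model$reactions) {
    v <- fluxes[[r$id]]
    if (is.null(v) || is.na(v)) next
    sdv <- if (!is.null(flux_sds) && r$id %in% names(flux_sds)) flux_sds[[r$id]] else 0
    for (cf in cofs) {
      rate <- v * r$cofactors[[cf]]
      if (rate > 0) {
        prod[cf] <- prod[cf] + rate
        prod_var[cf] <- prod_var[cf] + (sdv * r$cofactors[[cf]])^2
        prod_by_pathway[[cf]] <- c(prod_by_pathway[[cf]],
                                   stats::setNames(rate, r$pathway))
      } else if (rate < 0) {
        cons[cf] <- cons[cf] - rate
        cons_var[cf] <- cons_var[cf] + (sdv * r$cofactors[[cf]])^2
      }
    }
  }
  anab <- stats::setNames(rep(0, 3), cofs)
  anab["nadph"] <- anabolic_demand[["nadph"]]
  anab["atp"] <- anabolic_demand[["atp"]]
  anab["nadh_uqh2"] <- anabolic_demand[["nadh_uqh2"]]
  structure(list(
    production = prod, consumption = cons + anab,
    reaction_consumption = cons, anabolic_demand = anab,
    production_sd = sqrt(prod_var), consumption_sd = sqrt(cons_var),
    prod_by_pathway = prod_by_pathway,
    transhydrogenase_flux = NA_real_, closed = FALSE),
    class = "cofactor_ledger")
}

#' Close the NADPH balance with a transhydrogenase flux
#'
#' The net NADH -> NADPH transhydrogenase flux is exactly the anabolic NADPH
#' deficit (zero if production already covers consumption). It is credited to
#' NADPH production and debited from the NADH/UQH2 pool, so post-closure
#' NADPH production equals NADPH consumption identically.
#'
#' @param ledger `cofactor_ledger`
#' @return ledger with `transhydrogenase_flux` and `thd_fraction` set
#' @export
close_nadph <- function(ledger) {
  thd <- max(0, ledger$consumption[["nadph"]] - ledger$production[["nadph"]])
  ledger$transhydrogenase_flux <- thd
  ledger$production["nadph"] <- ledger$production[["nadph"]] + thd
  ledger$consumption["nadh_uqh2"] <- ledger$consumption[["nadh_uqh2"]] + thd
  ledger$thd_fraction <- if (ledger$production[["nadph"]] > 0)
    thd / ledger$production[["nadph"]] else 0
  ledger$closed <- TRUE
  ledger
}

#' ATP accounting at a fixed P/O ratio
#'
#' Respirable NADH/UQH2 is production minus all post-closure consumption
#' (transhydrogenase plus gluconeogenic/anabolic reduction steps); oxidative
#' phosphorylation yields `po_ratio` ATP per respired equivalent. Total ATP
#' production is oxphos plus substrate-level; the surplus (maintenance and
#' unmodeled processes) is production minus consumption, an exact identity.
#'
#' @param ledger closed `cofactor_ledger` (see [close_nadph()])
#' @param po_ratio mol ATP per mol NADH/UQH2 oxidized (default 1.5)
#' @return ledger with `oxphos_atp`, `substrate_level_atp`,
#'   `atp_production_total`, `atp_surplus`, `oxphos_fraction` set
#' @export
atp_accounting <- function(ledger, po_ratio = 1.5) {
  if (!isTRUE(ledger$closed))
    stop("close_nadph() must run before atp_accounting(): the transhydrogenase ",
         "flux debits the NADH pool before respiration")
  if (po_ratio <= 0) stop("po_ratio must be > 0")
  respirable <- ledger$production[["nadh_uqh2"]] - ledger$consumption[["nadh_uqh2"]]
  ledger$respirable_nadh <- respirable
  ledger$respiration_flag <- respirable < 0
  ledger$oxphos_atp <- po_ratio * max(0, respirable)
  ledger$po_ratio <- po_ratio
  ledger$substrate_level_atp <- ledger$production[["atp"]]
  ledger$atp_production_total <- ledger$oxphos_atp + ledger$substrate_level_atp
  ledger$atp_surplus <- ledger$atp_production_total - ledger$consumption[["atp"]]
  ledger$oxphos_fraction <- if (ledger$atp_production_total > 0)
    ledger$oxphos_atp / ledger$atp_production_total else 0
  # propagate the NADH-side uncertainty through the P/O multiplication
  ledger$production_sd["atp_total"] <- sqrt(
    ledger$production_sd[["atp"]]^2 + (po_ratio * ledger$production_sd[["nadh_uqh2"]])^2)
  ledger
}

#' Full cofactor ledger: build, close NADPH, account ATP
#'
#' @inheritParams ledger_from_fluxes
#' @inheritParams atp_accounting
#' @return closed, ATP-accounted `cofactor_ledger`
#' @export
cofactor_ledger <- function(fluxes, model, anabolic_demand = NULL,
                            po_ratio = 1.5, flux_sds = NULL) {
  atp_accounting(close_nadph(
    ledger_from_fluxes(fluxes, model, anabolic_demand, flux_sds)), po_ratio)
}

#' Attribute cofactor production to pathways
#'
#' Fractions of each cofactor's production by the reactions' pathway tags.
#' Transhydrogenase-derived NADPH is attributed to the pathways producing the
#' NADH it consumed (proportionally to NADH/UQH2 pathway production).
#'
#' @param ledger closed `cofactor_ledger`
#' @return named list per cofactor of pathway-fraction vectors
#' @export
attribute_pathways <- function(ledger) {
  out <- list()
  tally <- function(x) {
    if (is.null(x) || length(x) == 0) return(stats::setNames(numeric(0), character(0)))
    tapply(x, names(x), sum)
  }
  nadh_tally <- tally(ledger$prod_by_pathway[["nadh_uqh2"]])
  for (cf in COFACTOR_KEYS) {
    t <- tally(ledger$prod_by_pathway[[cf]])
    if (cf == "nadph" && isTRUE(ledger$closed) && ledger$transhydrogenase_flux > 0) {
      if (sum(nadh_tally) > 0) {
        add <- ledger$transhydrogenase_flux * nadh_tally / sum(nadh_tally)
        for (p in names(add)) t[p] <- ifelse(is.na(t[p]), 0, t[p]) + add[p]
      }
    }
    if (cf == "atp" && !is.null(ledger$oxphos_atp) && ledger$oxphos_atp > 0) {
      # oxphos ATP inherits the pathway mix of the NADH it oxidized
      if (sum(nadh_tally) > 0) {
        add <- ledger$oxphos_atp * nadh_tally / sum(nadh_tally)
        for (p in names(add)) t[p] <- ifelse(is.na(t[p]), 0, t[p]) + add[p]
      }
    }
    tot <- sum(t)
    out[[cf]] <- if (tot > 0) t[order(names(t))] / tot else t
  }
  out
}

#' @export
print.cofactor_ledger <- function(x, ...) {
  cat("cofactor_ledger (mmol gCDW^-1 h^-1)\n")
  for (cf in COFACTOR_KEYS)
    cat(sprintf("  %-10s production %8.3f  consumption %8.3f\n",
                cf, x$production[[cf]], x$consumption[[cf]]))
  if (isTRUE(x$closed))
    cat(sprintf("  transhydrogenase %.3f (%.0f%% of NADPH production)\n",
                x$transhydrogenase_flux, 100 * x$thd_fraction))
  if (!is.null(x$atp_surplus))
    cat(sprintf("  ATP: oxphos %.3f (%.0f%%), substrate-level %.3f, surplus %.3f\n",
                x$oxphos_atp, 100 * x$oxphos_fraction, x$substrate_level_atp,
                x$atp_surplus))
  invisible(x)
}

#' Adenylate energy charge
#'
#' EC = ([ATP] + 0.5 [ADP]) / ([ATP] + [ADP] + [AMP]); scale-invariant and
#' bounded in [0, 1].
#'
#' @param atp,adp,amp pool sizes (any common concentration unit), all >= 0
#' @return scalar in [0, 1]
#' @export
energy_charge <- function(atp, adp, amp) {
  if (any(c(atp, adp, amp) < 0)) stop("adenylate pools must be >= 0")
  tot <- atp + adp + amp
  if (tot == 0) stop("energy charge undefined for an all-zero adenylate pool")
  (atp + 0.5 * adp) / tot
}
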