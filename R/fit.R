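# Flux estimation from parallel-tracer MID data.
#
# Fluxes are parameterized by the free net fluxes of the steady-state basis
# plus one exchange coordinate per reversible atom-mapped reaction, carried
# as an unbounded logit of e = x/(1+x) so the optimizer never sits on a hard
# box. The variance-weighted residual vector stacks every MID entry of every
# tracer/replicate with every rate measurement; irreversibility and flux
# magnitude limits enter as smooth hinge residuals, and a weak L2 pull
# removes the otherwise-flat futile-cycle directions. Local solves are
# unconstrained Levenberg-Marquardt (minpack.lm) from sign-feasible,
# rate-consistent random starts.

#' Assemble a measurement set
#'
#' @param mids data.frame with columns `tracer`, `replicate`, `metabolite`,
#'   `mass` (0..n), `value`, `sd`
#' @param rates data.frame with columns `reaction`, `value`, `sd` and optional
#'   `type` (`"secretion"` or `"biomass"`); may be NULL
#' @return a `measurement_set`
#' @export
measurement_set <- function(mids, rates = NULL) {
  need <- c("tracer", "replicate", "metabolite", "mass", "value", "sd")
  if (!all(need %in% names(mids)))
    stop("mids must have columns: ", paste(need, collapse = ", "))
  if (is.null(rates))
    rates <- data.frame(reaction = character(0), value = numeric(0),
                        sd = numeric(0), type = character(0))
  if (is.null(rates$type)) rates$type <- rep("secretion", nrow(rates))
  structure(list(mids = mids, rates = rates), class = "measurement_set")
}

#' Read / write MID tables in the TSV dialect
#' `fragment  mass  fraction  sd  tracer_id  replicate`
#' @param path TSV path
#' @return data.frame in `measurement_set` mids layout
#' @export
read_mid_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("fragment", "mass", "fraction", "sd", "tracer_id", "replicate")
  if (!all(need %in% names(d))) stop("MID table must have columns: ",
                                     paste(need, collapse = ", "))
  data.frame(tracer = d$tracer_id, replicate = d$replicate,
             metabolite = d$fragment, mass = d$mass, value = d$fraction, sd = d$sd)
}

#' @rdname read_mid_table
#' @param mids mids data.frame
#' @export
write_mid_table <- function(mids, path) {
  utils::write.table(
    data.frame(fragment = mids$metabolite, mass = mids$mass,
               fraction = mids$value, sd = mids$sd,
               tracer_id = mids$tracer, replicate = mids$replicate),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

default_fit_options <- function(options = list()) {
  defaults <- list(
    sd_floor = 0.005,        # absolute SD floor on MID fractions
    flux_max = 500,          # soft magnitude limit on net fluxes
    influx_max = 100,        # carry-over influx upper bound = uptake
    exch_max = 0.9999,       # cap on transformed exchange e = x/(1+x)
    penalty_weight = 10,     # hinge weight per unit of sign violation
    reg_flux = 0.03,         # L2 pull on net fluxes; pins label-invisible
                             # futile-cycle directions near minimum norm
    reg_exch = 1e-2,         # L2 pull on exchange fluxes
    feas_tol = 0.5,          # tolerated sign-violation depth (flux scale)
    maxiter = 300,
    triage_maxiter = 50,     # short first-pass iterations per start
    triage_top = 8,          # starts kept for the full-depth polish
    start_net_max = 150,     # random starts drawn within +-this
    start_exch_max = 0.7,
    biomass_sd_factor = 1)   # set 2 for the two-standard-deviation option
  utils::modifyList(defaults, options)
}

# Build the residual machinery shared by the objective, fitter and profiler.
mfa_prepare <- function(model, measurements, tracers, fixed, options = list(),
                        reuse = NULL) {
  opt <- default_fit_options(options)
  basis <- flux_basis(model, fixed)
  free <- basis$free_reaction_ids
  nf <- length(free)
  exch_ids <- names(Filter(function(r) r$reversible && !is.null(r$transitions),
                           model$reactions))
  ne <- length(exch_ids)

  lower <- numeric(nf); upper <- numeric(nf)
  for (i in seq_len(nf)) {
    r <- model$reactions[[free[i]]]
    if (r$kind == "unlabeled_influx") { lower[i] <- 0; upper[i] <- opt$influx_max }
    else if (r$reversible) { lower[i] <- -opt$flux_max; upper[i] <- opt$flux_max }
    else { lower[i] <- 0; upper[i] <- opt$flux_max }
  }
  lower <- c(lower, rep(0, ne)); upper <- c(upper, rep(opt$exch_max, ne))

  irrev <- names(Filter(function(r) !r$reversible, model$reactions))
  irrev <- setdiff(irrev, names(fixed))

  mids <- measurements$mids
  mids$sd <- pmax(mids$sd, opt$sd_floor)
  rates <- measurements$rates
  if (nrow(rates) > 0 && opt$biomass_sd_factor != 1) {
    bio <- rates$type == "biomass"
    rates$sd[bio] <- rates$sd[bio] * opt$biomass_sd_factor
  }
  tr_ids <- unique(mids$tracer)
  if (!all(tr_ids %in% names(tracers)))
    stop("tracer ids in measurements lack tracer_spec: ",
         paste(setdiff(tr_ids, names(tracers)), collapse = ", "))
  targets <- sort(unique(mids$metabolite))
  if (!is.null(reuse)) {
    net <- reuse$net
    bound <- reuse$bound
  } else {
    net <- emu_network(model, targets)
    bound <- lapply(tracers[tr_ids], function(t) emu_bind_tracer(net, t))
  }

  # flat indexing of simulated MIDs per tracer
  tlen <- net$carbon_counts[targets] + 1
  offs <- stats::setNames(c(0, cumsum(tlen))[seq_along(targets)], targets)
  per_tracer <- lapply(tr_ids, function(t) {
    rows <- mids[mids$tracer == t, ]
    list(idx = offs[rows$metabolite] + rows$mass + 1,
         value = rows$value, sd = rows$sd)
  })
  names(per_tracer) <- tr_ids
  n_mid_res <- sum(vapply(per_tracer, function(p) length(p$value), 0L))

  # independent residual count: each (tracer, replicate, metabolite) MID
  # carries length-1 independent entries (fractions sum to 1)
  grp <- unique(mids[, c("tracer", "replicate", "metabolite")])
  n_indep <- sum(tlen[grp$metabolite] - 1) + nrow(rates)

  exch_pos <- match(exch_ids, names(model$reactions))
  n_rxn <- length(model$reactions)
  tloc <- net$target_loc[targets]

  # affine completion v = Cmat u + d0 (used by the linear start projection)
  d0 <- unname(basis$complete(stats::setNames(rep(0, nf), free)))
  Cmat <- matrix(0, n_rxn, nf)
  for (i in seq_len(nf)) {
    ei <- stats::setNames(rep(0, nf), free); ei[i] <- 1
    Cmat[, i] <- unname(basis$complete(ei)) - d0
  }
  irrev_idx <- match(irrev, names(model$reactions))

  influx_idx <- match(names(Filter(function(r) r$kind == "unlabeled_influx",
                                   model$reactions)), names(model$reactions))
  influx_idx <- setdiff(influx_idx, match(names(fixed), names(model$reactions)))

  # Parameter vector: free net fluxes, then unbounded logits z for the
  # exchange coordinates (e = exch_max * plogis(z), x = e / (1 - e)).
  # Constraints enter as smooth, gently weighted residuals rather than
  # optimizer boxes: a hinge on sign violations and soft magnitude limits,
  # plus a weak L2 pull that removes the flat futile-cycle plateau.
  resid_fn <- function(par, reg_mult = 1) {
    u <- par[seq_len(nf)]
    v <- basis$complete(stats::setNames(u, free))
    ex_full <- numeric(n_rxn)
    x <- numeric(0)
    if (ne > 0) {
      e <- opt$exch_max * stats::plogis(par[nf + seq_len(ne)])
      x <- e / (1 - e)
      ex_full[exch_pos] <- x
    }
    vdir <- dirflux_fast(net, unname(v), ex_full)
    mid_res <- tryCatch({
      Xs <- emu_forward(net, vdir, bound, strict = FALSE)
      unlist(lapply(seq_along(tr_ids), function(k) {
        simflat <- unlist(lapply(tloc, function(rf) Xs[[rf[1]]][[k]][rf[2], ]),
                          use.names = FALSE)
        p <- per_tracer[[tr_ids[k]]]
        (simflat[p$idx] - p$value) / p$sd
      }), use.names = FALSE)
    }, error = function(e) rep(1e3, n_mid_res))
    rate_res <- if (nrow(rates) > 0) (v[rates$reaction] - rates$value) / rates$sd
                else numeric(0)
    pen <- opt$penalty_weight * pmax(0, -v[irrev])
    soft_box <- opt$penalty_weight * pmax(abs(v) - opt$flux_max, 0)
    soft_influx <- if (length(influx_idx) > 0)
      opt$penalty_weight * pmax(v[influx_idx] - opt$influx_max, 0) else numeric(0)
    c(mid_res, rate_res, pen, soft_box, soft_influx,
      reg_mult * opt$reg_flux * v,
      reg_mult * opt$reg_exch * (if (ne > 0) par[nf + seq_len(ne)] else numeric(0)))
  }

  list(opt = opt, basis = basis, free = free, nf = nf, exch_ids = exch_ids,
       ne = ne, lower = lower, upper = upper, irrev = irrev,
       resid_fn = resid_fn, n_mid_res = n_mid_res, n_rate_res = nrow(rates),
       n_indep = n_indep, net = net, bound = bound, fixed = fixed,
       rates = rates, tracers = tracers, tr_ids = tr_ids,
       Cmat = Cmat, d0 = d0, irrev_idx = irrev_idx,
       rate_idx = match(rates$reaction, names(model$reactions)))
}

# Project a random start onto the cheap, entirely linear part of the
# problem: sign feasibility plus the rate residuals, with a weak pull toward
# the original draw so starts stay diverse. The completion map is affine
# (v = C u + d), so this is an iterated active-set linear least squares --
# no isotopomer simulation involved.
feasible_start <- function(prep, par) {
  nf <- prep$nf
  draw <- par[seq_len(nf)]
  lo <- prep$lower[seq_len(nf)]; hi <- prep$upper[seq_len(nf)]
  w_pull <- 1e-2; w_feas <- 10; margin <- 1
  rate_rows <- if (length(prep$rate_idx) > 0)
    prep$Cmat[prep$rate_idx, , drop = FALSE] / prep$rates$sd else NULL
  rate_b <- if (length(prep$rate_idx) > 0)
    (prep$rates$value - prep$d0[prep$rate_idx]) / prep$rates$sd else NULL
  u <- draw
  active <- integer(0)   # accumulated active set (prevents cycling)
  target <- numeric(0)   # random positive targets keep starts diverse
  for (it in 1:60) {
    v <- as.vector(prep$Cmat %*% u) + prep$d0
    neg <- prep$irrev_idx[v[prep$irrev_idx] < 1e-9]
    if (length(neg) == 0) break
    new <- setdiff(neg, active)
    if (length(new) > 0) {
      active <- c(active, new)
      target <- c(target, stats::runif(length(new), margin, 60))
    }
    M <- rbind(w_pull * diag(nf),
               if (!is.null(rate_rows)) rate_rows,
               w_feas * prep$Cmat[active, , drop = FALSE])
    b <- c(w_pull * draw,
           rate_b,
           w_feas * (pmax(v[active], target) - prep$d0[active]))
    u <- tryCatch(qr.solve(M, b), error = function(e) u)
    u <- pmin(pmax(u, lo), hi)
  }
  par[seq_len(nf)] <- u
  par
}

split_ssr <- function(prep, par) {
  res <- prep$resid_fn(par)
  nfit <- prep$n_mid_res + prep$n_rate_res
  v <- as.vector(prep$Cmat %*% par[seq_len(prep$nf)]) + prep$d0
  depth <- if (length(prep$irrev_idx) > 0)
    max(0, -min(v[prep$irrev_idx])) else 0
  list(ssr = sum(res[seq_len(nfit)]^2), penalty = depth,
       feasible = depth <= prep$opt$feas_tol)
}

# exchange flux <-> unbounded logit coordinate
exch_to_z <- function(x, emax) {
  e <- pmin(pmax(x / (1 + x), 1e-7), emax * (1 - 1e-7))
  stats::qlogis(e / emax)
}
z_to_exch <- function(z, emax) {
  e <- emax * stats::plogis(z)
  e / (1 - e)
}

#' Variance-weighted sum of squared residuals for a flux assignment
#'
#' @param model `flux_model`
#' @param measurements `measurement_set`
#' @param tracers named list of `tracer_spec` (names match `mids$tracer`)
#' @param free_values named free net flux values (over the basis implied by
#'   `fixed`)
#' @param exch named exchange fluxes (raw x >= 0 units), optional
#' @param fixed named equality constraints (e.g. uptake = 100)
#' @param options fit options (see [fit_fluxes()])
#' @return the scalar SSR
#' @export
mfa_objective <- function(model, measurements, tracers, free_values,
                          exch = NULL, fixed = NULL, options = list()) {
  prep <- mfa_prepare(model, measurements, tracers, fixed, options)
  x <- stats::setNames(rep(0, prep$ne), prep$exch_ids)
  if (!is.null(exch) && prep$ne > 0) x[names(exch)] <- exch
  par <- c(unname(free_values[prep$free]), exch_to_z(unname(x), prep$opt$exch_max))
  split_ssr(prep, par)$ssr
}

#' Estimate fluxes by multi-start variance-weighted least squares
#'
#' Runs `n_starts` Levenberg-Marquardt solves from random initial values
#' drawn uniformly inside the free-flux boxes (seeded, hence deterministic),
#' keeps the best feasible solution (ties broken by lowest start index), and
#' evaluates the chi-square goodness-of-fit cutoff at the 95% level with
#' dof = independent residuals - free parameters.
#'
#' @param model `flux_model`
#' @param measurements `measurement_set`
#' @param tracers named list of `tracer_spec`
#' @param fixed named equality constraints; typically `c(<uptake> = 100)` plus
#'   zero constraints on gated-off influx reactions
#' @param n_starts number of random restarts (default 100)
#' @param seed RNG seed for the start draws
#' @param start_values optional named list/vector of free-flux values to use
#'   as an additional first start
#' @param options list overriding [default_fit_options()]
#' @return an `mfa_fit`
#' @export
fit_fluxes <- function(model, measurements, tracers, fixed,
                       n_starts = 100, seed = 1, start_values = NULL,
                       options = list()) {
  prep <- mfa_prepare(model, measurements, tracers, fixed, options)
  opt <- prep$opt
  npar <- prep$nf + prep$ne
  if (prep$n_mid_res + prep$n_rate_res == 0) stop("measurement set is empty")

  set.seed(seed)
  starts <- matrix(0, n_starts, npar)
  for (i in seq_len(n_starts)) {
    lo <- pmax(prep$lower[seq_len(prep$nf)], -opt$start_net_max)
    hi <- pmin(prep$upper[seq_len(prep$nf)], opt$start_net_max)
    starts[i, seq_len(prep$nf)] <- stats::runif(prep$nf, lo, hi)
    if (prep$ne > 0)
      starts[i, prep$nf + seq_len(prep$ne)] <-
        stats::qlogis(stats::runif(prep$ne, 0.02, opt$start_exch_max) / opt$exch_max)
  }
  if (!is.null(start_values)) {
    s0 <- rep(0, npar)
    s0[seq_len(prep$nf)] <- pmin(pmax(unlist(start_values)[prep$free],
                                      prep$lower[seq_len(prep$nf)]),
                                 prep$upper[seq_len(prep$nf)])
    starts <- rbind(s0, starts)
  }

  run_lm <- function(par0, iters, reg_mult = 1) tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = par0, fn = function(p) prep$resid_fn(p, reg_mult),
      control = minpack.lm::nls.lm.control(
        maxiter = iters, ptol = 1e-11, ftol = 1e-11,
        maxfev = 100 * (npar + 1) * 5))),
    error = function(e) NULL)

  # two-phase multi-start: a short Levenberg-Marquardt pass over every start,
  # then full-depth polishing of the leaders
  per_start <- data.frame(start = seq_len(nrow(starts)), ssr = NA_real_,
                          penalty = NA_real_, feasible = FALSE)
  pars <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    sol <- run_lm(feasible_start(prep, starts[i, ]), opt$triage_maxiter)
    if (is.null(sol)) next
    pars[[i]] <- sol$par
    sp <- split_ssr(prep, sol$par)
    per_start$ssr[i] <- sp$ssr
    per_start$penalty[i] <- sp$penalty
    per_start$feasible[i] <- sp$feasible
  }
  ok <- which(!is.na(per_start$ssr))
  if (length(ok) == 0)
    stop("fit failure: every start failed to optimize (", n_starts, " starts)")
  polish <- ok[order(!per_start$feasible[ok], per_start$ssr[ok])]
  polish <- polish[seq_len(min(opt$triage_top, length(polish)))]
  best <- NULL
  for (i in polish) {
    sol <- run_lm(pars[[i]], opt$maxiter)
    if (is.null(sol)) next
    sp <- split_ssr(prep, sol$par)
    per_start$ssr[i] <- sp$ssr
    per_start$penalty[i] <- sp$penalty
    per_start$feasible[i] <- sp$feasible
    if (sp$feasible && (is.null(best) || sp$ssr < best$ssr - 1e-12)) {
      best <- list(par = sol$par, ssr = sp$ssr, start = i)
    }
  }
  if (is.null(best))
    stop("fit failure: no start produced a sign-feasible flux distribution (",
         n_starts, " starts)")

  u <- stats::setNames(best$par[seq_len(prep$nf)], prep$free)
  v <- prep$basis$complete(u)
  x <- if (prep$ne > 0)
    stats::setNames(z_to_exch(best$par[prep$nf + seq_len(prep$ne)], opt$exch_max),
                    prep$exch_ids) else stats::setNames(numeric(0), character(0))
  dof <- prep$n_indep - npar
  cutoff <- if (dof > 0) stats::qchisq(0.95, dof) else NA_real_
  structure(list(
    model = model, measurements = measurements, tracers = prep$tracers,
    fixed = fixed, options = options,
    free_reaction_ids = prep$free, exch_ids = prep$exch_ids,
    par = best$par, free_values = u,
    fluxes = list(net = v, exch = x),
    ssr = best$ssr, dof = dof, chi2_cutoff_95 = cutoff,
    accepted = if (is.na(cutoff)) NA else best$ssr <= cutoff,
    per_start = per_start, best_start = best$start, seed = seed,
    n_starts = n_starts),
    class = "mfa_fit")
}

#' @export
print.mfa_fit <- function(x, ...) {
  cat("mfa_fit:", length(x$fluxes$net), "reactions,",
      length(x$free_reaction_ids), "free net fluxes,",
      length(x$exch_ids), "exchange fluxes\n")
  cat(sprintf("  SSR = %.4g on dof = %d (chi2 95%% cutoff %.4g) -> %s\n",
              x$ssr, x$dof, x$chi2_cutoff_95,
              if (isTRUE(x$accepted)) "accepted" else "REJECTED"))
  invisible(x)
}

# re-optimize with an extra equality constraint (profile step); warm-started
# from a full flux vector since free fluxes are actual reactions.
profile_refit <- function(fit, rxn, value, warm_v, warm_x, options,
                          prep_cache = NULL) {
  fixed2 <- c(fit$fixed, stats::setNames(value, rxn))
  prep2 <- if (!is.null(prep_cache)) prep_cache(fixed2) else tryCatch(
    mfa_prepare(fit$model, fit$measurements, fit$tracers, fixed2, options),
    error = function(e) NULL)
  if (is.null(prep2)) return(list(ssr = Inf))
  emax <- prep2$opt$exch_max
  par0 <- c(unname(warm_v[prep2$free]),
            if (prep2$ne > 0) exch_to_z(unname(warm_x[prep2$exch_ids]), emax)
            else numeric(0))
  sol <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = par0, fn = prep2$resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 60,
                                           ptol = 1e-10, ftol = 1e-10))),
    error = function(e) NULL)
  if (is.null(sol)) return(list(ssr = Inf))
  sp <- split_ssr(prep2, sol$par)
  if (!sp$feasible) return(list(ssr = Inf))
  u <- stats::setNames(sol$par[seq_len(prep2$nf)], prep2$free)
  list(ssr = sp$ssr, v = prep2$basis$complete(u),
       x = if (prep2$ne > 0)
         stats::setNames(z_to_exch(sol$par[prep2$nf + seq_len(prep2$ne)], emax),
                         prep2$exch_ids) else numeric(0))
}

#' Profile-likelihood confidence interval for one net flux
#'
#' Constrains the reaction's net flux, re-optimizes all other parameters, and
#' locates by bisection the values where the SSR exceeds the best SSR by the
#' chi-square quantile (3.84 for 95%). Bounds hitting the flux box are
#' reported at the box limit and flagged.
#'
#' @param fit `mfa_fit`
#' @param reaction reaction id
#' @param alpha significance level (default 0.05)
#' @param tol absolute bisection tolerance on the flux scale (default 0.01 on
#'   the uptake-=-100 scale)
#' @param prep internal prepared-problem cache (reused across reactions when
#'   profiling many fluxes); computed when NULL
#' @return a `flux_estimate` with `estimate`, `lb95`, `ub95`, `sd`
#' @export
flux_confidence_interval <- function(fit, reaction, alpha = 0.05, tol = 0.01,
                                     prep = NULL) {
  if (!(reaction %in% names(fit$fluxes$net))) stop("unknown reaction: ", reaction)
  opt <- default_fit_options(fit$options)
  target <- fit$ssr + stats::qchisq(1 - alpha, 1)
  est <- fit$fluxes$net[[reaction]]
  r <- fit$model$reactions[[reaction]]
  box <- if (r$kind == "unlabeled_influx") c(0, opt$influx_max)
         else if (r$reversible) c(-opt$flux_max, opt$flux_max)
         else c(0, opt$flux_max)
  prep0 <- if (!is.null(prep)) prep
           else mfa_prepare(fit$model, fit$measurements, fit$tracers,
                            fit$fixed, fit$options)
  prep_cache <- function(fixed2) tryCatch(
    mfa_prepare(fit$model, fit$measurements, fit$tracers, fixed2,
                fit$options, reuse = prep0),
    error = function(e) NULL)

  search <- function(dir) {  # dir = +1 upper, -1 lower
    warm_v <- fit$fluxes$net
    warm_x <- fit$fluxes$exch
    inside <- est
    step <- max(tol * 10, 0.02 * abs(est), 0.5)
    outside <- NA
    repeat {
      cand <- inside + dir * step
      lim <- if (dir > 0) box[2] else box[1]
      hit_box <- (dir > 0 && cand >= lim) || (dir < 0 && cand <= lim)
      if (hit_box) cand <- lim
      pr <- profile_refit(fit, reaction, cand, warm_v, warm_x, fit$options,
                          prep_cache)
      if (is.finite(pr$ssr)) { warm_v <- pr$v; warm_x <- pr$x }
      if (pr$ssr > target) { outside <- cand; break }
      inside <- cand
      if (hit_box) return(list(bound = lim, flagged = TRUE))
      step <- step * 2
    }
    while (abs(outside - inside) > tol) {
      mid <- (outside + inside) / 2
      pr <- profile_refit(fit, reaction, mid, warm_v, warm_x, fit$options,
                          prep_cache)
      if (is.finite(pr$ssr)) { warm_v <- pr$v; warm_x <- pr$x }
      if (pr$ssr > target) outside <- mid else inside <- mid
    }
    list(bound = (outside + inside) / 2, flagged = FALSE)
  }

  up <- search(+1)
  lo <- search(-1)
  lb <- min(lo$bound, est); ub <- max(up$bound, est)
  structure(list(reaction = reaction, estimate = est,
                 lb95 = lb, ub95 = ub,
                 sd = (ub - lb) / (2 * stats::qnorm(0.975)),
                 alpha = alpha,
                 lb_at_box = lo$flagged, ub_at_box = up$flagged),
            class = "flux_estimate")
}

#' @export
print.flux_estimate <- function(x, ...) {
  cat(sprintf("%s: %.3f [%.3f, %.3f] sd %.3f%s\n", x$reaction, x$estimate,
              x$lb95, x$ub95, x$sd,
              if (x$lb_at_box || x$ub_at_box) " (bound at box limit)" else ""))
  invisible(x)
}

#' Flux precision score between two conditions
#'
#' P = ((UB95-LB95)_unwashed / (UB95-LB95)_washed)^2; values above 1 mean the
#' washed (reference) condition constrains the flux more tightly.
#'
#' @param ci_unwashed,ci_washed `flux_estimate` objects (or lists with
#'   `lb95`/`ub95`)
#' @return scalar P (Inf when the washed width is zero)
#' @export
precision_score <- function(ci_unwashed, ci_washed) {
  wu <- ci_unwashed$ub95 - ci_unwashed$lb95
  ww <- ci_washed$ub95 - ci_washed$lb95
  if (ww == 0) return(Inf)
  (wu / ww)^2
}

#' Gate unlabeled carry-over influx reactions on M+0 fractions
#'
#' An influx is enabled for a metabolite iff its mean natural-abundance-
#' corrected M+0 fraction strictly exceeds the threshold (default 0.01).
#'
#' @param m0 named vector of mean M+0 fractions per metabolite
#' @param model optional `flux_model`; when given, returns the ids of the
#'   model's `unlabeled_influx` reactions feeding the gated metabolites
#' @param threshold gating threshold (strict inequality)
#' @return character vector of metabolite ids, or influx reaction ids when
#'   `model` is supplied
#' @export
gate_unlabeled_influx <- function(m0, model = NULL, threshold = 0.01) {
  mets <- names(m0)[m0 > threshold]
  if (is.null(model)) return(mets)
  infl <- Filter(function(r) r$kind == "unlabeled_influx", model$reactions)
  ids <- vapply(infl, `[[`, "", "id")
  prods <- vapply(infl, function(r) names(r$products)[1], "")
  unname(ids[prods %in% mets])
}

#' Mean M+0 fraction per metabolite from a MID table
#' @param mids mids data.frame (see [measurement_set()])
#' @return named vector over metabolites
#' @export
mean_m0 <- function(mids) {
  z <- mids[mids$mass == 0, ]
  tapply(z$value, z$metabolite, mean)
}
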