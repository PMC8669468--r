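# Full isotopomer-space reference simulator.
#
# Enumerates all 2^n positional isotopomers of every balanced metabolite and
# iterates the steady-state balance to a fixed point. Exponential in network
# carbon count, so only usable on small networks -- it exists as an
# independent cross-check of the EMU cascade, and deliberately shares no code
# with it beyond the model structures.

#' Simulate MIDs by exhaustive isotopomer enumeration
#'
#' @param model small `flux_model` (total carbons per reaction modest; joint
#'   substrate spaces are enumerated)
#' @param fluxes list with `net` and optional `exch` named vectors
#' @param tracer `tracer_spec` or NULL
#' @param targets metabolite ids; default all balanced metabolites with known
#'   carbon counts
#' @param tol fixed-point convergence tolerance
#' @param maxit iteration cap
#' @return named list of MID vectors
#' @export
simulate_isotopomers <- function(model, fluxes, tracer = NULL, targets = NULL,
                                 tol = 1e-13, maxit = 20000) {
  cc <- model$carbon_counts
  if (is.null(targets))
    targets <- intersect(model$balanced, names(cc))
  slots <- directed_slots(model)
  vdir <- directed_fluxes(model, fluxes$net, fluxes$exch)

  bal <- intersect(model$balanced, names(cc))
  dist <- lapply(bal, function(m) c(1, rep(0, 2^cc[[m]] - 1)))
  names(dist) <- bal

  # tracer isotopomer distribution over the full substrate molecule
  tracer_dist <- function(n) {
    if (is.null(tracer)) return(c(1, rep(0, 2^n - 1)))
    out <- numeric(2^n)
    for (m in tracer$mixture) {
      bits <- strsplit(m$pattern, "")[[1]]
      d <- 1
      for (p in seq_len(n)) {
        pr <- if (bits[p] == "1") c(1 - tracer$purity, tracer$purity) else c(1, 0)
        d <- as.vector(d %o% pr)  # position p occupies bit p-1 (low bits first)
      }
      out <- out + m$fraction * d
    }
    out
  }

  # precompile producing terms: per balanced metabolite, a list of
  # (slot, weight, substrate mets, product-state map over the joint space)
  terms <- stats::setNames(vector("list", length(bal)), bal)
  cons <- stats::setNames(rep(0, length(bal)), bal)
  cons_slots <- stats::setNames(vector("list", length(bal)), bal)
  for (i in seq_along(slots)) {
    sd <- slot_sides(model, slots[[i]])
    for (met in names(sd$sub)) if (met %in% bal)
      cons_slots[[met]] <- rbind(cons_slots[[met]],
                                 data.frame(slot = i, coef = sd$sub[[met]]))
    alts <- slot_alternatives(model, slots[[i]])
    if (is.null(alts)) {
      for (met in names(sd$prod)) if (met %in% bal)
        stop("balanced metabolite '", met, "' produced by unmapped reaction '",
             slots[[i]]$rxn, "'")
      next
    }
    for (alt in alts) {
      subs <- vapply(alt$sub, `[[`, "", "met")
      nsub <- vapply(alt$sub, function(e) length(e$atoms), 0L)
      offs <- c(0, cumsum(nsub))[seq_along(subs)]
      N <- sum(nsub)
      combo <- 0:(2^N - 1)
      for (e in alt$prod) {
        if (!(e$met %in% bal)) next
        np <- length(e$atoms)
        pmap <- integer(length(combo))
        for (k in seq_len(np)) {
          letter <- e$atoms[k]
          bit <- NA_integer_
          for (si in seq_along(alt$sub)) {
            q <- match(letter, alt$sub[[si]]$atoms)
            if (!is.na(q)) { bit <- offs[si] + q - 1; break }
          }
          if (is.na(bit)) next  # unlabeled source atom stays 12C (bit 0)
          pmap <- pmap + bitwAnd(bitwShiftR(combo, bit), 1L) * 2L^(k - 1)
        }
        grp <- split(seq_along(pmap), pmap)
        terms[[e$met]] <- c(terms[[e$met]], list(list(
          slot = i, w = sd$prod[[e$met]] / length(alts),
          subs = subs, grp = grp,
          states = as.integer(names(grp)) + 1L, npstates = 2^np)))
      }
    }
  }

  ext_cache <- list()
  sub_dist <- function(met) {
    if (met %in% bal) return(dist[[met]])
    if (is.null(ext_cache[[met]])) {
      n <- cc[[met]]
      if (is.null(n) || is.na(n)) stop("unknown carbon count for ", met)
      d <- if (!is.null(tracer) && met == tracer$substrate) tracer_dist(n)
           else c(1, rep(0, 2^n - 1))
      ext_cache[[met]] <<- d
    }
    ext_cache[[met]]
  }

  for (m in bal) {
    cs <- cons_slots[[m]]
    if (is.null(cs)) stop("balanced metabolite '", m, "' is never consumed")
    cons[m] <- sum(cs$coef * vdir[cs$slot])
    if (cons[m] <= 0) stop("zero total flux through '", m, "'")
  }

  for (it in seq_len(maxit)) {
    delta <- 0
    for (m in bal) {
      acc <- numeric(length(dist[[m]]))
      for (tm in terms[[m]]) {
        v <- vdir[tm$slot] * tm$w
        if (v == 0) next
        joint <- 1
        for (sm in tm$subs) joint <- as.vector(joint %o% sub_dist(sm))
        d <- numeric(tm$npstates)
        for (gi in seq_along(tm$grp))
          d[tm$states[gi]] <- sum(joint[tm$grp[[gi]]])
        acc <- acc + v * d
      }
      newd <- acc / cons[m]
      delta <- max(delta, max(abs(newd - dist[[m]])))
      dist[[m]] <- newd  # Gauss-Seidel style in-place update
    }
    if (delta < tol) break
  }
  if (delta >= tol) warning("isotopomer fixed point did not reach tol (delta=", delta, ")")

  out <- lapply(targets, function(m) {
    d <- dist[[m]]
    n <- cc[[m]]
    counts <- vapply(0:(2^n - 1), function(s) sum(bitwAnd(bitwShiftR(s, 0:(n - 1)), 1L)), 0L)
    vapply(0:n, function(k) sum(d[counts == k]), 0)
  })
  names(out) <- targets
  out
}
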