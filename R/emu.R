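# Elementary metabolite unit (EMU) decomposition and forward simulation.
#
# The EMU of a metabolite is a subset of its carbon atoms; its mass isotopomer
# distribution (MID) can be balanced independently of the rest of the molecule.
# Starting from the observed fragments, the decomposition walks atom maps
# backwards to the tracer boundary, collecting the minimal set of EMUs needed.
# At steady state the EMUs of each size satisfy a linear system
# A(v) X = -B(v) Y, where Y stacks tracer EMUs and convolutions of smaller
# EMUs; the cascade is solved size by size with dense solves (models here are
# small). Reversible reactions enter as two opposing directed flows
# (net/exchange expanded to forward/backward).

emu_key <- function(met, pos) paste0(met, ":", paste(pos, collapse = "."))

#' Convolve two mass isotopomer distributions
#' @keywords internal
conv_mid <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  na <- length(a); nb <- length(b)
  out <- numeric(na + nb - 1)
  for (i in seq_len(na)) {
    j <- i:(i + nb - 1)
    out[j] <- out[j] + a[i] * b
  }
  out
}

# Directed reaction slots: one forward slot per reaction, plus a backward slot
# for reversible reactions. Returns slot table and per-metabolite consumption.
directed_slots <- function(model) {
  slots <- list()
  for (r in model$reactions) {
    slots[[length(slots) + 1]] <- list(rxn = r$id, dir = "f")
    if (r$reversible) slots[[length(slots) + 1]] <- list(rxn = r$id, dir = "b")
  }
  names(slots) <- vapply(slots, function(s) paste0(s$rxn, ".", s$dir), "")
  slots
}

# Per-slot substrate/product sides (equations) and mapped alternatives.
slot_sides <- function(model, slot) {
  r <- model$reactions[[slot$rxn]]
  if (slot$dir == "f") list(sub = r$reactants, prod = r$products)
  else list(sub = r$products, prod = r$reactants)
}

slot_alternatives <- function(model, slot) {
  r <- model$reactions[[slot$rxn]]
  if (is.null(r$transitions)) return(NULL)
  if (slot$dir == "f") r$transitions
  else lapply(r$transitions, function(a) list(sub = a$prod, prod = a$sub))
}

#' Expand net/exchange fluxes to directed fluxes
#'
#' Forward flux = max(net, 0) + exchange; backward = max(-net, 0) + exchange
#' (reversible reactions only). Net fluxes of irreversible reactions are
#' clamped at zero here; feasibility is enforced by the fitter's penalty.
#'
#' @param model `flux_model`
#' @param net named net flux vector
#' @param exch named exchange flux vector (missing reactions = 0)
#' @return named vector over directed slots
#' @export
directed_fluxes <- function(model, net, exch = NULL) {
  slots <- directed_slots(model)
  v <- numeric(length(slots)); names(v) <- names(slots)
  for (i in seq_along(slots)) {
    s <- slots[[i]]
    nv <- net[[s$rxn]]
    if (is.null(nv) || is.na(nv)) nv <- 0
    ex <- if (!is.null(exch) && s$rxn %in% names(exch)) exch[[s$rxn]] else 0
    rev <- model$reactions[[s$rxn]]$reversible
    if (s$dir == "f") v[i] <- max(nv, 0) + (if (rev) ex else 0)
    else v[i] <- max(-nv, 0) + ex
  }
  v
}

#' Decompose a model into the EMU network needed for a set of targets
#'
#' @param model carbon-balanced `flux_model`
#' @param targets character vector of balanced metabolite ids whose full
#'   carbon skeleton MIDs are to be simulated
#' @return an `emu_network` with size-stratified blocks and assembly maps
#' @export
emu_network <- function(model, targets) {
  cc <- model$carbon_counts
  slots <- directed_slots(model)
  slot_names <- names(slots)
  n_slot <- length(slots)

  # production / consumption bookkeeping per metabolite
  cons <- list()   # met -> data.frame(slot_idx, coef)
  prod_slots <- list()  # met -> slot idx that produce it (from equations)
  for (i in seq_along(slots)) {
    sd <- slot_sides(model, slots[[i]])
    for (met in names(sd$sub)) {
      cons[[met]] <- rbind(cons[[met]], data.frame(slot = i, coef = sd$sub[[met]]))
    }
    for (met in names(sd$prod)) prod_slots[[met]] <- c(prod_slots[[met]], i)
  }

  for (tg in targets) {
    if (!(tg %in% model$balanced))
      stop("unreachable EMU: target metabolite '", tg, "' is not a balanced metabolite")
    if (is.na(cc[tg]))
      stop("unreachable EMU: no atom map defines the carbon skeleton of '", tg, "'")
  }

  node_terms <- list()
  pending <- lapply(targets, function(tg) list(met = tg, pos = seq_len(cc[[tg]])))
  while (length(pending) > 0) {
    nd <- pending[[1]]; pending <- pending[-1]
    key <- emu_key(nd$met, nd$pos)
    if (!is.null(node_terms[[key]])) next
    pslots <- prod_slots[[nd$met]]
    if (is.null(pslots))
      stop("unreachable EMU: balanced metabolite '", nd$met, "' has no producing reaction")
    terms <- list()
    for (i in pslots) {
      alts <- slot_alternatives(model, slots[[i]])
      if (is.null(alts))
        stop("metabolite '", nd$met, "' is produced by unmapped reaction '",
             slots[[i]]$rxn, "'; atom map required for EMU simulation")
      sd <- slot_sides(model, slots[[i]])
      stoich <- sd$prod[[nd$met]]
      w_alt <- stoich / length(alts)
      for (alt in alts) {
        pe <- NULL
        for (e in alt$prod) if (e$met == nd$met) { pe <- e; break }
        if (is.null(pe)) next  # alternative does not produce this metabolite
        src_met <- character(length(nd$pos)); src_pos <- integer(length(nd$pos))
        unlab <- 0
        for (k in seq_along(nd$pos)) {
          letter <- pe$atoms[nd$pos[k]]
          found <- FALSE
          for (se in alt$sub) {
            q <- match(letter, se$atoms)
            if (!is.na(q)) { src_met[k] <- se$met; src_pos[k] <- q; found <- TRUE; break }
          }
          if (!found) {
            if (length(alt$sub) == 0) { src_met[k] <- ".unlabeled"; unlab <- unlab + 1 }
            else stop("carbon imbalance in reaction '", slots[[i]]$rxn,
                      "': product atom '", letter, "' of ", nd$met, " has no source")
          }
        }
        parts <- list()
        for (sm in unique(src_met)) {
          pos_k <- sort(src_pos[src_met == sm])
          if (sm == ".unlabeled") {
            parts[[length(parts) + 1]] <- list(type = "unlabeled",
                                               n = sum(src_met == sm))
          } else if (sm %in% model$balanced) {
            parts[[length(parts) + 1]] <- list(type = "emu", met = sm, pos = pos_k)
            pending[[length(pending) + 1]] <- list(met = sm, pos = pos_k)
          } else {
            parts[[length(parts) + 1]] <- list(type = "ext", met = sm, pos = pos_k)
          }
        }
        terms[[length(terms) + 1]] <- list(slot = i, w = w_alt, parts = parts)
      }
    }
    node_terms[[key]] <- list(met = nd$met, pos = nd$pos, size = length(nd$pos),
                              terms = terms)
  }

  # deterministic ordering: (size, metabolite, positions)
  keys <- names(node_terms)
  ord <- order(vapply(node_terms, `[[`, 0L, "size"),
               vapply(node_terms, `[[`, "", "met"),
               keys)
  keys <- keys[ord]
  sizes <- vapply(node_terms[keys], `[[`, 0L, "size")

  blocks <- list()
  for (s in sort(unique(sizes))) {
    bkeys <- keys[sizes == s]
    idx <- stats::setNames(seq_along(bkeys), bkeys)
    a_row <- integer(0); a_col <- integer(0); a_slot <- integer(0); a_w <- numeric(0)
    b_row <- integer(0); b_col <- integer(0); b_slot <- integer(0); b_w <- numeric(0)
    inputs <- list(); input_idx <- integer(0)
    get_input <- function(ikey, parts) {
      k <- input_idx[ikey]
      if (!is.na(k)) return(k)
      inputs[[length(inputs) + 1]] <<- list(key = ikey, parts = parts)
      input_idx[ikey] <<- length(inputs)
      length(inputs)
    }
    for (key in bkeys) {
      nd <- node_terms[[key]]
      j <- idx[[key]]
      # diagonal: total consumption of the metabolite
      cm <- cons[[nd$met]]
      if (is.null(cm))
        stop("degenerate network: balanced metabolite '", nd$met, "' is never consumed")
      for (q in seq_len(nrow(cm))) {
        a_row <- c(a_row, j); a_col <- c(a_col, j)
        a_slot <- c(a_slot, cm$slot[q]); a_w <- c(a_w, -cm$coef[q])
      }
      for (tm in nd$terms) {
        if (length(tm$parts) == 1 && tm$parts[[1]]$type == "emu" &&
            length(tm$parts[[1]]$pos) == s) {
          i <- idx[[emu_key(tm$parts[[1]]$met, tm$parts[[1]]$pos)]]
          a_row <- c(a_row, j); a_col <- c(a_col, i)
          a_slot <- c(a_slot, tm$slot); a_w <- c(a_w, tm$w)
        } else {
          ikey <- paste(vapply(tm$parts, function(p)
            switch(p$type,
                   emu = emu_key(p$met, p$pos),
                   ext = paste0("ext.", emu_key(p$met, p$pos)),
                   unlabeled = paste0("u", p$n)), ""), collapse = "|")
          k <- get_input(ikey, tm$parts)
          b_row <- c(b_row, j); b_col <- c(b_col, k)
          b_slot <- c(b_slot, tm$slot); b_w <- c(b_w, tm$w)
        }
      }
    }
    # aggregate duplicate cells into dense flux->value maps
    pack <- function(row, col, slot, w, ncolmax) {
      if (length(row) == 0)
        return(list(cells = cbind(integer(0), integer(0)),
                    map = matrix(0, 0, n_slot)))
      cell_id <- paste(row, col)
      u <- !duplicated(cell_id)
      cells <- cbind(row[u], col[u])
      map <- matrix(0, sum(u), n_slot)
      ui <- match(cell_id, cell_id[u])
      for (q in seq_along(row)) map[ui[q], slot[q]] <- map[ui[q], slot[q]] + w[q]
      list(cells = cells, map = map)
    }
    blocks[[length(blocks) + 1]] <- list(
      size = s, keys = bkeys, n = length(bkeys),
      A = pack(a_row, a_col, a_slot, a_w),
      B = pack(b_row, b_col, b_slot, b_w),
      inputs = inputs)
  }

  # (block, row) location of every node, for fast cross-references
  loc <- list()
  for (bi in seq_along(blocks))
    for (j in seq_along(blocks[[bi]]$keys))
      loc[[blocks[[bi]]$keys[j]]] <- c(bi, j)
  for (bi in seq_along(blocks)) {
    blocks[[bi]]$input_emu_loc <- lapply(blocks[[bi]]$inputs, function(inp) {
      refs <- list()
      for (p in inp$parts) if (p$type == "emu")
        refs[[length(refs) + 1]] <- loc[[emu_key(p$met, p$pos)]]
      refs
    })
  }
  target_keys <- stats::setNames(
    vapply(targets, function(tg) emu_key(tg, seq_len(cc[[tg]])), ""), targets)
  target_loc <- lapply(target_keys, function(k) loc[[k]])

  # vectorized directed-flux expansion tables
  rxn_ids <- names(model$reactions)
  slot_rxn <- match(vapply(slots, `[[`, "", "rxn"), rxn_ids)
  slot_fwd <- vapply(slots, function(s) s$dir == "f", TRUE)
  slot_rev <- vapply(slots, function(s) model$reactions[[s$rxn]]$reversible, TRUE)

  structure(list(blocks = blocks, targets = targets,
                 target_keys = target_keys, target_loc = target_loc,
                 slot_names = slot_names, n_slot = n_slot,
                 slot_rxn = slot_rxn, slot_fwd = slot_fwd, slot_rev = slot_rev,
                 rxn_ids = rxn_ids, carbon_counts = cc),
            class = "emu_network")
}

# fast directed-flux expansion given full net/exch vectors in model order
dirflux_fast <- function(net, v, ex) {
  vr <- v[net$slot_rxn]
  er <- ex[net$slot_rxn]
  ifelse(net$slot_fwd,
         pmax(vr, 0) + ifelse(net$slot_rev, er, 0),
         pmax(-vr, 0) + er)
}

#' Number of EMU nodes in a network
#' @param net `emu_network`
#' @return integer
#' @export
emu_node_count <- function(net) sum(vapply(net$blocks, `[[`, 0L, "n"))

#' Define a tracer experiment
#'
#' @param substrate extracellular substrate metabolite id (e.g. `"SUC_ext"`)
#' @param mixture list of `list(pattern=, fraction=)` entries; `pattern` is a
#'   0/1 string over substrate carbons, e.g. `"0110"` for `[2,3-13C4]`
#' @param purity isotopic enrichment of each labeled position (default 0.99)
#' @return a `tracer_spec`
#' @export
tracer_spec <- function(substrate, mixture, purity = 0.99) {
  if (is.character(mixture)) mixture <- list(list(pattern = mixture, fraction = 1))
  fr <- vapply(mixture, `[[`, 0, "fraction")
  if (abs(sum(fr) - 1) > 1e-9) stop("tracer mixture mole fractions must sum to 1")
  n <- unique(vapply(mixture, function(m) nchar(m$pattern), 0L))
  if (length(n) != 1) stop("tracer patterns must share one length")
  structure(list(substrate = substrate, mixture = mixture, purity = purity,
                 n_carbon = n), class = "tracer_spec")
}

# MID of a tracer EMU over a set of substrate positions.
tracer_emu_mid <- function(tracer, pos) {
  out <- numeric(length(pos) + 1)
  for (m in tracer$mixture) {
    bits <- strsplit(m$pattern, "")[[1]]
    mid <- 1
    for (p in pos) {
      pr <- if (bits[p] == "1") c(1 - tracer$purity, tracer$purity) else c(1, 0)
      mid <- conv_mid(mid, pr)
    }
    out <- out + m$fraction * mid
  }
  out
}

#' Bind a tracer to an EMU network
#'
#' Pre-computes the fixed (tracer/unlabeled) boundary MIDs of every input so
#' repeated simulation only convolves the flux-dependent parts.
#'
#' @param net `emu_network`
#' @param tracer `tracer_spec`
#' @return bound-input structure consumed by [emu_simulate()]
#' @export
emu_bind_tracer <- function(net, tracer) {
  lapply(net$blocks, function(bl) {
    lapply(bl$inputs, function(inp) {
      fixed <- NULL
      for (p in inp$parts) {
        if (p$type == "unlabeled") fixed <- conv_mid(fixed, c(1, rep(0, p$n)))
        else if (p$type == "ext") {
          mid <- if (!is.null(tracer) && p$met == tracer$substrate)
            tracer_emu_mid(tracer, p$pos) else c(1, rep(0, length(p$pos)))
          fixed <- conv_mid(fixed, mid)
        }
      }
      fixed
    })
  })
}

# Shared-factorization forward simulation: the balance matrices depend only
# on the fluxes, so one inversion per size block serves all tracers.
emu_forward <- function(net, vdir, bound_list, strict = TRUE) {
  ntr <- length(bound_list)
  Xs <- vector("list", length(net$blocks))
  for (bi in seq_along(net$blocks)) {
    bl <- net$blocks[[bi]]
    A <- matrix(0, bl$n, bl$n)
    if (nrow(bl$A$cells) > 0) A[bl$A$cells] <- as.vector(bl$A$map %*% vdir)
    ni <- length(bl$inputs)
    B <- matrix(0, bl$n, ni)
    if (nrow(bl$B$cells) > 0) B[bl$B$cells] <- as.vector(bl$B$map %*% vdir)
    # zero-turnover pools (a shut-down branch): MID is irrelevant downstream
    # (all consumer fluxes are zero); treat as unlabeled. A pool consumed
    # without production is a genuine degeneracy.
    dg <- diag(A)
    dead <- abs(dg) < 1e-9
    if (any(dead)) {
      prodmag <- rowSums(abs(A)) - abs(dg) + rowSums(abs(B))
      for (j in which(dead)) { A[j, ] <- 0; A[j, j] <- 1; B[j, ] <- 0 }
    }
    if (strict) {
      live_orphan <- !dead & (rowSums(abs(A)) - abs(dg) + rowSums(abs(B))) < 1e-12
      if (any(live_orphan))
        stop("degenerate flux distribution: zero total influx to live EMU ",
             bl$keys[which(live_orphan)[1]])
    }
    M <- tryCatch(-solve(A, B),
                  error = function(e) stop("degenerate flux distribution: ",
                                           "singular EMU balance (size ", bl$size,
                                           "): ", conditionMessage(e)))
    Xs[[bi]] <- vector("list", ntr)
    for (k in seq_len(ntr)) {
      Y <- matrix(0, ni, bl$size + 1)
      fx <- bound_list[[k]][[bi]]
      refs <- bl$input_emu_loc
      for (i in seq_len(ni)) {
        mid <- fx[[i]]
        for (rf in refs[[i]]) mid <- conv_mid(mid, Xs[[rf[1]]][[k]][rf[2], ])
        Y[i, ] <- mid
      }
      X <- M %*% Y
      if (any(dead)) X[dead, ] <- rep(c(1, numeric(bl$size)), each = sum(dead))
      Xs[[bi]][[k]] <- X
    }
  }
  Xs
}

#' Simulate mass isotopomer distributions by the EMU cascade
#'
#' @param net `emu_network` from [emu_network()]
#' @param model the `flux_model` the network was built from
#' @param fluxes list with `net` (named net fluxes) and optional `exch`
#'   (named exchange fluxes, >= 0)
#' @param tracer `tracer_spec`, or NULL for an unlabeled feed
#' @param bound optional pre-bound inputs from [emu_bind_tracer()]
#' @param vdir optional pre-computed directed flux vector
#' @return named list of MID vectors (M+0 ... M+n), one per target
#' @export
emu_simulate <- function(net, model, fluxes, tracer = NULL, bound = NULL,
                         vdir = NULL) {
  if (is.null(vdir)) vdir <- directed_fluxes(model, fluxes$net, fluxes$exch)
  if (is.null(bound)) bound <- emu_bind_tracer(net, tracer)
  Xs <- emu_forward(net, vdir, list(bound))
  out <- lapply(net$target_loc, function(rf) Xs[[rf[1]]][[1]][rf[2], ])
  names(out) <- names(net$target_loc)
  out
}

#' Mean fractional enrichment of a MID
#' @param mid MID vector (M+0..M+n)
#' @return scalar in [0, 1]
#' @export
mean_enrichment <- function(mid) {
  n <- length(mid) - 1
  if (n == 0) return(0)
  sum(mid * (0:n)) / n
}
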