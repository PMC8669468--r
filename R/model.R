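EXT_SUFFIX <- "_ext"
COFACTOR_KEYS <- c("nadh_uqh2", "nadph", "atp")
REACTION_KINDS <- c("internal", "uptake", "secretion", "biomass_drain", "unlabeled_influx")

#' Parse a reaction equation string
#'
#' Equations use carbon-carrying metabolites only; cofactor turnover is carried
#' in dedicated columns of the model file. Syntax: `1 SUC -> 1 FUM`, with
#' coefficients optional (`A + B -> C`). An empty side is allowed for uptake
#' sources, biomass drains (`1 G6P ->`) and unlabeled influxes (`-> 1 MAL`).
#'
#' @param eq equation string
#' @return list with named numeric vectors `reactants` and `products`
#' @keywords internal
parse_equation <- function(eq) {
  parts <- strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(parts) > 2) stop("equation has more than one '->': ", eq)
  if (length(parts) == 1) {
    parts <- c(parts, "")
    if (!grepl("->", eq, fixed = TRUE)) stop("equation lacks '->': ", eq)
  }
  side <- function(s) {
    s <- trimws(s)
    if (s == "") return(stats::setNames(numeric(0), character(0)))
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      toks <- strsplit(tm, "\\s+")[[1]]
      if (length(toks) == 1) {
        coef <- 1; met <- toks[1]
      } else if (length(toks) == 2) {
        coef <- suppressWarnings(as.numeric(toks[1]))
        if (is.na(coef)) stop("bad stoichiometric coefficient in term '", tm, "'")
        met <- toks[2]
      } else stop("cannot parse equation term '", tm, "'")
      if (coef <= 0) stop("stoichiometric coefficient must be > 0 in '", tm, "'")
      out[met] <- ifelse(is.na(out[met]), 0, out[met])[1] + coef
    }
    out
  }
  # handle leading '->' (influx) where strsplit gives empty first element
  lhs <- side(parts[1]); rhs <- side(parts[2])
  list(reactants = lhs, products = rhs)
}

#' Parse an atom-transition string
#'
#' Syntax mirrors the equation: `OAA:abcd + ACCOA:ef -> CIT:dcbfea`. Multiple
#' equally weighted alternatives (used for symmetric metabolites such as
#' succinate and fumarate) are separated by `;`:
#' `SUC:abcd -> FUM:abcd ; SUC:abcd -> FUM:dcba`. An empty substrate side
#' (`-> MAL:abcd`) marks an unlabeled source.
#'
#' @param s atom-map string (may be empty / NA for unmapped reactions)
#' @return list of alternatives; each is a list with `sub` and `prod`, lists of
#'   `(met, atoms)` entries; `NULL` when unmapped
#' @keywords internal
parse_atom_map <- function(s) {
  if (is.null(s) || is.na(s) || trimws(s) == "" || trimws(s) == ".") return(NULL)
  alts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  lapply(alts, function(a) {
    parts <- strsplit(a, "->", fixed = TRUE)[[1]]
    if (length(parts) == 1) parts <- c(parts, "")
    side <- function(x) {
      x <- trimws(x)
      if (x == "") return(list())
      terms <- trimws(strsplit(x, "+", fixed = TRUE)[[1]])
      lapply(terms, function(tm) {
        kv <- strsplit(tm, ":", fixed = TRUE)[[1]]
        if (length(kv) != 2) stop("cannot parse atom-map term '", tm, "'")
        list(met = trimws(kv[1]), atoms = strsplit(trimws(kv[2]), "")[[1]])
      })
    }
    list(sub = side(parts[1]), prod = side(parts[2]))
  })
}

format_atom_map <- function(tr) {
  if (is.null(tr)) return("")
  paste(vapply(tr, function(a) {
    f <- function(side) paste(vapply(side, function(e)
      paste0(e$met, ":", paste(e$atoms, collapse = "")), ""), collapse = " + ")
    paste(f(a$sub), "->", f(a$prod))
  }, ""), collapse = " ; ")
}

format_equation <- function(rxn) {
  f <- function(v) paste(sprintf("%g %s", unname(v), names(v)), collapse = " + ")
  paste(f(rxn$reactants), "->", f(rxn$products))
}

#' Load an atom-mapped metabolic network model
#'
#' Reads the line-oriented TSV model dialect: an optional leading comment line
#' `# {json metadata}` followed by a header
#' `id equation atom_map reversible kind pathway nadh_uqh2 nadph atp` and one
#' reaction per line. Metabolites whose id ends in `_ext` are extracellular and
#' excluded from steady-state balancing; all others are balanced.
#'
#' @param path path to a model TSV file
#' @return a `flux_model` object
#' @export
read_flux_model <- function(path) {
  if (!file.exists(path)) stop("model file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) == 0) stop("parse error at line 1: empty model file")
  meta <- list()
  line_offset <- 1  # header row
  if (startsWith(trimws(lines[1]), "#")) {
    line_offset <- 2
    js <- sub("^\\s*#\\s*", "", lines[1])
    meta <- tryCatch(jsonlite::fromJSON(js),
                     error = function(e) stop("parse error at line 1: bad JSON metadata header"))
    lines <- lines[-1]
  }
  if (length(lines) < 2) stop("parse error: model file has no reactions")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  required <- c("id", "equation", "atom_map", "reversible", "kind")
  if (!all(required %in% header))
    stop("parse error at line 1: header must contain ", paste(required, collapse = ", "))
  extra <- setdiff(header, c(required, "pathway", COFACTOR_KEYS))
  if (length(extra) > 0) stop("unknown cofactor/column key: ", paste(extra, collapse = ", "))
  reactions <- list()
  for (i in seq_along(lines[-1])) {
    ln <- lines[i + 1]
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < length(header)) f <- c(f, rep("", length(header) - length(f)))
    row <- stats::setNames(as.list(f[seq_along(header)]), header)
    rxn <- tryCatch(
      make_reaction(
        id = row$id, equation = row$equation, atom_map = row$atom_map,
        reversible = row$reversible %in% c("1", "TRUE", "true", "yes"),
        kind = row$kind,
        pathway = if (!is.null(row$pathway) && nzchar(row$pathway)) row$pathway else "unassigned",
        cofactors = vapply(COFACTOR_KEYS, function(k) {
          v <- row[[k]]
          if (is.null(v) || !nzchar(v)) 0 else as.numeric(v)
        }, 0)),
      error = function(e) stop("parse error at line ", i + line_offset, " (", row$id, "): ",
                               conditionMessage(e)))
    reactions[[length(reactions) + 1]] <- rxn
  }
  build_flux_model(reactions, species_tag = meta$species %||% "unknown", meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a single reaction
#' @keywords internal
make_reaction <- function(id, equation, atom_map = "", reversible = FALSE,
                          kind = "internal", pathway = "unassigned",
                          cofactors = c(nadh_uqh2 = 0, nadph = 0, atp = 0)) {
  if (!kind %in% REACTION_KINDS)
    stop("unknown reaction kind '", kind, "'")
  eq <- parse_equation(equation)
  tr <- parse_atom_map(atom_map)
  if (kind == "unlabeled_influx") {
    if (length(eq$reactants) != 0 || length(eq$products) != 1)
      stop("unlabeled_influx reactions must have no reactants and exactly one product")
  }
  cf <- stats::setNames(rep(0, length(COFACTOR_KEYS)), COFACTOR_KEYS)
  cf[names(cofactors)] <- cofactors
  structure(list(id = id, reactants = eq$reactants, products = eq$products,
                 reversible = isTRUE(reversible), kind = kind, pathway = pathway,
                 cofactors = cf, transitions = tr),
            class = "flux_reaction")
}

#' Assemble a flux_model from a reaction list
#'
#' @param reactions list of `flux_reaction` objects (order preserved)
#' @param species_tag free-text species label
#' @param meta metadata list (JSON header of the model file)
#' @return `flux_model`
#' @export
build_flux_model <- function(reactions, species_tag = "unknown", meta = list()) {
  ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate reaction ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(reactions) <- ids
  mets <- unique(unlist(lapply(reactions, function(r) c(names(r$reactants), names(r$products)))))
  balanced <- setdiff(mets[!endsWith(mets, EXT_SUFFIX)], character(0))
  # carbon counts from atom maps
  cc <- integer(0)
  for (r in reactions) for (a in r$transitions) for (e in c(a$sub, a$prod)) {
    n <- length(e$atoms)
    old <- suppressWarnings(cc[e$met])
    if (length(old) == 1 && !is.na(old) && old != n)
      stop("inconsistent carbon count for ", e$met, " in reaction ", r$id)
    cc[e$met] <- n
  }
  m <- structure(list(reactions = reactions, species_tag = species_tag,
                      metabolites = mets, balanced = sort(balanced),
                      carbon_counts = cc, meta = meta),
                 class = "flux_model")
  m$S <- stoichiometric_matrix(m)
  m
}

#' Stoichiometric matrix over balanced metabolites
#'
#' @param model a `flux_model`
#' @return numeric matrix, rows = balanced metabolites, columns = reactions
#' @export
stoichiometric_matrix <- function(model) {
  S <- matrix(0, length(model$balanced), length(model$reactions),
              dimnames = list(model$balanced, names(model$reactions)))
  for (r in model$reactions) {
    for (met in names(r$reactants)) if (met %in% model$balanced)
      S[met, r$id] <- S[met, r$id] - r$reactants[[met]]
    for (met in names(r$products)) if (met %in% model$balanced)
      S[met, r$id] <- S[met, r$id] + r$products[[met]]
  }
  S
}

#' Write a model back to the TSV dialect
#'
#' `read_flux_model(write_flux_model(m, f))` reproduces `m` field by field.
#'
#' @param model a `flux_model`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_flux_model <- function(model, path) {
  meta <- model$meta
  meta$species <- model$species_tag
  hdr <- paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE))
  cols <- c("id", "equation", "atom_map", "reversible", "kind", "pathway", COFACTOR_KEYS)
  rows <- vapply(model$reactions, function(r) {
    paste(c(r$id, format_equation(r), format_atom_map(r$transitions),
            as.integer(r$reversible), r$kind, r$pathway,
            sprintf("%g", r$cofactors)), collapse = "\t")
  }, "")
  writeLines(c(hdr, paste(cols, collapse = "\t"), rows), path)
  invisible(path)
}

#' Diagnose model invariant violations
#'
#' Reports (rather than throws) carbon-imbalanced atom maps, balanced
#' metabolites that are never produced (orphans) or never consumed
#' (dead ends), and malformed influx reactions. An empty report means the
#' model passes all structural invariants.
#'
#' @param model a `flux_model`
#' @return data.frame with columns `type`, `subject`, `message`
#' @export
validate_flux_model <- function(model) {
  findings <- list()
  add <- function(type, subject, message)
    findings[[length(findings) + 1]] <<- data.frame(type = type, subject = subject,
                                                    message = message)
  for (r in model$reactions) {
    for (a in r$transitions) {
      sub_atoms <- unlist(lapply(a$sub, `[[`, "atoms"))
      prod_atoms <- unlist(lapply(a$prod, `[[`, "atoms"))
      if (anyDuplicated(sub_atoms) || anyDuplicated(prod_atoms))
        add("atom_label_duplicate", r$id, "atom labels must be unique within one side")
      if (length(a$sub) > 0 && length(a$prod) > 0 &&
          !identical(sort(sub_atoms), sort(prod_atoms)))
        add("carbon_imbalance", r$id,
            sprintf("substrate atoms {%s} != product atoms {%s}",
                    paste(sort(sub_atoms), collapse = ""),
                    paste(sort(prod_atoms), collapse = "")))
    }
    if (r$kind == "unlabeled_influx" &&
        (length(r$reactants) != 0 || length(r$products) != 1))
      add("bad_influx", r$id, "unlabeled_influx must have no reactants and one product")
  }
  produced <- consumed <- character(0)
  for (r in model$reactions) {
    produced <- c(produced, names(r$products))
    consumed <- c(consumed, names(r$reactants))
    if (r$reversible) { # reverse direction can also produce/consume
      produced <- c(produced, names(r$reactants))
      consumed <- c(consumed, names(r$products))
    }
  }
  for (met in model$balanced) {
    if (!(met %in% produced) && (met %in% consumed))
      add("orphan_metabolite", met, "balanced metabolite is consumed but never produced")
    if ((met %in% produced) && !(met %in% consumed))
      add("dead_end_metabolite", met, "balanced metabolite is produced but never consumed")
  }
  if (length(findings) == 0)
    return(data.frame(type = character(0), subject = character(0), message = character(0)))
  do.call(rbind, findings)
}

#' Free-flux parameterization of the steady-state constraint
#'
#' Solves the affine system `S v = 0` plus user-supplied equality constraints
#' (typically `uptake = 100`) by QR factorization with column pivoting. The
#' non-pivot columns become free fluxes; completing any free-flux assignment
#' satisfies all constraints exactly (up to floating point).
#'
#' @param model a `flux_model`
#' @param fixed named numeric vector of equality constraints on reaction fluxes,
#'   e.g. `c(SUC_UPT = 100)`
#' @return a `flux_basis` object with `free_reaction_ids`, `dependent_ids`, and
#'   a `complete` closure
#' @export
flux_basis <- function(model, fixed = NULL) {
  S <- model$S
  rxn_ids <- colnames(S)
  A <- S
  b <- rep(0, nrow(S))
  if (length(fixed) > 0) {
    if (!all(names(fixed) %in% rxn_ids))
      stop("fixed constraint on unknown reaction: ",
           paste(setdiff(names(fixed), rxn_ids), collapse = ", "))
    for (nm in names(fixed)) {
      row <- rep(0, ncol(S)); names(row) <- rxn_ids; row[nm] <- 1
      A <- rbind(A, row); b <- c(b, fixed[[nm]])
    }
  }
  qa <- qr(A)
  r <- qa$rank
  piv <- qa$pivot
  dep <- rxn_ids[piv[seq_len(r)]]
  free <- rxn_ids[sort(piv[-seq_len(r)])]
  if (length(free) == 0 && r < length(rxn_ids)) free <- character(0)
  A_dep <- A[, dep, drop = FALSE]
  A_free <- A[, free, drop = FALSE]
  qa_dep <- qr(A_dep)
  # consistency check: constraints must be satisfiable at all
  v0 <- rep(0, length(free)); names(v0) <- free
  rhs0 <- b - as.vector(A_free %*% v0)
  sol0 <- qr.coef(qa_dep, rhs0)
  resid <- A_dep %*% sol0 - rhs0
  if (max(abs(resid)) > 1e-6 * max(1, max(abs(b))))
    stop("rank-deficiency inconsistency: no flux distribution satisfies the constraints")
  complete <- function(free_values) {
    if (!all(free %in% names(free_values)))
      stop("free flux values missing for: ",
           paste(setdiff(free, names(free_values)), collapse = ", "))
    u <- free_values[free]
    vd <- qr.coef(qa_dep, b - as.vector(A_free %*% u))
    v <- stats::setNames(rep(0, length(rxn_ids)), rxn_ids)
    v[dep] <- vd
    v[free] <- u
    v
  }
  structure(list(free_reaction_ids = free, dependent_ids = dep,
                 n_free = length(free), fixed = fixed, complete = complete,
                 rank = r, model_rxns = rxn_ids),
            class = "flux_basis")
}

#' Complete a free-flux assignment to a full steady-state flux vector
#'
#' @param basis a `flux_basis`
#' @param free_values named numeric vector over `basis$free_reaction_ids`
#' @return named flux vector over all reactions with `S v = 0` and all fixed
#'   constraints satisfied
#' @export
complete_fluxes <- function(basis, free_values) basis$complete(free_values)

#' Project a candidate flux vector onto the constraint manifold
#'
#' Returns the closest (least-squares) vector to `v0` satisfying `S v = 0`
#' plus the given equality constraints. Used to turn a hand-specified,
#' approximately balanced flux pattern into an exactly balanced one.
#'
#' @param model `flux_model`
#' @param v0 named numeric vector over all reactions (missing entries = 0)
#' @param fixed named equality constraints (as in [flux_basis()])
#' @return named flux vector
#' @export
project_fluxes <- function(model, v0, fixed = NULL) {
  rxn_ids <- names(model$reactions)
  x0 <- stats::setNames(rep(0, length(rxn_ids)), rxn_ids)
  x0[names(v0)] <- v0
  A <- model$S
  b <- rep(0, nrow(A))
  if (length(fixed) > 0) for (nm in names(fixed)) {
    row <- rep(0, ncol(A)); row[match(nm, rxn_ids)] <- 1
    A <- rbind(A, row); b <- c(b, fixed[[nm]])
  }
  # v = x0 - A^+ (A x0 - b), via SVD pseudo-inverse
  sv <- svd(A)
  tol <- max(dim(A)) * max(sv$d) * .Machine$double.eps
  pos <- sv$d > tol
  Ainv <- sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  v <- x0 - as.vector(Ainv %*% (A %*% x0 - b))
  stats::setNames(v, rxn_ids)
}

#' Check sign feasibility of a net flux vector
#'
#' @param model `flux_model`
#' @param v named net flux vector
#' @param tol tolerance below which small negatives are treated as zero
#' @return TRUE/FALSE
#' @export
is_feasible <- function(model, v, tol = 1e-8) {
  for (r in model$reactions) {
    if (!r$reversible && v[[r$id]] < -tol) return(FALSE)
  }
  TRUE
}

#' Summarize a model
#' @param x `flux_model`
#' @param ... unused
#' @export
print.flux_model <- function(x, ...) {
  cat("flux_model:", x$species_tag, "\n")
  cat("  reactions:", length(x$reactions),
      " balanced metabolites:", length(x$balanced), "\n")
  kinds <- table(vapply(x$reactions, `[[`, "", "kind"))
  cat("  kinds:", paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "), "\n")
  invisible(x)
}
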