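test_that("EMU decomposition keeps only the atoms the targets need", {
  m <- build_flux_model(list(
    make_reaction("u", "1 A_ext -> 1 A", "A_ext:ab -> A:ab", kind = "uptake"),
    make_reaction("r", "1 A -> 1 B", "A:ab -> B:ab"),
    make_reaction("d", "1 B ->", kind = "biomass_drain")))
  net <- emu_network(m, "B")
  expect_identical(emu_node_count(net), 2L)  # B[1,2] <- A[1,2]

  sp <- toy_model_split()
  net2 <- emu_network(sp, "B")  # A(abc) -> B(ab) + C(c); only A[1,2] needed
  keys <- unlist(lapply(net2$blocks, `[[`, "keys"))
  expect_true("A:1.2" %in% keys)
  expect_false(any(grepl("^A:1\\.2\\.3$", keys)))
  expect_false("A:3" %in% keys)
})

test_that("EMU node count matches an exhaustive closure oracle on the cycle toy", {
  m <- toy_model_cycle()
  net <- emu_network(m, c("CT", "KG", "OA"))
  # oracle: saturate the reachable-EMU set by repeated expansion over all
  # mapped reactions, tracking (metabolite, atom subset) pairs
  cc <- m$carbon_counts
  key <- function(met, pos) paste0(met, ":", paste(pos, collapse = "."))
  want <- c(key("CT", 1:4), key("KG", 1:3), key("OA", 1:2))
  seen <- character(0)
  queue <- want
  while (length(queue) > 0) {
    k <- queue[1]; queue <- queue[-1]
    if (k %in% seen) next
    seen <- c(seen, k)
    parts <- strsplit(k, ":")[[1]]
    met <- parts[1]; pos <- as.integer(strsplit(parts[2], ".", fixed = TRUE)[[1]])
    for (r in m$reactions) for (a in r$transitions) {
      sides <- list(a)
      if (r$reversible) sides <- c(sides, list(list(sub = a$prod, prod = a$sub)))
      for (s in sides) {
        pe <- Filter(function(e) e$met == met, s$prod)
        if (length(pe) == 0) next
        src <- lapply(pos, function(p) {
          letter <- pe[[1]]$atoms[p]
          for (se in s$sub) {
            q <- match(letter, se$atoms)
            if (!is.na(q)) return(c(se$met, q))
          }
          NULL
        })
        src <- Filter(Negate(is.null), src)
        if (length(src) == 0) next
        mets <- vapply(src, `[[`, "", 1)
        for (sm in unique(mets)) {
          if (!(sm %in% m$balanced)) next
          qs <- sort(as.integer(vapply(src[mets == sm], `[[`, "", 2)))
          queue <- c(queue, key(sm, qs))
        }
      }
    }
  }
  expect_identical(emu_node_count(net), length(seen))
})

test_that("label conservation: a pure fully-labeled tracer saturates every pool", {
  m <- toy_model_cycle()
  b <- flux_basis(m, c(upt = 100, oa_in = 0))
  v <- complete_fluxes(b, stats::setNames(rep(20, b$n_free), b$free_reaction_ids))
  net <- emu_network(m, c("CT", "KG", "OA"))
  tr <- tracer_spec("X_ext", "11", purity = 1)
  sim <- emu_simulate(net, m, list(net = v), tr)
  for (mid in sim) {
    expect_equal(sum(mid), 1, tolerance = 1e-9)
    expect_equal(mean_enrichment(mid), 1, tolerance = 1e-9)
  }
  # unlabeled feed leaves everything at M+0
  sim0 <- emu_simulate(net, m, list(net = v), tracer_spec("X_ext", "00", purity = 1))
  for (mid in sim0) expect_equal(mid[1], 1, tolerance = 1e-9)
})

test_that("positionally distinct tracers with two labels meet at M+2 in a pass-through pool", {
  m <- build_flux_model(list(
    make_reaction("u", "1 S_ext -> 1 P", "S_ext:abcd -> P:abcd", kind = "uptake"),
    make_reaction("d", "1 P ->", kind = "biomass_drain")))
  net <- emu_network(m, "P")
  tr <- tracer_spec("S_ext", list(list(pattern = "1001", fraction = 0.5),
                                  list(pattern = "0110", fraction = 0.5)),
                    purity = 1)
  sim <- emu_simulate(net, m, list(net = c(u = 10, d = 10)), tr)
  expect_equal(sim$P, c(0, 0, 1, 0, 0), tolerance = 1e-12)
})

test_that("EMU cascade matches exhaustive isotopomer enumeration on random feasible fluxes", {
  set.seed(2024)
  cases <- list(
    list(m = toy_model_linear(), tr = tracer_spec("SRC_ext", "10", 0.95),
         targets = c("B", "C"), fixed = c(upt = 100)),
    list(m = toy_model_branch(), tr = toy_tracer_branch(),
         targets = c("T", "P", "Q"), fixed = c(upt = 100)),
    list(m = toy_model_cycle(), tr = tracer_spec("X_ext", "10", 0.99),
         targets = c("CT", "KG", "OA"), fixed = c(upt = 100)))
  for (cs in cases) {
    net <- emu_network(cs$m, cs$targets)
    for (k in 1:8) {
      fl <- random_toy_fluxes(cs$m, cs$fixed)
      sim <- emu_simulate(net, cs$m, fl, cs$tr)
      ora <- simulate_isotopomers(cs$m, fl, cs$tr, targets = cs$targets)
      expect_lt(max(abs(unlist(sim) - unlist(ora[cs$targets]))), 1e-8)
    }
  }
})

test_that("an unlabeled influx monotonically raises M+0 in the fed pool and downstream", {
  m <- toy_model_cycle()
  net <- emu_network(m, c("CT", "KG", "OA"))
  tr <- tracer_spec("X_ext", "11", 0.99)
  b0 <- flux_basis(m, c(upt = 100, oa_in = 0))
  v0 <- complete_fluxes(b0, stats::setNames(rep(30, b0$n_free), b0$free_reaction_ids))
  b1 <- flux_basis(m, c(upt = 100, oa_in = 5))
  v1 <- complete_fluxes(b1, stats::setNames(rep(30, b1$n_free), b1$free_reaction_ids))
  s0 <- emu_simulate(net, m, list(net = v0), tr)
  s1 <- emu_simulate(net, m, list(net = v1), tr)
  for (met in c("OA", "CT", "KG")) {
    expect_gt(s1[[met]][1], s0[[met]][1])
    expect_lt(mean_enrichment(s1[[met]]), mean_enrichment(s0[[met]]))
  }
})

test_that("simulation errors name the degenerate pool when a live EMU has no influx", {
  m <- build_flux_model(list(
    make_reaction("u", "1 A_ext -> 1 A", "A_ext:ab -> A:ab", kind = "uptake"),
    make_reaction("r", "1 A -> 1 B", "A:ab -> B:ab"),
    make_reaction("r2", "1 C -> 1 B", "C:ab -> B:ab"),
    make_reaction("s", "1 B -> 1 C", "B:ab -> C:ab"),
    make_reaction("d", "1 B ->", kind = "biomass_drain")))
  net <- emu_network(m, "B")
  # r2/s cycle with r2 > s would need C produced from nothing; force via raw
  # directed fluxes on an infeasible assignment
  expect_error(
    emu_simulate(net, m, list(net = c(u = 0, r = 0, r2 = 5, s = 5, d = 0))),
    "degenerate")
})
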