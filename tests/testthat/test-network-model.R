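test_that("bundled species reconstructions load with the declared reaction counts", {
  pp <- read_flux_model(species_model_path("pputida"))
  ct <- read_flux_model(species_model_path("ctestosteroni"))
  expect_length(pp$reactions, 63)
  expect_length(ct$reactions, 51)
  expect_equal(names(pp$reactions)[1], "SUC_UPT")  # file order preserved
  expect_identical(nrow(validate_flux_model(pp)), 0L)
  expect_identical(nrow(validate_flux_model(ct)), 0L)
  # C. testosteroni lacks the oxidative PP and ED routes
  expect_false(any(c("ZWF", "GND", "EDD", "EDA") %in% names(ct$reactions)))
})

test_that("degenerate and malformed model files raise parse errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), f)
  expect_error(read_flux_model(f), "empty")
  writeLines(c("id\tequation\tatom_map\treversible\tkind\tbogus_col",
               "r1\t1 A -> 1 B\t\t0\tinternal\t1"), f)
  expect_error(read_flux_model(f), "unknown cofactor")
  writeLines(c("id\tequation\tatom_map\treversible\tkind",
               "r1\t1 A -> \t\t0\tunlabeled_influx"), f)
  expect_error(read_flux_model(f), "line 2")
})

test_that("write/read round trip reproduces a model field by field", {
  m <- build_flux_model(list(
    make_reaction("u", "1 A_ext -> 1 A", "A_ext:ab -> A:ab", kind = "uptake",
                  pathway = "transport"),
    make_reaction("r", "1 A -> 1 B", "A:ab -> B:ba", reversible = TRUE,
                  pathway = "core", cofactors = c(nadh_uqh2 = 1, atp = -0.5)),
    make_reaction("d", "1 B ->", kind = "biomass_drain", pathway = "biomass")),
    species_tag = "roundtrip toy", meta = list(substrate = "A"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_flux_model(m, f)
  m2 <- read_flux_model(f)
  expect_identical(names(m2$reactions), names(m$reactions))
  expect_identical(m2$species_tag, m$species_tag)
  for (id in names(m$reactions)) {
    expect_equal(m2$reactions[[id]]$reactants, m$reactions[[id]]$reactants)
    expect_equal(m2$reactions[[id]]$products, m$reactions[[id]]$products)
    expect_identical(m2$reactions[[id]]$reversible, m$reactions[[id]]$reversible)
    expect_identical(m2$reactions[[id]]$kind, m$reactions[[id]]$kind)
    expect_equal(m2$reactions[[id]]$cofactors, m$reactions[[id]]$cofactors)
    expect_equal(m2$reactions[[id]]$transitions, m$reactions[[id]]$transitions)
  }
  expect_equal(m2$S, m$S)
})

test_that("validation reports carbon imbalance and dead-end metabolites", {
  bal <- toy_model_linear()
  expect_identical(nrow(validate_flux_model(bal)), 0L)
  bad <- build_flux_model(list(
    make_reaction("u", "1 A_ext -> 1 A", "A_ext:abcd -> A:abcd", kind = "uptake"),
    make_reaction("r", "1 A -> 1 B", "A:abcd -> B:abc"),
    make_reaction("d", "1 B ->", kind = "biomass_drain")))
  rep <- validate_flux_model(bad)
  expect_true("carbon_imbalance" %in% rep$type)
  expect_true("r" %in% rep$subject[rep$type == "carbon_imbalance"])
  dead <- build_flux_model(list(
    make_reaction("u", "1 A_ext -> 1 A", "A_ext:ab -> A:ab", kind = "uptake"),
    make_reaction("r", "1 A -> 1 B", "A:ab -> B:ab"),
    make_reaction("r2", "1 A -> 1 C", "A:ab -> C:ab"),
    make_reaction("d", "1 B ->", kind = "biomass_drain")))
  rep2 <- validate_flux_model(dead)
  expect_true(any(rep2$type == "dead_end_metabolite" & rep2$subject == "C"))
})

test_that("free-flux dimension equals n_reactions - rank(S), per an independent oracle", {
  chain <- build_flux_model(list(
    make_reaction("u", "1 A_ext -> 1 A", "A_ext:ab -> A:ab", kind = "uptake"),
    make_reaction("r1", "1 A -> 1 B", "A:ab -> B:ab"),
    make_reaction("d", "1 B ->", kind = "biomass_drain")))
  expect_identical(flux_basis(chain)$n_free, 1L)

  branch <- toy_model_branch()
  bb <- flux_basis(branch)
  expect_equal(bb$n_free, length(branch$reactions) - rank_oracle(branch$S))

  pp <- read_flux_model(species_model_path("pputida"))
  expect_equal(flux_basis(pp)$n_free,
               length(pp$reactions) - rank_oracle(pp$S))
})

test_that("completion of any free-flux assignment satisfies the steady state exactly", {
  set.seed(101)
  for (m in list(toy_model_branch(), toy_model_cycle(),
                 read_flux_model(species_model_path("pputida")))) {
    up <- names(Filter(function(r) r$kind == "uptake", m$reactions))[1]
    b <- flux_basis(m, fixed = stats::setNames(100, up))
    for (k in 1:20) {
      u <- stats::setNames(stats::runif(b$n_free, -200, 200), b$free_reaction_ids)
      v <- complete_fluxes(b, u)
      expect_lt(max(abs(m$S %*% v)), 1e-9 * max(1, max(abs(v))))
      expect_equal(unname(v[up]), 100)
    }
  }
})

test_that("inconsistent equality constraints are rejected", {
  chain <- build_flux_model(list(
    make_reaction("u", "1 A_ext -> 1 A", "A_ext:ab -> A:ab", kind = "uptake"),
    make_reaction("r1", "1 A -> 1 B", "A:ab -> B:ab"),
    make_reaction("d", "1 B ->", kind = "biomass_drain")))
  expect_error(flux_basis(chain, fixed = c(u = 100, r1 = 50)),
               "inconsistency")
})

test_that("projection onto the constraint manifold is exact and minimal", {
  m <- toy_model_branch()
  v0 <- stats::setNames(rep(10, length(m$reactions)), names(m$reactions))
  v <- project_fluxes(m, v0, fixed = c(upt = 100))
  expect_lt(max(abs(m$S %*% v)), 1e-8)
  expect_equal(unname(v["upt"]), 100)
})
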