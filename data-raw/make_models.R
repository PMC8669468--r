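# Generates the bundled species model files under inst/extdata and sanity
# checks them (counts, validation, feasibility of the demo flux pattern).
for (f in list.files("R", full.names = TRUE)) source(f)

rxn <- function(id, eq, map = "", rev = FALSE, kind = "internal", pw = "unassigned",
                nadh = 0, nadph = 0, atp = 0)
  make_reaction(id, eq, map, rev, kind, pw,
                c(nadh_uqh2 = nadh, nadph = nadph, atp = atp))

core <- list(
  rxn("SUC_UPT", "1 SUC_ext -> 1 SUC",
      "SUC_ext:abcd -> SUC:abcd ; SUC_ext:abcd -> SUC:dcba",
      kind = "uptake", pw = "transport"),
  rxn("SDH", "1 SUC -> 1 FUM",
      "SUC:abcd -> FUM:abcd ; SUC:abcd -> FUM:dcba", pw = "TCA", nadh = 1),
  rxn("FUMH", "1 FUM -> 1 MAL",
      "FUM:abcd -> MAL:abcd ; FUM:abcd -> MAL:dcba", rev = TRUE, pw = "TCA"),
  rxn("MDH", "1 MAL -> 1 OAA", "MAL:abcd -> OAA:abcd", rev = TRUE, pw = "TCA",
      nadh = 1),
  rxn("CS", "1 OAA + 1 ACCOA -> 1 CIT", "OAA:abcd + ACCOA:ef -> CIT:dcbfea",
      pw = "TCA"),
  rxn("ACONTA", "1 CIT -> 1 ACO", "CIT:abcdef -> ACO:abcdef", pw = "TCA"),
  rxn("ACONTB", "1 ACO -> 1 ICIT", "ACO:abcdef -> ICIT:abcdef", pw = "TCA"),
  rxn("ICDH", "1 ICIT -> 1 AKG + 1 CO2", "ICIT:abcdef -> AKG:abcde + CO2:f",
      pw = "TCA", nadph = 1),
  rxn("AKGDH", "1 AKG -> 1 SUCCOA + 1 CO2", "AKG:abcde -> SUCCOA:bcde + CO2:a",
      pw = "TCA", nadh = 1),
  rxn("SUCOAS", "1 SUCCOA -> 1 SUC",
      "SUCCOA:abcd -> SUC:abcd ; SUCCOA:abcd -> SUC:dcba", pw = "TCA", atp = 1),
  rxn("ICL", "1 ICIT -> 1 GLX + 1 SUC",
      "ICIT:abcdef -> GLX:ab + SUC:cdef ; ICIT:abcdef -> GLX:ab + SUC:fedc",
      pw = "glyoxylate"),
  rxn("MALS", "1 GLX + 1 ACCOA -> 1 MAL", "GLX:ab + ACCOA:cd -> MAL:abdc",
      pw = "glyoxylate"),
  rxn("PCK", "1 OAA -> 1 PEP + 1 CO2", "OAA:abcd -> PEP:abc + CO2:d",
      pw = "anaplerosis", atp = -1),
  rxn("MAE", "1 MAL -> 1 PYR + 1 CO2", "MAL:abcd -> PYR:abc + CO2:d",
      pw = "anaplerosis", nadh = 1),
  rxn("PDH", "1 PYR -> 1 ACCOA + 1 CO2", "PYR:abc -> ACCOA:bc + CO2:a",
      pw = "EMP", nadh = 1),
  rxn("PYK", "1 PEP -> 1 PYR", "PEP:abc -> PYR:abc", pw = "EMP", atp = 1),
  rxn("ENO", "1 PEP -> 1 PG2", "PEP:abc -> PG2:abc", pw = "EMP"),
  rxn("PGM", "1 PG2 -> 1 PG3", "PG2:abc -> PG3:abc", pw = "EMP"),
  rxn("PGK", "1 PG3 -> 1 BPG", "PG3:abc -> BPG:abc", pw = "EMP", atp = -1),
  rxn("GAPDH", "1 BPG -> 1 GAP", "BPG:abc -> GAP:abc", pw = "EMP", nadh = -1),
  rxn("TPI", "1 GAP -> 1 DHAP", "GAP:abc -> DHAP:cba", pw = "EMP"),
  rxn("FBA", "1 DHAP + 1 GAP -> 1 FBP", "DHAP:abc + GAP:def -> FBP:abcdef",
      pw = "EMP"),
  rxn("FBP", "1 FBP -> 1 F6P", "FBP:abcdef -> F6P:abcdef", pw = "EMP"),
  rxn("PGI", "1 F6P -> 1 G6P", "F6P:abcdef -> G6P:abcdef", pw = "EMP"),
  rxn("RPI", "1 RU5P -> 1 R5P", "RU5P:abcde -> R5P:abcde", pw = "PP"),
  rxn("RPE", "1 X5P -> 1 RU5P", "X5P:abcde -> RU5P:abcde", pw = "PP"),
  rxn("TKT1", "1 S7P + 1 GAP -> 1 X5P + 1 R5P",
      "S7P:abfghij + GAP:cde -> X5P:abcde + R5P:fghij", pw = "PP"),
  rxn("TAL", "1 E4P + 1 F6P -> 1 S7P + 1 GAP",
      "E4P:defg + F6P:abchij -> S7P:abcdefg + GAP:hij", pw = "PP"),
  rxn("TKT2", "1 F6P + 1 GAP -> 1 X5P + 1 E4P",
      "F6P:abfghi + GAP:cde -> X5P:abcde + E4P:fghi", pw = "PP"),
  rxn("ASPTA", "1 OAA -> 1 ASP", "OAA:abcd -> ASP:abcd", pw = "anabolism"),
  rxn("GLUDH", "1 AKG -> 1 GLU", "AKG:abcde -> GLU:abcde", pw = "anabolism",
      nadph = -1),
  rxn("THD", "->", kind = "internal", pw = "transhydrogenase",
      nadh = -1, nadph = 1),
  rxn("CO2_EX", "1 CO2 -> 1 CO2_ext", "CO2:a -> CO2_ext:a", kind = "secretion",
      pw = "transport"),
  rxn("MAL_IN", "-> 1 MAL", "-> MAL:abcd", kind = "unlabeled_influx", pw = "influx"),
  rxn("PYR_IN", "-> 1 PYR", "-> PYR:abc", kind = "unlabeled_influx", pw = "influx"),
  rxn("G6P_IN", "-> 1 G6P", "-> G6P:abcdef", kind = "unlabeled_influx", pw = "influx"),
  rxn("DHAP_IN", "-> 1 DHAP", "-> DHAP:abc", kind = "unlabeled_influx", pw = "influx"),
  rxn("ACCOA_IN", "-> 1 ACCOA", "-> ACCOA:ab", kind = "unlabeled_influx", pw = "influx"))

drains <- lapply(c("G6P", "F6P", "R5P", "E4P", "GAP", "PG3", "PEP", "PYR",
                   "ACCOA", "OAA", "AKG", "ASP", "GLU"),
                 function(m) rxn(paste0("BM_", m), paste0("1 ", m, " ->"),
                                 kind = "biomass_drain", pw = "biomass"))

pputida_only <- list(
  rxn("PPC", "1 PEP + 1 CO2 -> 1 OAA", "PEP:abc + CO2:d -> OAA:abcd",
      pw = "anaplerosis"),
  rxn("PYC", "1 PYR + 1 CO2 -> 1 OAA", "PYR:abc + CO2:d -> OAA:abcd",
      pw = "anaplerosis", atp = -1),
  rxn("ODX", "1 OAA -> 1 PYR + 1 CO2", "OAA:abcd -> PYR:abc + CO2:d",
      pw = "anaplerosis"),
  rxn("PPS", "1 PYR -> 1 PEP", "PYR:abc -> PEP:abc", pw = "EMP", atp = -2),
  rxn("ZWF", "1 G6P -> 1 GL6P", "G6P:abcdef -> GL6P:abcdef", pw = "PP", nadph = 1),
  rxn("PGL", "1 GL6P -> 1 PG6", "GL6P:abcdef -> PG6:abcdef", pw = "PP"),
  rxn("GND", "1 PG6 -> 1 RU5P + 1 CO2", "PG6:abcdef -> RU5P:bcdef + CO2:a",
      pw = "PP", nadph = 1),
  rxn("EDD", "1 PG6 -> 1 KDPG", "PG6:abcdef -> KDPG:abcdef", pw = "ED"),
  rxn("EDA", "1 KDPG -> 1 PYR + 1 GAP", "KDPG:abcdef -> PYR:abc + GAP:def",
      pw = "ED"),
  rxn("ACK", "1 ACCOA -> 1 ACE", "ACCOA:ab -> ACE:ab", pw = "overflow", atp = 1),
  rxn("ACE_EX", "1 ACE -> 1 ACE_ext", "ACE:ab -> ACE_ext:ab", kind = "secretion",
      pw = "overflow"),
  rxn("PYR_EX", "1 PYR -> 1 PYR_ext", "PYR:abc -> PYR_ext:abc", kind = "secretion",
      pw = "overflow"))

pp <- build_flux_model(c(core, pputida_only, drains),
                       species_tag = "P. putida KT2440",
                       meta = list(
                         substrate = "succinate",
                         normalization = "substrate uptake = 100",
                         granularity = paste(
                           "curated central-carbon reconstruction; lumped steps:",
                           "GAPDH+phosphatase chain expanded to PGK/GAPDH,",
                           "aconitase split A/B; FADH2/ubiquinol lumped with NADH"),
                         note = "reconstruction from pathway topology, not a deposited model"))
ct <- build_flux_model(c(core, drains),
                       species_tag = "C. testosteroni KF-1",
                       meta = list(
                         substrate = "succinate",
                         normalization = "substrate uptake = 100",
                         granularity = paste(
                           "curated central-carbon reconstruction; no oxidative PP,",
                           "ED pathway, pyruvate carboxylase or PEP carboxylase",
                           "(genome-based absences); FADH2/ubiquinol lumped with NADH"),
                         note = "reconstruction from pathway topology, not a deposited model"))

cat("P. putida reactions:", length(pp$reactions), "\n")
cat("C. testosteroni reactions:", length(ct$reactions), "\n")
stopifnot(nrow(validate_flux_model(pp)) == 0)
stopifnot(nrow(validate_flux_model(ct)) == 0)

# --- demo flux pattern feasibility (P. putida, uptake = 100) ---------------
comp <- default_biomass_composition("pputida")
mu <- 0.55; q <- 9.5
dem <- biomass_efflux(mu, comp)
pct <- dem$rates / q * 100
fixed <- c(SUC_UPT = 100,
           setNames(as.numeric(pct), paste0("BM_", names(pct))),
           BM_ASP = 1.0, BM_GLU = 1.5, GLUDH = 1.5, ASPTA = 1.0,
           ICL = 0, PYC = 0, PPC = 0, PYK = 0, PPS = 0,
           ZWF = 0, EDD = 0, ACK = 0, PYR_EX = 0, THD = 0, ODX = 2,
           MAL_IN = 0, PYR_IN = 0, G6P_IN = 0, DHAP_IN = 0, ACCOA_IN = 0)
b <- flux_basis(pp, fixed)
cat("remaining free after demo constraints:", b$free_reaction_ids, "\n")
v <- complete_fluxes(b, setNames(rep(0, b$n_free), b$free_reaction_ids))
print(round(v[c("SDH","FUMH","MDH","CS","ICDH","AKGDH","MAE","PCK","ENO","PDH",
                "PGI","RPI","TKT1","TAL","TKT2","CO2_EX")], 2))
cat("feasible:", is_feasible(pp, v), "  S.v max:", max(abs(pp$S %*% v)), "\n")

write_flux_model(pp, "inst/extdata/pputida_kt2440_succinate.tsv")
write_flux_model(ct, "inst/extdata/ctestosteroni_kf1_succinate.tsv")
pp2 <- read_flux_model("inst/extdata/pputida_kt2440_succinate.tsv")
stopifnot(length(pp2$reactions) == length(pp$reactions))
cat("round trip ok\n")
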