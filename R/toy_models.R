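# Small constructed networks used for oracle cross-checks, confidence
# interval calibration and degenerate-input tests. All are built in code;
# total carbon content stays small enough for exhaustive isotopomer
# enumeration.

#' Linear chain toy network (6 balanced carbons)
#'
#' `SRC_ext -> A -> B -> C -> (drain)`, two carbons each; A -> B is
#' reversible (exercises exchange-flux expansion), B -> C flips the carbons.
#'
#' @return `flux_model`
#' @export
toy_model_linear <- function() {
  build_flux_model(list(
    make_reaction("upt", "1 SRC_ext -> 1 A", "SRC_ext:ab -> A:ab",
                  kind = "uptake", pathway = "uptake"),
    make_reaction("r1", "1 A -> 1 B", "A:ab -> B:ab", reversible = TRUE,
                  pathway = "chain"),
    make_reaction("r2", "1 B -> 1 C", "B:ab -> C:ba", pathway = "chain"),
    make_reaction("out", "1 C ->", kind = "biomass_drain", pathway = "chain")),
    species_tag = "toy_linear")
}

#' Branched split/recombination toy network (9 balanced carbons)
#'
#' A 3-carbon substrate S either passes directly to T or is cleaved into
#' P (2C) + Q (1C) which can recombine to T; P and Q also leak out, so the
#' cleavage and recombination fluxes are separate degrees of freedom. With
#' uptake fixed this model has exactly two free net fluxes, and a mixed
#' fully-labeled/unlabeled tracer makes the direct-vs-recombined split
#' identifiable from T's mass correlations.
#'
#' @return `flux_model`
#' @export
toy_model_branch <- function() {
  build_flux_model(list(
    make_reaction("upt", "1 S_ext -> 1 S", "S_ext:abc -> S:abc",
                  kind = "uptake", pathway = "uptake"),
    make_reaction("vA", "1 S -> 1 T", "S:abc -> T:abc", pathway = "direct"),
    make_reaction("vB", "1 S -> 1 P + 1 Q", "S:abc -> P:ab + Q:c",
                  pathway = "cleave"),
    make_reaction("vC", "1 P + 1 Q -> 1 T", "P:ab + Q:c -> T:abc",
                  pathway = "cleave"),
    make_reaction("vP", "1 P ->", kind = "biomass_drain", pathway = "leak"),
    make_reaction("vE", "1 Q ->", kind = "secretion", pathway = "leak"),
    make_reaction("outT", "1 T ->", kind = "biomass_drain", pathway = "direct")),
    species_tag = "toy_branch")
}

#' Condensed TCA-like cycle toy network (12 balanced carbons)
#'
#' A 2-carbon uptake condenses with a 2-carbon acceptor OA into CT (4C),
#' which is decarboxylated twice back to OA; OA turnover includes an
#' unlabeled influx and a drain, and the final decarboxylation scrambles the
#' acceptor orientation (symmetric-intermediate behaviour).
#'
#' @return `flux_model`
#' @export
toy_model_cycle <- function() {
  build_flux_model(list(
    make_reaction("upt", "1 X_ext -> 1 X", "X_ext:ab -> X:ab",
                  kind = "uptake", pathway = "uptake"),
    make_reaction("k1", "1 OA + 1 X -> 1 CT", "OA:ab + X:cd -> CT:adcb",
                  pathway = "cycle"),
    make_reaction("k2", "1 CT -> 1 KG + 1 C1", "CT:abcd -> KG:abc + C1:d",
                  pathway = "cycle"),
    make_reaction("k3", "1 KG -> 1 OA + 1 C1",
                  "KG:abc -> OA:bc + C1:a ; KG:abc -> OA:cb + C1:a",
                  pathway = "cycle"),
    make_reaction("oa_in", "-> 1 OA", "-> OA:ab", kind = "unlabeled_influx",
                  pathway = "influx"),
    make_reaction("oa_out", "1 OA ->", kind = "biomass_drain", pathway = "cycle"),
    make_reaction("co2_out", "1 C1 ->", kind = "secretion", pathway = "cycle")),
    species_tag = "toy_cycle")
}

#' Cleavage-only toy network (used for EMU minimality checks)
#' @return `flux_model`
#' @export
toy_model_split <- function() {
  build_flux_model(list(
    make_reaction("upt", "1 A_ext -> 1 A", "A_ext:abc -> A:abc",
                  kind = "uptake", pathway = "uptake"),
    make_reaction("cut", "1 A -> 1 B + 1 C", "A:abc -> B:ab + C:c",
                  pathway = "split"),
    make_reaction("outB", "1 B ->", kind = "biomass_drain", pathway = "split"),
    make_reaction("outC", "1 C ->", kind = "secretion", pathway = "split")),
    species_tag = "toy_split")
}
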