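#!/usr/bin/env Rscript
# Physiology and proteomics stages on their own: growth rate and uptake from
# the time series, carbon partitioning of uptake, differential protein
# abundance, and the adenylate energy charge.

library(emumfa)

dir.create("results", showWarnings = FALSE)
sc <- pputida_succinate_demo(seed = 7)
cfg <- sc$config

growth <- fit_growth(sc$physiology$od, window = c(cfg$lag + 0.5,
                                                  max(sc$physiology$od$time)))
print(growth)
uptake <- exchange_rates(sc$physiology$substrate, sc$physiology$cdw, growth$mu)
cat(sprintf("substrate uptake q = %.2f mmol/gCDW/h (R2 %.3f), yield %.3f gCDW/mmol\n",
            uptake$q, uptake$r2, uptake$yield))

demand <- biomass_efflux(growth$mu, default_biomass_composition(cfg$species))
part <- carbon_partition(uptake$q, 4, biomass_demand = demand)
cat(sprintf("carbon partition: biomass %.2f, secretion %.2f, other %.2f\n",
            part["biomass"], part["secretion"], part["other"]))
pw <- pathway_partition(demand)
cat("biosynthetic carbon by pathway:",
    paste(sprintf("%s %.2f", names(pw), pw), collapse = ", "), "\n")

res <- differential_proteins(sc$proteome$table, "succinate", "gluconate")
truth <- sc$proteome$truth
tr <- truth$differential[match(res$protein, truth$protein)]
cat(sprintf("proteome: %d/%d true shifts flagged, %.1f%% of nulls flagged\n",
            sum(res$significant[tr]), sum(tr),
            100 * mean(res$significant[!tr])))
utils::write.table(res, "results/proteome_differential.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

ec <- energy_charge(sc$pools["atp"], sc$pools["adp"], sc$pools["amp"])
cat(sprintf("adenylate energy charge: %.3f\n", ec))
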