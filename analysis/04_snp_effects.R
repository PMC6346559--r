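#!/usr/bin/env Rscript
# SNPs inside protospacer / PAM sequences: classify planted SNP-guide
# pairs, correlate guide LFC with genotype dose across cell lines against
# a permutation null, and compare PAM-proximal vs PAM-distal disruption.
# Writes results/04_snp_pairs.csv.

suppressMessages(library(screenaudit))
dir.create("results", showWarnings = FALSE)
seed <- 20260926L

scr <- make_fixture("snp_pam_like", seed = seed, n_cells = 100)
aud <- run_audit(scr, stages = "snp", B_permutations = 100, seed = seed + 1L)
st <- aud$snp_table
write.csv(st, "results/04_snp_pairs.csv", row.names = FALSE)

message("Mean genotype-LFC correlation by planted effect category:")
print(round(tapply(st$r, st$effect_category, mean), 3))

strat <- position_stratified_correlations(
  st[st$effect_category == "efficiency_loss", ])
message(sprintf(
  "PAM-proximal vs PAM-distal protospacer SNPs: mean r %.3f vs %.3f (rank-sum p = %.2g)",
  strat$proximal$mean, strat$distal$mean, strat$p_value))

message(sprintf(
  "Permutation calls: %d of %d pairs beyond the 95%% null quantile",
  sum(st$call_positive | st$call_negative, na.rm = TRUE), nrow(st)))
message("Minor alleles in the seed region or the PAM guanines abolish ",
        "cutting (positive genotype-LFC correlation: homozygous-minor ",
        "lines behave like NTCs); a minor allele matching the spacer at a ",
        "single-mismatch off-target turns it into a second on-target ",
        "(negative correlation: extra cutting).")
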