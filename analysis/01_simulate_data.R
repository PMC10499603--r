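#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# One reference locus around a CRISPR cut site; wild-type and Polq-null
# repair-product reads with truth tables; a 582-gene x 3-siRNA screen in
# three replicates with planted hits; a qPCR Ct table with a programmed
# mitotic end-joining deficit; and two BLI titration series with a
# programmed 65-fold affinity difference.

suppressMessages(library(mitorepair))
seed <- 20260930L
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

locus <- gen_reference_locus(length = 400, cut_fraction = 0.5, seed = seed)
write_locus_config(locus, file.path(out, "locus.cfg"))
cat(sprintf("locus: %d bp amplicon, cut at %d, %d planted repeat pairs\n",
            nchar(locus$amplicon), locus$cut_position,
            nrow(attr(locus, "repeat_pairs"))))

for (genotype in c("wt", "polq_ko")) {
  sim <- simulate_repair_reads(locus, repair_profile(genotype), n = 500,
                               seed = seed + match(genotype, c("wt", "polq_ko")))
  write_fasta(sim$reads, file.path(out, paste0("reads_", genotype, ".fasta")))
  utils::write.csv(sim$truth, file.path(out, paste0("truth_", genotype, ".csv")),
                   row.names = FALSE)
  cat(sprintf("%s: %d reads (%d truncated, %d with substitution noise)\n",
              genotype, length(sim$reads), sum(sim$truth$truncated),
              sum(sim$truth$noisy)))
}

wells <- simulate_plate(seed = seed)
utils::write.csv(wells, file.path(out, "screen_wells.csv"), row.names = FALSE)
utils::write.csv(attr(wells, "truth"), file.path(out, "screen_truth.csv"),
                 row.names = FALSE)
cat(sprintf("screen: %d wells, %d planted hit genes\n", nrow(wells),
            sum(attr(wells, "truth")$is_hit)))

qpcr <- simulate_qpcr(c(mitotic_wt = 1, mitotic_polq_ko = 0.25),
                      sd = 0.1, n = 6, seed = seed)
utils::write.csv(qpcr, file.path(out, "qpcr_ct.csv"), row.names = FALSE)

bli <- rbind(
  cbind(ligand = "4S_like", simulate_bli(650, 1.0, 2000 / 2^(0:6),
                                         0.01, seed = seed)),
  cbind(ligand = "4SP_like", simulate_bli(10, 1.0, 500 / 2^(0:6),
                                          0.01, seed = seed + 1L)))
utils::write.csv(bli, file.path(out, "bli_series.csv"), row.names = FALSE)
cat("wrote qPCR and BLI tables\n")
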