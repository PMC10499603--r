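#!/usr/bin/env Rscript
# Stage 3: validate the end-joining substrate design and quantify repair.
#
# Checks that the published duplex oligos segment as printed (17/69 and
# 15/71 nt), that the two 3' overhangs anneal through the designed 4-nt
# GCAG microhomology, and that the junction qPCR primers can only amplify
# the head-to-tail end-joining product. Then computes ddCt repair
# efficiencies from the simulated Ct table.

suppressMessages(library(mitorepair))
out <- "results/substrate"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ol <- ej_substrate_oligos()
d1 <- anneal_duplex(ol$oligo_1a, ol$oligo_1b)
d2 <- anneal_duplex(ol$oligo_2a, ol$oligo_2b)
print(d1); print(d2)
sub <- build_published_substrate()
print(sub)
ej <- predict_ej_product(sub, ol$fwd_qpcr_ej, ol$rev_qpcr_ej)
cat(sprintf("junction primers amplify the end-joining product: %s\n",
            ej$primers_valid))
cat(sprintf("junction primers amplify a single fragment: %s\n",
            mitorepair:::.amplifiable(sub$fragment_sense, ol$fwd_qpcr_ej,
                                      ol$rev_qpcr_ej)))

qpcr <- utils::read.csv("results/simulated/qpcr_ct.csv")
eff <- ddct_efficiency(qpcr, reference_condition = "mitotic_wt")
utils::write.csv(eff, file.path(out, "ddct_efficiency.csv"),
                 row.names = FALSE)
by_cond <- tapply(eff$efficiency, eff$condition, mean)
cat("\nmean relative end-joining efficiency by condition:\n")
print(round(by_cond, 3))
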