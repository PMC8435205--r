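#!/usr/bin/env Rscript
# Step 2 — morphometric dissimilarity analysis, both arms.
#
# Arm A estimates missing measurements first (Lleonart back-projection) and
# then size-corrects, filters, scales, ordinates and runs the Mantel test;
# arm B drops incomplete specimens instead, as a check that estimation does
# not manufacture structure. Artifacts go to results/morphospace/.

library(moonjelly)

seed <- 1
tm <- read_trait_csv("results/data/traits.csv")
cfg <- run_config(seed = seed)

imp <- run_morphospace(tm, cfg, "results/morphospace/with_estimation",
                       impute = TRUE)
cc <- run_morphospace(tm, cfg, "results/morphospace/without_estimation",
                      impute = FALSE)

cat(sprintf("arm A (with estimation): %d cells imputed, stress %.3f\n",
            imp$n_imputed, imp$ordination$stress))
cat(sprintf("  Mantel: r2 = %.3f, p = %.4f (B = %d, n = %d)\n",
            imp$mantel$r_squared, imp$mantel$p, imp$mantel$permutations,
            imp$mantel$n))
cat(sprintf("arm B (complete cases, n = %d): stress %.3f\n",
            nrow(cc$tm_final$values), cc$ordination$stress))
cat(sprintf("  Mantel: r2 = %.3f, p = %.4f\n",
            cc$mantel$r_squared, cc$mantel$p))
cat(sprintf("features removed: %s\n",
            paste(imp$removal_log$feature, collapse = ", ")))
cat("interpretation: a weak geographic signal is present by construction;\n")
cat("specimen scatter in the ordination still mixes localities broadly.\n")
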