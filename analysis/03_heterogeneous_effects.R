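#!/usr/bin/env Rscript
# Step 3: heterogeneous effects -- actor-matched trust moderation (each
# producer, endorser, and distributor dummy interacted with the
# respondent's 1-4 trust in that actor) and an Evangelical subgroup
# moderator for the religious-leader endorsement.
#
# Reads:  results/synthetic_conjoint.csv
# Writes: results/heterogeneous_trust.csv, results/heterogeneous_evangelical.csv

library(conjointvax)

d <- read_conjoint_data("results/synthetic_conjoint.csv",
                        catalog = build_catalog())

ft <- fit_heterogeneous(d, moderator = "trust")
write_results(ft, "results/heterogeneous_trust.csv", format = "csv")
tt <- tidy_fit(ft)
slope <- function(t) sprintf("%+.3f (se %.3f)",
                             tt$estimate[tt$term == t],
                             tt$se[tt$term == t])
cat("per-unit-of-trust changes in the effect:\n")
cat("  Pfizer x trust in USA:      ", slope("producer_pfizer_x_trust"), "\n")
cat("  Sinovac x trust in China:   ", slope("producer_sinovac_x_trust"), "\n")
cat("  President x trust in pres.: ", slope("endorser_president_x_trust"), "\n")
cat("  military x trust in armed forces:",
    slope("distributor_military_x_trust"), "\n")

d$evangelical <- as.numeric(d$religion == "evangelical")
fe <- fit_heterogeneous(d, moderator = "evangelical")
write_results(fe, "results/heterogeneous_evangelical.csv", format = "csv")
te <- tidy_fit(fe)
cat("religious-leader endorsement, Evangelical interaction:",
    sprintf("%+.3f (se %.3f)\n",
            te$estimate[te$term == "endorser_religious_leader_x_evangelical"],
            te$se[te$term == "endorser_religious_leader_x_evangelical"]))
cat("wrote heterogeneous-effect tables under results/\n")
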