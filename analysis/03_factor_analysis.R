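#!/usr/bin/env Rscript
# Stage 3: reduce the 22 call parameters to orthogonal factor scores.
#
# Applies the per-parameter symmetrizing transformations, checks sampling
# adequacy (Bartlett sphericity, KMO), extracts principal components of the
# correlation matrix with the eigenvalue > 1 rule, varimax-rotates, and
# computes regression-method scores. Subadult males are excluded here (they
# only appear in the descriptive tables). Writes results/factor_model.json
# and results/factor_scores.csv.

library(gibbonsong)

calls <- read.csv("results/call_features.csv", stringsAsFactors = FALSE)
modeled <- calls[calls$age_class %in% c("adult", "senior"), ]

# calls whose log-transformed parameters are degenerate (zero within-call
# variation of intervals) cannot be transformed; exclude and count
log_cols <- names(which(default_transforms() == "log"))
bad <- rep(FALSE, nrow(modeled))
for (nm in log_cols) bad <- bad | (!is.na(modeled[[nm]]) & modeled[[nm]] <= 0)
cat(sprintf("calls: %d measured, %d subadult excluded, %d degenerate excluded\n",
            nrow(calls), sum(!calls$age_class %in% c("adult", "senior")), sum(bad)))
modeled <- modeled[!bad, ]

tspec <- transform_spec(modeled)
trans <- apply_transforms(modeled, tspec)

fm <- fit_factor_model(trans, tspec)
dg <- fm$diagnostics
cat(sprintf("Bartlett chi2 = %.0f on %d df (p %s); KMO = %.3f\n",
            dg$bartlett_chi2, dg$bartlett_df,
            format.pval(dg$bartlett_p), dg$kmo))
cat(sprintf("%d factors with eigenvalue > 1, explaining %.1f%% of variance\n",
            fm$n_factors, sum(fm$variance_explained)))
cat(sprintf("calls dropped for missing parameters (1-element calls): %d\n",
            fm$n_dropped))

scores <- factor_scores(trans, fm)
out <- cbind(trans[, c("male_id", "song_id", "call_id", "recording_day",
                       "date", "time_days", "age_class", "status", "group_id")],
             scores)
out <- out[complete.cases(scores), ]

write_factor_model(fm, "results/factor_model.json", tspec)
write.csv(out, "results/factor_scores.csv", row.names = FALSE)
# the transformed parameters feed the discriminant stage
write.csv(trans, "results/call_features_transformed.csv", row.names = FALSE)
cat("wrote results/factor_model.json, results/factor_scores.csv\n")
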