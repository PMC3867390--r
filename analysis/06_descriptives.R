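#!/usr/bin/env Rscript
# Stage 6: descriptive acoustic statistics by age class.
#
# Median, quartiles and range of the measured element and call parameters in
# the three age classes (subadult, adult, senior) — the one place subadult
# males enter the analysis. Writes results/descriptives.csv.

library(gibbonsong)

calls <- read.csv("results/call_features.csv", stringsAsFactors = FALSE)
elements <- read.csv("results/elements_measured.csv", stringsAsFactors = FALSE)

d <- descriptive_by_age(elements, calls)
write.csv(d, "results/descriptives.csv", row.names = FALSE)

wide <- d[!d$parameter %in% c("counts", "call counts"), ]
cat("median (q1, q3) by age class:\n")
for (p in unique(wide$parameter)) {
  rows <- wide[wide$parameter == p, ]
  cat(sprintf("  %-24s %s\n", p, paste(sprintf(
    "%s %.2f (%.2f, %.2f)", substr(rows$age_class, 1, 3),
    rows$median, rows$q1, rows$q3), collapse = "  ")))
}
counts <- d[d$parameter %in% c("counts", "call counts"), ]
cat(sprintf("elements: %s | calls: %s\n",
            paste(counts$n[counts$parameter == "counts"], collapse = "/"),
            paste(counts$n[counts$parameter == "call counts"], collapse = "/")))
cat("wrote results/descriptives.csv\n")
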