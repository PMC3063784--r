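#!/usr/bin/env Rscript
# Normalize and expand both cohorts: per-sample z-scores over the 120 base
# proteins (each abundance becomes relative to the rest of the panel in the
# same sample), then all 7,140 pairwise-difference metafeatures, giving
# 7,260 columns. Metafeatures cancel the per-sample offset shared by their
# two members, which is what makes imbalance signal visible.

suppressMessages(library(metasig))

dir.create("results/expanded", recursive = TRUE, showWarnings = FALSE)

for (cohort in c("train", "test")) {
  raw <- read_panel(file.path("results/data", paste0(cohort, ".tsv")))
  ex <- expand_metafeatures(zscore_rows(raw))
  write_panel(ex, file.path("results/expanded", paste0(cohort, ".tsv")))
  cat(sprintf("%s: %d samples x %d columns (%d base + %d metafeatures)\n",
              cohort, nrow(ex$values), ncol(ex$values),
              sum(ex$provenance$kind == "base"),
              sum(ex$provenance$kind == "metafeature")))
}
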