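#!/usr/bin/env Rscript
# Diagnostic figures for the run: stacked signature-value profiles per
# cohort (good signatures push the case group visibly below the controls)
# and the per-sample classifier-disagreement histogram that drives the
# pruning decision.

suppressMessages(library(metasig))
suppressMessages(library(ggplot2))

dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)
design <- jsonlite::read_json("results/data/design.json",
                              simplifyVector = TRUE)
trace <- jsonlite::read_json("results/prune/trace.json",
                             simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)

train <- expand_metafeatures(zscore_rows(read_panel("results/data/train.tsv")))
test <- expand_metafeatures(zscore_rows(read_panel("results/data/test.tsv")))

s2 <- unlist(trace$iterations[[length(trace$iterations)]]$signature)
s3 <- unlist(trace$S3)

for (p in list(list("train", train), list("test", test))) {
  prof <- stacked_profile(p[[2L]], s2)
  ggsave(sprintf("results/figures/stacked_S2_%s.png", p[[1L]]),
         plot_stacked_profile(
           prof, sprintf("Stacked signature values (S2), %s cohort",
                         p[[1L]])),
         width = 9, height = 3.2, dpi = 150)
  prof3 <- stacked_profile(p[[2L]], s3)
  ggsave(sprintf("results/figures/stacked_S3_%s.png", p[[1L]]),
         plot_stacked_profile(
           prof3, sprintf("Stacked metafeature differences (S3), %s cohort",
                          p[[1L]])),
         width = 9, height = 3.2, dpi = 150)
}

members <- classifier_panel(25L)
s1 <- unlist(trace$iterations[[1L]]$signature)
r1 <- ensemble_fit_predict(train, signature = s1, members = members)
ggsave("results/figures/disagreement_iter1.png",
       plot_disagreement_histogram(r1, tau = 0.30),
       width = 7, height = 3.2, dpi = 150)

cat("figures written to results/figures\n")
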