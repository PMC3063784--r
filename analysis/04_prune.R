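#!/usr/bin/env Rscript
# The full iterative procedure: select a signature, classify the training
# cohort with the 25-member panel, remove training samples whose label is
# contradicted by more than 30% of the classifiers, and repeat until the
# panel is satisfied or the signature stabilizes. Produces the three
# comparison signatures: S1 (first iteration), S2 (after pruning), S3 (S2
# with single features stripped, metafeatures only), and their metric
# tables on the training and independent test cohorts.

suppressMessages(library(metasig))

dir.create("results/prune", recursive = TRUE, showWarnings = FALSE)
design <- jsonlite::read_json("results/data/design.json",
                              simplifyVector = TRUE)

train <- expand_metafeatures(zscore_rows(read_panel("results/data/train.tsv")))
test <- expand_metafeatures(zscore_rows(read_panel("results/data/test.tsv")))

pc <- prune_config(k = 10L, forced = design$single_markers, tau = 0.30,
                   members = classifier_panel(25L))
trace <- prune_run(train, list(test = test), config = pc)
print(trace)

planted_mis <- intersect(design$mislabelled, rownames(train$values))
cat("planted mislabelled in training cohort:",
    paste(planted_mis, collapse = ", "), "\n")
cat("removed by pruning:            ",
    paste(trace$removed_all, collapse = ", "), "\n")

s1 <- trace$iterations[[1L]]$signature
s2 <- trace$final_signature
s3 <- strip_single_features(s2, train$provenance)
cat("S3 (metafeatures of S2):", paste(s3$selected, collapse = ", "), "\n")

members <- classifier_panel(25L)
reports <- list(
  S1 = ensemble_fit_predict(train, list(test = test), s1, members),
  S2 = ensemble_fit_predict(train, list(test = test), s2, members),
  S3 = ensemble_fit_predict(train, list(test = test), s3, members))
tab <- metric_table(reports)
print(tab, digits = 3)
utils::write.table(tab, "results/prune/metric_table.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

jsonlite::write_json(
  list(stop_reason = trace$stop_reason,
       iterations = lapply(trace$iterations, function(it) list(
         n_train = length(it$train_ids),
         alpha = it$signature$alpha, beta = it$signature$beta,
         signature = it$signature$selected,
         disagreement = as.list(it$disagreement),
         removed = it$removed)),
       S3 = s3$selected),
  "results/prune/trace.json", auto_unbox = TRUE)
for (nm in names(reports))
  write_report(reports[[nm]], file.path("results/prune", nm))
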