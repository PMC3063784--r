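#!/usr/bin/env Rscript
# Simulate the study: a 120-protein plasma panel measured on a training
# cohort (43 cases / 40 controls) and an independent test cohort (42 / 39),
# with planted signal of both kinds — five singly discriminative proteins
# (standing in for a known published panel) and five protein pairs whose
# members are individually uninformative but whose difference separates the
# classes — plus a handful of mislabelled training samples emulating
# clinically uncertain diagnoses.
#
# Both cohorts are drawn as one generator call (so the planted protein
# identities coincide) and split afterwards.

suppressMessages(library(metasig))

seed <- 20260924L
out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(
  n_proteins = 120L,
  n_samples_per_class = c(85L, 79L),    # split below into 43/40 + 42/39
  n_single_markers = 5L, single_effect = 2,
  n_imbalance_pairs = 5L, imbalance_effect = 2,
  shared_noise_sd = 5, background_sd = 1,
  mislabel_fraction = 6 / 164,          # ~3 per cohort
  seed = seed)

ds <- generate_dataset(cfg)
write_dataset(ds, file.path(out_dir, "full"))

ids <- rownames(ds$panel$values)
case_ids <- ids[ds$true_labels == "case"]
ctrl_ids <- ids[ds$true_labels == "control"]
train_ids <- c(case_ids[1:43], ctrl_ids[1:40])
test_ids <- setdiff(ids, train_ids)

write_panel(panel_subset(ds$panel, samples = train_ids),
            file.path(out_dir, "train.tsv"))
write_panel(panel_subset(ds$panel, samples = test_ids),
            file.path(out_dir, "test.tsv"))
jsonlite::write_json(
  list(seed = seed,
       train_ids = train_ids, test_ids = test_ids,
       single_markers = ds$truth$single_markers,
       imbalance_pairs = apply(ds$truth$imbalance_pairs, 1L, paste,
                               collapse = "/"),
       planted_metafeatures = planted_metafeatures(ds),
       mislabelled = ds$truth$mislabelled),
  file.path(out_dir, "design.json"), auto_unbox = TRUE)

cat(sprintf("training cohort: %d samples; test cohort: %d samples\n",
            length(train_ids), length(test_ids)))
cat("planted single markers:",
    paste(ds$truth$single_markers, collapse = ", "), "\n")
cat("planted imbalance metafeatures:",
    paste(planted_metafeatures(ds), collapse = ", "), "\n")
cat("mislabelled training samples:",
    paste(intersect(ds$truth$mislabelled, train_ids), collapse = ", "),
    "\n")
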