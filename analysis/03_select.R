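#!/usr/bin/env Rscript
# First-pass feature selection on the training cohort: MDL entropy filter
# over all 7,260 columns, then exact (alpha,beta)-k-feature-set selection
# with k = 10 and the five planted single markers forced in — the analogue
# of forcing a known published panel and letting the optimizer complete it
# with complementary (meta)features.

suppressMessages(library(metasig))

dir.create("results/selection", recursive = TRUE, showWarnings = FALSE)
design <- jsonlite::read_json("results/data/design.json",
                              simplifyVector = TRUE)

raw <- read_panel("results/data/train.tsv")
train <- expand_metafeatures(zscore_rows(raw))

scheme <- filter_matrix(train)
prov <- train$provenance
passed <- names(scheme$passed)[scheme$passed]
passed_base <- intersect(passed, prov$name[prov$kind == "base"])
passed_meta <- setdiff(passed, passed_base)
base_in_meta <- unique(unlist(
  prov[prov$name %in% passed_meta, c("member1", "member2")]))
cat(sprintf("entropy filter: %d of %d columns pass\n",
            length(passed), length(scheme$passed)))
cat(sprintf("  %d of 120 proteins pass alone; %d appear in a passing metafeature\n",
            length(passed_base), length(base_in_meta)))

forced <- design$single_markers
sig <- select_signature(train, k = 10L, forced = forced)
cat(sprintf("alpha = %d, beta = %d, objective = %d (%s)\n",
            sig$alpha, sig$beta, sig$objective, sig$status))
cat("signature:", paste(sig$selected, collapse = ", "), "\n")
cat("planted metafeatures selected:",
    sum(design$planted_metafeatures %in% sig$selected), "of",
    length(design$planted_metafeatures), "\n")

jsonlite::write_json(
  list(k = sig$k, alpha = sig$alpha, beta = sig$beta,
       objective = sig$objective, status = sig$status,
       forced = sig$forced, selected = sig$selected,
       n_passed = length(passed)),
  "results/selection/signature_iter1.json", auto_unbox = TRUE)
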