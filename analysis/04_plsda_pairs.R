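#!/usr/bin/env Rscript
# Pairwise PLS-DA models for class pairs the one-class membership test
# cannot keep apart (overlapping light honeys), plus the dark-honey pairs
# the study resolved with 3-sample classes. Reports components used, R2Y,
# cross-validated Q2Y and training accuracy per pair.

suppressPackageStartupMessages(library(honeyprint))
dir.create("results", showWarnings = FALSE)

study <- if (file.exists("results/synthetic_study.csv")) {
  read_fingerprint_table("results/synthetic_study.csv")
} else {
  sample_study(default_study_spec(), seed = 42)
}
lib <- build_model_library(filter_groups_min_n(study, 3)$table)

pairs <- list(c("orange:Spain", "rosemary:Spain"),
              c("orange:Italy", "robinia:Hungary"),
              c("lavender:France", "lavender:Portugal"),
              c("chestnut:Italy", "chestnut:Spain"),
              c("robinia:Hungary", "robinia:Romania"))

rows <- lapply(pairs, function(pr) {
  m <- get_plsda(lib, pr[1], pr[2])
  keys <- class_keys(study)
  sub <- ft_rows(study, keys %in% pr)
  acc <- mean(predict_plsda(m, sub)$class == class_keys(sub))
  data.frame(class_0 = m$class_pair[1], class_1 = m$class_pair[2],
             N = m$N, K = m$K, A = m$A,
             panel = paste(m$panel_used, collapse = "+"),
             R2Y = m$r2y, Q2Y = m$q2y, training_accuracy = acc)
})
summ <- do.call(rbind, rows)
print(summ, digits = 3, row.names = FALSE)
write.csv(summ, "results/plsda_pairs.csv", row.names = FALSE)
cat("wrote results/plsda_pairs.csv\n")
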