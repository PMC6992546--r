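#!/usr/bin/env Rscript
# External validation of the label-verification cascade: a fresh draw of
# one honey per modelled class is tested against every one-class model,
# with pairwise PLS-DA contests wherever more than one class accepts a
# sample. Also reports the plain sensitivity/specificity of the one-class
# models on a full fresh study draw.

suppressPackageStartupMessages(library(honeyprint))
dir.create("results", showWarnings = FALSE)

train <- sample_study(default_study_spec(), seed = 42, min_n = 5)
lib <- build_model_library(train)

vspec <- default_study_spec()
vspec$classes <- lapply(vspec$classes, function(cl) { cl$n_default <- 1L; cl })
val <- sample_study(vspec, seed = 43)
vkeys <- class_keys(val)

rows <- lapply(names(lib$pca_models), function(key) {
  v <- verify_claim(ft_rows(val, which(vkeys == key)[1]), key, lib)
  data.frame(claimed_class = key, verdict = v$verdict,
             n_accepting_models = sum(v$memberships$member),
             n_contests = nrow(v$plsda_contests),
             reassigned_to = if (length(v$reassigned_to)) v$reassigned_to[1] else "")
})
verdicts <- do.call(rbind, rows)
print(verdicts, row.names = FALSE)
ok <- sum(verdicts$verdict %in% c("consistent", "consistent_resolved_by_plsda"))
cat(sprintf("\n%d of %d labelled samples verified as consistent.\n", ok, nrow(verdicts)))
write.csv(verdicts, "results/cascade_verdicts.csv", row.names = FALSE)

full_val <- sample_study(default_study_spec(), seed = 44, min_n = 5)
perf <- evaluate_performance(lib, full_val)
print(perf)
write.csv(data.frame(perf$counts,
                     specificity = perf$specificity[perf$counts$class_key],
                     sensitivity_overall = perf$sensitivity),
          "results/performance.csv", row.names = FALSE)
cat("wrote results/cascade_verdicts.csv, results/performance.csv\n")
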