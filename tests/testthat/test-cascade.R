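test_that("the default synthetic study yields eleven one-class models", {
  tab <- sample_study(default_study_spec(), seed = 42, min_n = 5)
  lib <- build_model_library(tab)
  expect_length(lib$pca_models, 11L)
  expect_setequal(names(lib$pca_models),
                  c("robinia:Hungary", "robinia:Italy", "orange:Italy",
                    "orange:Spain", "lavender:France", "lavender:Portugal",
                    "lavender:Spain", "rosemary:Spain", "lime:Romania",
                    "chestnut:Italy", "manuka:New Zealand"))
  for (m in lib$pca_models) {
    expect_gte(m$N, 5L)
    expect_lte(m$A, 4L)
    expect_true(all(m$r2x_per_component >= 0 & m$r2x_per_component <= 1))
    expect_lte(sum(m$r2x_per_component), 1 + 1e-8)
    expect_gt(m$s0, 0)
  }
})

test_that("small classes are excluded from PCA but available to PLS-DA", {
  tab <- sample_study(default_study_spec(), seed = 42)  # includes n=3 groups
  lib <- build_model_library(tab)
  expect_false("chestnut:Spain" %in% names(lib$pca_models))
  expect_true("chestnut:Spain" %in% lib$plsda_capable)
  m <- get_plsda(lib, "chestnut:Italy", "chestnut:Spain")
  expect_s3_class(m, "plsda_model")
  # cache returns the identical object, in either key order
  expect_identical(get_plsda(lib, "chestnut:Spain", "chestnut:Italy"), m)
})

test_that("the training-set outlier screen flags few samples on clean data", {
  tab <- sample_study(default_study_spec(), seed = 42, min_n = 5)
  lib <- build_model_library(tab)
  flagged <- sum(lengths(lib$training_outliers))
  expect_lte(flagged / nrow(tab$values), 0.10)
})

test_that("a sample accepted only by its own class is consistent without contests", {
  tab <- sample_study(disjoint_study_spec(), seed = 3)
  lib <- build_model_library(tab)
  v <- verify_claim(ft_rows(tab, 1), "alpha:X", lib)
  expect_identical(v$verdict, "consistent")
  expect_equal(nrow(v$plsda_contests), 0L)
})

test_that("rejection by the claimed model is terminal", {
  tab <- sample_study(disjoint_study_spec(), seed = 3)
  lib <- build_model_library(tab)
  # an alpha-class sample claimed as beta: the beta model rejects it
  v <- verify_claim(ft_rows(tab, 1), "beta:Y", lib)
  expect_identical(v$verdict, "inconsistent_rejected")
  expect_error(verify_claim(ft_rows(tab, 1), "gamma:Z", lib), "known classes")
})

test_that("class centroids verify as their own class when classes are resolvable", {
  tab <- sample_study(disjoint_study_spec(), seed = 4)
  lib <- build_model_library(tab)
  for (key in names(lib$pca_models)) {
    m <- lib$pca_models[[key]]
    vals <- matrix(NA_real_, 1, length(default_panel()),
                   dimnames = list(NULL, default_panel()))
    vals[1, m$panel_used] <- m$scaling$means
    s <- fingerprint_table(vals, "centroid", sub(":.*$", "", key),
                           sub("^.*?:", "", key))
    v <- verify_claim(s, key, lib)
    expect_true(v$verdict %in% c("consistent", "consistent_resolved_by_plsda"),
                label = paste("centroid verdict for", key))
  }
})

test_that("verdicts are deterministic for a frozen library", {
  tab <- sample_study(default_study_spec(), seed = 42, min_n = 5)
  lib <- build_model_library(tab)
  val <- sample_study(default_study_spec(), seed = 43, min_n = 5)
  v1 <- verify_claim(ft_rows(val, 1), class_keys(val)[1], lib)
  v2 <- verify_claim(ft_rows(val, 1), class_keys(val)[1], lib)
  expect_identical(v1$verdict, v2$verdict)
  expect_equal(v1$memberships, v2$memberships)
})

test_that("removing a competitor can only help a consistent claim", {
  tab <- sample_study(default_study_spec(), seed = 42, min_n = 5)
  lib <- build_model_library(tab)
  val <- sample_study(default_study_spec(), seed = 44, min_n = 5)
  keys <- class_keys(val)
  picked <- match(unique(keys), keys)[1:5]
  for (i in picked) {
    claim <- keys[i]
    v_full <- verify_claim(ft_rows(val, i), claim, lib)
    competitors <- setdiff(names(lib$pca_models), claim)
    lib_red <- lib
    lib_red$pca_models <- lib$pca_models[c(claim, competitors[1:5])]
    v_red <- verify_claim(ft_rows(val, i), claim, lib_red)
    if (v_full$verdict %in% c("consistent", "consistent_resolved_by_plsda")) {
      expect_true(v_red$verdict %in% c("consistent", "consistent_resolved_by_plsda"))
    }
    # own-model rejection does not depend on the competitor set at all
    if (v_full$verdict == "inconsistent_rejected") {
      expect_identical(v_red$verdict, "inconsistent_rejected")
    }
  }
})

test_that("well-separated classes verify perfectly across seeds", {
  ok <- vapply(1:20, function(s) {
    tab <- sample_study(disjoint_study_spec(), seed = s)
    lib <- build_model_library(tab)
    keys <- class_keys(tab)
    all(vapply(seq_along(keys), function(i) {
      verify_claim(ft_rows(tab, i), keys[i], lib)$verdict %in%
        c("consistent", "consistent_resolved_by_plsda")
    }, TRUE))
  }, TRUE)
  expect_true(all(ok))
})

test_that("a claim without a PCA model goes straight to discriminant contests", {
  tab <- sample_study(default_study_spec(), seed = 42)
  lib <- build_model_library(tab)
  val <- sample_study(default_study_spec(), seed = 45)
  i <- which(class_keys(val) == "chestnut:Spain")[1]
  v <- verify_claim(ft_rows(val, i), "chestnut:Spain", lib)
  expect_match(paste(v$evidence, collapse = " "), "own-model test skipped")
  expect_false(identical(v$verdict, "inconsistent_rejected"))
})

test_that("sensitivity and specificity are computed per their definitions", {
  tab <- sample_study(disjoint_study_spec(), seed = 6)
  lib <- build_model_library(tab)
  val <- sample_study(disjoint_study_spec(), seed = 7)
  perf <- evaluate_performance(lib, val)
  # recompute from the membership matrix the report carries
  truth <- class_keys(val)
  for (key in names(lib$pca_models)) {
    own <- truth == key
    expect_equal(perf$counts$tp[perf$counts$class_key == key],
                 sum(perf$membership[own, key]))
    expect_equal(unname(perf$specificity[key]),
                 sum(!perf$membership[!own, key]) / sum(!own))
  }
  expect_equal(perf$sensitivity,
               sum(perf$counts$tp) / (sum(perf$counts$tp) + sum(perf$counts$fn)))
  # disjoint classes: no non-member is ever accepted
  expect_true(all(perf$specificity == 1))
  expect_error(evaluate_performance(lib, sample_study(default_study_spec(), 8)),
               "no PCA model")
})
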