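# End-to-end label verification: one PCA model per eligible class, DModX
# membership against every model, and pairwise PLS-DA contests when more
# than one class accepts a sample.

#' Settings for a model library
#'
#' @param alpha DModX significance level (default 0.05, the 95% limit).
#' @param tau Loading-plot elimination threshold, see
#'   [select_variables_by_loadings()].
#' @param min_vars Minimum panel size kept by variable selection.
#' @param component_cap Default PCA components per class (study convention
#'   3).
#' @param component_overrides Named integer vector (class key -> components)
#'   for the classes modelled with 4 components.
#' @param plsda_components Components for pairwise PLS-DA models (default
#'   3).
#' @param plsda_overrides Named integer vector (unordered pair key
#'   `"a||b"`, keys sorted -> components) for hard pairs needing more.
#' @param min_n_pca Minimum class size for a one-class PCA model (default
#'   5).
#' @param min_n_plsda Minimum class size to take part in PLS-DA contests
#'   (default 3).
#' @param scaling Scaling method.
#' @param min_detect Minimum detected values per retained element.
#' @param autofit_pca Choose each PCA model's component count (up to its
#'   cap) by cross-validated Q2 instead of extracting the cap. Default
#'   FALSE: with 5-11 training samples the element-wise Q2 estimates are
#'   too unstable to drive component selection, so the caps are used as-is.
#' @param autofit_plsda Choose each pair model's component count (up to the
#'   cap) by cross-validated Q2Y (default TRUE); some pairs separate with a
#'   single component and further ones only fit noise.
#' @return A list of settings.
#' @export
library_settings <- function(alpha = 0.05, tau = 0.15, min_vars = 4L,
                             component_cap = 3L,
                             component_overrides = c("robinia:Hungary" = 4L,
                                                     "orange:Spain" = 4L,
                                                     "rosemary:Spain" = 4L),
                             plsda_components = 3L,
                             plsda_overrides = integer(),
                             min_n_pca = 5L, min_n_plsda = 3L,
                             scaling = "uv", min_detect = 3L,
                             autofit_pca = FALSE, autofit_plsda = TRUE) {
  list(alpha = alpha, tau = tau, min_vars = min_vars,
       autofit_pca = autofit_pca, autofit_plsda = autofit_plsda,
       component_cap = component_cap,
       component_overrides = component_overrides,
       plsda_components = plsda_components, plsda_overrides = plsda_overrides,
       min_n_pca = min_n_pca, min_n_plsda = min_n_plsda,
       scaling = scaling, min_detect = min_detect)
}

.pair_id <- function(key1, key2) paste(sort(c(key1, key2)), collapse = "||")

#' Build the per-class model library
#'
#' For every class with at least `min_n_pca` training samples: loading-plot
#' variable selection, a PCA fit at the class's component cap, and a
#' workset-mode DModX screen of the training set at `alpha`. Training
#' observations above the critical limit are reported as outliers but
#' retained (on the study's own data this screen flagged nobody, and
#' dropping them silently would hide that check). Pairwise PLS-DA models
#' are fitted lazily on demand and cached; classes down to `min_n_plsda`
#' rows take part in contests even without a PCA model of their own.
#'
#' @param table Training `fingerprint_table` with class labels.
#' @param settings See [library_settings()].
#' @return An object of class `model_library`.
#' @export
build_model_library <- function(table, settings = library_settings()) {
  stopifnot(inherits(table, "fingerprint_table"))
  keys <- class_keys(table)
  sizes <- table(keys)
  eligible <- names(sizes)[sizes >= settings$min_n_pca]
  if (length(eligible) == 0L) {
    stop("no class reaches min_n_pca = ", settings$min_n_pca)
  }
  pca_models <- list()
  outliers <- list()
  for (key in eligible) {
    sub <- ft_rows(table, keys == key)
    A <- settings$component_cap
    if (key %in% names(settings$component_overrides)) {
      A <- settings$component_overrides[[key]]
    }
    sel <- select_variables_by_loadings(sub, A = A, tau = settings$tau,
                                        min_vars = settings$min_vars,
                                        scaling = settings$scaling,
                                        min_detect = settings$min_detect)
    model <- sel$model
    if (isTRUE(settings$autofit_pca)) {
      model <- fit_pca_class(ft_elements(sub, sel$panel), A = A,
                             scaling = settings$scaling,
                             min_detect = settings$min_detect,
                             select = "q2")
    }
    screen <- dmodx(model, alpha = settings$alpha, mode = "workset")
    model$training_outliers <- screen$obs$sample_id[!screen$obs$member]
    pca_models[[key]] <- model
    outliers[[key]] <- model$training_outliers
  }
  plsda_capable <- names(sizes)[sizes >= settings$min_n_plsda]
  structure(list(pca_models = pca_models,
                 training_table = table,
                 plsda_cache = new.env(parent = emptyenv()),
                 plsda_capable = plsda_capable,
                 training_outliers = outliers,
                 settings = settings),
            class = "model_library")
}

#' @export
print.model_library <- function(x, ...) {
  cat("<model_library> ", length(x$pca_models), " PCA models; ",
      length(x$plsda_capable), " classes usable for PLS-DA\n", sep = "")
  for (m in x$pca_models) {
    cat(sprintf("  %-24s N=%2d K=%d A=%d R2X(cum)=%.3f Q2X(cum)=%6.3f\n",
                m$class_key, m$N, m$K, m$A, sum(m$r2x_per_component), m$q2_cum))
  }
  invisible(x)
}

#' Fetch (fitting and caching on first use) a pairwise PLS-DA model
#'
#' The pair's training data are the library's training rows of the two
#' classes; the variables are re-optimised on the pooled pair data via the
#' loading-plot procedure before the discriminant fit.
#'
#' @param library A `model_library`.
#' @param key1,key2 Class keys; the model codes `key1` as 0 and `key2` as 1
#'   internally, but the cache is per unordered pair.
#' @return A `plsda_model`.
#' @export
get_plsda <- function(library, key1, key2) {
  stopifnot(inherits(library, "model_library"))
  for (k in c(key1, key2)) {
    if (!k %in% library$plsda_capable) {
      stop("class ", k, " has fewer than min_n_plsda training rows")
    }
  }
  id <- .pair_id(key1, key2)
  if (!is.null(library$plsda_cache[[id]])) return(library$plsda_cache[[id]])
  st <- library$settings
  pair <- sort(c(key1, key2))
  keys <- class_keys(library$training_table)
  sub <- ft_rows(library$training_table, keys %in% pair)
  A <- st$plsda_components
  if (id %in% names(st$plsda_overrides)) A <- st$plsda_overrides[[id]]
  panel <- tryCatch(
    select_variables_by_loadings(sub, A = min(A, 3L), tau = st$tau,
                                 min_vars = st$min_vars,
                                 scaling = st$scaling,
                                 min_detect = st$min_detect)$panel,
    error = function(e) NULL)
  if (!is.null(panel)) sub <- ft_elements(sub, panel)
  model <- fit_plsda(sub, class_pair = pair, A = A,
                     select = if (isTRUE(st$autofit_plsda)) "q2" else "fixed",
                     min_detect = st$min_detect, scaling = st$scaling)
  library$plsda_cache[[id]] <- model
  model
}

#' Verify the label claim of one sample
#'
#' Step 1: prediction-mode DModX of the sample against every PCA model in
#' the library. Step 2: if the claimed class's model rejects the sample the
#' verdict is `inconsistent_rejected`; if only the claimed model accepts it,
#' `consistent`. Step 3: every other accepting class contests the claim
#' through the pairwise PLS-DA model (claim vs competitor): winning all
#' contests gives `consistent_resolved_by_plsda`; losing to exactly one
#' competitor gives `reassigned` (to that competitor); losses to several
#' competitors give `ambiguous`. A claimed class that has PLS-DA-capable
#' training rows but no PCA model (3 or 4 samples) skips the own-model test
#' and goes straight to the contests.
#'
#' @param sample A one-row `fingerprint_table` (or a larger table plus
#'   `sample_id`).
#' @param claim Class key stated on the label.
#' @param library A `model_library`.
#' @param sample_id Optional: pick one row of `sample` by id.
#' @return An object of class `cascade_verdict`.
#' @export
verify_claim <- function(sample, claim, library, sample_id = NULL) {
  stopifnot(inherits(sample, "fingerprint_table"),
            inherits(library, "model_library"))
  if (!is.null(sample_id)) sample <- ft_rows(sample, sample_id)
  if (nrow(sample$values) != 1L) stop("exactly one sample is required")
  known <- union(names(library$pca_models), library$plsda_capable)
  if (!claim %in% known) {
    stop("claim '", claim, "' unknown to the library; known classes: ",
         paste(sort(known), collapse = ", "))
  }
  alpha <- library$settings$alpha
  evidence <- character()
  memberships <- do.call(rbind, lapply(names(library$pca_models), function(key) {
    rep <- dmodx(library$pca_models[[key]], sample, alpha = alpha,
                 mode = "prediction")
    data.frame(class_key = key, dmodx = rep$obs$dmodx, dcrit = rep$dcrit,
               member = rep$obs$member, stringsAsFactors = FALSE)
  }))
  accepting <- memberships$class_key[memberships$member]
  claimed_has_pca <- claim %in% names(library$pca_models)

  contests <- data.frame(competitor = character(), predicted = character(),
                         score = numeric(), stringsAsFactors = FALSE)
  verdict <- NULL
  if (claimed_has_pca && !claim %in% accepting) {
    verdict <- "inconsistent_rejected"
    evidence <- c(evidence,
                  sprintf("claimed model %s rejects the sample (DModX %.3f > Dcrit %.3f)",
                          claim, memberships$dmodx[memberships$class_key == claim],
                          memberships$dcrit[memberships$class_key == claim]))
    if (length(setdiff(accepting, claim))) {
      evidence <- c(evidence, paste0("accepting competitor(s): ",
                                     paste(setdiff(accepting, claim), collapse = ", ")))
    }
  } else {
    if (claimed_has_pca) {
      evidence <- c(evidence, sprintf("claimed model %s accepts the sample", claim))
    } else {
      evidence <- c(evidence, sprintf(
        "no PCA model for claimed class %s (PLS-DA-only class); own-model test skipped",
        claim))
    }
    competitors <- setdiff(accepting, claim)
    competitors <- competitors[competitors %in% library$plsda_capable]
    if (length(competitors) == 0L) {
      verdict <- "consistent"
      evidence <- c(evidence, "no competing model accepts the sample")
    } else {
      lost_to <- character()
      for (comp in competitors) {
        m <- get_plsda(library, claim, comp)
        pred <- predict_plsda(m, sample)
        contests <- rbind(contests, data.frame(
          competitor = comp, predicted = pred$class, score = pred$score,
          stringsAsFactors = FALSE))
        evidence <- c(evidence, sprintf(
          "PLS-DA %s vs %s: predicted %s (score %.3f)",
          claim, comp, pred$class, pred$score))
        if (pred$class != claim) lost_to <- c(lost_to, comp)
      }
      verdict <- if (length(lost_to) == 0L) {
        "consistent_resolved_by_plsda"
      } else if (length(unique(lost_to)) == 1L) {
        evidence <- c(evidence, paste0("reassigned to ", lost_to[1]))
        "reassigned"
      } else {
        evidence <- c(evidence, paste0("conflicting winners: ",
                                       paste(unique(lost_to), collapse = ", ")))
        "ambiguous"
      }
    }
  }
  structure(list(sample_id = sample$meta$sample_id,
                 claimed_class = claim,
                 memberships = memberships,
                 plsda_contests = contests,
                 verdict = verdict,
                 reassigned_to = if (verdict == "reassigned")
                   unique(contests$predicted[contests$predicted != claim]) else NULL,
                 evidence = evidence),
            class = "cascade_verdict")
}

#' @export
print.cascade_verdict <- function(x, ...) {
  cat("<cascade_verdict> sample ", x$sample_id, ", claim ", x$claimed_class,
      " -> ", x$verdict, "\n", sep = "")
  for (e in x$evidence) cat("  - ", e, "\n", sep = "")
  invisible(x)
}

#' Sensitivity and specificity of the PCA model library
#'
#' Sensitivity is the fraction of validation samples accepted by the model
#' of their own (true) class; per-model specificity is the fraction of
#' validation samples from other classes that the model rejects. Both use
#' prediction-mode DModX at the library's `alpha`.
#'
#' @param library A `model_library`.
#' @param validation A `fingerprint_table` whose labels are taken as truth;
#'   every label must have a PCA model.
#' @return An object of class `performance_report` with fields
#'   `sensitivity`, `specificity` (named per model), and `counts` (data
#'   frame of TP/FN/TN/FP per model).
#' @export
evaluate_performance <- function(library, validation) {
  stopifnot(inherits(library, "model_library"),
            inherits(validation, "fingerprint_table"))
  if (nrow(validation$values) == 0L) stop("validation table is empty")
  truth <- class_keys(validation)
  missing <- setdiff(unique(truth), names(library$pca_models))
  if (length(missing)) {
    stop("no PCA model for label(s): ", paste(missing, collapse = ", "))
  }
  model_keys <- names(library$pca_models)
  member <- sapply(model_keys, function(key) {
    dmodx(library$pca_models[[key]], validation,
          alpha = library$settings$alpha, mode = "prediction")$obs$member
  })
  member <- matrix(member, nrow = nrow(validation$values),
                   dimnames = list(validation$meta$sample_id, model_keys))
  counts <- do.call(rbind, lapply(model_keys, function(key) {
    own <- truth == key
    data.frame(class_key = key,
               tp = sum(member[own, key]), fn = sum(!member[own, key]),
               tn = sum(!member[!own, key]), fp = sum(member[!own, key]),
               stringsAsFactors = FALSE)
  }))
  tp <- sum(counts$tp); fn <- sum(counts$fn)
  sensitivity <- tp / (tp + fn)
  specificity <- with(counts, ifelse(tn + fp > 0, tn / (tn + fp), NA_real_))
  names(specificity) <- counts$class_key
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 counts = counts, membership = member),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("<performance_report> sensitivity = ",
      sprintf("%.1f%%", 100 * x$sensitivity), "\n", sep = "")
  for (k in names(x$specificity)) {
    cat(sprintf("  %-24s specificity %5.1f%%\n", k, 100 * x$specificity[[k]]))
  }
  invisible(x)
}
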