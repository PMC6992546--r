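# Reproducibility evaluation: variance components from a days x replicates
# design, and pairwise two-sample t-tests between honeys per element. The
# ANOVA mean squares are computed closed-form here (they are the quantity
# this module exists for); stats::aov serves as the independent oracle in
# the test suite, and the t-tests delegate to stats::t.test.

#' A days-by-replicates measurement design
#'
#' @param measurements Numeric `D x J` matrix: `D` days (rows), `J`
#'   replicates per day (columns), in mg/kg. The study design is triplicate
#'   measurements on three different days (`3 x 3`, nine results per
#'   element and honey).
#' @param honey_id,element Identifiers carried along in results.
#' @return An object of class `replicate_design`.
#' @export
replicate_design <- function(measurements, honey_id = "honey", element = "element") {
  m <- as.matrix(measurements)
  storage.mode(m) <- "double"
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("design needs at least 2 days and 2 replicates per day")
  }
  if (anyNA(m)) stop("designs with missing cells are not supported")
  structure(list(honey_id = honey_id, element = element, measurements = m),
            class = "replicate_design")
}

#' Reproducibility from one-way ANOVA over days
#'
#' One-way ANOVA with day as the grouping factor:
#' `ms_between = J * sum_d (ybar_d - ybar)^2 / (D - 1)`,
#' `ms_within = sum_dj (y_dj - ybar_d)^2 / (D * (J - 1))`. The between-day
#' variance component is `(ms_between - ms_within) / J`, clamped at zero
#' when the day effect estimate is negative (the clamp is reported).
#' Reproducibility combines both components:
#' `s_R = sqrt(s_within^2 + s_days^2)`, expressed relative to the grand
#' mean as `rep_percent = 100 * s_R / grand_mean`.
#'
#' @param design A [replicate_design()].
#' @return An object of class `precision_result` with fields `grand_mean`,
#'   `ms_between`, `ms_within`, `s_within2`, `s_between_days2`, `clamped`,
#'   `s_reproducibility`, `rep_percent`.
#' @export
reproducibility_anova <- function(design) {
  stopifnot(inherits(design, "replicate_design"))
  m <- design$measurements
  D <- nrow(m); J <- ncol(m)
  grand <- mean(m)
  if (grand <= 0) stop("grand mean <= 0: relative reproducibility undefined")
  day_means <- rowMeans(m)
  ms_between <- J * sum((day_means - grand)^2) / (D - 1)
  ms_within <- sum((m - day_means)^2) / (D * (J - 1))
  s_within2 <- ms_within
  raw_between <- (ms_between - ms_within) / J
  clamped <- raw_between < 0
  s_between_days2 <- max(0, raw_between)
  s_r <- sqrt(s_within2 + s_between_days2)
  structure(list(honey_id = design$honey_id, element = design$element,
                 grand_mean = grand, ms_between = ms_between,
                 ms_within = ms_within, s_within2 = s_within2,
                 s_between_days2 = s_between_days2, clamped = clamped,
                 s_reproducibility = s_r,
                 rep_percent = 100 * s_r / grand),
            class = "precision_result")
}

#' @export
print.precision_result <- function(x, ...) {
  cat("<precision_result> ", x$honey_id, " / ", x$element,
      ": reproducibility ", sprintf("%.1f%%", x$rep_percent),
      if (x$clamped) " (between-day component clamped to 0)" else "",
      "\n", sep = "")
  invisible(x)
}

#' Pairwise per-element t-tests between honeys
#'
#' Two-sample t-tests (Welch by default; `pooled = TRUE` gives the
#' classical equal-variance Student test) for every element and every pair
#' of honeys, at significance `alpha`. An element detected in fewer than
#' two honeys is skipped entirely; a pair where one honey has fewer than
#' two detected values for the element is skipped with the cause recorded
#' (this mirrors elements that are simply not detected in some honey
#' types). No multiplicity correction is applied by default;
#' `p_adjust = "bonferroni"` (or any [stats::p.adjust()] method) is
#' available.
#'
#' @param tables Named list (honey id -> data frame or matrix with element
#'   columns) of measurement sets; `NA` marks non-detects.
#' @param alpha Significance level, default 0.05.
#' @param pooled Use the pooled-variance Student test instead of Welch.
#' @param p_adjust Multiplicity adjustment method, default `"none"`.
#' @return List with `results` (data frame: element, group1, group2,
#'   statistic, df, p_value, significant) and `skipped` (data frame:
#'   element, group1, group2, reason).
#' @export
pairwise_element_tests <- function(tables, alpha = 0.05, pooled = FALSE,
                                   p_adjust = "none") {
  if (!is.list(tables) || length(tables) < 2L || is.null(names(tables))) {
    stop("tables must be a named list of at least two measurement sets")
  }
  ids <- names(tables)
  tables <- lapply(tables, function(t) as.matrix(as.data.frame(t)))
  elements <- Reduce(union, lapply(tables, colnames))
  res <- list(); skip <- list()
  for (el in elements) {
    vals <- lapply(tables, function(t) {
      if (!el %in% colnames(t)) return(numeric())
      v <- t[, el]
      v[!is.na(v)]
    })
    have <- vapply(vals, function(v) length(v) >= 2L, TRUE)
    if (sum(have) < 2L) {
      reason <- if (any(have)) {
        paste0("detected in ", paste(ids[have], collapse = ", "), " only")
      } else "not detected in any honey"
      skip[[length(skip) + 1L]] <- data.frame(
        element = el, group1 = NA_character_, group2 = NA_character_,
        reason = reason, stringsAsFactors = FALSE)
      next
    }
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (j <= i) next
      if (!have[i] || !have[j]) {
        lacking <- ids[c(i, j)][!have[c(i, j)]]
        skip[[length(skip) + 1L]] <- data.frame(
          element = el, group1 = ids[i], group2 = ids[j],
          reason = paste0(el, " not detected in ",
                          paste(lacking, collapse = " and ")),
          stringsAsFactors = FALSE)
        next
      }
      tt <- stats::t.test(vals[[i]], vals[[j]], var.equal = pooled)
      res[[length(res) + 1L]] <- data.frame(
        element = el, group1 = ids[i], group2 = ids[j],
        statistic = unname(tt$statistic), df = unname(tt$parameter),
        p_value = tt$p.value, stringsAsFactors = FALSE)
    }
  }
  results <- if (length(res)) do.call(rbind, res) else
    data.frame(element = character(), group1 = character(),
               group2 = character(), statistic = numeric(), df = numeric(),
               p_value = numeric(), stringsAsFactors = FALSE)
  if (nrow(results)) {
    results$p_value <- stats::p.adjust(results$p_value, method = p_adjust)
    results$significant <- results$p_value < alpha
  } else {
    results$significant <- logical()
  }
  skipped <- if (length(skip)) do.call(rbind, skip) else
    data.frame(element = character(), group1 = character(),
               group2 = character(), reason = character(),
               stringsAsFactors = FALSE)
  list(results = results, skipped = skipped)
}
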