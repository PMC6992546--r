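#' Default element panel
#'
#' The ten elements quantifiable by ED-XRF in most mono-floral honeys, in
#' fixed panel order. All mass fractions handled by this package are in
#' mg element per kg honey (mg/kg).
#'
#' @return Character vector of element symbols.
#' @export
#' @examples
#' default_panel()
default_panel <- function() {
  c("Al", "P", "Cl", "K", "Ca", "Fe", "Zn", "Mn", "Rb", "Br")
}

#' Construct a fingerprint table
#'
#' A fingerprint table holds a samples-by-elements matrix of mass fractions
#' (mg/kg) together with per-sample botanical-variety and country labels and
#' a per-cell detection mask. Non-detects (below the limit of detection, or
#' simply not reported) carry no numeric value: they are stored as `NA` in
#' `values` with `detected = FALSE`, never as imputed zeros. Downstream
#' modelling decides how to treat them.
#'
#' @param values Numeric matrix, samples x elements. `NA` marks non-detects.
#' @param sample_id Character vector of unique sample identifiers.
#' @param botanical_variety,country Character vectors of class labels.
#' @param panel Element symbols naming the columns of `values`; defaults to
#'   `colnames(values)`.
#' @param detected Logical matrix of the same shape as `values`; defaults to
#'   `!is.na(values)`.
#' @param provenance Character vector of free-text processing notes.
#' @return An object of class `fingerprint_table`.
#' @export
fingerprint_table <- function(values, sample_id, botanical_variety, country,
                              panel = colnames(values),
                              detected = !is.na(values),
                              provenance = character()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(panel)) stop("an element panel is required (column names or `panel`)")
  panel <- as.character(panel)
  if (length(panel) < 1L) stop("panel must contain at least one element")
  if (anyDuplicated(panel)) stop("panel symbols must be unique")
  if (ncol(values) != length(panel)) {
    stop("values has ", ncol(values), " columns but the panel lists ",
         length(panel), " elements")
  }
  n <- nrow(values)
  sample_id <- as.character(sample_id)
  botanical_variety <- as.character(botanical_variety)
  country <- as.character(country)
  if (length(sample_id) != n || length(botanical_variety) != n ||
      length(country) != n) {
    stop("sample_id, botanical_variety and country must each have one entry per row")
  }
  if (anyDuplicated(sample_id)) {
    dup <- unique(sample_id[duplicated(sample_id)])
    stop("duplicate sample_id: ", paste(dup, collapse = ", "))
  }
  detected <- as.matrix(detected)
  if (!identical(dim(detected), dim(values))) {
    stop("detected mask must have the same shape as values")
  }
  values[!detected] <- NA_real_
  dimnames(values) <- list(sample_id, panel)
  dimnames(detected) <- list(sample_id, panel)
  structure(
    list(panel = panel, values = values, detected = detected,
         meta = data.frame(sample_id = sample_id,
                           botanical_variety = botanical_variety,
                           country = country,
                           stringsAsFactors = FALSE),
         provenance = as.character(provenance)),
    class = "fingerprint_table")
}

#' @export
print.fingerprint_table <- function(x, ...) {
  cat("<fingerprint_table> ", nrow(x$values), " samples x ",
      length(x$panel), " elements (mg/kg)\n", sep = "")
  cat("  panel: ", paste(x$panel, collapse = ", "), "\n", sep = "")
  keys <- table(class_keys(x))
  cat("  classes: ", paste(sprintf("%s (n=%d)", names(keys), as.integer(keys)),
                           collapse = "; "), "\n", sep = "")
  nd <- sum(!x$detected)
  cat("  non-detects: ", nd, " of ", length(x$detected), " cells\n", sep = "")
  if (length(x$provenance)) {
    cat("  provenance: ", paste(x$provenance, collapse = " | "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.fingerprint_table <- function(x, ...) {
  cbind(x$meta, as.data.frame(x$values, row.names = FALSE))
}

#' Class key of a botanical-variety / country combination
#'
#' Classes ("BV-C groups") are identified throughout the package by the
#' string `"<botanical_variety>:<country>"`.
#'
#' @param botanical_variety,country Character vectors, recycled together.
#' @return Character vector of class keys.
#' @export
class_key <- function(botanical_variety, country) {
  paste(botanical_variety, country, sep = ":")
}

#' Per-row class keys of a fingerprint table
#' @param table A `fingerprint_table`.
#' @return Character vector, one key per sample.
#' @export
class_keys <- function(table) {
  stopifnot(inherits(table, "fingerprint_table"))
  class_key(table$meta$botanical_variety, table$meta$country)
}

#' Subset rows of a fingerprint table
#' @param table A `fingerprint_table`.
#' @param i Row index (logical, integer or sample_id character).
#' @return A `fingerprint_table`.
#' @export
ft_rows <- function(table, i) {
  stopifnot(inherits(table, "fingerprint_table"))
  if (is.character(i)) i <- match(i, table$meta$sample_id)
  fingerprint_table(table$values[i, , drop = FALSE],
                    sample_id = table$meta$sample_id[i],
                    botanical_variety = table$meta$botanical_variety[i],
                    country = table$meta$country[i],
                    panel = table$panel,
                    detected = table$detected[i, , drop = FALSE],
                    provenance = table$provenance)
}

#' Restrict a fingerprint table to a sub-panel
#' @param table A `fingerprint_table`.
#' @param elements Element symbols to keep (order respected).
#' @return A `fingerprint_table`.
#' @export
ft_elements <- function(table, elements) {
  stopifnot(inherits(table, "fingerprint_table"))
  miss <- setdiff(elements, table$panel)
  if (length(miss)) stop("elements not in panel: ", paste(miss, collapse = ", "))
  j <- match(elements, table$panel)
  fingerprint_table(table$values[, j, drop = FALSE],
                    sample_id = table$meta$sample_id,
                    botanical_variety = table$meta$botanical_variety,
                    country = table$meta$country,
                    panel = elements,
                    detected = table$detected[, j, drop = FALSE],
                    provenance = table$provenance)
}

#' Concatenate fingerprint tables sharing a panel
#' @param ... `fingerprint_table` objects with identical panels.
#' @return A `fingerprint_table`.
#' @export
ft_bind <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]]) &&
      !inherits(tabs[[1]], "fingerprint_table")) tabs <- tabs[[1]]
  stopifnot(length(tabs) >= 1L)
  panel <- tabs[[1]]$panel
  for (t in tabs) {
    if (!identical(t$panel, panel)) stop("all tables must share the same panel")
  }
  fingerprint_table(do.call(rbind, lapply(tabs, `[[`, "values")),
                    sample_id = unlist(lapply(tabs, function(t) t$meta$sample_id)),
                    botanical_variety = unlist(lapply(tabs, function(t) t$meta$botanical_variety)),
                    country = unlist(lapply(tabs, function(t) t$meta$country)),
                    panel = panel,
                    detected = do.call(rbind, lapply(tabs, `[[`, "detected")),
                    provenance = unique(unlist(lapply(tabs, `[[`, "provenance"))))
}

#' Read a fingerprint table from delimited text
#'
#' Expects a header row naming `sample_id`, `botanical_variety`, `country`
#' and then the element columns of `panel`. Empty cells and the literal
#' `"n.d."` (any case, with or without trailing dot) are non-detects.
#'
#' @param path Path to the delimited file.
#' @param panel Element panel to read; defaults to [default_panel()].
#' @param sep Field separator, `","` (default) or `";"` for European exports.
#' @param dec Decimal mark, `"."` (default) or `","`.
#' @return A `fingerprint_table`.
#' @export
read_fingerprint_table <- function(path, panel = default_panel(),
                                   sep = ",", dec = ".") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE, fileEncoding = "UTF-8")
  mandatory <- c("sample_id", "botanical_variety", "country", panel)
  miss <- setdiff(mandatory, names(raw))
  if (length(miss)) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  n <- nrow(raw)
  vals <- matrix(NA_real_, n, length(panel), dimnames = list(NULL, panel))
  det <- matrix(FALSE, n, length(panel))
  for (j in seq_along(panel)) {
    cell <- raw[[panel[j]]]
    nd <- is.na(cell) | cell == "" | grepl("^n\\.?d\\.?$", cell, ignore.case = TRUE)
    txt <- cell[!nd]
    if (dec == ",") txt <- sub(",", ".", txt, fixed = TRUE)
    num <- suppressWarnings(as.numeric(txt))
    if (anyNA(num)) {
      bad <- which(!nd)[which(is.na(num))[1]]
      stop("non-numeric value '", cell[bad], "' in column ", panel[j],
           ", row ", bad)
    }
    vals[!nd, j] <- num
    det[, j] <- !nd
  }
  fingerprint_table(vals, sample_id = raw$sample_id,
                    botanical_variety = raw$botanical_variety,
                    country = raw$country, panel = panel, detected = det,
                    provenance = paste0("read from ", basename(path)))
}

#' Write a fingerprint table to delimited text
#'
#' Non-detects are written as `"n.d."`; a table written and re-read is
#' value-identical, including the detection mask.
#'
#' @param table A `fingerprint_table`.
#' @param path Output path.
#' @param sep Field separator.
#' @param dec Decimal mark.
#' @return `path`, invisibly.
#' @export
write_fingerprint_table <- function(table, path, sep = ",", dec = ".") {
  stopifnot(inherits(table, "fingerprint_table"))
  chr <- matrix("n.d.", nrow(table$values), ncol(table$values))
  ok <- table$detected
  txt <- format(table$values[ok], digits = 15, trim = TRUE, scientific = FALSE)
  if (dec == ",") txt <- sub(".", ",", txt, fixed = TRUE)
  chr[ok] <- txt
  out <- cbind(table$meta, as.data.frame(chr, stringsAsFactors = FALSE))
  names(out) <- c(names(table$meta), table$panel)
  utils::write.table(out, path, sep = sep, dec = dec, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Correction configuration for blank and recovery bias
#'
#' The polypropylene film at the bottom of the liquid sample holders
#' contributes blank signal for P, Ca and Zn; blank subtraction applies only
#' to the elements listed in `blank_means`. The factory quantification
#' application, optimised for oils and fuels, recovers on average 50% of the
#' true mass fraction on aqueous standards, so the default recovery factor
#' (measured/true) is 0.5 for every element, with per-element overrides.
#'
#' @param blank_means Named numeric vector of per-element blank offsets
#'   (mg/kg), all `>= 0`. Default names P, Ca, Zn.
#' @param recovery_factors Named numeric vector of dimensionless recoveries
#'   in (0, 2]. Empty means "0.5 for every element".
#' @return An object of class `correction_config`.
#' @export
correction_config <- function(blank_means = numeric(), recovery_factors = numeric()) {
  blank_means <- unlist(blank_means)
  recovery_factors <- unlist(recovery_factors)
  if (length(blank_means) && (is.null(names(blank_means)) || any(names(blank_means) == ""))) {
    stop("blank_means must be named by element")
  }
  if (any(blank_means < 0)) stop("blank_means must be >= 0")
  if (length(recovery_factors) && (is.null(names(recovery_factors)) || any(names(recovery_factors) == ""))) {
    stop("recovery_factors must be named by element")
  }
  if (any(recovery_factors <= 0) || any(recovery_factors > 2)) {
    stop("recovery_factors must lie in (0, 2]")
  }
  structure(list(blank_means = blank_means, recovery_factors = recovery_factors),
            class = "correction_config")
}

#' @rdname correction_config
#' @param path Path of a JSON document `{"blank_means": {...},
#'   "recovery_factors": {...}}`.
#' @export
read_correction_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  correction_config(blank_means = doc$blank_means,
                    recovery_factors = doc$recovery_factors)
}

#' @rdname correction_config
#' @param config A `correction_config`.
#' @export
write_correction_config <- function(config, path) {
  stopifnot(inherits(config, "correction_config"))
  jsonlite::write_json(list(blank_means = as.list(config$blank_means),
                            recovery_factors = as.list(config$recovery_factors)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Subtract film-blank offsets
#'
#' Subtracts the configured per-element blank means from the detected values
#' of the listed elements (all other elements and the detection mask are
#' untouched). Results are not clamped: subtraction of a blank from a sample
#' with a low mass fraction can yield a negative artefact, which is kept and
#' counted in the provenance so that reporting layers can flag it. Modelling
#' deliberately runs on uncorrected data, so this is a reporting path.
#'
#' @param table A `fingerprint_table`.
#' @param config A `correction_config` with non-empty `blank_means`.
#' @return A blank-corrected `fingerprint_table`.
#' @export
blank_correct <- function(table, config) {
  stopifnot(inherits(table, "fingerprint_table"),
            inherits(config, "correction_config"))
  bl <- config$blank_means
  bad <- setdiff(names(bl), table$panel)
  if (length(bad)) {
    stop("blank_means element(s) absent from panel: ", paste(bad, collapse = ", "))
  }
  vals <- table$values
  for (el in names(bl)) {
    j <- match(el, table$panel)
    vals[, j] <- vals[, j] - bl[[el]]
  }
  n_neg <- sum(vals < 0, na.rm = TRUE)
  note <- sprintf("blank-corrected (%s)%s",
                  paste(names(bl), collapse = ","),
                  if (n_neg > 0) sprintf("; %d negative artefact(s)", n_neg) else "")
  fingerprint_table(vals, sample_id = table$meta$sample_id,
                    botanical_variety = table$meta$botanical_variety,
                    country = table$meta$country, panel = table$panel,
                    detected = table$detected,
                    provenance = c(table$provenance, note))
}

#' Divide out the recovery bias
#'
#' Converts measured mass fractions to recovery-corrected ones by dividing
#' each element by its recovery factor (measured/true). Elements without an
#' explicit factor use the default 0.5.
#'
#' @param table A `fingerprint_table`.
#' @param config A `correction_config`; an empty `recovery_factors` applies
#'   the default 0.5 to every element.
#' @return A bias-corrected `fingerprint_table`.
#' @export
bias_correct <- function(table, config = correction_config()) {
  stopifnot(inherits(table, "fingerprint_table"),
            inherits(config, "correction_config"))
  rf <- config$recovery_factors
  bad <- setdiff(names(rf), table$panel)
  if (length(bad)) {
    stop("recovery_factors element(s) absent from panel: ", paste(bad, collapse = ", "))
  }
  factors <- rep(0.5, length(table$panel))
  names(factors) <- table$panel
  factors[names(rf)] <- rf
  vals <- sweep(table$values, 2L, factors, "/")
  fingerprint_table(vals, sample_id = table$meta$sample_id,
                    botanical_variety = table$meta$botanical_variety,
                    country = table$meta$country, panel = table$panel,
                    detected = table$detected,
                    provenance = c(table$provenance, "recovery-corrected"))
}

#' Keep only classes with enough samples
#'
#' One-class models are only built for botanical-variety / country groups
#' with at least `min_n` samples; smaller groups are dropped (they remain
#' usable for pairwise discriminant models, which tolerate n of 3).
#'
#' @param table A `fingerprint_table`.
#' @param min_n Minimum class size, `>= 1`. Default 5.
#' @return A list with elements `table` (the filtered `fingerprint_table`)
#'   and `summary` (a data frame of group sizes with a `kept` flag).
#' @export
filter_groups_min_n <- function(table, min_n = 5L) {
  stopifnot(inherits(table, "fingerprint_table"))
  if (!is.numeric(min_n) || length(min_n) != 1L || min_n < 1) {
    stop("min_n must be a single integer >= 1")
  }
  keys <- class_keys(table)
  sizes <- table(keys)
  summary <- data.frame(
    class_key = names(sizes),
    botanical_variety = sub(":.*$", "", names(sizes)),
    country = sub("^.*?:", "", names(sizes)),
    n = as.integer(sizes),
    kept = as.integer(sizes) >= min_n,
    stringsAsFactors = FALSE)
  keep <- keys %in% summary$class_key[summary$kept]
  list(table = ft_rows(table, keep), summary = summary)
}
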