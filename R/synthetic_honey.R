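# Published per-class element ranges (mg/kg) for the 17 botanical-variety /
# country groups, with the per-class sample size. Elements without a printed
# range are typically below the ~0.1 mg/kg detection limit in that class.
# "detect_n" records, for sporadically detected elements, in how many of the
# n samples the element was quantifiable.
.study_ranges <- function() {
  r <- function(lo, hi) c(lo, hi)
  list(
    list(bv = "robinia", country = "Hungary", n = 11L,
         ranges = list(Cl = r(51.2, 357.2), K = r(132.4, 313.9),
                       Ca = r(19.7, 126.9), Fe = r(1.5, 5.5), Zn = r(0.3, 2.4))),
    list(bv = "robinia", country = "Italy", n = 5L,
         ranges = list(Cl = r(36.1, 96.0), K = r(137.0, 380.6),
                       Ca = r(4.7, 17.2), Fe = r(1.4, 2.0), Zn = r(0.6, 1.3))),
    list(bv = "robinia", country = "Romania", n = 3L,
         ranges = list(Cl = r(65.4, 67.6), K = r(143.9, 160.3),
                       Ca = r(20.9, 37.6), Fe = r(2.1, 2.3), Zn = r(0.6, 1.1))),
    list(bv = "orange", country = "Italy", n = 6L,
         ranges = list(Cl = r(50.0, 286.3), K = r(137.3, 368.2),
                       Ca = r(25.9, 59.9), Fe = r(1.7, 3.4), Zn = r(0.4, 1.4),
                       Mn = r(1.8, 1.8)),
         detect_n = c(Mn = 1L)),
    list(bv = "orange", country = "Spain", n = 9L,
         ranges = list(Cl = r(49.5, 68.7), K = r(180.0, 271.6),
                       Ca = r(39.2, 65.5), Fe = r(1.9, 3.5), Zn = r(0.4, 1.6))),
    list(bv = "lavender", country = "France", n = 5L,
         ranges = list(Cl = r(62.6, 113.9), K = r(167.5, 287.9),
                       Ca = r(29.9, 46.6), Fe = r(1.7, 3.3), Zn = r(0.6, 0.9),
                       Mn = r(1.0, 1.0)),
         detect_n = c(Mn = 1L)),
    list(bv = "lavender", country = "Portugal", n = 6L,
         ranges = list(Cl = r(93.6, 117.0), K = r(202.6, 316.4),
                       Ca = r(19.5, 47.8), Fe = r(1.7, 2.2), Zn = r(0.5, 2.5),
                       Mn = r(1.6, 2.3), Rb = r(1.8, 1.8)),
         detect_n = c(Mn = 5L, Rb = 1L)),
    list(bv = "lavender", country = "Spain", n = 5L,
         ranges = list(Cl = r(88.9, 362.5), K = r(295.7, 1243.1),
                       Ca = r(20.6, 81.3), Fe = r(2.3, 6.3), Zn = r(0.8, 3.4),
                       Mn = r(1.1, 6.2)),
         detect_n = c(Mn = 3L)),
    list(bv = "rosemary", country = "Spain", n = 7L,
         ranges = list(Cl = r(34.3, 119.2), K = r(86.4, 183.8),
                       Ca = r(17.0, 83.7), Fe = r(1.4, 2.9), Zn = r(0.2, 1.0))),
    list(bv = "thyme", country = "Spain", n = 3L,
         ranges = list(Cl = r(128.8, 284.0), K = r(435.6, 599.0),
                       Ca = r(62.3, 111.5), Fe = r(3.1, 3.7), Zn = r(1.1, 1.7),
                       Mn = r(1.9, 1.9)),
         detect_n = c(Mn = 1L)),
    list(bv = "thyme", country = "New Zealand", n = 3L,
         ranges = list(Cl = r(48.1, 100.8), K = r(450.0, 553.8),
                       Ca = r(21.0, 62.9), Fe = r(1.9, 3.4), Zn = r(0.1, 0.7),
                       Mn = r(1.1, 2.5)),
         detect_n = c(Mn = 2L)),
    list(bv = "manuka", country = "New Zealand", n = 7L,
         ranges = list(Cl = r(180.1, 481.6), K = r(446.5, 1640.4),
                       Ca = r(31.5, 59.0), Fe = r(1.5, 3.5), Zn = r(1.0, 2.0),
                       Mn = r(1.6, 12.8), Rb = r(4.0, 6.0)),
         detect_n = c(Mn = 6L, Rb = 5L)),
    list(bv = "chestnut", country = "Italy", n = 5L,
         ranges = list(Cl = r(172.4, 575.7), K = r(1883.8, 3324.1),
                       Ca = r(101.0, 182.8), Fe = r(2.2, 3.6), Zn = r(0.8, 2.2),
                       Mn = r(1.9, 16.7), Rb = r(8.6, 22.0))),
    list(bv = "chestnut", country = "Spain", n = 3L,
         ranges = list(Cl = r(147.1, 273.5), K = r(1730.5, 3451.3),
                       Ca = r(92.3, 187.7), Fe = r(2.9, 5.8), Zn = r(0.8, 2.4),
                       Mn = r(4.3, 28.4), Rb = r(7.2, 16.14))),
    list(bv = "eucalyptus", country = "Spain", n = 3L,
         ranges = list(Cl = r(326.7, 443.6), K = r(408.1, 740.5),
                       Ca = r(92.9, 122.9), Fe = r(3.0, 5.8), Zn = r(1.13, 4.3),
                       Mn = r(3.8, 5.8), Rb = r(1.8, 6.6)),
         detect_n = c(Mn = 2L, Rb = 2L)),
    list(bv = "lime", country = "Romania", n = 5L,
         ranges = list(Cl = r(86.5, 217.7), K = r(193.0, 1034.9),
                       Ca = r(41.1, 110.7), Fe = r(1.7, 10.3), Zn = r(0.3, 1.3))),
    list(bv = "sunflower", country = "Romania", n = 3L,
         ranges = list(Cl = r(208.6, 360.6), K = r(293.0, 360.6),
                       Ca = r(118.5, 127.2), Fe = r(2.2, 3.7), Zn = r(1.3, 2.6),
                       Mn = r(2.1, 2.1), Rb = r(1.6, 1.6)),
         detect_n = c(Mn = 1L, Rb = 1L))
  )
}

#' Specification of one synthetic honey class
#'
#' @param botanical_variety,country Class labels.
#' @param n_default Number of samples drawn for this class by
#'   [sample_study()].
#' @param element_ranges Named list of `c(low, high)` mass-fraction ranges in
#'   mg/kg, `0 < low <= high`. Elements absent from the list are treated as
#'   non-detects for this class.
#' @param detect_prob Named numeric in \[0, 1\]: probability that a ranged
#'   element is quantifiable in a given sample. Defaults to 1 for every
#'   ranged element; sporadic single-sample detections are modelled as a low
#'   probability with a point range rather than as a separate mechanism.
#' @return An object of class `class_spec`.
#' @export
class_spec <- function(botanical_variety, country, n_default, element_ranges,
                       detect_prob = NULL) {
  stopifnot(length(element_ranges) >= 0)
  for (el in names(element_ranges)) {
    rg <- element_ranges[[el]]
    if (length(rg) != 2L || any(rg <= 0) || rg[1] > rg[2]) {
      stop("invalid range for ", el, ": need 0 < low <= high")
    }
  }
  dp <- rep(1, length(element_ranges))
  names(dp) <- names(element_ranges)
  if (!is.null(detect_prob)) {
    if (any(detect_prob < 0 | detect_prob > 1)) stop("detect_prob must lie in [0, 1]")
    dp[names(detect_prob)] <- detect_prob
  }
  structure(list(botanical_variety = as.character(botanical_variety),
                 country = as.character(country),
                 n_default = as.integer(n_default),
                 element_ranges = element_ranges,
                 detect_prob = dp),
            class = "class_spec")
}

#' Measurement-noise specification for the generator
#'
#' @param cv Relative standard deviation of measurement, either a single
#'   value applied to every element or a named per-element vector.
#'   Default 0.10.
#' @param lod Limit of detection in mg/kg (default 0.1); simulated values
#'   below it become non-detects.
#' @param blank_offsets Named additive film-blank contributions in mg/kg,
#'   applied to detected values of the named elements (default P, Ca, Zn).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(cv = 0.10, lod = 0.1,
                       blank_offsets = c(P = 300, Ca = 150, Zn = 1)) {
  if (any(cv < 0)) stop("cv must be >= 0")
  if (length(lod) != 1L || lod <= 0) stop("lod must be a single value > 0")
  if (any(blank_offsets < 0)) stop("blank_offsets must be >= 0")
  structure(list(cv = cv, lod = lod, blank_offsets = blank_offsets),
            class = "noise_spec")
}

#' Study-level generator specification
#'
#' @param classes List of [class_spec()] objects with unique
#'   (botanical_variety, country) pairs.
#' @param noise A [noise_spec()].
#' @param correlation_strength Scalar in \[0, 1\]: weight of a single latent
#'   total-mineral factor that couples all elements within a sample
#'   (0 = independent placement, 1 = fully coupled). Default 0.5.
#' @return An object of class `study_spec`.
#' @export
study_spec <- function(classes, noise = noise_spec(), correlation_strength = 0.5) {
  keys <- vapply(classes, function(cl) class_key(cl$botanical_variety, cl$country), "")
  if (anyDuplicated(keys)) stop("duplicate class keys: ",
                                paste(unique(keys[duplicated(keys)]), collapse = ", "))
  if (correlation_strength < 0 || correlation_strength > 1) {
    stop("correlation_strength must lie in [0, 1]")
  }
  structure(list(classes = classes, noise = noise,
                 correlation_strength = correlation_strength),
            class = "study_spec")
}

#' The default synthetic study: 17 published honey classes
#'
#' One class per published variety-country group, with the printed
#' mass-fraction ranges and per-class sample sizes. Elements quantified in
#' only a subset of a group's honeys get `detect_prob = k/n`; single-honey
#' detections become point ranges with `detect_prob = 1/n`. Al, P and Br
#' carry no published ranges and are generated as non-detects.
#'
#' @param cv Per-element measurement coefficient of variation (default 0.10).
#' @param correlation_strength Latent-factor coupling, see [study_spec()].
#' @param lod Detection limit in mg/kg.
#' @param blank_offsets Film-blank offsets, see [noise_spec()].
#' @return A `study_spec` with 17 classes.
#' @export
default_study_spec <- function(cv = 0.10, correlation_strength = 0.5,
                               lod = 0.1,
                               blank_offsets = c(P = 300, Ca = 150, Zn = 1)) {
  classes <- lapply(.study_ranges(), function(row) {
    dp <- NULL
    if (!is.null(row$detect_n)) dp <- row$detect_n / row$n
    class_spec(row$bv, row$country, row$n, row$ranges, detect_prob = dp)
  })
  study_spec(classes,
             noise = noise_spec(cv = cv, lod = lod, blank_offsets = blank_offsets),
             correlation_strength = correlation_strength)
}

#' Derive a reproducible child seed
#'
#' Child streams (one per class) use `hash(parent_seed, index)` so that the
#' draw for one class does not depend on how many samples earlier classes
#' consumed. Stable across runs and platforms; result is below 2^31.
#'
#' @param parent_seed,index Non-negative integers.
#' @return A single integer seed.
#' @export
derive_seed <- function(parent_seed, index) {
  m <- 2147483647
  s <- (abs(as.numeric(parent_seed)) %% m) * 48271 + as.numeric(index) * 16807
  as.integer(s %% m)
}

#' Draw synthetic fingerprints for one class
#'
#' Each sample gets a latent factor `u ~ U(0,1)`; every ranged element is
#' placed at position `cs*u + (1-cs)*v` (with `v ~ U(0,1)` per element and
#' `cs` the correlation strength) inside its `(low, high)` range on a log
#' scale — mass fractions are strictly positive and ranges span orders of
#' magnitude, so placement is log-uniform. Multiplicative lognormal noise
#' with the element's cv is applied, film-blank offsets are added to the
#' detected values of the configured elements, and values below the limit
#' of detection become non-detects.
#'
#' @param spec A [class_spec()].
#' @param noise A [noise_spec()].
#' @param n Number of samples, `>= 1`.
#' @param seed Integer seed; the same spec and seed give bit-identical
#'   output.
#' @param correlation_strength Latent-factor coupling in \[0, 1\].
#' @param panel Element panel of the output table.
#' @return A `fingerprint_table` with `n` rows.
#' @export
sample_class <- function(spec, noise, n, seed, correlation_strength = 0.5,
                         panel = default_panel()) {
  stopifnot(inherits(spec, "class_spec"), inherits(noise, "noise_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("n must be an integer >= 1")
  n <- as.integer(n)
  ranged <- names(spec$element_ranges)
  if (length(ranged) == 0L) {
    stop("class ", class_key(spec$botanical_variety, spec$country),
         " has no ranged elements")
  }
  miss <- setdiff(ranged, panel)
  if (length(miss)) stop("ranged element(s) not in panel: ", paste(miss, collapse = ", "))
  cv <- noise$cv
  if (is.null(names(cv))) {
    cv <- rep(cv[1], length(panel))
    names(cv) <- panel
  } else {
    full <- rep(0, length(panel)); names(full) <- panel
    full[names(cv)] <- cv
    cv <- full
  }

  set.seed(as.integer(seed %% 2147483647))
  u <- stats::runif(n)
  v <- matrix(stats::runif(n * length(ranged)), n, length(ranged))
  det_draw <- matrix(stats::runif(n * length(ranged)), n, length(ranged))
  z <- matrix(stats::rnorm(n * length(ranged)), n, length(ranged))

  vals <- matrix(NA_real_, n, length(panel), dimnames = list(NULL, panel))
  det <- matrix(FALSE, n, length(panel))
  cs <- correlation_strength
  for (j in seq_along(ranged)) {
    el <- ranged[j]
    rg <- spec$element_ranges[[el]]
    pos <- cs * u + (1 - cs) * v[, j]
    x <- exp(log(rg[1]) + pos * (log(rg[2]) - log(rg[1])))
    if (cv[el] > 0) {
      sdlog <- sqrt(log(1 + cv[el]^2))
      x <- x * exp(z[, j] * sdlog - sdlog^2 / 2) # lognormal, mean 1, sd = cv
    }
    dj <- det_draw[, j] < spec$detect_prob[[el]]
    col <- match(el, panel)
    vals[dj, col] <- x[dj]
    det[, col] <- dj
  }
  for (el in names(noise$blank_offsets)) {
    col <- match(el, panel)
    if (is.na(col)) next
    vals[det[, col], col] <- vals[det[, col], col] + noise$blank_offsets[[el]]
  }
  below <- !is.na(vals) & vals < noise$lod
  vals[below] <- NA_real_
  det[below] <- FALSE

  key <- class_key(spec$botanical_variety, spec$country)
  fingerprint_table(vals,
                    sample_id = sprintf("%s-%03d", key, seq_len(n)),
                    botanical_variety = rep(spec$botanical_variety, n),
                    country = rep(spec$country, n),
                    panel = panel, detected = det,
                    provenance = sprintf("synthetic (%s, seed %d)", key,
                                         as.integer(seed %% 2147483647)))
}

#' Draw a full synthetic study
#'
#' Concatenates [sample_class()] over every class of the study at its
#' default sample size, with per-class child seeds derived deterministically
#' from `seed` by [derive_seed()].
#'
#' @param spec A [study_spec()].
#' @param seed Integer seed.
#' @param min_n Optional: drop classes with fewer than `min_n` samples after
#'   generation (via [filter_groups_min_n()]).
#' @param panel Element panel of the output table.
#' @return A `fingerprint_table`.
#' @export
sample_study <- function(spec, seed, min_n = NULL, panel = default_panel()) {
  stopifnot(inherits(spec, "study_spec"))
  tabs <- lapply(seq_along(spec$classes), function(i) {
    cl <- spec$classes[[i]]
    t <- sample_class(cl, spec$noise, cl$n_default, derive_seed(seed, i),
                      correlation_strength = spec$correlation_strength,
                      panel = panel)
    t$provenance <- character() # per-class seeds recorded at study level
    t
  })
  out <- ft_bind(tabs)
  out$provenance <- sprintf("synthetic study (%d classes, seed %d)",
                            length(spec$classes), as.integer(seed))
  if (!is.null(min_n)) out <- filter_groups_min_n(out, min_n)$table
  out
}

#' Serialize a study specification to JSON
#' @param spec A `study_spec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_spec <- function(spec, path) {
  stopifnot(inherits(spec, "study_spec"))
  doc <- list(
    correlation_strength = spec$correlation_strength,
    noise = list(cv = as.list(spec$noise$cv), lod = spec$noise$lod,
                 blank_offsets = as.list(spec$noise$blank_offsets)),
    classes = lapply(spec$classes, function(cl) {
      list(botanical_variety = cl$botanical_variety, country = cl$country,
           n_default = cl$n_default,
           element_ranges = lapply(cl$element_ranges, as.numeric),
           detect_prob = as.list(cl$detect_prob))
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a study specification from JSON
#' @param path Path written by [write_study_spec()].
#' @return A `study_spec`.
#' @export
read_study_spec <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  nz <- doc$noise
  cvl <- unlist(nz$cv)
  classes <- lapply(doc$classes, function(cl) {
    class_spec(cl$botanical_variety, cl$country, cl$n_default,
               lapply(cl$element_ranges, as.numeric),
               detect_prob = unlist(cl$detect_prob))
  })
  study_spec(classes,
             noise = noise_spec(cv = cvl, lod = nz$lod,
                                blank_offsets = unlist(nz$blank_offsets)),
             correlation_strength = doc$correlation_strength)
}
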