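test_that("default study mirrors the published class table", {
  spec <- default_study_spec()
  keys <- sapply(spec$classes, function(cl) class_key(cl$botanical_variety, cl$country))
  expect_length(keys, 17L)
  expect_false(anyDuplicated(keys) > 0)
  ci <- spec$classes[[which(keys == "chestnut:Italy")]]
  expect_equal(ci$element_ranges$K, c(1883.8, 3324.1))
  rh <- spec$classes[[which(keys == "robinia:Hungary")]]
  expect_equal(rh$n_default, 11L)
  # single-honey sporadic detections carry detect_prob 1/n with a point range
  oi <- spec$classes[[which(keys == "orange:Italy")]]
  expect_equal(oi$detect_prob[["Mn"]], 1 / 6)
  expect_equal(oi$element_ranges$Mn, c(1.8, 1.8))
  # total and >=5-group sample counts implied by the class table
  ns <- sapply(spec$classes, `[[`, "n_default")
  expect_equal(sum(ns), 89L)
  expect_equal(sum(ns[ns >= 5]), 71L)
  expect_equal(sum(ns >= 5), 11L)
})

test_that("study spec round-trips through JSON, including the shipped default", {
  spec <- default_study_spec()
  path <- withr::local_tempfile(fileext = ".json")
  write_study_spec(spec, path)
  spec2 <- read_study_spec(path)
  expect_equal(length(spec2$classes), length(spec$classes))
  expect_equal(spec2$correlation_strength, spec$correlation_strength)
  expect_equal(spec2$noise$lod, spec$noise$lod)
  i <- 13 # chestnut-Italy
  expect_equal(spec2$classes[[i]]$element_ranges, spec$classes[[i]]$element_ranges)
  expect_identical(sample_study(spec2, 5)$values, sample_study(spec, 5)$values)
  shipped <- system.file("extdata", "default_study_spec.json", package = "honeyprint")
  expect_true(nzchar(shipped))
  expect_identical(sample_study(read_study_spec(shipped), 5)$values,
                   sample_study(spec, 5)$values)
})

test_that("generation is bit-identical per seed and differs across seeds", {
  spec <- default_study_spec()
  t1 <- sample_study(spec, seed = 7)
  t2 <- sample_study(spec, seed = 7)
  expect_identical(t1$values, t2$values)
  expect_identical(t1$detected, t2$detected)
  t3 <- sample_study(spec, seed = 8)
  expect_false(identical(t1$values, t3$values))
  cl <- spec$classes[[1]]
  expect_identical(sample_class(cl, spec$noise, 20, seed = 7)$values,
                   sample_class(cl, spec$noise, 20, seed = 7)$values)
})

test_that("noise-free draws stay inside the published ranges for every class", {
  spec <- default_study_spec(cv = 0, blank_offsets = c(P = 0, Ca = 0, Zn = 0))
  for (i in seq_along(spec$classes)) {
    cl <- spec$classes[[i]]
    tab <- sample_class(cl, spec$noise, 200, seed = 100 + i,
                        correlation_strength = spec$correlation_strength)
    for (el in names(cl$element_ranges)) {
      v <- tab$values[tab$detected[, el], el]
      rg <- cl$element_ranges[[el]]
      expect_true(all(v >= rg[1] - 1e-12 & v <= rg[2] + 1e-12),
                  label = paste0(class_key(cl$botanical_variety, cl$country),
                                 " ", el, " inside its range"))
    }
  }
})

test_that("non-detect fraction converges to 1 - detect_prob", {
  cl <- class_spec("test", "T", 5,
                   list(Cl = c(100, 200), K = c(100, 200), Mn = c(5, 10)),
                   detect_prob = c(Mn = 0.6))
  tab <- sample_class(cl, noise_spec(cv = 0, blank_offsets = c(P = 0)),
                      5000, seed = 11, correlation_strength = 0)
  p_hat <- mean(tab$detected[, "Mn"])
  se3 <- 3 * sqrt(0.6 * 0.4 / 5000)
  expect_true(abs(p_hat - 0.6) <= se3)
})

test_that("measurement noise reproduces the configured coefficient of variation", {
  # point range pins the latent placement, so spread is purely the cv
  cl <- class_spec("cvtest", "T", 5, list(Cl = c(100, 100)))
  tab <- sample_class(cl, noise_spec(cv = 0.10, blank_offsets = c(P = 0)),
                      10000, seed = 21)
  v <- tab$values[, "Cl"]
  expect_true(sd(v) / mean(v) >= 0.095 && sd(v) / mean(v) <= 0.105)
  expect_equal(mean(v), 100, tolerance = 0.01)
})

test_that("values pushed below the detection limit become non-detects", {
  cl <- class_spec("lod", "T", 5, list(Zn = c(0.05, 0.2), K = c(100, 200)))
  tab <- sample_class(cl, noise_spec(cv = 0, blank_offsets = c(P = 0), lod = 0.1),
                      500, seed = 31, correlation_strength = 0)
  v <- tab$values[, "Zn"]
  expect_true(all(v[!is.na(v)] >= 0.1))
  expect_true(any(!tab$detected[, "Zn"]))  # part of the range sits below LoD
})

test_that("film-blank offsets shift only the configured elements", {
  cl <- class_spec("blank", "T", 5, list(Ca = c(50, 50), K = c(100, 100)))
  nz <- noise_spec(cv = 0, blank_offsets = c(P = 300, Ca = 150, Zn = 1))
  tab <- sample_class(cl, nz, 10, seed = 41)
  expect_equal(unname(tab$values[, "Ca"]), rep(200, 10))
  expect_equal(unname(tab$values[, "K"]), rep(100, 10))
})

test_that("dark honeys run higher in potassium than light honeys", {
  spec <- default_study_spec()
  keys <- sapply(spec$classes, function(cl) class_key(cl$botanical_variety, cl$country))
  ci <- sample_class(spec$classes[[which(keys == "chestnut:Italy")]], spec$noise,
                     200, seed = 51, correlation_strength = 0.5)
  rh <- sample_class(spec$classes[[which(keys == "robinia:Hungary")]], spec$noise,
                     200, seed = 52, correlation_strength = 0.5)
  expect_gt(median(ci$values[, "K"]), median(rh$values[, "K"]))
})

test_that("restricting the default study to modelled groups gives the 11 classes", {
  tab <- sample_study(default_study_spec(), seed = 9, min_n = 5)
  expect_equal(length(unique(class_keys(tab))), 11L)
  expect_equal(nrow(tab$values), 71L)
})

test_that("generator argument errors are caught", {
  spec <- default_study_spec()
  expect_error(sample_class(spec$classes[[1]], spec$noise, 0, seed = 1), "n must")
  empty <- spec$classes[[1]]; empty$element_ranges <- list(); empty$detect_prob <- numeric()
  expect_error(sample_class(empty, spec$noise, 5, seed = 1), "no ranged elements")
  expect_error(noise_spec(lod = 0), "lod")
  expect_error(study_spec(spec$classes[c(1, 1)]), "duplicate")
})

test_that("child seeds are deterministic, distinct and within integer range", {
  s <- sapply(1:17, function(i) derive_seed(42, i))
  expect_false(anyDuplicated(s) > 0)
  expect_true(all(s >= 0 & s < 2^31))
  expect_identical(s, sapply(1:17, function(i) derive_seed(42, i)))
})
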