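# Shared fixtures, built in code at test time.

# A tiny fully-detected table on the standard panel.
tiny_table <- function(n = 3, seed = 1, bv = "orange", country = "Spain") {
  set.seed(seed)
  panel <- default_panel()
  vals <- matrix(exp(rnorm(n * length(panel), 3, 0.3)), n,
                 dimnames = list(NULL, panel))
  fingerprint_table(vals, sprintf("%s-%s-%02d", bv, country, seq_len(n)),
                    rep(bv, n), rep(country, n))
}

# Wrap a plain numeric matrix as a single-class table.
matrix_table <- function(X, bv = "a", country = "b", prefix = "s") {
  if (is.null(colnames(X))) colnames(X) <- paste0("E", seq_len(ncol(X)))
  fingerprint_table(X, paste0(prefix, seq_len(nrow(X))),
                    rep(bv, nrow(X)), rep(country, nrow(X)))
}

# Two classes fully separated on Cl (no overlap), everything else shared.
separable_pair <- function(n = 6, seed = 2) {
  cl1 <- class_spec("low", "X", n, list(Cl = c(40, 60), K = c(100, 200),
                                        Ca = c(10, 30), Fe = c(1, 2), Zn = c(0.3, 0.8)))
  cl2 <- class_spec("high", "Y", n, list(Cl = c(400, 600), K = c(100, 200),
                                         Ca = c(10, 30), Fe = c(1, 2), Zn = c(0.3, 0.8)))
  sp <- study_spec(list(cl1, cl2), noise = noise_spec(blank_offsets = c(P = 0)),
                   correlation_strength = 0.5)
  sample_study(sp, seed = seed)
}

# Two classes with disjoint ranges on every element (strongly separated).
disjoint_study_spec <- function(n = 8) {
  cl1 <- class_spec("alpha", "X", n, list(Cl = c(50, 80), K = c(100, 150),
                                          Ca = c(10, 20), Fe = c(1, 2), Zn = c(0.3, 0.6)))
  cl2 <- class_spec("beta", "Y", n, list(Cl = c(300, 500), K = c(1000, 1500),
                                         Ca = c(100, 200), Fe = c(5, 9), Zn = c(2, 4)))
  study_spec(list(cl1, cl2), noise = noise_spec(blank_offsets = c(P = 0)),
             correlation_strength = 0.5)
}

# Multivariate-normal data from a 2-component latent model (the DModX
# calibration setting): returns training and held-out null observations.
latent2_data <- function(N = 150, K = 7, n_test = 25, noise_sd = 0.5) {
  L <- matrix(rnorm(2 * K), 2, K)
  X <- matrix(rnorm(N * 2), N, 2) %*% L +
    matrix(rnorm(N * K, sd = noise_sd), N, K)
  Xn <- matrix(rnorm(n_test * 2), n_test, 2) %*% L +
    matrix(rnorm(n_test * K, sd = noise_sd), n_test, K)
  colnames(X) <- colnames(Xn) <- paste0("E", seq_len(K))
  list(train = X, test = Xn)
}

# The published variety-country group list with its per-group sample sizes
# (the eleven modelled groups plus the smaller discriminant-only groups),
# expanded to one row per sample for group-filtering checks.
printed_group_table <- function() {
  groups <- c("orange:Italy" = 6, "orange:Spain" = 9, "lavender:France" = 5,
              "lavender:Portugal" = 7, "lavender:Spain" = 5,
              "rosemary:Spain" = 5, "robinia:Hungary" = 11,
              "robinia:Italy" = 5, "lime:Romania" = 5, "chestnut:Italy" = 5,
              "manuka:New Zealand" = 7,
              "robinia:Romania" = 3, "thyme:Spain" = 3,
              "thyme:New Zealand" = 3, "chestnut:Spain" = 3,
              "eucalyptus:Spain" = 3, "sunflower:Romania" = 3)
  bv <- rep(sub(":.*$", "", names(groups)), groups)
  co <- rep(sub("^.*?:", "", names(groups)), groups)
  n <- length(bv)
  vals <- matrix(1, n, length(default_panel()),
                 dimnames = list(NULL, default_panel()))
  fingerprint_table(vals, sprintf("s%03d", seq_len(n)), bv, co)
}
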