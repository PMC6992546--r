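test_that("scaling parameters match closed forms and invert exactly", {
  X <- cbind(a = c(1, 2, 3), b = c(10, 20, 60))
  sc <- fit_scaling(X, "uv")
  expect_equal(unname(sc$means), c(2, 30))
  expect_equal(unname(sc$sds[1]), 1)
  sc0 <- fit_scaling(X, "center_only")
  expect_equal(unname(sc0$sds), c(1, 1))
  scp <- fit_scaling(X, "pareto")
  expect_equal(unname(scp$sds), unname(sqrt(apply(X, 2, sd))))
  for (m in list(sc, sc0, scp)) {
    expect_equal(invert_scaling(m, apply_scaling(m, X)), X, tolerance = 1e-12)
  }
  expect_error(fit_scaling(cbind(a = c(1, 1, 1), b = 1:3), "uv"), "a")
})

test_that("a rank-one matrix is fully explained by one component", {
  set.seed(1)
  X <- outer(rnorm(8), rnorm(5))
  f <- fit_pca_nipals(X, 1)
  expect_equal(f$r2x_per_component, 1, tolerance = 1e-10)
  expect_lt(max(abs(f$residuals)), 1e-8)
})

test_that("NIPALS matches the singular value decomposition on complete data", {
  set.seed(2)
  for (rep in 1:10) {
    N <- sample(6:20, 1); K <- sample(4:10, 1)
    X <- scale(matrix(rnorm(N * K), N, K), center = TRUE, scale = FALSE)
    A <- min(3L, N - 1L, K)
    f <- fit_pca_nipals(X, A)
    sv <- svd(X)
    r2_svd <- sv$d[seq_len(A)]^2 / sum(sv$d^2)
    expect_equal(f$r2x_per_component, r2_svd, tolerance = 1e-6)
    for (a in seq_len(A)) { # scores agree up to a column sign flip
      s <- sv$u[, a] * sv$d[a]
      expect_lt(min(max(abs(f$T[, a] - s)), max(abs(f$T[, a] + s))),
                1e-4 * sv$d[a])
    }
    # full decomposition recovers all the variance
    ffull <- fit_pca_nipals(X, min(N - 1L, K))
    expect_equal(sum(ffull$r2x_per_component), 1, tolerance = 1e-8)
  }
})

test_that("scores are orthogonal and loadings orthonormal on complete data", {
  set.seed(3)
  for (rep in 1:5) {
    X <- scale(matrix(rnorm(12 * 7), 12, 7), center = TRUE, scale = FALSE)
    f <- fit_pca_nipals(X, 3)
    G <- crossprod(f$T)
    expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
    expect_equal(crossprod(f$P), diag(3), tolerance = 1e-8)
    expect_true(all(diff(f$r2x_per_component) <= 1e-10)) # variance order
  }
})

test_that("the orientation rule makes each loading's largest entry positive", {
  set.seed(4)
  X <- scale(matrix(rnorm(10 * 6), 10, 6), center = TRUE, scale = FALSE)
  f <- fit_pca_nipals(X, 3)
  for (a in 1:3) expect_gt(f$P[which.max(abs(f$P[, a])), a], 0)
})

test_that("missing entries are skipped, not imputed", {
  set.seed(5)
  X <- outer(rnorm(10), rnorm(6)) + matrix(rnorm(60, sd = 0.01), 10, 6)
  Xm <- X; Xm[cbind(c(1, 4, 7), c(2, 5, 3))] <- NA
  f <- fit_pca_nipals(scale(Xm, scale = FALSE), 1)
  fc <- fit_pca_nipals(scale(X, scale = FALSE), 1)
  # strong structure: the component is close to the complete-data one
  expect_gt(abs(cor(f$P[, 1], fc$P[, 1])), 0.999)
  expect_true(all(is.na(f$residuals[cbind(c(1, 4, 7), c(2, 5, 3))])))
})

test_that("component count is validated", {
  X <- matrix(rnorm(12), 4, 3)
  expect_error(fit_pca_nipals(X, 4), "min\\(N-1, K\\)")
  expect_error(fit_pca_nipals(X, 0), "A must")
})

test_that("cross-validated Q2 separates structure from noise", {
  set.seed(6)
  t <- rnorm(20); p <- rnorm(8)
  X <- outer(t, p)
  Xn <- X + matrix(rnorm(160, sd = 0.01 * sd(X)), 20, 8)
  q2 <- cross_validate_q2(scale(Xn, scale = FALSE), 1)
  expect_gt(q2$q2_cum, 0.9)
  set.seed(7)
  Z <- matrix(rnorm(70), 10, 7)
  q2n <- cross_validate_q2(scale(Z), 2)
  expect_lt(q2n$q2_cum, 0.2)           # negativity admissible
  expect_true(all(q2$q2_per_component <= 1))
  expect_true(all(q2n$q2_per_component <= 1))
  expect_error(cross_validate_q2(Z, 2, groups = 1000), "present entries")
})

test_that("Q2 is deterministic and reproducible", {
  set.seed(8)
  X <- scale(matrix(rnorm(60), 10, 6))
  expect_identical(cross_validate_q2(X, 2), cross_validate_q2(X, 2))
})

test_that("DModX is zero at the centroid and matches brute-force residuals", {
  set.seed(9)
  for (rep in 1:5) {
    d <- latent2_data(N = 15, K = 7, n_test = 1)
    tab <- matrix_table(d$train)
    m <- fit_pca_class(tab, A = 2, cv_groups = NULL)
    # training observations against direct residual recomputation
    E <- m$X_scaled - tcrossprod(m$T, m$P)
    s_i <- sqrt(rowSums(E^2) / (m$K - m$A))
    d_ws <- (s_i / m$s0) * sqrt(m$N / (m$N - m$A - m$A0))
    rep_ws <- dmodx(m, mode = "workset")
    expect_equal(rep_ws$obs$dmodx, unname(d_ws), tolerance = 1e-8)
    rep_ps <- dmodx(m, mode = "prediction")
    expect_equal(rep_ps$obs$dmodx, unname(s_i / m$s0), tolerance = 1e-8)
    # the centroid projects to the origin: zero distance, member
    centroid <- matrix(0, 1, m$K)
    r0 <- dmodx(m, centroid, mode = "prediction")
    expect_equal(r0$obs$dmodx, 0)
    expect_true(r0$obs$member)
  }
})

test_that("the critical limit is the square root of the stated F quantile", {
  set.seed(10)
  # N = 12, K = 8, A = 3, mean-centred: df (K-A, (N-A-A0)(K-A)) = (5, 40)
  X <- matrix(rnorm(12 * 8), 12, 8)
  m <- fit_pca_class(matrix_table(X), A = 3, cv_groups = NULL)
  expect_equal(m$K - m$A, 5L)
  expect_equal((m$N - m$A - m$A0) * (m$K - m$A), 40L)
  r <- dmodx(m, alpha = 0.05)
  expect_equal(r$dcrit, sqrt(qf(0.95, 5, 40)), tolerance = 1e-12)
  r10 <- dmodx(m, alpha = 0.10)
  expect_equal(r10$dcrit, sqrt(qf(0.90, 5, 40)), tolerance = 1e-12)
  expect_error(dmodx(m, alpha = 0.7), "alpha")
})

test_that("DModX grows strictly with an off-model perturbation", {
  set.seed(11)
  d <- latent2_data(N = 30, K = 7, n_test = 1)
  m <- fit_pca_class(matrix_table(d$train), A = 2, cv_groups = NULL)
  x0 <- apply_scaling(m$scaling, d$test)
  x_on <- matrix(as.vector(m$P %*% crossprod(m$P, as.vector(x0))), 1) # on-model part
  v <- rnorm(7)
  v_res <- v - as.vector(m$P %*% crossprod(m$P, v))   # off-model direction
  v_res <- v_res / sqrt(sum(v_res^2))
  dist <- sapply(seq(0, 3, by = 0.5), function(g) {
    dmodx(m, x_on + g * matrix(v_res, 1), mode = "prediction")$obs$dmodx
  })
  expect_true(all(diff(dist) > 0))
})

test_that("loading-plot elimination removes inert variables and stops cleanly", {
  # a column that is constant contributes a zero loading and goes first
  set.seed(12)
  base <- outer(rnorm(10), rnorm(4)) + matrix(rnorm(40, sd = 0.05), 10, 4)
  X <- cbind(base, Al = rep(5, 10))
  colnames(X) <- c("Cl", "K", "Ca", "Fe", "Al")
  sel <- select_variables_by_loadings(matrix_table(X), A = 2,
                                      scaling = "center_only",
                                      cv_groups = NULL)
  expect_false("Al" %in% sel$panel)
  expect_setequal(sel$panel, c("Cl", "K", "Ca", "Fe"))
  # equal-magnitude loadings: nothing to remove, single pass
  X1 <- outer(rnorm(10), c(1, 1, 1, 1)) + matrix(rnorm(40, sd = 1e-6), 10, 4)
  colnames(X1) <- c("Cl", "K", "Ca", "Fe")
  sel1 <- select_variables_by_loadings(matrix_table(X1), A = 1,
                                       scaling = "center_only",
                                       cv_groups = NULL)
  expect_setequal(sel1$panel, c("Cl", "K", "Ca", "Fe"))
  # an independent-noise variable among informative ones is dropped: two
  # latent factors carry five elements, the sixth is pure noise and sits at
  # the centre of the loading plot
  set.seed(13)
  n <- 400
  u1 <- rnorm(n); u2 <- rnorm(n)
  X2 <- cbind(u1 + rnorm(n, sd = 0.1), u1 + rnorm(n, sd = 0.1),
              u1 + rnorm(n, sd = 0.1), u2 + rnorm(n, sd = 0.1),
              u2 + rnorm(n, sd = 0.1), rnorm(n))
  colnames(X2) <- c("Cl", "K", "Ca", "Fe", "Zn", "Mn")
  sel2 <- select_variables_by_loadings(matrix_table(X2), A = 2, cv_groups = NULL)
  expect_false("Mn" %in% sel2$panel)
  # brute-force single pass agrees: Mn is the only sub-threshold radius
  m2 <- fit_pca_class(matrix_table(X2), A = 2, cv_groups = NULL)
  r <- sqrt(m2$P[, 1]^2 + m2$P[, 2]^2)
  expect_identical(names(which(r < 0.15 * max(r))), "Mn")
  expect_error(select_variables_by_loadings(matrix_table(X2), A = 2, tau = 1.5),
               "tau")
})

test_that("a PCA class model survives JSON serialization for prediction", {
  set.seed(14)
  d <- latent2_data(N = 20, K = 6, n_test = 4)
  m <- fit_pca_class(matrix_table(d$train), A = 2, cv_groups = 7)
  path <- withr::local_tempfile(fileext = ".json")
  write_pca_model(m, path)
  m2 <- read_pca_model(path)
  expect_equal(m2$s0, m$s0)
  expect_equal(m2$P, m$P, ignore_attr = TRUE)
  q_new <- matrix_table(d$test)
  r1 <- dmodx(m, q_new, mode = "prediction")
  r2 <- dmodx(m2, q_new, mode = "prediction")
  expect_equal(r2$obs$dmodx, r1$obs$dmodx, tolerance = 1e-12)
  expect_equal(r2$dcrit, r1$dcrit)
})
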