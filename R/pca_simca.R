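# One-class PCA modelling in the SIMCA style. The NIPALS core supports
# missing entries (non-detects are never imputed at the modelling layer:
# they are skipped in the inner regressions), which is why it is authored
# here rather than delegated to svd()/prcomp(); those serve as oracles in
# the test suite on complete data.

#' Fit column scaling parameters
#'
#' Means and standard deviations are computed over the detected values of
#' each element. Methods: `"uv"` (unit variance: centre and divide by sd,
#' the SIMCA convention and the package default), `"center_only"`, and
#' `"pareto"` (divide by the square root of the sd).
#'
#' @param table A `fingerprint_table` (or a numeric matrix with `NA` for
#'   missing entries).
#' @param method One of `"uv"`, `"center_only"`, `"pareto"`.
#' @return An object of class `scaling_params` with fields `means`, `sds`
#'   (the divisors actually applied), `method`.
#' @export
fit_scaling <- function(table, method = c("uv", "center_only", "pareto")) {
  method <- match.arg(method)
  X <- if (inherits(table, "fingerprint_table")) table$values else as.matrix(table)
  if (nrow(X) < 2L) stop("at least 2 rows are required to fit scaling")
  means <- colMeans(X, na.rm = TRUE)
  sds <- apply(X, 2L, stats::sd, na.rm = TRUE)
  cols <- colnames(X)
  if (is.null(cols)) cols <- paste0("V", seq_len(ncol(X)))
  if (method %in% c("uv", "pareto")) {
    bad <- which(is.na(sds) | sds <= 0)
    if (length(bad)) {
      stop("constant or all-missing column(s) under ", method, " scaling: ",
           paste(cols[bad], collapse = ", "))
    }
  }
  div <- switch(method,
                uv = sds,
                center_only = rep(1, length(means)),
                pareto = sqrt(sds))
  names(div) <- names(means) <- cols
  structure(list(means = means, sds = div, method = method),
            class = "scaling_params")
}

#' Apply / invert a fitted scaling
#' @param scaling A `scaling_params` object.
#' @param X Numeric matrix (columns aligned with the scaling).
#' @return The (un)scaled matrix.
#' @export
apply_scaling <- function(scaling, X) {
  X <- as.matrix(X)
  sweep(sweep(X, 2L, scaling$means, "-"), 2L, scaling$sds, "/")
}

#' @rdname apply_scaling
#' @export
invert_scaling <- function(scaling, X) {
  X <- as.matrix(X)
  sweep(sweep(X, 2L, scaling$sds, "*"), 2L, scaling$means, "+")
}

# One NIPALS component on a (possibly incomplete) matrix. Returns t, p and
# the iteration count; regressions skip missing entries. Zero denominators
# (a fold emptying a column, say) contribute a zero coefficient.
#
# Stopping: primary criterion is the relative change of the score vector
# (<= tol). A secondary stall criterion handles (near-)degenerate leading
# eigenvalues, where the score rotates inside the degenerate subspace for
# thousands of iterations while the captured variance is fully converged —
# any vector of that subspace is an equally valid component, so iteration
# stops once the score is quasi-stable and the captured variance no longer
# moves at 1e-13 relative (which bounds the explained-variance error far
# below the 1e-6 the downstream statistics care about).
#
# On complete data, scores are re-orthogonalized against the previously
# extracted components (T_prev) each iteration; plain NIPALS only attains
# score orthogonality in the limit of exact eigenvector convergence.
#
# With strict = FALSE, non-convergence returns the last iterate instead of
# erroring (incomplete matrices can cycle between near-solutions; the
# cross-validation folds tolerate that, a reported model fit does not).
.nipals_component <- function(X, tol = 1e-9, max_iter = 20000L, strict = TRUE,
                              T_prev = NULL) {
  pres <- !is.na(X)
  complete <- all(pres)
  X0 <- X
  X0[!pres] <- 0
  vars <- apply(X, 2L, function(col) {
    col <- col[!is.na(col)]
    if (length(col) < 1L) return(-Inf)
    sum(col^2)
  })
  t <- X0[, which.max(vars)]
  orthogonalize <- complete && !is.null(T_prev) && ncol(T_prev) > 0L
  if (orthogonalize) tt_prev <- colSums(T_prev^2)
  eig_old <- sum(t^2)
  for (it in seq_len(max_iter)) {
    den_p <- crossprod(pres, t^2)             # per-column sum of t_i^2 over present rows
    p <- as.vector(crossprod(X0, t))
    p <- ifelse(den_p > 0, p / den_p, 0)
    nrm <- sqrt(sum(p^2))
    if (nrm == 0) stop("NIPALS degenerate: zero loading vector")
    p <- p / nrm
    den_t <- as.vector(pres %*% p^2)
    t_new <- as.vector(X0 %*% p)
    t_new <- ifelse(den_t > 0, t_new / den_t, 0)
    if (orthogonalize) {
      t_new <- t_new - T_prev %*% (crossprod(T_prev, t_new) / tt_prev)
      t_new <- as.vector(t_new)
    }
    eig_new <- sum(t_new^2)
    delta_t <- sqrt(sum((t_new - t)^2)) / max(sqrt(eig_new), 1e-300)
    if (delta_t <= tol) {
      return(list(t = t_new, p = p, iterations = it))
    }
    if (it > 1L && delta_t <= 1e-4 &&
        abs(eig_new - eig_old) <= 1e-13 * max(eig_new, 1e-300)) {
      return(list(t = t_new, p = p, iterations = it))
    }
    eig_old <- eig_new
    t <- t_new
  }
  if (strict) stop("NIPALS did not converge within ", max_iter, " iterations")
  list(t = t, p = p, iterations = max_iter, converged = FALSE)
}

# Orient a component so the largest-|loading| entry is positive (ties break
# to the lowest panel index, which is how which.max resolves them).
.orient <- function(t, p) {
  j <- which.max(abs(p))
  if (p[j] < 0) list(t = -t, p = -p) else list(t = t, p = p)
}

#' NIPALS principal component analysis
#'
#' Extracts `A` components sequentially by NIPALS with deflation from an
#' already-scaled matrix. Missing entries (non-detects) are skipped in the
#' inner regressions, not imputed. Explained variation per component is the
#' sum of squares removed by its deflation divided by the total sum of
#' squares of `X` (over present entries).
#'
#' @param X Scaled numeric matrix, `NA` for missing entries.
#' @param A Number of components, `1 <= A <= min(N-1, K)`.
#' @param tol Convergence tolerance on the relative change of the score
#'   vector (default 1e-9).
#' @param max_iter Maximum NIPALS iterations per component (default
#'   20000; iterations are cheap and near-degenerate eigenvalue pairs
#'   converge slowly).
#' @return List with `T` (N x A scores), `P` (K x A loadings),
#'   `r2x_per_component`, `ss_total`, and `residuals` (the deflated matrix,
#'   `NA` where `X` was missing).
#' @export
fit_pca_nipals <- function(X, A, tol = 1e-9, max_iter = 20000L) {
  X <- as.matrix(X)
  N <- nrow(X); K <- ncol(X)
  if (N < 2L) stop("at least 2 rows are required")
  if (!is.numeric(A) || length(A) != 1L || A < 1) stop("A must be an integer >= 1")
  A <- as.integer(A)
  if (A > min(N - 1L, K)) {
    stop("A = ", A, " exceeds min(N-1, K) = ", min(N - 1L, K))
  }
  ss_total <- sum(X^2, na.rm = TRUE)
  Tm <- matrix(0, N, A)
  Pm <- matrix(0, K, A, dimnames = list(colnames(X), NULL))
  r2x <- numeric(A)
  Xa <- X
  for (a in seq_len(A)) {
    comp <- tryCatch(.nipals_component(Xa, tol = tol, max_iter = max_iter,
                                       T_prev = Tm[, seq_len(a - 1L), drop = FALSE]),
                     error = function(e) {
                       stop("component ", a, ": ", conditionMessage(e), call. = FALSE)
                     })
    comp <- .orient(comp$t, comp$p)
    ss_before <- sum(Xa^2, na.rm = TRUE)
    Xa <- Xa - tcrossprod(comp$t, comp$p)
    ss_after <- sum(Xa^2, na.rm = TRUE)
    Tm[, a] <- comp$t
    Pm[, a] <- comp$p
    r2x[a] <- (ss_before - ss_after) / ss_total
  }
  list(T = Tm, P = Pm, r2x_per_component = r2x, ss_total = ss_total,
       residuals = Xa)
}

#' Cross-validated predicted variation (Q2)
#'
#' Wold-style element-wise deletion: the present entries of the (deflated)
#' matrix are assigned to `groups` diagonal stripes by
#' `(row_index + col_index) mod groups`; for each stripe the component is
#' refit on the remaining entries with missing-value NIPALS and the deleted
#' entries are predicted, accumulating PRESS. `Q2_a = 1 - PRESS_a/SS_{a-1}`
#' and `q2_cum = 1 - prod_a(PRESS_a/SS_{a-1})`. The stripe rule is
#' deterministic; `seed` is accepted for interface stability but unused.
#'
#' @param X Scaled numeric matrix (`NA` = missing).
#' @param A Number of components.
#' @param groups Number of deletion stripes (default 7).
#' @param seed Unused; the stripe assignment is deterministic.
#' @param tol,max_iter NIPALS controls.
#' @return List with `q2_per_component` and `q2_cum`.
#' @export
cross_validate_q2 <- function(X, A, groups = 7L, seed = NULL,
                              tol = 1e-9, max_iter = 1000L) {
  X <- as.matrix(X)
  if (groups < 2L) stop("groups must be >= 2")
  pres <- !is.na(X)
  if (groups > sum(pres)) stop("groups exceeds the number of present entries")
  stripe <- (row(X) + col(X)) %% groups
  Xa <- X
  q2 <- numeric(A)
  ratios <- numeric(A)
  for (a in seq_len(A)) {
    ss_prev <- sum(Xa^2, na.rm = TRUE)
    press <- 0
    for (g in seq_len(groups) - 1L) {
      del <- pres & stripe == g
      if (!any(del)) next
      Xg <- Xa
      Xg[del] <- NA
      comp <- .nipals_component(Xg, tol = tol, max_iter = max_iter,
                                strict = FALSE)
      pred <- tcrossprod(comp$t, comp$p)
      press <- press + sum((Xa[del] - pred[del])^2)
    }
    ratios[a] <- press / ss_prev
    q2[a] <- 1 - ratios[a]
    full <- .nipals_component(Xa, tol = tol, max_iter = max_iter,
                              strict = FALSE)
    Xa <- Xa - tcrossprod(full$t, full$p)
  }
  list(q2_per_component = q2, q2_cum = 1 - prod(ratios))
}

#' Fit a one-class PCA model for a variety-country group
#'
#' Scales the training fingerprints, drops elements with too few detected
#' values to scale (fewer than `min_detect`), runs missing-value NIPALS,
#' and stores everything the DModX membership test needs: the pooled
#' residual standard deviation `s0`, dimensions, and the scaled training
#' matrix. `A0 = 1` records that the model is mean-centred.
#'
#' @param table A `fingerprint_table`, all rows from one class.
#' @param A Components to extract (capped at `min(N-1, K)` when
#'   `cap_A = TRUE`; the study convention is at most 3, occasionally 4).
#' @param scaling Scaling method, see [fit_scaling()].
#' @param min_detect Minimum detected values an element needs to stay in the
#'   model panel (default 3).
#' @param cv_groups Stripes for the Q2 cross-validation; `NULL` skips Q2.
#' @param cap_A Reduce `A` to the feasible maximum instead of erroring.
#' @param select `"fixed"` (default) extracts exactly `A` components;
#'   `"q2"` treats `A` as a cap and keeps the component count that
#'   maximises the cumulative cross-validated Q2 (the autofit convention:
#'   components that only fit noise are not retained).
#' @param tol,max_iter NIPALS controls.
#' @return An object of class `pca_class_model`.
#' @export
fit_pca_class <- function(table, A = 3L, scaling = "uv", min_detect = 3L,
                          cv_groups = 7L, cap_A = TRUE,
                          select = c("fixed", "q2"),
                          tol = 1e-9, max_iter = 20000L) {
  select <- match.arg(select)
  stopifnot(inherits(table, "fingerprint_table"))
  keys <- unique(class_keys(table))
  key <- if (length(keys) == 1L) keys else paste(keys, collapse = "+")
  n_det <- colSums(table$detected)
  panel_used <- table$panel[n_det >= min_detect]
  if (length(panel_used) < 2L) {
    stop("class ", key, ": fewer than 2 elements with >= ", min_detect,
         " detected values")
  }
  tab <- ft_elements(table, panel_used)
  sc <- fit_scaling(tab, scaling)
  Xs <- apply_scaling(sc, tab$values)
  N <- nrow(Xs); K <- ncol(Xs)
  A_max <- min(N - 1L, K)
  A0 <- if (sc$method %in% c("uv", "center_only", "pareto")) 1L else 0L
  # s0 needs positive df and the DModX F-test needs residual room in the
  # variable direction: keep K - A >= 2 and N - A - A0 >= 1
  A_feas <- min(A_max, N - A0 - 1L, K - 2L)
  if (A > A_feas) {
    if (!cap_A) stop("A = ", A, " infeasible for N = ", N, ", K = ", K)
    A <- A_feas
  }
  q2 <- NULL
  if (!is.null(cv_groups)) {
    q2 <- tryCatch(cross_validate_q2(Xs, A, groups = cv_groups, tol = tol,
                                     max_iter = min(max_iter, 1000L)),
                   error = function(e) NULL)
  }
  if (select == "q2") {
    if (is.null(q2)) stop("component selection by Q2 requires cv_groups")
    ratios <- 1 - q2$q2_per_component
    cum <- 1 - cumprod(ratios)
    A <- which.max(cum)
    q2 <- list(q2_per_component = q2$q2_per_component[seq_len(A)],
               q2_cum = cum[A])
  }
  fit <- fit_pca_nipals(Xs, A, tol = tol, max_iter = max_iter)
  E <- fit$residuals
  s0 <- sqrt(sum(E^2, na.rm = TRUE) / ((N - A - A0) * (K - A)))
  structure(
    list(class_key = key, panel_used = panel_used, scaling = sc,
         A = A, A0 = A0, N = N, K = K,
         T = fit$T, P = fit$P,
         r2x_per_component = fit$r2x_per_component,
         q2_cum = if (is.null(q2)) NA_real_ else q2$q2_cum,
         q2_per_component = if (is.null(q2)) NULL else q2$q2_per_component,
         s0 = s0, X_scaled = Xs,
         sample_id = tab$meta$sample_id),
    class = "pca_class_model")
}

#' @export
print.pca_class_model <- function(x, ...) {
  cat("<pca_class_model> ", x$class_key, ": N=", x$N, ", K=", x$K,
      ", A=", x$A, "\n", sep = "")
  cat("  panel: ", paste(x$panel_used, collapse = ", "), "\n", sep = "")
  cat("  R2X per component: ", paste(sprintf("%.3f", x$r2x_per_component),
                                     collapse = ", "),
      "  Q2X(cum): ", sprintf("%.3f", x$q2_cum), "\n", sep = "")
  invisible(x)
}

# Project one scaled observation (with possible missing entries) on the
# loadings; scores by least squares over the present entries.
.project_obs <- function(x, P, A) {
  m <- !is.na(x)
  k <- sum(m)
  if (k <= A) return(NULL) # not enough detected variables to leave residual df
  Pm <- P[m, , drop = FALSE]
  t <- tryCatch(qr.solve(Pm, x[m]), error = function(e) NULL)
  if (is.null(t)) return(NULL)
  e <- x[m] - as.vector(Pm %*% t)
  list(t = t, rss = sum(e^2), k = k)
}

#' Distance to model (DModX) and membership at a critical limit
#'
#' For each observation the residual after projection on the model's
#' loadings gives an absolute residual standard deviation
#' `s_i = sqrt(RSS_i / (K - A))` (with the observation's detected-variable
#' count in place of `K` when entries are missing). Normalising by the
#' model's pooled `s0` gives DModX: in `"workset"` mode (training
#' observations) the small-sample factor `sqrt(N/(N - A - A0))` is included;
#' in `"prediction"` mode (new observations, "DModX PS") it is not. An
#' observation is a member of the class when its DModX does not exceed
#' `Dcrit = sqrt(F_{1-alpha}(K - A, (N - A - A0)(K - A)))`; every sample
#' above `Dcrit` does not belong to the population at significance `alpha`.
#'
#' @param model A `pca_class_model`.
#' @param newdata A `fingerprint_table` (or scaled-space matrix), or `NULL`
#'   to evaluate the training set.
#' @param alpha Significance level in (0, 0.5], default 0.05 (the 95% limit).
#' @param mode `"prediction"` or `"workset"`; defaults to `"workset"` for
#'   training data and `"prediction"` otherwise.
#' @return An object of class `dmodx_report`: data frame `obs` with columns
#'   `sample_id`, `s_i`, `dmodx`, `member`, plus `dcrit`, `alpha`, `mode`.
#' @export
dmodx <- function(model, newdata = NULL, alpha = 0.05, mode = NULL) {
  stopifnot(inherits(model, "pca_class_model"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 0.5) {
    stop("alpha must lie in (0, 0.5]")
  }
  A <- model$A; A0 <- model$A0; N <- model$N; K <- model$K
  if (K <= A) stop("no residual degrees of freedom: K <= A")
  if (is.null(mode)) mode <- if (is.null(newdata)) "workset" else "prediction"
  mode <- match.arg(mode, c("workset", "prediction"))
  if (is.null(newdata)) {
    Xs <- model$X_scaled
    ids <- model$sample_id
  } else if (inherits(newdata, "fingerprint_table")) {
    tab <- ft_elements(newdata, model$panel_used)
    Xs <- apply_scaling(model$scaling, tab$values)
    ids <- tab$meta$sample_id
  } else {
    Xs <- as.matrix(newdata)
    if (ncol(Xs) != K) stop("newdata must have ", K, " columns (scaled space)")
    ids <- rownames(Xs)
    if (is.null(ids)) ids <- sprintf("obs%03d", seq_len(nrow(Xs)))
  }
  s_i <- rep(NA_real_, nrow(Xs))
  for (i in seq_len(nrow(Xs))) {
    pr <- .project_obs(Xs[i, ], model$P, A)
    if (is.null(pr)) next
    s_i[i] <- sqrt(pr$rss / (pr$k - A))
  }
  corr <- if (mode == "workset") sqrt(N / (N - A - A0)) else 1
  d <- (s_i / model$s0) * corr
  dcrit <- sqrt(stats::qf(1 - alpha, K - A, (N - A - A0) * (K - A)))
  member <- !is.na(d) & d <= dcrit
  structure(list(obs = data.frame(sample_id = ids, s_i = s_i, dmodx = d,
                                  member = member, stringsAsFactors = FALSE),
                 dcrit = dcrit, alpha = alpha, mode = mode,
                 class_key = model$class_key),
            class = "dmodx_report")
}

#' @export
print.dmodx_report <- function(x, ...) {
  cat("<dmodx_report> model ", x$class_key, " (", x$mode, " mode), Dcrit(alpha=",
      x$alpha, ") = ", sprintf("%.3f", x$dcrit), "\n", sep = "")
  cat("  members: ", sum(x$obs$member), " / ", nrow(x$obs), "\n", sep = "")
  invisible(x)
}

#' Iterative loading-plot variable elimination
#'
#' Emulates the manual workflow of removing elements that sit at (or very
#' close to) the centre of the loading plot and refitting: at each pass the
#' loading-plot radius `r_k = sqrt(p_k1^2 + p_k2^2)` (or `|p_k1|` for a
#' one-component model) is computed and every element with
#' `r_k < tau * max(r_k)` is removed, until nothing is removed or fewer than
#' `min_vars` elements would remain.
#'
#' @param table A `fingerprint_table` of one class (or class pair).
#' @param A Components for each fit.
#' @param tau Relative radius threshold in (0, 1), default 0.15.
#' @param min_vars Minimum panel size to retain, `>= 2` (default 4).
#' @param ... Passed to [fit_pca_class()].
#' @return List with `panel` (retained elements) and `model` (the final
#'   `pca_class_model`).
#' @export
select_variables_by_loadings <- function(table, A = 3L, tau = 0.15,
                                         min_vars = 4L, ...) {
  stopifnot(inherits(table, "fingerprint_table"))
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)")
  if (min_vars < 2L) stop("min_vars must be >= 2")
  current <- table
  repeat {
    model <- fit_pca_class(current, A = A, ...)
    if (length(model$panel_used) < min_vars) {
      stop("fewer than min_vars = ", min_vars, " usable elements")
    }
    P <- model$P
    r <- if (ncol(P) >= 2L) sqrt(P[, 1]^2 + P[, 2]^2) else abs(P[, 1])
    drop <- model$panel_used[r < tau * max(r)]
    keep <- setdiff(model$panel_used, drop)
    if (length(drop) == 0L || length(keep) < min_vars) {
      return(list(panel = model$panel_used, model = model))
    }
    current <- ft_elements(current, keep)
  }
}

# jsonlite simplifies a serialized list of matrix columns to a transposed
# matrix (one row per column), a single column to a bare vector.
.json_cols <- function(x) {
  if (is.matrix(x)) t(x)
  else if (is.list(x)) do.call(cbind, lapply(x, unlist))
  else matrix(unlist(x), ncol = 1L)
}

#' Serialize a PCA class model to JSON
#' @param model A `pca_class_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pca_model <- function(model, path) {
  stopifnot(inherits(model, "pca_class_model"))
  doc <- list(class_key = model$class_key, panel_used = model$panel_used,
              scaling = list(means = as.list(model$scaling$means),
                             sds = as.list(model$scaling$sds),
                             method = model$scaling$method),
              A = model$A, A0 = model$A0, N = model$N, K = model$K,
              P = apply(model$P, 2L, identity, simplify = FALSE),
              r2x_per_component = model$r2x_per_component,
              q2_cum = model$q2_cum, s0 = model$s0)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a PCA class model from JSON
#'
#' Restores everything needed for prediction-mode DModX (scores and the
#' scaled training matrix are not serialized, so workset-mode re-evaluation
#' of the training set is not available on a deserialized model).
#'
#' @param path Path written by [write_pca_model()].
#' @return A `pca_class_model`.
#' @export
read_pca_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- structure(list(means = unlist(doc$scaling$means),
                       sds = unlist(doc$scaling$sds),
                       method = doc$scaling$method),
                  class = "scaling_params")
  P <- .json_cols(doc$P)
  rownames(P) <- doc$panel_used
  structure(list(class_key = doc$class_key, panel_used = doc$panel_used,
                 scaling = sc, A = doc$A, A0 = doc$A0, N = doc$N, K = doc$K,
                 T = NULL, P = P,
                 r2x_per_component = doc$r2x_per_component,
                 q2_cum = doc$q2_cum, s0 = doc$s0,
                 X_scaled = NULL, sample_id = NULL),
            class = "pca_class_model")
}
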