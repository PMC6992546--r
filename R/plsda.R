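# Two-class PLS discriminant analysis (PLS1 against a 0/1 dummy response).
# The label-verification cascade only ever opposes the labelled class to one
# competing class at a time, so a single-response PLS1 gives the same
# decision boundary as a two-column dummy PLS2 with less machinery.

# PLS1 NIPALS recursion on a complete centred/scaled matrix.
.pls1 <- function(Xs, yc, A) {
  N <- nrow(Xs); K <- ncol(Xs)
  W <- matrix(0, K, A); P <- matrix(0, K, A); Cc <- numeric(A)
  Tm <- matrix(0, N, A)
  Xa <- Xs; ya <- yc
  for (a in seq_len(A)) {
    w <- as.vector(crossprod(Xa, ya))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) { # response fully deflated; stop early
      W <- W[, seq_len(a - 1L), drop = FALSE]
      P <- P[, seq_len(a - 1L), drop = FALSE]
      Tm <- Tm[, seq_len(a - 1L), drop = FALSE]
      Cc <- Cc[seq_len(a - 1L)]
      break
    }
    w <- w / nw
    t <- as.vector(Xa %*% w)
    tt <- sum(t^2)
    cc <- sum(t * ya) / tt
    p <- as.vector(crossprod(Xa, t)) / tt
    Xa <- Xa - tcrossprod(t, p)
    ya <- ya - cc * t
    W[, a] <- w; P[, a] <- p; Cc[a] <- cc; Tm[, a] <- t
  }
  b <- as.vector(W %*% solve(crossprod(P, W), Cc))
  list(W = W, P = P, c = Cc, T = Tm, b = b, y_res = ya)
}

# Regression vector of the leading `a`-component sub-model.
.pls1_b <- function(fit, a) {
  W <- fit$W[, seq_len(a), drop = FALSE]
  P <- fit$P[, seq_len(a), drop = FALSE]
  as.vector(W %*% solve(crossprod(P, W), fit$c[seq_len(a)]))
}

# Scale a pair table for PLS: drop sparsely detected elements, centre/scale
# by the pooled statistics, impute remaining non-detects at the column mean
# (zero in scaled space), and remember which cells were imputed.
.plsda_design <- function(table, min_detect = 3L, scaling = "uv") {
  n_det <- colSums(table$detected)
  keep <- table$panel[n_det >= min_detect]
  if (length(keep) < 2L) stop("fewer than 2 elements usable for PLS-DA")
  tab <- ft_elements(table, keep)
  sc <- fit_scaling(tab, scaling)
  Xs <- apply_scaling(sc, tab$values)
  imputed <- is.na(Xs)
  Xs[imputed] <- 0
  list(Xs = Xs, scaling = sc, panel = keep, imputed = imputed, table = tab)
}

#' Fit a two-class PLS-DA model
#'
#' NIPALS PLS1 of the centred/scaled element matrix against the centred 0/1
#' class coding (`class_pair[1]` coded 0, `class_pair[2]` coded 1). The
#' regression vector `b` is assembled from the weights, loadings and inner
#' coefficients; a new observation scores
#' `yhat = mean(y) + x_scaled . b` and is assigned class 1 when
#' `yhat >= threshold`. `q2y` comes from row-wise leave-group-out
#' cross-validation with 7 round-robin groups (leave-one-out below 7 rows).
#' Non-detects are imputed at the column mean (zero in scaled space) after
#' dropping elements detected fewer than `min_detect` times.
#'
#' @param table A `fingerprint_table` containing both classes.
#' @param class_pair Character(2) of class keys (see [class_key()]); rows of
#'   other classes are rejected. Defaults to the two keys present.
#' @param A Component cap, `>= 1`; study convention at most 3, with 5 used
#'   for one hard robinia pair. Capped at `min(N-1, K)`.
#' @param select `"q2"` (default) keeps the number of components (up to
#'   `A`) that maximises the cross-validated `q2y` — some pairs separate
#'   with a single component and more would only fit noise; `"fixed"` uses
#'   exactly `A` components.
#' @param threshold Decision cut on the 0/1 response scale, default 0.5.
#' @param min_detect Minimum detected values per retained element.
#' @param scaling Scaling method for [fit_scaling()].
#' @return An object of class `plsda_model`.
#' @export
fit_plsda <- function(table, class_pair = NULL, A = 3L,
                      select = c("q2", "fixed"), threshold = 0.5,
                      min_detect = 3L, scaling = "uv") {
  select <- match.arg(select)
  stopifnot(inherits(table, "fingerprint_table"))
  keys <- class_keys(table)
  if (is.null(class_pair)) class_pair <- unique(keys)
  if (length(class_pair) != 2L) stop("exactly two classes are required")
  if (!all(keys %in% class_pair)) {
    stop("table contains rows outside the class pair: ",
         paste(setdiff(unique(keys), class_pair), collapse = ", "))
  }
  y <- as.numeric(keys == class_pair[2])
  if (sum(y == 0) < 2L || sum(y == 1) < 2L) {
    stop("both classes need at least 2 rows")
  }
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  des <- .plsda_design(table, min_detect = min_detect, scaling = scaling)
  N <- nrow(des$Xs); K <- ncol(des$Xs)
  if (!is.numeric(A) || length(A) != 1L || A < 1) stop("A must be an integer >= 1")
  A <- min(as.integer(A), N - 1L, K)
  y_mean <- mean(y)
  ss_y <- sum((y - y_mean)^2)

  # row-wise leave-group-out CV, accumulating PRESS for every sub-model
  # with 1..A components
  G <- if (N < 7L) N else 7L
  fold <- (seq_len(N) - 1L) %% G
  press <- numeric(A)
  for (g in seq_len(G) - 1L) {
    inb <- fold != g
    if (length(unique(y[inb])) < 2L) next
    sc_g <- fit_scaling(des$table$values[inb, , drop = FALSE], scaling)
    Xg <- apply_scaling(sc_g, des$table$values[inb, , drop = FALSE])
    Xg[is.na(Xg)] <- 0
    yg <- y[inb]
    Ag <- min(A, sum(inb) - 1L)
    fg <- .pls1(Xg, yg - mean(yg), Ag)
    Xt <- apply_scaling(sc_g, des$table$values[!inb, , drop = FALSE])
    Xt[is.na(Xt)] <- 0
    for (a in seq_len(A)) {
      aa <- min(a, ncol(fg$W))
      pred <- mean(yg) + as.vector(Xt %*% .pls1_b(fg, aa))
      press[a] <- press[a] + sum((y[!inb] - pred)^2)
    }
  }
  q2y_by_a <- 1 - press / ss_y
  A_used <- if (select == "q2") which.max(q2y_by_a) else A
  q2y <- q2y_by_a[A_used]

  fit <- .pls1(des$Xs, y - y_mean, A_used)
  r2y <- 1 - sum(fit$y_res^2) / ss_y

  structure(list(class_pair = class_pair, panel_used = des$panel,
                 scaling = des$scaling, A = ncol(fit$W),
                 W = fit$W, P = fit$P, c = fit$c, b = fit$b,
                 y_mean = y_mean, threshold = threshold,
                 r2y = r2y, q2y = q2y, N = N, K = K),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat("<plsda_model> ", x$class_pair[1], " (0) vs ", x$class_pair[2],
      " (1): N=", x$N, ", K=", x$K, ", A=", x$A, "\n", sep = "")
  cat("  R2Y = ", sprintf("%.3f", x$r2y), ", Q2Y = ", sprintf("%.3f", x$q2y),
      "\n", sep = "")
  invisible(x)
}

#' Predict class membership with a PLS-DA model
#'
#' @param model A `plsda_model`.
#' @param table A `fingerprint_table` of query samples.
#' @return Data frame with `sample_id`, `score` (predicted 0/1 response),
#'   `class` (the winning class key), and `imputed` (TRUE when any panel
#'   element of the sample was a non-detect and entered as the scaled zero).
#' @export
predict_plsda <- function(model, table) {
  stopifnot(inherits(model, "plsda_model"), inherits(table, "fingerprint_table"))
  tab <- ft_elements(table, model$panel_used)
  Xs <- apply_scaling(model$scaling, tab$values)
  imputed <- rowSums(is.na(Xs)) > 0
  Xs[is.na(Xs)] <- 0
  score <- model$y_mean + as.vector(Xs %*% model$b)
  data.frame(sample_id = tab$meta$sample_id,
             score = score,
             class = ifelse(score >= model$threshold,
                            model$class_pair[2], model$class_pair[1]),
             imputed = imputed,
             stringsAsFactors = FALSE)
}

#' Serialize / deserialize a PLS-DA model
#' @param model A `plsda_model`.
#' @param path File path.
#' @return `path` invisibly; `read_plsda_model()` returns a `plsda_model`.
#' @export
write_plsda_model <- function(model, path) {
  stopifnot(inherits(model, "plsda_model"))
  doc <- list(class_pair = model$class_pair, panel_used = model$panel_used,
              scaling = list(means = as.list(model$scaling$means),
                             sds = as.list(model$scaling$sds),
                             method = model$scaling$method),
              A = model$A,
              W = apply(model$W, 2L, identity, simplify = FALSE),
              P = apply(model$P, 2L, identity, simplify = FALSE),
              c = model$c, b = model$b, y_mean = model$y_mean,
              threshold = model$threshold, r2y = model$r2y, q2y = model$q2y,
              N = model$N, K = model$K)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_plsda_model
#' @export
read_plsda_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- structure(list(means = unlist(doc$scaling$means),
                       sds = unlist(doc$scaling$sds),
                       method = doc$scaling$method),
                  class = "scaling_params")
  structure(list(class_pair = doc$class_pair, panel_used = doc$panel_used,
                 scaling = sc, A = doc$A,
                 W = .json_cols(doc$W), P = .json_cols(doc$P),
                 c = doc$c, b = doc$b, y_mean = doc$y_mean,
                 threshold = doc$threshold, r2y = doc$r2y, q2y = doc$q2y,
                 N = doc$N, K = doc$K),
            class = "plsda_model")
}
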