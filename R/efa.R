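#' Eigenvalues of the item correlation matrix
#'
#' @param x numeric matrix, observations in rows, items in columns
#' @return eigenvalues of the Pearson correlation matrix, descending; their
#'   sum equals the number of items
#' @export
correlation_eigenvalues <- function(x) {
  x <- as.matrix(x)
  const <- which(apply(x, 2, stats::sd) == 0)
  if (length(const))
    stop_msrs("constant column(s): ", paste(colnames(x)[const] %||% const, collapse = ", "),
              class = "msrs_degenerate_error")
  sort(eigen(stats::cor(x), symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

#' Bootstrap eigenvalue confidence intervals and factor retention
#'
#' Strengthens the Kaiser "eigenvalues greater-than-one" rule: rows
#' (subjects) are resampled with replacement, ordered eigenvalues are
#' recorded per replicate, and a factor is retained when the lower bound of
#' the percentile CI of its ordered eigenvalue exceeds 1.
#'
#' @inheritParams correlation_eigenvalues
#' @param n_boot bootstrap replicates (>= 100; percentiles are unstable below)
#' @param seed RNG seed
#' @param level CI level (default 0.95, percentile method)
#' @return list of class `msrs_eigen`: `eigenvalues`, `boot_median`,
#'   `ci_lower`, `ci_upper`, `n_retained`, `n_boot`, `level`, `seed`
#' @export
bootstrap_eigen_retention <- function(x, n_boot = 10000, seed = NULL, level = 0.95) {
  if (n_boot < 100)
    stop_msrs("n_boot < 100 gives unstable percentile CIs; refusing",
              class = "msrs_domain_error")
  x <- as.matrix(x)
  ev <- correlation_eigenvalues(x)
  p <- ncol(x); n <- nrow(x)
  boot <- with_seed(seed, {
    out <- matrix(NA_real_, n_boot, p)
    b <- 0L
    while (b < n_boot) {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- x[idx, , drop = FALSE]
      if (any(apply(xb, 2, stats::sd) == 0)) next  # degenerate resample, redraw
      b <- b + 1L
      out[b, ] <- sort(eigen(stats::cor(xb), symmetric = TRUE, only.values = TRUE)$values,
                       decreasing = TRUE)
    }
    out
  })
  a <- (1 - level) / 2
  qs <- apply(boot, 2, stats::quantile, probs = c(a, 0.5, 1 - a), names = FALSE)
  structure(list(eigenvalues = ev,
                 boot_median = qs[2, ], ci_lower = qs[1, ], ci_upper = qs[3, ],
                 n_retained = sum(qs[1, ] > 1),
                 n_boot = n_boot, level = level, seed = seed),
            class = "msrs_eigen")
}

#' @export
print.msrs_eigen <- function(x, ...) {
  cat(sprintf("<msrs_eigen> %d eigenvalue(s) with lower %.0f%% CI > 1 (of %d)\n",
              x$n_retained, 100 * x$level, length(x$eigenvalues)))
  invisible(x)
}

#' Varimax rotation
#'
#' Orthogonal rotation maximizing the varimax simple-structure criterion by
#' cyclic pairwise planar rotations with the classical closed-form angle
#' (`4*theta = atan2(D - 2AB/p, C - (A^2 - B^2)/p)` per factor pair). The
#' closed form solves each pair exactly, which keeps the sweep from stalling
#' on symmetric loading patterns where gradient-projection iterations
#' converge too slowly. Row communalities are preserved. A single-factor
#' matrix is returned unchanged.
#'
#' @param loadings p x K loading matrix
#' @param tol convergence tolerance on the largest pair rotation angle
#' @param max_iter maximum number of full pair sweeps
#' @param normalize apply Kaiser row normalization during rotation (the
#'   convention used by `factanal`'s varimax)
#' @return rotated loading matrix with attribute `"rotmat"`
#' @export
varimax_rotate <- function(loadings, tol = 1e-8, max_iter = 1000, normalize = TRUE) {
  L <- as.matrix(loadings)
  K <- ncol(L)
  if (K < 2) {
    attr(L, "rotmat") <- diag(K)
    return(L)
  }
  h <- rep(1, nrow(L))
  if (normalize) {
    h <- sqrt(rowSums(L^2))
    h[h == 0] <- 1
  }
  Z <- L / h
  p <- nrow(Z)
  rotmat <- diag(K)
  for (sweep in seq_len(max_iter)) {
    max_angle <- 0
    for (i in seq_len(K - 1)) for (j in (i + 1):K) {
      x <- Z[, i]; y <- Z[, j]
      u <- x^2 - y^2; v <- 2 * x * y
      A <- sum(u); B <- sum(v)
      num <- sum(2 * u * v) - 2 * A * B / p
      den <- sum(u^2 - v^2) - (A^2 - B^2) / p
      theta <- atan2(num, den) / 4
      if (abs(theta) > tol) {
        G <- diag(K)
        G[i, i] <- G[j, j] <- cos(theta)
        G[i, j] <- -sin(theta); G[j, i] <- sin(theta)
        Z <- Z %*% G
        rotmat <- rotmat %*% G
        max_angle <- max(max_angle, abs(theta))
      }
    }
    if (max_angle <= tol) break
  }
  out <- Z * h
  dimnames(out) <- dimnames(L)
  attr(out, "rotmat") <- rotmat
  out
}

varimax_criterion <- function(L) {
  # sum over factors of the variance of squared loadings
  sum(apply(L^2, 2, function(u) sum((u - mean(u))^2))) / nrow(L)
}

#' Maximum-likelihood exploratory factor analysis
#'
#' ML extraction on the Pearson correlation matrix (via `factanal`),
#' optionally varimax-rotated. Uniquenesses are bounded to \[0.005, 1\], so
#' Heywood cases are clamped at the boundary (a warning is emitted when a
#' uniqueness sits on the bound). Percent variance explained per factor is
#' `100 * colSums(loadings^2) / p`.
#'
#' @inheritParams correlation_eigenvalues
#' @param k number of factors, `1 <= k < p`
#' @param rotation `"varimax"` or `"none"`
#' @return list of class `msrs_efa`: `loadings` (p x k), `uniquenesses`,
#'   `communalities`, `var_explained` (percent), `k`, `rotation`, `n`
#' @export
fit_efa <- function(x, k, rotation = c("varimax", "none")) {
  rotation <- match.arg(rotation)
  x <- as.matrix(x)
  p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(p))
  if (!is_count(k) || k < 1 || k >= p)
    stop_msrs("k must satisfy 1 <= k < p", class = "msrs_domain_error")
  R <- stats::cor(x)
  if (anyNA(R))
    stop_msrs("correlation matrix has NA (constant column?)", class = "msrs_degenerate_error")
  fit <- tryCatch(
    stats::factanal(covmat = R, n.obs = nrow(x), factors = k, rotation = "none",
                    control = list(lower = 0.005)),
    error = function(e) stop_msrs("factor extraction failed to converge: ",
                                  conditionMessage(e), class = "msrs_convergence_error"))
  L <- unclass(fit$loadings)[, , drop = FALSE]
  if (rotation == "varimax" && k > 1) L <- varimax_rotate(L)
  u <- fit$uniquenesses
  if (any(u <= 0.005 + 1e-12))
    warning("Heywood case: ", sum(u <= 0.005 + 1e-12),
            " uniqueness(es) clamped at the 0.005 lower bound")
  # order factors by explained variance, fix sign so column sums are positive
  ssl <- colSums(L^2)
  ord <- order(ssl, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  sgn <- ifelse(colSums(L) < 0, -1, 1)
  L <- sweep(L, 2, sgn, `*`)
  dimnames(L) <- list(colnames(x), paste0("F", seq_len(k)))
  structure(list(loadings = L,
                 uniquenesses = stats::setNames(u, colnames(x)),
                 communalities = stats::setNames(1 - u, colnames(x)),
                 var_explained = 100 * colSums(L^2) / p,
                 k = k, rotation = rotation, n = nrow(x)),
            class = "msrs_efa")
}

#' @export
print.msrs_efa <- function(x, ...) {
  cat(sprintf("<msrs_efa> %d items, %d factor(s) [%s]; %% variance: %s\n",
              nrow(x$loadings), x$k, x$rotation,
              paste(sprintf("%.2f", x$var_explained), collapse = " / ")))
  invisible(x)
}

#' Tucker congruence between two loading vectors
#' @param a,b numeric vectors of equal length
#' @return cosine similarity in \[-1, 1\]
#' @export
tucker_congruence <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

#' Align a loading matrix to a reference solution
#'
#' Resolves the order and sign indeterminacy of factor solutions across
#' bootstrap replicates: factors are matched one-to-one to the reference by
#' greedy maximal absolute Tucker congruence, and a matched column's sign is
#' flipped when its congruence is negative.
#'
#' @param L loading matrix to align
#' @param ref reference loading matrix (same dimensions)
#' @return aligned matrix with attributes `perm` and `signs`
#' @export
align_factors <- function(L, ref) {
  L <- as.matrix(L); ref <- as.matrix(ref)
  stopifnot(identical(dim(L), dim(ref)))
  K <- ncol(L)
  C <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K))
    C[i, j] <- tucker_congruence(L[, i], ref[, j])
  perm <- integer(K); signs <- numeric(K)
  Cw <- abs(C)
  for (step in seq_len(K)) {
    ij <- arrayInd(which.max(Cw), dim(Cw))
    i <- ij[1]; j <- ij[2]
    perm[j] <- i
    signs[j] <- if (C[i, j] < 0) -1 else 1
    Cw[i, ] <- -Inf; Cw[, j] <- -Inf
  }
  out <- sweep(L[, perm, drop = FALSE], 2, signs, `*`)
  dimnames(out) <- dimnames(ref)
  attr(out, "perm") <- perm
  attr(out, "signs") <- signs
  out
}

#' Bootstrap factor loadings with percentile confidence intervals
#'
#' Resamples rows with replacement; each replicate is re-extracted
#' (ML + varimax), aligned to the full-sample rotated solution by
#' Tucker-congruence greedy matching with sign flips, and its loadings
#' recorded. Reported per cell: bootstrap median, percentile CI, and a
#' significance flag (CI strictly excludes 0). Replicates that fail to
#' converge (or resample a constant column) are redrawn and counted; more
#' than 20% failures aborts.
#'
#' @inheritParams fit_efa
#' @param n_boot bootstrap replicates
#' @param seed RNG seed
#' @param level CI level
#' @return list of class `msrs_efa_boot`: the full-sample `solution`
#'   (an `msrs_efa`), plus `boot_median`, `boot_lower`, `boot_upper`,
#'   `significant` (p x k matrices), `var_explained_median` /
#'   `var_explained_lower` / `var_explained_upper` (per factor, percent),
#'   `n_boot`, `n_failed`, `level`, `seed`, `alignment = "tucker_greedy"`
#' @export
bootstrap_loadings <- function(x, k, n_boot = 10000, seed = NULL, level = 0.95) {
  x <- as.matrix(x)
  full <- fit_efa(x, k, rotation = "varimax")
  p <- ncol(x); n <- nrow(x)
  boot <- array(NA_real_, c(n_boot, p, k))
  ve <- matrix(NA_real_, n_boot, k)
  n_failed <- 0L
  max_failed <- ceiling(0.2 * n_boot)
  with_seed(seed, {
    b <- 0L
    while (b < n_boot) {
      idx <- sample.int(n, n, replace = TRUE)
      Lb <- tryCatch({
        # Heywood-clamp warnings are routine inside replicates; the full-sample
        # fit already surfaced any, so keep the loop quiet
        fb <- suppressWarnings(fit_efa(x[idx, , drop = FALSE], k, rotation = "varimax"))
        fb$loadings
      }, error = function(e) NULL)
      if (is.null(Lb)) {
        n_failed <- n_failed + 1L
        if (n_failed > max_failed)
          stop_msrs("more than 20% of bootstrap replicates failed (",
                    n_failed, " failures)", class = "msrs_bootstrap_error")
        next
      }
      b <- b + 1L
      A <- align_factors(Lb, full$loadings)
      boot[b, , ] <- A
      ve[b, ] <- 100 * colSums(A^2) / p
    }
  })
  a <- (1 - level) / 2
  qfun <- function(probs) {
    out <- apply(boot, c(2, 3), stats::quantile, probs = probs, names = FALSE)
    dimnames(out) <- dimnames(full$loadings)
    out
  }
  lo <- qfun(a); med <- qfun(0.5); hi <- qfun(1 - a)
  structure(list(solution = full,
                 boot_median = med, boot_lower = lo, boot_upper = hi,
                 significant = lo > 0 | hi < 0,
                 var_explained_median = apply(ve, 2, stats::median),
                 var_explained_lower = apply(ve, 2, stats::quantile, probs = a),
                 var_explained_upper = apply(ve, 2, stats::quantile, probs = 1 - a),
                 n_boot = n_boot, n_failed = n_failed, level = level,
                 seed = seed, alignment = "tucker_greedy"),
            class = "msrs_efa_boot")
}

#' @export
print.msrs_efa_boot <- function(x, ...) {
  cat(sprintf("<msrs_efa_boot> %d replicates (%d failed), %d factor(s); %d significant loading(s)\n",
              x$n_boot, x$n_failed, x$solution$k, sum(x$significant)))
  invisible(x)
}

#' Items loading significantly on a factor
#'
#' An item is significant on a factor when the bootstrap CI of its loading
#' strictly excludes zero (an interval touching zero does not qualify).
#'
#' @param solution an `msrs_efa_boot`
#' @param factor factor index (1-based)
#' @return list with `positive` and `negative` item name vectors
#' @export
significant_items <- function(solution, factor = 1) {
  stopifnot(inherits(solution, "msrs_efa_boot"))
  if (!is_count(factor) || factor < 1 || factor > solution$solution$k)
    stop_msrs("factor index out of range", class = "msrs_domain_error")
  lo <- solution$boot_lower[, factor]
  hi <- solution$boot_upper[, factor]
  items <- rownames(solution$boot_lower)
  list(positive = items[lo > 0], negative = items[hi < 0])
}
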