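# Independent oracle implementations used to cross-check the package's
# statistics. These deliberately take different computational routes than
# the code under test.

# Sup-distance between the ECDF of x and Normal(mean(x), sd(x)), by brute
# evaluation of the step function just left and right of every jump.
oracle_lilliefors_stat <- function(x) {
  x <- sort(x)
  n <- length(x)
  Fhat <- stats::ecdf(x)
  eps <- 1e-9  # smaller than any gap between distinct sorted values
  z <- stats::pnorm(x, mean(x), stats::sd(x))
  max(abs(Fhat(x) - z), abs(Fhat(x - eps) - z))
}

# Two-way ANOVA mean squares via R's aov(), then the average-measures ICCs.
oracle_icc <- function(m, variant) {
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(nrow(m)), ncol(m))),
                   rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  if (variant == "consistency") (msr - mse) / msr
  else (msr - mse) / (msr + (msc - mse) / nrow(m))
}

# Cronbach's alpha from the covariance matrix: k/(k-1) * (1 - tr(C)/sum(C)).
oracle_alpha <- function(m) {
  C <- stats::cov(m)
  k <- ncol(m)
  k / (k - 1) * (1 - sum(diag(C)) / sum(C))
}

# Pearson correlation matrix assembled entry-by-entry from first principles.
oracle_cor <- function(x) {
  p <- ncol(x)
  R <- diag(p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    a <- x[, i] - mean(x[, i]); b <- x[, j] - mean(x[, j])
    R[i, j] <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }
  R
}

# Spearman rho: midranks built by hand from sorted positions, then the
# explicit product-moment formula.
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (val in unique(v)) r[v == val] <- mean(which(sort(v) == val))
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  a <- rx - mean(rx); b <- ry - mean(ry)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# Varimax criterion (variance of squared loadings per factor, summed).
oracle_varimax_criterion <- function(L) {
  sum(apply(L^2, 2, function(u) sum((u - mean(u))^2))) / nrow(L)
}

# Random orthogonal K x K matrix (QR of a Gaussian matrix).
random_orthogonal <- function(K) {
  qr.Q(qr(matrix(stats::rnorm(K * K), K, K)))
}

# Small complete survey table built directly from a response matrix
# (surveys x items), bypassing the generator.
table_from_matrix <- function(resp, rater_id, monkey_id,
                              questionnaire = NULL) {
  p <- ncol(resp)
  if (is.null(questionnaire))
    questionnaire <- msrs_questionnaire(data.frame(
      item_id = seq_len(p), text = paste("item", seq_len(p)),
      reverse_keyed = FALSE))
  long <- data.frame(rater_id = rep(rater_id, each = p),
                     monkey_id = rep(monkey_id, each = p),
                     item_id = rep(seq_len(p), length(rater_id)),
                     response = as.integer(t(resp)))
  msrs_survey(long, questionnaire)
}
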