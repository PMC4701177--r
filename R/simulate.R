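#' Simulation configuration for synthetic multi-rater surveys
#'
#' Describes an ordinal latent-factor world: each monkey has factor scores,
#' each item a loading row, raters observe the item latents with their own
#' noise, and observations are discretized to the 1..4 response scale by
#' fixed thresholds. Three item classes are supported: *loaded* items
#' (rows of `loadings` with nonzero norm), *anti-correlated* items
#' (`anticorr_items`; raters see a shared per-monkey value whose sign
#' alternates with rater parity, driving Cronbach's alpha negative), and
#' *zero-variance* items (a constant response).
#'
#' @param n_monkeys number of monkeys in the sparse main sample
#' @param n_items number of questionnaire items
#' @param loadings `n_items x K` generating loading matrix (zero rows allowed)
#' @param factor_corr `K x K` factor correlation matrix
#' @param rater_noise_sd per-rater observation noise SD (recycled across all
#'   raters, sparse then block)
#' @param thresholds 3 strictly increasing cutpoints mapping latents to 1..4
#' @param reverse_keyed item ids emitted flipped (so scoring un-flips them)
#' @param zero_variance_items item ids emitting a constant response
#' @param anticorr_items item ids with rater-parity anti-correlated noise
#' @param anticorr_scale latent scale of the anti-correlated component
#' @param missing_rate probability a response is skipped (`NA`)
#' @param design list with optional `sparse = list(n_raters, n_surveys)` and
#'   `block = list(n_raters, n_monkeys)` components
#' @param age_effect per-year shift of factor 1 (age centered at its mean)
#' @param rank_effect named shifts of factor 1 per rank level
#' @param contaminants list `(n, shift)`: monkeys with elevated factor-1
#'   scores, inducing the positive tail / outlier structure
#' @param sex_split named counts or weights `c(female=, male=)`
#' @param seed default RNG seed used by [simulate_survey()]
#' @param metadata free-form list carried through to the truth object
#' @return validated list of class `msrs_sim_config`
#' @export
sim_config <- function(n_monkeys = 105, n_items = 36,
                       loadings = NULL, factor_corr = NULL,
                       rater_noise_sd = 0.25,
                       thresholds = c(-1, 0.5, 1.5),
                       reverse_keyed = integer(0),
                       zero_variance_items = integer(0),
                       anticorr_items = integer(0),
                       anticorr_scale = 0.9,
                       missing_rate = 0,
                       design = list(sparse = list(n_raters = 15, n_surveys = 175),
                                     block = NULL),
                       age_effect = 0, rank_effect = c(low = 0, middle = 0, high = 0, unknown = 0),
                       contaminants = list(n = 0, shift = 0),
                       sex_split = c(female = 0.85, male = 0.15),
                       seed = 1L, metadata = list()) {
  if (is.null(loadings)) loadings <- matrix(0.6, n_items, 1)
  loadings <- as.matrix(loadings)
  K <- ncol(loadings)
  if (is.null(factor_corr)) factor_corr <- diag(K)
  if (nrow(loadings) != n_items)
    stop_msrs("loadings must have n_items rows", class = "msrs_config_error")
  if (!identical(dim(factor_corr), c(K, K)))
    stop_msrs("factor_corr must be K x K", class = "msrs_config_error")
  if (length(thresholds) != 3 || any(diff(thresholds) <= 0))
    stop_msrs("thresholds must be 3 strictly increasing cutpoints",
              class = "msrs_config_error")
  if (missing_rate < 0 || missing_rate >= 1)
    stop_msrs("missing_rate must be in [0, 1)", class = "msrs_config_error")
  for (ids in list(reverse_keyed, zero_variance_items, anticorr_items))
    if (length(ids) && !all(ids %in% seq_len(n_items)))
      stop_msrs("item id set outside 1..n_items", class = "msrs_config_error")
  if (is.null(design$sparse) && is.null(design$block))
    stop_msrs("design needs at least one of sparse/block", class = "msrs_config_error")
  structure(list(n_monkeys = n_monkeys, n_items = n_items, loadings = loadings,
                 n_factors = K, factor_corr = factor_corr,
                 rater_noise_sd = rater_noise_sd, thresholds = thresholds,
                 reverse_keyed = as.integer(reverse_keyed),
                 zero_variance_items = as.integer(zero_variance_items),
                 anticorr_items = as.integer(anticorr_items),
                 anticorr_scale = anticorr_scale,
                 missing_rate = missing_rate, design = design,
                 age_effect = age_effect, rank_effect = rank_effect,
                 contaminants = contaminants, sex_split = sex_split,
                 seed = seed, metadata = metadata),
            class = "msrs_sim_config")
}

#' Canonical preset mirroring the validation study's design
#'
#' 36 items over 3 latent factors: 17 rater-reliable items (12 loading on
#' factor 1, two of them negatively, 3 on factor 2, 2 on factor 3 plus mild
#' cross-loadings), 14 anti-correlated (unreliable) items, and 5
#' zero-variance items (7, 19, 24, 25, 30). The sparse design has 15 raters
#' completing 175 surveys on 105 monkeys; a separate complete block has 4
#' raters scoring 16 additional females. Mild positive age effect, rank
#' ordering low > middle > high, and 6 contaminant monkeys with elevated
#' factor-1 scores give the totals a positive skew with upper outliers.
#'
#' @param seed default seed stored in the config
#' @return an `msrs_sim_config`
#' @export
paperlike_preset <- function(seed = 1L) {
  p <- 36
  L <- matrix(0, p, 3)
  f1 <- c(`1` = 0.65, `2` = -0.45, `3` = 0.80, `5` = -0.40, `9` = 0.65,
          `10` = 0.75, `13` = 0.50, `15` = 0.70, `17` = 0.75, `18` = 0.80,
          `21` = 0.50, `31` = 0.45)
  f2 <- c(`14` = 0.60, `23` = 0.55, `28` = 0.75)
  f3 <- c(`16` = 0.65, `26` = 0.70, `13` = 0.30, `21` = 0.35)
  L[as.integer(names(f1)), 1] <- f1
  L[as.integer(names(f2)), 2] <- f2
  L[as.integer(names(f3)), 3] <- f3
  q <- default_questionnaire()
  sim_config(
    n_monkeys = 105, n_items = p, loadings = L,
    rater_noise_sd = c(seq(0.2, 0.4, length.out = 15), rep(0.15, 4)),
    thresholds = c(-1, 0.5, 1.5),
    reverse_keyed = reverse_keyed_items(q),
    zero_variance_items = c(7L, 19L, 24L, 25L, 30L),
    anticorr_items = c(4L, 6L, 8L, 11L, 12L, 20L, 22L, 27L, 29L, 32L, 33L, 34L, 35L, 36L),
    anticorr_scale = 1.3,
    missing_rate = 0.01,
    design = list(sparse = list(n_raters = 15, n_surveys = 175),
                  block = list(n_raters = 4, n_monkeys = 16)),
    age_effect = 0.06,
    rank_effect = c(low = 0.8, middle = 0.4, high = 0, unknown = 0.4),
    contaminants = list(n = 6, shift = 2.2),
    sex_split = c(female = 91, male = 14),
    seed = seed,
    metadata = list(expect_positive_skew = TRUE,
                    reliable_items = sort(as.integer(unique(c(names(f1), names(f2), names(f3))))))
  )
}

#' Generate a synthetic survey dataset
#'
#' Draws monkeys' factor scores from a multivariate normal, forms item
#' latents `y* = loadings %*% eta + demographic shift + uniqueness noise`,
#' lets each rater observe `y*` plus rater noise, discretizes by the
#' config's thresholds to the 1..4 scale, flips reverse-keyed items on
#' emission, blanks responses at `missing_rate`, and writes constant
#' responses for zero-variance items. Deterministic given the seed.
#'
#' @param config an `msrs_sim_config`
#' @param seed overrides `config$seed`
#' @return list with `table` (an `msrs_survey`), `demographics`, `truth`
#'   (factor scores, shifts, generating loadings, assignment tables) and the
#'   `config`
#' @export
simulate_survey <- function(config, seed = NULL) {
  stopifnot(inherits(config, "msrs_sim_config"))
  seed <- seed %||% config$seed
  set.seed(seed)
  p <- config$n_items
  K <- config$n_factors
  sparse <- config$design$sparse
  block <- config$design$block
  n_main <- if (is.null(sparse)) 0L else config$n_monkeys
  n_block <- if (is.null(block)) 0L else block$n_monkeys
  n_all <- n_main + n_block
  n_raters_sparse <- if (is.null(sparse)) 0L else sparse$n_raters
  n_raters <- n_raters_sparse + (if (is.null(block)) 0L else block$n_raters)
  noise_sd <- rep_len(config$rater_noise_sd, n_raters)

  ## demographics -----------------------------------------------------------
  n_f <- round(n_all * config$sex_split[["female"]] / sum(config$sex_split))
  sex <- sample(c(rep("female", n_f), rep("male", n_all - n_f)))
  if (n_block > 0) sex[(n_main + 1):n_all] <- "female"  # block is an all-female group
  age <- round(stats::runif(n_all, 4, 25), 1)
  rank_levels <- c("low", "middle", "high", "unknown")
  rank <- sample(rank_levels, n_all, replace = TRUE,
                 prob = c(0.34, 0.20, 0.37, 0.09))
  demo <- msrs_demographics(data.frame(
    monkey_id = seq_len(n_all), age_years = age, sex = sex, rank = rank,
    housing = "compound"))

  ## latent structure -------------------------------------------------------
  Rchol <- chol(config$factor_corr)
  eta <- matrix(stats::rnorm(n_all * K), n_all, K) %*% Rchol
  contam_ids <- integer(0)
  if (config$contaminants$n > 0 && n_main > 0) {
    contam_ids <- sample(seq_len(n_main), config$contaminants$n)
    eta[contam_ids, 1] <- eta[contam_ids, 1] + config$contaminants$shift
  }
  shift <- config$age_effect * (age - mean(age)) +
    unname(config$rank_effect[rank])
  eta_shifted <- eta
  eta_shifted[, 1] <- eta_shifted[, 1] + shift

  uniq <- pmax(1 - rowSums(config$loadings^2), 0.05)
  ylat <- eta_shifted %*% t(config$loadings) +
    matrix(stats::rnorm(n_all * p, 0, rep(sqrt(uniq), each = n_all)), n_all, p)
  zanti <- matrix(stats::rnorm(n_all * p), n_all, p)  # shared anti-correlated latents

  ## survey assignment ------------------------------------------------------
  assign <- data.frame(rater_id = integer(), monkey_id = integer())
  if (!is.null(sparse)) {
    n_extra <- sparse$n_surveys - n_main
    if (n_extra < 0 || n_extra > n_main)
      stop_msrs("sparse n_surveys must be in [n_monkeys, 2*n_monkeys]",
                class = "msrs_config_error")
    primary <- sample.int(n_raters_sparse, n_main, replace = TRUE)
    assign <- data.frame(rater_id = primary, monkey_id = seq_len(n_main))
    extra_m <- sample(seq_len(n_main), n_extra)
    second <- ((primary[extra_m] - 1 + sample(1:2, n_extra, replace = TRUE)) %%
                 n_raters_sparse) + 1
    assign <- rbind(assign, data.frame(rater_id = second, monkey_id = extra_m))
  }
  if (!is.null(block)) {
    block_raters <- n_raters_sparse + seq_len(block$n_raters)
    block_monkeys <- n_main + seq_len(n_block)
    assign <- rbind(assign, expand.grid(rater_id = block_raters,
                                        monkey_id = block_monkeys))
  }

  ## responses --------------------------------------------------------------
  is_anti <- seq_len(p) %in% config$anticorr_items
  is_zero <- seq_len(p) %in% config$zero_variance_items
  is_rev <- seq_len(p) %in% config$reverse_keyed
  rows <- vector("list", nrow(assign))
  for (s in seq_len(nrow(assign))) {
    r <- assign$rater_id[s]; m <- assign$monkey_id[s]
    v <- ylat[m, ]
    if (r > n_raters_sparse) {
      # complete-block raters: shared per-monkey value with rater-parity
      # sign flips -> anti-correlated columns -> negative per-item alpha
      sgn <- if (r %% 2 == 0) -1 else 1
      v[is_anti] <- sgn * config$anticorr_scale * zanti[m, is_anti]
    } else {
      # sparse raters: rater-specific noise with no shared signal, so
      # unreliable items attenuate total-score ICCs without reversing them
      v[is_anti] <- config$anticorr_scale * stats::rnorm(sum(is_anti))
    }
    v <- v + stats::rnorm(p, 0, noise_sd[r])
    resp <- 1L + findInterval(v, config$thresholds)
    resp[is_zero] <- 1L
    resp[is_rev] <- 5L - resp[is_rev]
    if (config$missing_rate > 0)
      resp[stats::runif(p) < config$missing_rate] <- NA_integer_
    rows[[s]] <- data.frame(rater_id = r, monkey_id = m,
                            item_id = seq_len(p), response = resp)
  }
  responses <- do.call(rbind, rows)

  q <- if (p == 36 && identical(sort(config$reverse_keyed),
                                sort(reverse_keyed_items(default_questionnaire())))) {
    default_questionnaire()
  } else {
    msrs_questionnaire(data.frame(item_id = seq_len(p),
                                  text = sprintf("synthetic item %d", seq_len(p)),
                                  reverse_keyed = is_rev))
  }
  table <- msrs_survey(responses, q)

  truth <- list(factor_scores = eta, factor_scores_shifted = eta_shifted,
                demographic_shift = shift, loadings = config$loadings,
                uniquenesses = uniq, contaminant_ids = contam_ids,
                anticorr_items = config$anticorr_items,
                zero_variance_items = config$zero_variance_items,
                block_raters = if (is.null(block)) integer(0) else
                  n_raters_sparse + seq_len(block$n_raters),
                block_monkeys = if (is.null(block)) integer(0) else
                  n_main + seq_len(n_block),
                assignment = assign, seed = seed,
                metadata = config$metadata)
  list(table = table, demographics = demo, truth = truth, config = config)
}
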