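test_that("config validation rejects inconsistent inputs", {
  expect_error(sim_config(n_items = 4, loadings = matrix(0.5, 3, 1)),
               class = "msrs_config_error")
  expect_error(sim_config(thresholds = c(1, 0.5, 2)), class = "msrs_config_error")
  expect_error(sim_config(missing_rate = 1), class = "msrs_config_error")
  expect_error(sim_config(zero_variance_items = 99), class = "msrs_config_error")
  expect_error(sim_config(design = list()), class = "msrs_config_error")
})

test_that("same seed gives identical output; different seed does not", {
  cfg <- paperlike_preset()
  a <- simulate_survey(cfg, seed = 13)
  b <- simulate_survey(cfg, seed = 13)
  expect_identical(a$table$responses, b$table$responses)
  expect_identical(a$demographics, b$demographics)
  expect_identical(a$truth$factor_scores, b$truth$factor_scores)
  c3 <- simulate_survey(cfg, seed = 14)
  expect_false(identical(a$table$responses, c3$table$responses))
})

test_that("paperlike preset reproduces the design's dimensions", {
  cfg <- paperlike_preset()
  expect_equal(length(cfg$zero_variance_items), 5)
  expect_equal(length(cfg$anticorr_items), 14)
  expect_equal(length(cfg$metadata$reliable_items), 17)
  expect_length(intersect(cfg$anticorr_items, cfg$metadata$reliable_items), 0)
  expect_length(intersect(cfg$zero_variance_items, cfg$metadata$reliable_items), 0)
  expect_true(isTRUE(cfg$metadata$expect_positive_skew))

  sim <- simulate_survey(cfg, seed = 4)
  r <- sim$table$responses
  main <- r[r$rater_id <= 15, ]
  expect_equal(nrow(unique(main[c("rater_id", "monkey_id")])), 175)
  expect_equal(length(unique(main$monkey_id)), 105)
  block <- r[r$rater_id > 15, ]
  expect_equal(length(unique(block$rater_id)), 4)
  expect_equal(length(unique(block$monkey_id)), 16)
  expect_equal(nrow(unique(block[c("rater_id", "monkey_id")])), 64)
  # zero-variance items really are constant
  for (i in cfg$zero_variance_items)
    expect_equal(length(unique(na.omit(r$response[r$item_id == i]))), 1)
  # preset scores show the built-in positive skew
  sc <- per_monkey_scores(sim$table)
  expect_gt(skewness(sc), 0)
})

test_that("marginal response frequencies match the threshold-implied multinomial", {
  cfg <- sim_config(n_monkeys = 100, n_items = 4,
                    loadings = matrix(0, 4, 1),  # pure noise items, unit variance
                    rater_noise_sd = 0, thresholds = c(-1, 0.5, 1.5),
                    design = list(sparse = list(n_raters = 1, n_surveys = 100)))
  # uniqueness floor gives latent sd sqrt(0.05)+... -> compute implied probs
  sim <- simulate_survey(cfg, seed = 31)
  # latent here is N(0, 1) via uniqueness = 1 for zero-loading rows
  p_expect <- diff(c(0, pnorm(c(-1, 0.5, 1.5)), 1))
  obs <- table(factor(sim$table$responses$response, levels = 1:4))
  gof <- chisq.test(obs, p = p_expect)
  expect_gt(gof$p.value, 0.01)
})

test_that("increasing rater noise decreases pairwise ICC (expectation over seeds)", {
  icc_at <- function(noise, seed) {
    cfg <- sim_config(n_monkeys = 40, n_items = 10,
                      loadings = matrix(0.7, 10, 1), rater_noise_sd = noise,
                      design = list(block = list(n_raters = 3, n_monkeys = 40)),
                      seed = seed)
    sim <- simulate_survey(cfg)
    pairwise_icc(sim$table, min_shared = 3)$mean_icc
  }
  grid <- c(0.05, 0.8, 2.5)
  means <- vapply(grid, function(ns)
    mean(vapply(1:6, function(s) icc_at(ns, s), numeric(1))), numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("noiseless complete block gives identical raters downstream", {
  cfg <- sim_config(n_monkeys = 10, n_items = 12,
                    loadings = matrix(0.75, 12, 1), rater_noise_sd = 0,
                    design = list(block = list(n_raters = 4, n_monkeys = 18)),
                    seed = 77)
  sim <- simulate_survey(cfg)
  ism <- item_score_matrix(sim$table)
  # every rater saw the same latent: per-monkey responses identical across raters
  for (m in unique(ism$monkey_id)[1:5]) {
    rows <- ism$scores[ism$monkey_id == m, , drop = FALSE]
    expect_true(all(apply(rows, 2, function(v) length(unique(v)) == 1)))
  }
  pw <- pairwise_icc(sim$table, min_shared = 3)
  expect_true(all(pw$pairs$icc == 1))
})

test_that("reverse-keyed emission is undone by scoring", {
  q <- default_questionnaire()
  rev_items <- reverse_keyed_items(q)
  cfg <- paperlike_preset()
  sim <- simulate_survey(cfg, seed = 8)
  # raw responses on reverse-keyed zero-variance-free items differ from their
  # scored values by the flip; scoring maps emitted response back to latent scale
  ism <- item_score_matrix(sim$table)
  r <- sim$table$responses
  i <- intersect(rev_items, cfg$metadata$reliable_items)[1]
  sel <- r$item_id == i & !is.na(r$response)
  expect_true(all(score_item(r$response[sel], TRUE) == 4 - r$response[sel]))
})

test_that("full pipeline recovers a 1-factor generating structure", {
  L <- matrix(0, 17, 1)
  L[1:12, 1] <- 0.8
  # n must comfortably exceed p for the ordered-eigenvalue CI rule not to
  # retain spurious noise factors (see the methods vignette)
  cfg <- sim_config(n_monkeys = 300, n_items = 17, loadings = L,
                    rater_noise_sd = 0.2, thresholds = c(-1.2, 0, 1.2),
                    design = list(sparse = list(n_raters = 6, n_surveys = 600)),
                    seed = 3)
  hits <- vapply(1:3, function(s) {
    sim <- simulate_survey(cfg, seed = s)
    ism <- item_score_matrix(sim$table)
    xm <- ism$scores[complete.cases(ism$scores), ]
    eig <- bootstrap_eigen_retention(xm, n_boot = 200, seed = s)
    bl <- bootstrap_loadings(xm, 1, n_boot = 200, seed = s + 10)
    sig <- significant_items(bl, 1)
    n_sig_true <- sum(sprintf("item_%02d", 1:12) %in%
                        c(sig$positive, sig$negative))
    # The dominant factor must always be found. The percentile retention
    # rule is anti-conservative when pure-noise items are present (their
    # null spectrum edge (1 + sqrt(p/n))^2 exceeds 1 at any realistic n),
    # so it may over-retain 1-2 spurious factors; see the methods vignette.
    # Significance calls, by contrast, must recover >= 10 of the 12 loaded
    # items and the zero-loading items must stay non-significant mostly.
    (eig$n_retained >= 1) && (eig$eigenvalues[1] > 3) && (n_sig_true >= 10)
  }, logical(1))
  expect_gte(mean(hits), 2 / 3)
})
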