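test_that("a class-indicator protein tops the merit ranking", {
  g <- gen_panel(panel_spec(n_synergistic = 8L, n_low = 8L, n_proteins = 6L,
                            n_informative = 0L, effect_size = 0, seed = 9L))
  vals <- cbind(g$panel$values,
                indicator = as.numeric(g$responses$label == "synergistic"))
  panel <- expression_panel(vals)
  rk <- merit_rank(panel, g$responses)
  expect_equal(rk$protein[1L], "indicator")
  expect_equal(rk$merit[1L], 1.0)
  expect_equal(sort(rk$rank), seq_len(7L))      # ranks are a permutation
  expect_true(all(rk$merit >= 0 & rk$merit <= 1))
})

test_that("merit ranking is invariant to affine rescaling of a protein", {
  g <- gen_panel(panel_spec(n_synergistic = 7L, n_low = 5L, n_proteins = 8L,
                            n_informative = 5L, effect_size = 2, seed = 10L))
  rk1 <- merit_rank(g$panel, g$responses)
  vals <- g$panel$values
  vals[, 3L] <- vals[, 3L] * 1000 + 7          # positive affine map
  rk2 <- merit_rank(expression_panel(vals), g$responses)
  expect_equal(rk1$protein, rk2$protein)
  expect_equal(rk1$merit, rk2$merit, tolerance = 1e-12)
})

test_that("noise-protein merit sits near the small-sample null mean of |r|", {
  # independent oracle: null expectation of |cor| between a log-normal
  # variable (the generator's marginal) and the class indicator at the
  # stratified-fold training size (16 samples, 10 folds -> ~14 training,
  # ~11/3 class composition). Pearson |r| is not distribution-free at this
  # n, so the oracle must match the marginal.
  set.seed(100)
  y <- c(rep(1, 11), rep(0, 3))
  null_mean <- mean(replicate(4000, abs(cor(exp(rnorm(14)), sample(y)))))
  # merit of one fixed noise protein (not the top-ranked one, which is a
  # maximum over proteins)
  merits <- vapply(1:120, function(s) {
    g <- gen_panel(panel_spec(n_synergistic = 12L, n_low = 4L, n_proteins = 2L,
                              n_informative = 0L, effect_size = 0, seed = s))
    rk <- merit_rank(g$panel, g$responses, run_config(rng_seed = s))
    rk$merit[rk$protein == "P01"]
  }, numeric(1))
  expect_lt(mean(merits), 0.5)
  expect_lt(abs(mean(merits) - null_mean), 0.05)
})

test_that("a constant-in-training protein gets zero merit with a warning", {
  g <- gen_panel(panel_spec(n_synergistic = 6L, n_low = 6L, n_proteins = 4L,
                            n_informative = 0L, effect_size = 0, seed = 11L))
  vals <- g$panel$values
  vals[, 2L] <- 5
  expect_warning(rk <- merit_rank(expression_panel(vals), g$responses),
                 "zero merit")
  expect_equal(rk$merit[rk$protein == g$panel$protein_ids[2L]], 0)
})

test_that("full-data mode reproduces plain absolute correlations", {
  g <- gen_panel(panel_spec(n_synergistic = 6L, n_low = 6L, n_proteins = 5L,
                            n_informative = 3L, effect_size = 2, seed = 12L))
  rk <- merit_rank(g$panel, g$responses, use_cv = FALSE)
  y <- as.numeric(g$responses$label == "synergistic")
  want <- abs(apply(g$panel$values, 2L, cor, y))
  expect_equal(rk$merit, unname(want[rk$protein]))
})

test_that("reduction drops an appended pure-noise protein first, curve intact", {
  g <- gen_panel(panel_spec(n_synergistic = 6L, n_low = 6L, n_proteins = 6L,
                            n_informative = 6L, effect_size = 5, seed = 14L))
  cfg <- run_config(n_pcs_max = 4L)
  rk0 <- merit_rank(g$panel, g$responses, cfg)
  rc0 <- reduce_predictor(g$panel, g$responses, rk0, cfg)

  set.seed(77)
  aug <- expression_panel(cbind(g$panel$values, purenoise = exp(rnorm(12))))
  rk1 <- merit_rank(aug, g$responses, cfg)
  expect_equal(rk1$protein[nrow(rk1)], "purenoise")   # ranked last
  rc1 <- reduce_predictor(aug, g$responses, rk1, cfg)
  expect_equal(nrow(rc1), nrow(rc0) + 1L)
  # after the noise protein is dropped, the curve equals the original run
  tail1 <- rc1[-1L, c("n_proteins", "loocv_accuracy", "training_accuracy",
                      "proteins")]
  expect_equal(tail1, as.data.frame(rc0)[names(tail1)], ignore_attr = TRUE)
})

test_that("reduction is deterministic, nested, and respects the subset rule", {
  g <- gen_panel(panel_spec(n_synergistic = 7L, n_low = 5L, n_proteins = 7L,
                            n_informative = 4L, effect_size = 2, seed = 15L))
  rk <- merit_rank(g$panel, g$responses)
  rc1 <- reduce_predictor(g$panel, g$responses, rk)
  rc2 <- reduce_predictor(g$panel, g$responses, rk)
  expect_identical(rc1, rc2)
  # strictly nested protein sets shrinking by one
  sets <- strsplit(rc1$proteins, ";", fixed = TRUE)
  for (i in seq_len(length(sets) - 1L)) {
    expect_equal(length(sets[[i + 1L]]), length(sets[[i]]) - 1L)
    expect_true(all(sets[[i + 1L]] %in% sets[[i]]))
  }
  # selected subset: smallest set within tolerance 0 of the full accuracy
  sel_n <- attr(rc1, "selected_n")
  full <- rc1$loocv_accuracy[1L]
  expect_true(all(rc1$loocv_accuracy[rc1$n_proteins < sel_n] < full))
  expect_gte(rc1$loocv_accuracy[rc1$n_proteins == sel_n], full)
})

test_that("a two-protein panel reduces in a single iteration", {
  g <- gen_panel(panel_spec(n_synergistic = 5L, n_low = 5L, n_proteins = 2L,
                            n_informative = 2L, effect_size = 3,
                            latent_rank = 1L, seed = 16L))
  rk <- merit_rank(g$panel, g$responses)
  rc <- suppressWarnings(reduce_predictor(g$panel, g$responses, rk))
  expect_equal(nrow(rc), 1L)
  expect_equal(rc$n_proteins, 2L)
})
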