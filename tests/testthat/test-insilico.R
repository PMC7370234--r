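test_that("the log2(FPKM-UQ+1) back-transform inverts the normalization", {
  expect_equal(back_transform(0), 0)
  expect_equal(back_transform(1), 1)
  expect_equal(back_transform(log2(10)), 9, tolerance = 1e-3)
  v <- seq(0, 12, by = 0.5)
  expect_equal(log2(back_transform(v) + 1), v)
  expect_error(back_transform(-0.1), "non-negative")
})

test_that("interpolation curves pass exactly through the range endpoints", {
  g <- gen_panel(panel_spec(seed = 19L))
  map <- default_gene_map()
  sub <- subset_panel(g$panel, proteins = map$protein)
  co <- gen_cohort(sub, g$responses, map, n_patients = 40L, seed = 19L)
  imap <- fit_interpolation(sub, co$cohort, map)
  expect_equal(imap$protein, map$protein)
  for (i in seq_len(nrow(imap))) {
    expect_equal(imap$intercept[i] + imap$slope[i] * imap$mrna_min[i],
                 imap$prot_min[i], tolerance = 1e-10)
    expect_equal(imap$intercept[i] + imap$slope[i] * imap$mrna_max[i],
                 imap$prot_max[i], tolerance = 1e-10)
    expect_gt(imap$mrna_max[i], imap$mrna_min[i])
    expect_gt(imap$prot_max[i], imap$prot_min[i])
  }
  # cohort extremes map onto the panel extremes per protein
  est <- suppressMessages(estimate_profiles(co$cohort, imap, map))
  expect_equal(apply(est$values, 2L, min),
               apply(sub$values[, imap$protein], 2L, min), tolerance = 1e-8)
  expect_equal(apply(est$values, 2L, max),
               apply(sub$values[, imap$protein], 2L, max), tolerance = 1e-8)
})

test_that("a constant gene column yields a degenerate-map error", {
  g <- gen_panel(panel_spec(seed = 20L))
  map <- default_gene_map()
  sub <- subset_panel(g$panel, proteins = map$protein)
  vals <- matrix(5, nrow = 4, ncol = nrow(map),
                 dimnames = list(paste0("p", 1:4), map$gene))
  expect_error(fit_interpolation(sub, cohort_matrix(vals), map),
               "degenerate mRNA range")
})

test_that("profile estimation matches a per-cell loop oracle and is monotone", {
  g <- gen_panel(panel_spec(seed = 22L))
  map <- default_gene_map()
  sub <- subset_panel(g$panel, proteins = map$protein)
  co <- gen_cohort(sub, g$responses, map, n_patients = 25L, seed = 22L)
  imap <- fit_interpolation(sub, co$cohort, map)
  est <- suppressMessages(estimate_profiles(co$cohort, imap, map))
  # naive per-cell re-computation
  for (pt in c(1L, 7L, 20L)) for (i in seq_len(nrow(imap))) {
    x <- 2^co$cohort$values[pt, imap$gene[i]] - 1
    want <- imap$intercept[i] + imap$slope[i] * x
    want <- min(max(want, imap$prot_min[i]), imap$prot_max[i])
    expect_equal(est$values[pt, imap$protein[i]], want, tolerance = 1e-10)
  }
  # monotonicity: estimated protein non-decreasing in mRNA
  ord <- order(co$cohort$values[, imap$gene[1L]])
  expect_true(all(diff(est$values[ord, imap$protein[1L]]) >= 0))
})

test_that("a noise-free generated cohort round-trips to the true profiles", {
  g <- gen_panel(panel_spec(seed = 25L))
  map <- default_gene_map()
  sub <- subset_panel(g$panel, proteins = map$protein)
  co <- gen_cohort(sub, g$responses, map, n_patients = 60L, noise_sd = 0,
                   seed = 25L)
  imap <- fit_interpolation(sub, co$cohort, map)
  est <- suppressMessages(estimate_profiles(co$cohort, imap, map))
  rel <- abs(est$values - co$true_profiles$values) /
    pmax(co$true_profiles$values, 1e-12)
  expect_lt(max(rel), 1e-8)
})

test_that("trial prevalence reflects the cohort composition", {
  g <- gen_panel(panel_spec(effect_size = 5, seed = 26L))
  map <- default_gene_map()
  sub <- subset_panel(g$panel, proteins = map$protein)
  model <- train_predictor(sub, g$responses)

  co2 <- gen_cohort(sub, g$responses, map, n_patients = 50L, class_mix = 0.4,
                    seed = 27L)
  imap2 <- fit_interpolation(sub, co2$cohort, map)

  # cohort of copies of the synergistic class-mean profile, inverted
  # through the fitted curves -> prevalence 1
  syn_mean <- colMeans(sub$values[g$responses$label == "synergistic",
                                  imap2$protein])
  mrna <- (syn_mean - imap2$intercept) / imap2$slope
  cvals <- matrix(log2(mrna + 1), nrow = 30L, ncol = length(mrna),
                  byrow = TRUE,
                  dimnames = list(sprintf("c%02d", 1:30), imap2$gene))
  tr1 <- suppressMessages(run_trial(model, cohort_matrix(cvals), imap2, map))
  expect_equal(tr1$prevalence, 1.0)

  # patient reordering leaves prevalence unchanged
  tr2 <- suppressMessages(run_trial(model, co2$cohort, imap2, map))
  perm <- sample(nrow(co2$cohort$values))
  co2p <- cohort_matrix(co2$cohort$values[perm, ])
  tr2p <- suppressMessages(run_trial(model, co2p, imap2, map))
  expect_equal(tr2p$prevalence, tr2$prevalence)

  # model proteins not covered by the map -> error
  expect_error(run_trial(train_predictor(g$panel, g$responses), co2$cohort,
                         imap2, map), "does not cover")
})

test_that("cohort matrices validate ids and value ranges", {
  m <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(c("p1", "p2"), c("g1", "g2")))
  expect_s3_class(cohort_matrix(m), "cohort_matrix")
  m2 <- m; m2[1, 1] <- -1
  expect_error(cohort_matrix(m2), "non-negative")
  expect_error(cohort_matrix(matrix(1, 2, 2)), "identifiers")
})
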