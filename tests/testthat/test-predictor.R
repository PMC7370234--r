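test_that("standardization yields unit-scale columns and records parameters", {
  p <- expression_panel(matrix(c(1, 2, 3, 5, 6, 10), 3, 2,
                               dimnames = list(c("a", "b", "c"), c("x", "y"))))
  s <- standardize(p)
  expect_equal(s$z[, "x"], c(a = -1, b = 0, c = 1))
  expect_equal(s$params$mean[["x"]], 2)
  expect_equal(s$params$sd[["x"]], 1)

  rp <- random_panel(12, 7, 3)
  z <- standardize(rp)$z
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_equal(apply(z, 2, sd), rep(1, 7), ignore_attr = TRUE,
               tolerance = 1e-10)

  const <- expression_panel(matrix(c(5, 5, 5, 1, 2, 3), 3, 2,
                                   dimnames = list(letters[1:3], c("flat", "y"))))
  expect_error(standardize(const), "zero-variance.*flat")
})

test_that("training parameters position new samples without re-estimation", {
  rp <- random_panel(8, 5, 11)
  s <- standardize(rp)
  # training sample re-applied reproduces its own z row
  expect_equal(apply_standardization(rp$values[3, ], s$params), s$z[3, ])
  # sample at the training means maps to the origin
  expect_equal(unname(apply_standardization(s$params$mean, s$params)),
               rep(0, 5))
  expect_error(apply_standardization(s$params$mean[-1], s$params),
               "lacks protein")
})

test_that("PCA matches a brute-force correlation-matrix eigendecomposition", {
  rp <- random_panel(8, 5, 21)
  z <- standardize(rp)$z
  m <- fit_pca(z, run_config(n_pcs_max = 5))
  o <- eigen(cor(rp$values), symmetric = TRUE)
  expect_equal(m$eigenvalues, o$values, tolerance = 1e-8)
  expect_equal(sum(m$eigenvalues), 5, tolerance = 1e-8)     # trace identity
  for (j in seq_len(m$n_retained)) {
    dot <- abs(sum(m$loadings[, j] * o$vectors[, j]))
    expect_equal(dot, 1, tolerance = 1e-8)                   # same axis up to sign
  }
  # loadings columns orthonormal
  expect_equal(crossprod(m$loadings), diag(ncol(m$loadings)),
               ignore_attr = TRUE, tolerance = 1e-10)
  # deterministic sign convention: largest-magnitude entry positive
  for (j in seq_len(ncol(m$loadings)))
    expect_gt(m$loadings[which.max(abs(m$loadings[, j])), j], 0)
})

test_that("two perfectly correlated variables collapse to one component", {
  x <- c(1, 2, 3, 4)
  p <- expression_panel(matrix(c(x, 2 * x), 4, 2,
                               dimnames = list(letters[1:4], c("u", "v"))))
  m <- fit_pca(standardize(p)$z)
  expect_equal(m$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_equal(m$n_retained, 1L)
})

test_that("variance explained is eigenvalue over protein count", {
  m <- structure(list(loadings = matrix(0, 4, 4),
                      eigenvalues = c(2, 1, 1, 0), n_retained = 2L),
                 class = "pca_model")
  ve <- variance_explained(m)
  expect_equal(ve$per_component, c(0.5, 0.25, 0.25, 0))
  expect_equal(ve$cumulative, c(0.5, 0.75, 1, 1))
})

test_that("projection is the plain dot product with retained loadings", {
  rp <- random_panel(9, 6, 31)
  s <- standardize(rp)
  m <- fit_pca(s$z, run_config(n_pcs_max = 3, kaiser_threshold = 0))
  v <- s$z[4, ]
  got <- project(v, m)
  want <- vapply(seq_len(m$n_retained), function(j)
    sum(v * m$loadings[, j]), numeric(1))
  expect_equal(unname(got), want)
  expect_equal(unname(project(rep(0, 6), m)), rep(0, m$n_retained))
  expect_error(project(v[-1], m), "dimension")
  # matrix projection consistent with per-row vectors
  expect_equal(project(s$z, m)[4, ], got)
})

test_that("the 1-D symmetric discriminant reduces to the midpoint rule", {
  scores <- matrix(c(-1.5, -1, -0.5, 0.5, 1, 1.5), ncol = 1)
  lab <- c(rep("low", 3), rep("synergistic", 3))
  cfg <- run_config(lda_priors = "equal")
  m <- fit_lda(scores, lab, cfg)
  expect_equal(m$offset, 0)                     # boundary exactly at 0
  expect_gt(trailstrat:::.lda_discriminant(m, 0.5), 0)
  expect_lt(trailstrat:::.lda_discriminant(m, -0.5), 0)
  # discriminant has opposite signs on the two class means
  expect_lt(trailstrat:::.lda_discriminant(m, m$means["low", ]) *
              trailstrat:::.lda_discriminant(m, m$means["synergistic", ]), 0)
  # label swap mirrors the discriminant
  m2 <- fit_lda(scores, rev(lab), cfg)
  expect_equal(m2$weights, -m$weights)
  expect_equal(m2$offset, -m$offset)
})

test_that("well-separated Gaussian clusters are perfectly segmented", {
  set.seed(5)
  sc <- rbind(matrix(rnorm(40, mean = 5, sd = 0.3), ncol = 2),
              matrix(rnorm(40, mean = -5, sd = 0.3), ncol = 2))
  lab <- rep(c("synergistic", "low"), each = 20)
  m <- fit_lda(sc, lab)
  d <- trailstrat:::.lda_discriminant(m, sc)
  expect_equal(ifelse(d > 0, "synergistic", "low"), lab)
  expect_error(fit_lda(sc, rep("low", 40)), "both response classes")
})

test_that("the hand-rolled discriminant agrees with an independent LDA fit", {
  skip_if_not_installed("MASS")
  g <- gen_panel(panel_spec(seed = 17L))
  cfg <- run_config()
  m <- train_predictor(g$panel, g$responses, cfg)
  ref <- MASS::lda(m$scores, grouping = factor(.subset2(g$responses, "label"),
                                               levels = c("low", "synergistic")))
  ours <- predict(m, g$panel)
  theirs <- predict(ref, as.data.frame(m$scores))
  expect_equal(ours$label, as.character(theirs$class))
  expect_equal(ours$posterior, unname(theirs$posterior[, "synergistic"]),
               tolerance = 1e-8)
})

test_that("training composes the stages consistently", {
  g <- gen_panel(panel_spec(seed = 23L))
  m <- train_predictor(g$panel, g$responses)
  # projection consistency: stored scores equal re-projected training rows
  z <- apply_standardization(g$panel, m$standardization)
  expect_equal(unname(project(z, m$pca)), unname(m$scores))
  # column order invariance: shuffled protein columns give identical predictions
  shuf <- sample(length(g$panel$protein_ids))
  panel2 <- expression_panel(g$panel$values[, shuf], g$panel$sample_ids,
                             g$panel$protein_ids[shuf])
  expect_equal(predict(m, panel2), predict(m, g$panel))
})

test_that("prediction honours the tie policy on the decision boundary", {
  scores <- matrix(c(-1, 1), ncol = 1)
  g <- gen_panel(panel_spec(n_synergistic = 3L, n_low = 3L, n_proteins = 4L,
                            n_informative = 4L, effect_size = 4, seed = 3L))
  m <- train_predictor(g$panel, g$responses, run_config(lda_priors = "equal"))
  # synthesize an exact-tie sample: solve for zero discriminant along PC1
  m$lda$weights <- c(1, rep(0, length(m$lda$weights) - 1))
  m$lda$offset <- 0
  z0 <- m$standardization$mean  # origin in z-space -> PC coords 0 -> tie
  pred <- predict(m, z0)
  expect_equal(pred$label, "low")              # default conservative policy
  m$config$tie_policy <- "synergistic"
  expect_equal(predict(m, z0)$label, "synergistic")
})

test_that("serialized predictors reproduce predictions and bytes", {
  g <- gen_panel(panel_spec(seed = 41L))
  m <- train_predictor(g$panel, g$responses)
  js <- write_predictor(m)
  m2 <- read_predictor(js)
  expect_identical(write_predictor(m2), js)     # byte-stable round trip
  set.seed(99)
  probe <- matrix(exp(rnorm(100 * 19)), 100, 19,
                  dimnames = list(NULL, g$panel$protein_ids))
  p1 <- predict(m, probe); p2 <- predict(m2, probe)
  expect_identical(p1$label, p2$label)
  expect_equal(p1$posterior, p2$posterior, tolerance = 1e-12)
  # file round trip
  f <- tempfile(fileext = ".json")
  write_predictor(m, f)
  expect_identical(write_predictor(read_predictor(f)), js)
})

test_that("training is deterministic for fixed inputs and config", {
  g <- gen_panel(panel_spec(seed = 8L))
  m1 <- train_predictor(g$panel, g$responses)
  m2 <- train_predictor(g$panel, g$responses)
  expect_identical(write_predictor(m1), write_predictor(m2))
})
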