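# Synthetic-data generators emulating the statistical structure of the
# three measured inputs: a two-class protein panel with heterogeneous
# per-protein scales and shared low-rank covariance, factorial dose-response
# grids with injected super-independence synergy, and a cohort transcriptome
# monotonically related to protein quantities. Every generator is a pure
# function of its parameters and seed.

#' Specification of a synthetic protein panel
#'
#' Defaults mirror the measured study design: 12 synergistic and 4 low
#' responders over the 19-protein apoptosis panel, 11 informative proteins
#' (the size of the reduced predictor), a rank-6 shared latent structure
#' (the number of retained components) and baselines spanning three orders
#' of magnitude, emulating the strong between-protein expression
#' heterogeneity of immunoblot and receptor-count data.
#'
#' @param n_synergistic,n_low Samples per response class.
#' @param n_proteins Number of proteins; 19 uses the canonical panel names.
#' @param n_informative Number of proteins carrying class signal.
#' @param effect_size Class-mean shift of informative proteins, in
#'   within-class standard-deviation units on the latent (log) scale.
#' @param latent_rank Rank of the shared covariance structure.
#' @param scale_heterogeneity Orders of magnitude spanned by per-protein
#'   baseline scales.
#' @param seed Integer RNG seed.
#' @return An object of class `"panel_spec"`.
#' @export
panel_spec <- function(n_synergistic = 12L, n_low = 4L, n_proteins = 19L,
                       n_informative = 11L, effect_size = 1.5,
                       latent_rank = 6L, scale_heterogeneity = 3,
                       seed = 20170101L) {
  spec <- list(n_synergistic = as.integer(n_synergistic),
               n_low = as.integer(n_low),
               n_proteins = as.integer(n_proteins),
               n_informative = as.integer(n_informative),
               effect_size = as.numeric(effect_size),
               latent_rank = as.integer(latent_rank),
               scale_heterogeneity = as.numeric(scale_heterogeneity),
               seed = as.integer(seed))
  if (spec$n_synergistic < 1L || spec$n_low < 1L || spec$n_proteins < 2L)
    stop("panel_spec requires at least 1 sample per class and 2 proteins",
         call. = FALSE)
  if (spec$n_informative > spec$n_proteins)
    stop("n_informative exceeds n_proteins", call. = FALSE)
  if (spec$n_informative < 0L || spec$effect_size < 0 ||
      spec$latent_rank < 1L || spec$scale_heterogeneity < 0)
    stop("invalid panel_spec parameter", call. = FALSE)
  structure(spec, class = "panel_spec")
}

#' Generate a synthetic two-class expression panel
#'
#' Samples are drawn from a low-rank Gaussian factor model on a latent log
#' scale: shared factors induce correlation between proteins, informative
#' proteins additionally receive a class-mean shift of `effect_size`
#' within-class standard deviations (with alternating sign, emulating pro-
#' and anti-apoptotic proteins associating with responsiveness in opposite
#' directions). Latent values are exponentiated and multiplied by
#' heterogeneous per-protein baselines so that quantities are positive,
#' right-skewed and span orders of magnitude — the regime the
#' standardization step has to handle.
#'
#' @param spec A [panel_spec()].
#' @return List with `panel` (an [expression_panel()]) and `responses`
#'   (a [response_table()], synergistic samples first).
#' @export
gen_panel <- function(spec = panel_spec()) {
  stopifnot(inherits(spec, "panel_spec"))
  n <- spec$n_synergistic + spec$n_low
  p <- spec$n_proteins
  r <- spec$latent_rank
  labels <- c(rep("synergistic", spec$n_synergistic), rep("low", spec$n_low))
  .with_seed(spec$seed, {
    L <- matrix(stats::rnorm(p * r, sd = sqrt(0.5 / r)), nrow = p)
    sig_e <- sqrt(0.5)
    # normalize rows so every protein has unit within-class latent variance
    tot <- sqrt(rowSums(L^2) + sig_e^2)
    L <- L / tot
    sig_e <- sig_e / tot
    shift <- numeric(p)
    if (spec$n_informative > 0L) {
      idx <- seq_len(spec$n_informative)
      shift[idx] <- spec$effect_size * (-1)^(idx + 1L)
    }
    f <- matrix(stats::rnorm(n * r), nrow = n)
    e <- sweep(matrix(stats::rnorm(n * p), nrow = n), 2L, sig_e, "*")
    latent <- f %*% t(L) + e +
      outer(as.numeric(labels == "synergistic"), shift)
    baseline <- 10^stats::runif(p, 0, spec$scale_heterogeneity)
    values <- sweep(exp(latent), 2L, baseline, "*")
  })
  prot <- if (p == 19L) panel_proteins() else sprintf("P%02d", seq_len(p))
  ids <- sprintf("S%02d", seq_len(n))
  dimnames(values) <- list(ids, prot)
  list(panel = expression_panel(values),
       responses = response_table(ids, labels))
}

#' Generate a synthetic factorial dose-response grid
#'
#' Builds the 15-condition design used for response profiling: two
#' three-dose monotherapy series plus their 3 x 3 factorial combinations.
#' Monotherapy fractions are the supplied series; combination fractions are
#' the fractional-product independence expectation plus a constant synergy
#' `boost` and optional Gaussian noise, clipped to `[0, 1]`.
#'
#' @param f_a_series,f_b_series Monotherapy fractions affected in `[0, 1]`
#'   for agent A (doses in nM) and agent B (doses in uM).
#' @param synergy_boost Excess over independence injected into every
#'   combination, in `[-1, 1]`.
#' @param noise_sd Standard deviation of measurement noise added to
#'   combination fractions.
#' @param seed Integer RNG seed.
#' @param sample_id Sample name.
#' @param dose_a,dose_b Dose series labelling the conditions.
#' @param include_control Add an untreated `(0, 0)` condition with zero
#'   spontaneous death (16 conditions instead of 15).
#' @return A [dose_response_grid()].
#' @export
gen_grid <- function(f_a_series = c(0.05, 0.2, 0.5),
                     f_b_series = c(0.05, 0.2, 0.5),
                     synergy_boost = 0, noise_sd = 0, seed = 1L,
                     sample_id = "SYN1",
                     dose_a = c(0.1, 1, 10), dose_b = c(0.1, 1, 10),
                     include_control = FALSE) {
  if (any(f_a_series < 0 | f_a_series > 1) || any(f_b_series < 0 | f_b_series > 1))
    stop("monotherapy fractions must lie in [0, 1]", call. = FALSE)
  if (abs(synergy_boost) > 1) stop("synergy_boost must lie in [-1, 1]", call. = FALSE)
  stopifnot(length(dose_a) == length(f_a_series),
            length(dose_b) == length(f_b_series))
  mono_a <- data.frame(dose_a = dose_a, dose_b = 0, f_dead = f_a_series)
  mono_b <- data.frame(dose_a = 0, dose_b = dose_b, f_dead = f_b_series)
  combos <- expand.grid(ia = seq_along(dose_a), ib = seq_along(dose_b))
  f_exp <- webb_expected(f_a_series[combos$ia], f_b_series[combos$ib])
  noise <- .with_seed(seed, stats::rnorm(nrow(combos), sd = noise_sd))
  comb <- data.frame(dose_a = dose_a[combos$ia], dose_b = dose_b[combos$ib],
                     f_dead = pmin(pmax(f_exp + synergy_boost + noise, 0), 1))
  cond <- rbind(mono_a, mono_b, comb)
  if (include_control)
    cond <- rbind(data.frame(dose_a = 0, dose_b = 0, f_dead = 0), cond)
  dose_response_grid(sample_id, cond)
}

#' Generate a synthetic cohort transcriptome from a protein panel
#'
#' Emulates the in silico trial inputs: patient protein profiles are drawn
#' from class-conditional log-normal generators fitted to the panel's
#' response classes, mapped to a linear mRNA scale through per-gene inverse
#' min-max curves, log2(x+1)-transformed and optionally perturbed with
#' Gaussian noise. Two anchor patients carrying exactly the per-protein
#' panel minima and maxima are prepended by default so that interpolation
#' curves fitted on the generated cohort invert the generator map exactly;
#' true classes are returned for recovery testing but are never consumed by
#' the pipeline.
#'
#' @param panel Training [expression_panel()].
#' @param responses [response_table()] for the panel (defines the
#'   class-conditional generators).
#' @param map A [gene_protein_map()] naming the cohort genes.
#' @param n_patients Number of patients to draw.
#' @param class_mix Probability that a patient is drawn from the
#'   synergistic-responder generator.
#' @param noise_sd Gaussian noise added on the log2 mRNA scale.
#' @param profile_spread Multiplier on the class-conditional log-scale
#'   standard deviations.
#' @param seed Integer RNG seed.
#' @param anchors Prepend the two extreme anchor patients (default `TRUE`).
#' @return List with `cohort` (a [cohort_matrix()]), `truth` (data frame
#'   `patient_id`, `class`, `is_anchor`) and `true_profiles` (the generated
#'   protein quantities as an [expression_panel()]).
#' @export
gen_cohort <- function(panel, responses, map, n_patients = 100L,
                       class_mix = 0.3, noise_sd = 0, profile_spread = 1,
                       seed = 1L, anchors = TRUE) {
  stopifnot(inherits(panel, "expression_panel"),
            inherits(map, "gene_protein_map"))
  lab <- .align_labels(panel, responses)
  prot <- map$protein
  miss <- setdiff(prot, panel$protein_ids)
  if (length(miss)) stop("panel lacks mapped protein(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (class_mix < 0 || class_mix > 1) stop("class_mix must lie in [0, 1]",
                                           call. = FALSE)
  x <- panel$values[, prot, drop = FALSE]
  lx <- log(x)
  p_lo <- apply(x, 2L, min); p_hi <- apply(x, 2L, max)
  if (any(p_hi <= p_lo)) stop("degenerate protein range in panel", call. = FALSE)
  fit_class <- function(cl) list(
    mu = colMeans(lx[lab == cl, , drop = FALSE]),
    sd = apply(lx[lab == cl, , drop = FALSE], 2L, stats::sd))
  gens <- list(synergistic = fit_class("synergistic"), low = fit_class("low"))
  p <- length(prot)
  .with_seed(seed, {
    cls <- ifelse(stats::runif(n_patients) < class_mix, "synergistic", "low")
    prof <- t(vapply(cls, function(cl)
      exp(stats::rnorm(p, gens[[cl]]$mu, gens[[cl]]$sd * profile_spread)),
      numeric(p)))
    prof <- pmin(pmax(prof, matrix(p_lo, n_patients, p, byrow = TRUE)),
                 matrix(p_hi, n_patients, p, byrow = TRUE))
    is_anchor <- rep(FALSE, n_patients)
    if (anchors) {
      prof <- rbind(p_lo, p_hi, prof)
      cls <- c(NA_character_, NA_character_, cls)
      is_anchor <- c(TRUE, TRUE, is_anchor)
    }
    # inverse min-max map: panel protein range -> per-gene linear mRNA range
    g_lo <- 2^stats::runif(p, 1, 3) - 1
    g_hi <- 2^stats::runif(p, 8, 12) - 1
    mrna <- sweep(sweep(prof, 2L, p_lo, "-"), 2L,
                  (p_hi - p_lo) / (g_hi - g_lo), "/")
    mrna <- sweep(mrna, 2L, g_lo, "+")
    cvals <- log2(mrna + 1)
    if (noise_sd > 0)
      cvals <- cvals + matrix(stats::rnorm(length(cvals), sd = noise_sd),
                              nrow = nrow(cvals))
    cvals <- pmax(cvals, 0)
  })
  ids <- sprintf("PT%04d", seq_len(nrow(prof)))
  dimnames(cvals) <- list(ids, map$gene)
  dimnames(prof) <- list(ids, prot)
  list(cohort = cohort_matrix(cvals),
       truth = data.frame(patient_id = ids, class = cls,
                          is_anchor = is_anchor, stringsAsFactors = FALSE),
       true_profiles = expression_panel(prof))
}
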