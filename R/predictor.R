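# The core predictor: per-protein standardization, correlation-matrix PCA
# with Kaiser-criterion retention, and a two-class linear discriminant in
# the retained component space. A trained predictor is a self-contained,
# serializable object; new samples are positioned in its PC space using the
# training parameters only.

#' Standardize an expression panel
#'
#' Mean-centres each protein and divides by its sample standard deviation
#' (n - 1 denominator), so every protein enters the PCA on the same scale
#' regardless of measurement units (arbitrary immunoblot fluorescence or
#' receptor molecules per cell).
#'
#' @param panel An [expression_panel()] with at least 2 samples.
#' @return List with `z` (standardized matrix, columns of mean 0 and sd 1)
#'   and `params` (class `"standardization_params"`: named vectors `mean`
#'   and `sd`).
#' @export
standardize <- function(panel) {
  stopifnot(inherits(panel, "expression_panel"))
  x <- panel$values
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  dead <- which(sd == 0 | !is.finite(sd))
  if (length(dead))
    stop("zero-variance protein(s): ",
         paste(colnames(x)[dead], collapse = ", "), call. = FALSE)
  z <- sweep(sweep(x, 2L, mu, "-"), 2L, sd, "/")
  params <- structure(list(mean = mu, sd = sd),
                      class = "standardization_params")
  list(z = z, params = params)
}

#' Standardize a sample with training parameters
#'
#' Positions a new sample on the training scale using the training means
#' and standard deviations only; nothing is re-estimated, so held-out or
#' external samples never influence the space they are projected into.
#'
#' @param sample Named numeric vector, or a matrix / [expression_panel()]
#'   with samples in rows; names must cover every protein in `params`.
#' @param params `standardization_params` from [standardize()].
#' @return Standardized vector or matrix with proteins in training order.
#' @export
apply_standardization <- function(sample, params) {
  stopifnot(inherits(params, "standardization_params"))
  prot <- names(params$mean)
  if (inherits(sample, "expression_panel")) sample <- sample$values
  if (is.matrix(sample)) {
    colnames(sample) <- canonical_protein(colnames(sample))
    miss <- setdiff(prot, colnames(sample))
    if (length(miss)) stop("sample lacks protein(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    x <- sample[, prot, drop = FALSE]
    return(sweep(sweep(x, 2L, params$mean, "-"), 2L, params$sd, "/"))
  }
  names(sample) <- canonical_protein(names(sample))
  miss <- setdiff(prot, names(sample))
  if (length(miss)) stop("sample lacks protein(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  (sample[prot] - params$mean) / params$sd
}

#' Principal component analysis of a standardized panel
#'
#' Computes the eigendecomposition of the protein correlation matrix via
#' the singular value decomposition of the standardized data (numerically
#' stable and exactly equivalent). Components with eigenvalue above the
#' Kaiser threshold are retained, capped at `n_pcs_max`; the classifier
#' operates in this retained space. A deterministic sign convention (the
#' largest-magnitude entry of each loading column is positive) removes the
#' sign indeterminacy of eigenvectors so that models serialize bit-stably.
#'
#' @param z Standardized matrix from [standardize()].
#' @param config A [run_config()]; uses `kaiser_threshold` and `n_pcs_max`.
#' @return An object of class `"pca_model"`: `loadings` (proteins x
#'   components), `eigenvalues` (length = protein count, descending,
#'   zero-padded past the data rank), `n_retained`, and
#'   `variance_explained` (`per_component` and `cumulative` fractions).
#' @export
fit_pca <- function(z, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  z <- as.matrix(z)
  if (nrow(z) < 2L) stop("PCA requires at least 2 samples", call. = FALSE)
  p <- ncol(z)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  ev <- c(ev, numeric(max(0L, p - length(ev))))[seq_len(p)]
  loadings <- pc$rotation
  # sign convention: largest-|entry| of each column positive
  for (j in seq_len(ncol(loadings))) {
    k <- which.max(abs(loadings[, j]))
    if (loadings[k, j] < 0) loadings[, j] <- -loadings[, j]
  }
  n_ret <- sum(ev > config$kaiser_threshold)
  n_ret <- min(n_ret, config$n_pcs_max, ncol(loadings))
  if (n_ret < 1L) {
    warning("no eigenvalue above the Kaiser threshold; retaining 1 component")
    n_ret <- 1L
  }
  colnames(loadings) <- paste0("PC", seq_len(ncol(loadings)))
  model <- structure(list(loadings = loadings, eigenvalues = ev,
                          n_retained = as.integer(n_ret)),
                     class = "pca_model")
  model$variance_explained <- variance_explained(model)
  model
}

#' Variance explained by principal components
#'
#' On the correlation scale each protein contributes unit variance, so the
#' fraction explained by component i is its eigenvalue divided by the
#' protein count.
#'
#' @param model A [fit_pca()] model.
#' @return List with `per_component` and `cumulative` fractions (the latter
#'   non-decreasing, ending at 1).
#' @export
variance_explained <- function(model) {
  stopifnot(inherits(model, "pca_model"))
  frac <- model$eigenvalues / nrow(model$loadings)
  list(per_component = frac, cumulative = cumsum(frac))
}

#' Project standardized samples into the retained component space
#'
#' @param z Standardized vector or matrix (proteins in training order, as
#'   produced by [apply_standardization()]).
#' @param model A [fit_pca()] model.
#' @return Coordinates on the retained components (vector, or matrix with
#'   one row per sample).
#' @export
project <- function(z, model) {
  stopifnot(inherits(model, "pca_model"))
  W <- model$loadings[, seq_len(model$n_retained), drop = FALSE]
  if (is.matrix(z)) {
    if (ncol(z) != nrow(W)) stop("dimension mismatch: expected ",
                                 nrow(W), " proteins", call. = FALSE)
    return(z %*% W)
  }
  if (length(z) != nrow(W)) stop("dimension mismatch: expected ",
                                 nrow(W), " proteins", call. = FALSE)
  drop(z %*% W)
}

#' Two-class linear discriminant in component space
#'
#' Fits the classical linear discriminant: class means, pooled within-class
#' covariance and priors give a separating hyperplane of equal posterior.
#' With small training sets and several components the pooled covariance can
#' be ill-conditioned; it is then ridge-regularized
#' (epsilon = 1e-6 * trace / dim added to the diagonal) with a warning
#' rather than failing.
#'
#' @param scores Samples x components matrix of PC coordinates.
#' @param labels Character vector of responses (`synergistic` / `low`), or a
#'   [response_table()] matching the score rows by `sample_id`.
#' @param config A [run_config()]; uses `lda_priors`.
#' @return An object of class `"lda_model"`: class `means`, `pooled_cov`,
#'   `priors`, discriminant `weights` and `offset`. The discriminant
#'   `x . weights + offset` is positive on the synergistic side.
#' @export
fit_lda <- function(scores, labels, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  scores <- as.matrix(scores)
  if (inherits(labels, "response_table")) {
    if (is.null(rownames(scores)))
      stop("scores need rownames to match a response table", call. = FALSE)
    labels <- labels$label[match(rownames(scores), labels$sample_id)]
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(scores))
    stop("labels and score rows differ in length", call. = FALSE)
  if (!all(labels %in% .response_levels()))
    stop("labels must be 'synergistic' or 'low'", call. = FALSE)
  n_syn <- sum(labels == "synergistic"); n_low <- sum(labels == "low")
  if (n_syn == 0L || n_low == 0L)
    stop("both response classes must be present to fit a discriminant",
         call. = FALSE)
  d <- ncol(scores)
  m_syn <- colMeans(scores[labels == "synergistic", , drop = FALSE])
  m_low <- colMeans(scores[labels == "low", , drop = FALSE])
  dev <- scores
  dev[labels == "synergistic", ] <-
    sweep(scores[labels == "synergistic", , drop = FALSE], 2L, m_syn, "-")
  dev[labels == "low", ] <-
    sweep(scores[labels == "low", , drop = FALSE], 2L, m_low, "-")
  df <- nrow(scores) - 2L
  if (df < 1L) stop("too few samples to estimate within-class covariance",
                    call. = FALSE)
  S <- crossprod(dev) / df
  w <- tryCatch({
    if (rcond(S) < 1e-10) stop("ill-conditioned")
    solve(S, m_syn - m_low)
  }, error = function(e) {
    eps <- 1e-6 * sum(diag(S)) / d
    warning("pooled covariance singular or ill-conditioned; ridge-regularized")
    S <<- S + diag(eps, d)
    solve(S, m_syn - m_low)
  })
  priors <- if (config$lda_priors == "equal") c(low = 0.5, synergistic = 0.5)
            else c(low = n_low, synergistic = n_syn) / (n_low + n_syn)
  offset <- -sum(w * (m_syn + m_low)) / 2 +
    log(priors[["synergistic"]] / priors[["low"]])
  structure(list(means = rbind(low = m_low, synergistic = m_syn),
                 pooled_cov = S, priors = priors,
                 weights = as.numeric(w), offset = as.numeric(offset)),
            class = "lda_model")
}

# linear discriminant value: positive = synergistic side
.lda_discriminant <- function(model, scores) {
  scores <- if (is.matrix(scores)) scores else matrix(scores, nrow = 1L)
  drop(scores %*% model$weights + model$offset)
}

#' Train the full PCA/LDA response predictor
#'
#' Composition of the pipeline stages: standardize the training panel, fit
#' the correlation PCA, project the training samples, and fit the linear
#' discriminant separating synergistic from low responders in the retained
#' component space. The returned object is the deployable predictor.
#'
#' @param panel Training [expression_panel()].
#' @param labels [response_table()] covering the panel's samples.
#' @param config A [run_config()].
#' @return An object of class `"predictor_model"`: `proteins`,
#'   `standardization`, `pca`, `lda`, `config`, `config_hash`, and the
#'   training `scores`.
#' @export
train_predictor <- function(panel, labels, config = run_config()) {
  stopifnot(inherits(panel, "expression_panel"))
  lab <- .align_labels(panel, labels)
  std <- standardize(panel)
  pca <- fit_pca(std$z, config)
  scores <- project(std$z, pca)
  rownames(scores) <- panel$sample_ids
  lda <- fit_lda(scores, lab, config)
  structure(list(proteins = panel$protein_ids,
                 standardization = std$params,
                 pca = pca, lda = lda,
                 config = config, config_hash = config_hash(config),
                 scores = scores),
            class = "predictor_model")
}

#' @export
print.predictor_model <- function(x, ...) {
  cat(sprintf("PCA/LDA response predictor: %d proteins, %d retained PCs\n",
              length(x$proteins), x$pca$n_retained))
  ve <- x$pca$variance_explained$cumulative[x$pca$n_retained]
  cat(sprintf("retained components capture %.1f%% of the variance\n", 100 * ve))
  invisible(x)
}

#' Predict responsiveness of new samples
#'
#' Each sample is standardized with the training parameters, projected into
#' the trained component space, and classified by the linear discriminant;
#' the positioning in the segmented PC space is the response prediction.
#' An exact posterior tie is resolved by the configured `tie_policy`
#' (default `"low"`).
#'
#' @param object A trained [train_predictor()] model.
#' @param newdata Named numeric vector (one sample), a matrix with samples
#'   in rows, or an [expression_panel()]; must cover the model's proteins.
#' @param ... Unused.
#' @return Data frame with `sample_id`, `label`, `posterior` (posterior
#'   probability of the synergistic class) and the retained PC coordinates.
#' @export
predict.predictor_model <- function(object, newdata, ...) {
  if (inherits(newdata, "expression_panel")) {
    ids <- newdata$sample_ids
    x <- newdata$values
  } else if (is.matrix(newdata)) {
    ids <- rownames(newdata)
    if (is.null(ids)) ids <- paste0("sample", seq_len(nrow(newdata)))
    x <- newdata
  } else {
    ids <- "sample1"
    x <- matrix(newdata, nrow = 1L, dimnames = list(NULL, names(newdata)))
  }
  z <- apply_standardization(x, object$standardization)
  sc <- project(z, object$pca)
  if (!is.matrix(sc)) sc <- matrix(sc, nrow = nrow(z))
  disc <- .lda_discriminant(object$lda, sc)
  post <- stats::plogis(disc)
  label <- ifelse(disc > 0, "synergistic",
                  ifelse(disc < 0, "low", object$config$tie_policy))
  out <- data.frame(sample_id = ids, label = label, posterior = post,
                    stringsAsFactors = FALSE)
  colnames(sc) <- paste0("PC", seq_len(ncol(sc)))
  cbind(out, as.data.frame(sc, row.names = NULL))
}

#' Serialize a trained predictor to JSON
#'
#' A versioned, portable JSON document carrying the protein subset,
#' standardization parameters, PC loadings and eigenvalues, discriminant and
#' configuration, at full double precision so that a deserialized model
#' reproduces predictions exactly.
#'
#' @param model A [train_predictor()] model.
#' @param path Optional output path; when omitted the JSON text is returned.
#' @return Invisibly `path`, or the JSON string when `path` is `NULL`.
#' @export
write_predictor <- function(model, path = NULL) {
  stopifnot(inherits(model, "predictor_model"))
  doc <- list(
    version = 1L,
    proteins = model$proteins,
    means = as.numeric(model$standardization$mean),
    sds = as.numeric(model$standardization$sd),
    loadings = unname(model$pca$loadings),
    eigenvalues = model$pca$eigenvalues,
    n_retained = model$pca$n_retained,
    lda = list(means = unname(model$lda$means),
               pooled_cov = unname(model$lda$pooled_cov),
               priors = as.numeric(model$lda$priors),
               weights = model$lda$weights,
               offset = model$lda$offset),
    config = unclass(model$config),
    config_hash = model$config_hash
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Deserialize a predictor written by [write_predictor()]
#'
#' @param input Path to a predictor JSON file, or the JSON text itself.
#' @return A `predictor_model` producing identical predictions to the
#'   serialized model.
#' @export
read_predictor <- function(input) {
  doc <- jsonlite::fromJSON(input)
  if (is.null(doc$version) || doc$version != 1L)
    stop("unsupported predictor document version", call. = FALSE)
  prot <- doc$proteins
  p <- length(prot)
  loadings <- matrix(as.numeric(doc$loadings), nrow = p)
  colnames(loadings) <- paste0("PC", seq_len(ncol(loadings)))
  rownames(loadings) <- prot
  pca <- structure(list(loadings = loadings,
                        eigenvalues = as.numeric(doc$eigenvalues),
                        n_retained = as.integer(doc$n_retained)),
                   class = "pca_model")
  pca$variance_explained <- variance_explained(pca)
  d <- as.integer(doc$n_retained)
  lda <- structure(list(
    means = matrix(as.numeric(doc$lda$means), nrow = 2L,
                   dimnames = list(c("low", "synergistic"), NULL)),
    pooled_cov = matrix(as.numeric(doc$lda$pooled_cov), nrow = d),
    priors = stats::setNames(as.numeric(doc$lda$priors), c("low", "synergistic")),
    weights = as.numeric(doc$lda$weights),
    offset = as.numeric(doc$lda$offset)), class = "lda_model")
  cfg <- do.call(run_config, doc$config)
  std <- structure(list(mean = stats::setNames(as.numeric(doc$means), prot),
                        sd = stats::setNames(as.numeric(doc$sds), prot)),
                   class = "standardization_params")
  structure(list(proteins = prot, standardization = std, pca = pca, lda = lda,
                 config = cfg, config_hash = doc$config_hash, scores = NULL),
            class = "predictor_model")
}
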