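# Data model and delimited-text I/O for protein panels, response labels and
# run configuration. All downstream stages consume the validated containers
# built here, so validation is strict: malformed input fails loudly, nothing
# is imputed.

#' Canonical 19-protein apoptosis panel
#'
#' The fixed vocabulary of TRAIL-pathway regulators quantified in the
#' melanoma cell line panel: surface death receptors, the DISC components,
#' Bcl-2 family members, apoptosome constituents and the IAPs. Protein
#' columns read from files are canonicalized against this vocabulary (with a
#' case-insensitive alias table, e.g. \code{"SMAC/DIABLO"} maps to
#' \code{"Smac"}) so that columns cannot silently mismatch across pipeline
#' stages.
#'
#' @return Character vector of the 19 canonical protein names.
#' @export
#' @examples
#' panel_proteins()
panel_proteins <- function() {
  c("TRAIL-R1", "TRAIL-R2", "Procaspase 8", "FADD", "cFLIP",
    "Bid", "Bcl-2", "Bcl-xL", "Mcl-1", "Bax", "Bak",
    "Smac", "Cytochrome C", "Apaf-1", "Procaspase 9", "Procaspase 3",
    "XIAP", "cIAP1", "cIAP2")
}

# normalization key: case-insensitive, alphanumeric only
.protein_key <- function(x) toupper(gsub("[^A-Za-z0-9]", "", x))

.protein_aliases <- function() {
  canon <- panel_proteins()
  alias <- c(
    "TNFRSF10A"   = "TRAIL-R1",  "DR4"   = "TRAIL-R1",
    "TNFRSF10B"   = "TRAIL-R2",  "DR5"   = "TRAIL-R2",
    "CASP8"       = "Procaspase 8", "CASPASE8" = "Procaspase 8",
    "CFLAR"       = "cFLIP",     "FLIP"  = "cFLIP",
    "BCL2L1"      = "Bcl-xL",    "BCLX"  = "Bcl-xL", "BCLXL" = "Bcl-xL",
    "MCL1"        = "Mcl-1",
    "BAK1"        = "Bak",
    "DIABLO"      = "Smac",      "SMACDIABLO" = "Smac",
    "CYCS"        = "Cytochrome C", "CYTC" = "Cytochrome C",
    "CYTOCHROMEC" = "Cytochrome C",
    "APAF1"       = "Apaf-1",
    "CASP9"       = "Procaspase 9", "CASPASE9" = "Procaspase 9",
    "CASP3"       = "Procaspase 3", "CASPASE3" = "Procaspase 3",
    "BIRC2"       = "cIAP1",
    "BIRC3"       = "cIAP2",
    "BCL2"        = "Bcl-2",
    "BID"         = "Bid",
    "BAX"         = "Bax",
    "FADD"        = "FADD",
    "XIAP"        = "XIAP"
  )
  tab <- c(stats::setNames(canon, .protein_key(canon)), stats::setNames(alias, names(alias)))
  tab[!duplicated(names(tab))]
}

#' Canonicalize protein names
#'
#' Maps protein identifiers onto the canonical panel vocabulary via a
#' case-insensitive alias table. Names with no known alias are returned
#' unchanged, so panels of arbitrary (e.g. simulated) proteins pass through.
#'
#' @param x Character vector of protein names.
#' @return Character vector of the same length with panel proteins in
#'   canonical spelling.
#' @export
#' @examples
#' canonical_protein(c("smac/DIABLO", "casp3", "MyNovelProtein"))
canonical_protein <- function(x) {
  tab <- .protein_aliases()
  key <- .protein_key(x)
  hit <- !is.na(tab[key])
  x[hit] <- tab[key[hit]]
  x
}

.response_levels <- function() c("synergistic", "low")

#' Construct a validated expression panel
#'
#' An expression panel holds non-negative relative protein quantities
#' (immunoblot fluorescence corrected for loading; surface receptors as
#' molecules per cell) for a set of samples, one row per sample and one
#' column per protein. Values are in arbitrary units and may span orders of
#' magnitude between proteins; the predictor standardizes each protein
#' before analysis.
#'
#' @param values Numeric matrix, samples in rows, proteins in columns.
#' @param sample_ids Sample names; default taken from `rownames(values)`.
#' @param protein_ids Protein names; default taken from `colnames(values)`.
#'   Names are canonicalized against [panel_proteins()].
#' @return An object of class `"expression_panel"` with elements
#'   `values`, `sample_ids`, `protein_ids`.
#' @export
expression_panel <- function(values, sample_ids = rownames(values),
                             protein_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids) || is.null(protein_ids))
    stop("expression panel requires sample and protein identifiers", call. = FALSE)
  sample_ids <- as.character(sample_ids)
  protein_ids <- canonical_protein(as.character(protein_ids))
  if (nrow(values) != length(sample_ids) || ncol(values) != length(protein_ids))
    stop("matrix dimensions do not match identifier lists", call. = FALSE)
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("expression panel needs at least 2 samples and 2 proteins", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(protein_ids))
    stop("duplicate protein ids: ",
         paste(unique(protein_ids[duplicated(protein_ids)]), collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-finite or negative value at sample '%s', protein '%s'",
                 sample_ids[bad[1L, 1L]], protein_ids[bad[1L, 2L]]), call. = FALSE)
  dimnames(values) <- list(sample_ids, protein_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 protein_ids = protein_ids),
            class = "expression_panel")
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("expression panel: %d samples x %d proteins\n",
              length(x$sample_ids), length(x$protein_ids)))
  cat("proteins:", paste(utils::head(x$protein_ids, 8L), collapse = ", "),
      if (length(x$protein_ids) > 8L) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.expression_panel <- function(x) dim(x$values)

#' Subset an expression panel
#'
#' @param panel An [expression_panel()].
#' @param samples,proteins Optional character vectors of ids to keep,
#'   in the order given.
#' @return A new `expression_panel`.
#' @export
subset_panel <- function(panel, samples = NULL, proteins = NULL) {
  stopifnot(inherits(panel, "expression_panel"))
  s <- if (is.null(samples)) panel$sample_ids else as.character(samples)
  p <- if (is.null(proteins)) panel$protein_ids else canonical_protein(as.character(proteins))
  miss <- setdiff(s, panel$sample_ids)
  if (length(miss)) stop("unknown sample ids: ", paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(p, panel$protein_ids)
  if (length(miss)) stop("unknown protein ids: ", paste(miss, collapse = ", "), call. = FALSE)
  expression_panel(panel$values[s, p, drop = FALSE], s, p)
}

#' Construct a validated response table
#'
#' Two response classes are recognized: `"synergistic"` (cell killing by the
#' combination exceeds the fractional-product independence expectation) and
#' `"low"`.
#'
#' @param sample_ids Character vector of unique sample names.
#' @param labels Character vector of class labels, one per sample.
#' @return An object of class `"response_table"`: a data frame with columns
#'   `sample_id` and `label`.
#' @export
response_table <- function(sample_ids, labels) {
  sample_ids <- as.character(sample_ids)
  labels <- as.character(labels)
  if (length(sample_ids) != length(labels))
    stop("sample_ids and labels differ in length", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(labels), .response_levels())
  if (length(bad))
    stop("unknown response label(s): ", paste(bad, collapse = ", "),
         "; expected one of: ", paste(.response_levels(), collapse = ", "),
         call. = FALSE)
  structure(data.frame(sample_id = sample_ids, label = labels,
                       stringsAsFactors = FALSE),
            class = c("response_table", "data.frame"))
}

# Align a response table to a panel's sample order; id sets must match.
.align_labels <- function(panel, labels) {
  stopifnot(inherits(panel, "expression_panel"), inherits(labels, "response_table"))
  if (!setequal(panel$sample_ids, labels$sample_id))
    stop("sample ids of panel and response table do not match", call. = FALSE)
  labels$label[match(panel$sample_ids, labels$sample_id)]
}

# Sniff the field delimiter of a delimited text file (tab canonical,
# comma accepted).
.sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path, call. = FALSE)
  ntab <- lengths(regmatches(first, gregexpr("\t", first)))
  ncom <- lengths(regmatches(first, gregexpr(",", first)))
  if (ntab >= ncom) "\t" else ","
}

#' Read an expression panel from delimited text
#'
#' Reads a TSV or CSV matrix (delimiter sniffed from the header line) with
#' sample and protein identifiers in the header row and first column. Either
#' orientation is accepted and normalized to samples-in-rows, so reading a
#' matrix and its transpose yields identical panels.
#'
#' @param path Path to a delimited text file.
#' @param orientation `"samples-in-rows"` (default) or `"proteins-in-rows"`.
#' @return An [expression_panel()].
#' @export
read_panel <- function(path, orientation = c("samples-in-rows", "proteins-in-rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, row.names = NULL,
                          colClasses = "character", comment.char = "")
  if (ncol(df) < 2L || nrow(df) < 1L)
    stop("malformed panel file (need id column plus data): ", path, call. = FALSE)
  ids <- df[[1L]]
  body <- df[, -1L, drop = FALSE]
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  num <- matrix(num, nrow = nrow(body),
                dimnames = list(ids, colnames(body)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s' in %s",
                 body[bad[1L, 1L], bad[1L, 2L]], ids[bad[1L, 1L]],
                 colnames(body)[bad[1L, 2L]], path), call. = FALSE)
  if (orientation == "proteins-in-rows") num <- t(num)
  expression_panel(num)
}

#' Write an expression panel to delimited text
#'
#' @param panel An [expression_panel()].
#' @param path Output path; tab-separated, samples in rows.
#' @return Invisibly, `path`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "expression_panel"))
  df <- data.frame(sample = panel$sample_ids, panel$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a response label table from delimited text
#'
#' Expects two columns: sample id and response label
#' (`synergistic` or `low`).
#'
#' @param path Path to a delimited text file with a header row.
#' @return A [response_table()].
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2L) stop("response file needs two columns (id, label): ", path,
                          call. = FALSE)
  response_table(df[[1L]], df[[2L]])
}

#' Write a response table to delimited text
#'
#' @param table A [response_table()].
#' @param path Output path; tab-separated.
#' @return Invisibly, `path`.
#' @export
write_responses <- function(table, path) {
  stopifnot(inherits(table, "response_table"))
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write per-sample predictions
#'
#' Writes one row per sample with id, predicted label, discriminant
#' posterior and the principal-component coordinates, tab-separated at full
#' double precision so the file round-trips losslessly.
#'
#' @param predictions Data frame as returned by
#'   [predict.predictor_model()]: columns `sample_id`, `label`, `posterior`
#'   and one column per retained component.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_predictions <- function(predictions, path) {
  if (!is.data.frame(predictions) || nrow(predictions) == 0L)
    stop("no predictions to write", call. = FALSE)
  need <- c("sample_id", "label", "posterior")
  miss <- setdiff(need, names(predictions))
  if (length(miss)) stop("prediction table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  out <- predictions
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a predictions file written by [write_predictions()]
#'
#' @param path Path to the predictions file.
#' @return Data frame with `sample_id`, `label`, `posterior` and component
#'   coordinate columns.
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  df
}

#' Pipeline run configuration
#'
#' Collects the tunable parameters of the pipeline with their documented
#' defaults.
#'
#' @param kaiser_threshold Eigenvalue cutoff for component retention
#'   (Kaiser criterion); default 1.
#' @param n_pcs_max Cap on retained components; default 6, matching the
#'   six-component space used for classification.
#' @param lda_priors `"empirical"` (class frequencies, default) or
#'   `"equal"`.
#' @param synergy_threshold Minimum mean synergy score for the
#'   `synergistic` class; default 0.1.
#' @param cv_folds Folds for merit ranking; default 10.
#' @param rng_seed Integer seed for stochastic stages (fold shuffling);
#'   default 20170101.
#' @param tie_policy Class assigned on an exact posterior tie; default
#'   `"low"` (conservative: a knife-edge sample is not called a responder).
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(kaiser_threshold = 1.0, n_pcs_max = 6L,
                       lda_priors = c("empirical", "equal"),
                       synergy_threshold = 0.1, cv_folds = 10L,
                       rng_seed = 20170101L,
                       tie_policy = c("low", "synergistic")) {
  lda_priors <- match.arg(lda_priors)
  tie_policy <- match.arg(tie_policy)
  cfg <- list(kaiser_threshold = as.numeric(kaiser_threshold),
              n_pcs_max = as.integer(n_pcs_max),
              lda_priors = lda_priors,
              synergy_threshold = as.numeric(synergy_threshold),
              cv_folds = as.integer(cv_folds),
              rng_seed = as.integer(rng_seed),
              tie_policy = tie_policy)
  num <- c(cfg$kaiser_threshold, cfg$n_pcs_max, cfg$synergy_threshold,
           cfg$cv_folds, cfg$rng_seed)
  if (any(!is.finite(num))) stop("run_config fields must be finite", call. = FALSE)
  if (cfg$cv_folds < 2L) stop("cv_folds must be at least 2", call. = FALSE)
  if (cfg$n_pcs_max < 1L) stop("n_pcs_max must be at least 1", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Unset fields take the documented defaults of [run_config()].
#'
#' @param path Path to a YAML file whose keys mirror [run_config()]
#'   arguments.
#' @return A `run_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) stop("unknown config key(s): ", paste(extra, collapse = ", "),
                          call. = FALSE)
  do.call(run_config, vals)
}

#' Deterministic fingerprint of a run configuration
#'
#' A human-readable key=value digest recorded in trained models so that a
#' serialized predictor carries the configuration it was fitted under.
#'
#' @param config A [run_config()].
#' @return Single character string.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "run_config"))
  paste(vapply(names(config), function(k)
    sprintf("%s=%s", k, format(config[[k]], digits = 15)), character(1L)),
    collapse = ";")
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. Keeps every stochastic stage a pure function of its seed
# without clobbering the session RNG.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
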