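# In silico cohort trial: map cohort mRNA profiles (log2(FPKM-UQ+1)) onto
# the measured protein scale through per-protein min-max point-to-point
# standard curves, then classify every patient with a trained predictor to
# estimate response prevalence.

#' Construct a validated cohort expression matrix
#'
#' Holds normalized transcriptome values on the log2(FPKM-UQ+1) scale
#' (upper-quartile-normalized fragments per kilobase per million mapped
#' reads), one row per patient.
#'
#' @param values Numeric matrix, patients in rows, genes in columns; finite
#'   and non-negative.
#' @param patient_ids,gene_ids Identifiers; defaults from dimnames.
#' @return An object of class `"cohort_matrix"`.
#' @export
cohort_matrix <- function(values, patient_ids = rownames(values),
                          gene_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(patient_ids) || is.null(gene_ids))
    stop("cohort matrix requires patient and gene identifiers", call. = FALSE)
  patient_ids <- as.character(patient_ids)
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(patient_ids)) stop("duplicate patient ids", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids", call. = FALSE)
  if (any(!is.finite(values) | values < 0))
    stop("cohort values must be finite and non-negative (log2(FPKM-UQ+1))",
         call. = FALSE)
  dimnames(values) <- list(patient_ids, gene_ids)
  structure(list(values = values, patient_ids = patient_ids,
                 gene_ids = gene_ids),
            class = "cohort_matrix")
}

#' Read a cohort matrix from delimited text
#'
#' @param path Delimited text file, patients in rows, genes in columns.
#' @return A [cohort_matrix()].
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  cohort_matrix(m)
}

#' Gene-to-protein mapping table
#'
#' @param genes Gene symbols as used in the cohort matrix.
#' @param proteins Matching panel protein names (canonicalized).
#' @return An object of class `"gene_protein_map"`: data frame with columns
#'   `gene`, `protein`, one gene per protein.
#' @export
gene_protein_map <- function(genes, proteins) {
  genes <- as.character(genes)
  proteins <- canonical_protein(as.character(proteins))
  if (length(genes) != length(proteins))
    stop("genes and proteins differ in length", call. = FALSE)
  if (anyDuplicated(proteins)) stop("a protein is mapped to multiple genes",
                                    call. = FALSE)
  if (anyDuplicated(genes)) stop("a gene is mapped to multiple proteins",
                                 call. = FALSE)
  structure(data.frame(gene = genes, protein = proteins,
                       stringsAsFactors = FALSE),
            class = c("gene_protein_map", "data.frame"))
}

#' Default gene map for the 11-protein reduced predictor
#'
#' Covers the eleven highest-merit proteins with their unambiguous coding
#' genes. The full 19-protein panel has no default map because surface
#' receptor and cFLIP isoform mappings are ambiguous and must be supplied
#' by the user.
#'
#' @return A [gene_protein_map()] of 11 pairs.
#' @export
default_gene_map <- function() {
  gene_protein_map(
    genes = c("XIAP", "CASP3", "CYCS", "MCL1", "BIRC2", "BAX",
              "BID", "BCL2L1", "DIABLO", "FADD", "BAK1"),
    proteins = c("XIAP", "Procaspase 3", "Cytochrome C", "Mcl-1", "cIAP1",
                 "Bax", "Bid", "Bcl-xL", "Smac", "FADD", "Bak"))
}

#' Back-transform log-scale cohort expression to the linear scale
#'
#' Inverts the log2(FPKM-UQ+1) normalization: returns `2^v - 1`.
#'
#' @param v Values on the log2(FPKM-UQ+1) scale; non-negative, vectorized.
#' @return Linear-scale expression values.
#' @export
#' @examples
#' back_transform(c(0, 1, log2(11)))  # 0, 1, 10
back_transform <- function(v) {
  if (any(!is.finite(v)) || any(v < 0))
    stop("log2(FPKM-UQ+1) values must be finite and non-negative", call. = FALSE)
  2^v - 1
}

#' Fit per-protein min-max interpolation curves
#'
#' For every mapped protein a point-to-point standard curve is drawn through
#' two anchor points: (minimum back-transformed cohort mRNA, minimum panel
#' protein quantity) and (maximum cohort mRNA, maximum panel protein
#' quantity). With two points the point-to-point curve is exactly the
#' connecting line; cohort extremes map onto the panel's measured expression
#' range per protein. Interpolation operates on the back-transformed
#' (linear) mRNA scale by default; a log-scale mode is available for
#' sensitivity analysis.
#'
#' @param panel Training [expression_panel()] providing the protein ranges.
#' @param cohort A [cohort_matrix()] providing the mRNA ranges.
#' @param map A [gene_protein_map()]; every mapped protein must be in the
#'   panel and every mapped gene in the cohort.
#' @param scale `"linear"` (default; back-transform before fitting) or
#'   `"log"`.
#' @return An object of class `"interpolation_map"`: data frame with one
#'   row per protein (`protein`, `gene`, `mrna_min`, `mrna_max`,
#'   `prot_min`, `prot_max`, `slope`, `intercept`).
#' @export
fit_interpolation <- function(panel, cohort, map, scale = c("linear", "log")) {
  stopifnot(inherits(panel, "expression_panel"),
            inherits(cohort, "cohort_matrix"),
            inherits(map, "gene_protein_map"))
  scale <- match.arg(scale)
  miss <- setdiff(map$protein, panel$protein_ids)
  if (length(miss)) stop("panel lacks mapped protein(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(map$gene, cohort$gene_ids)
  if (length(miss)) stop("cohort lacks mapped gene(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  rows <- lapply(seq_len(nrow(map)), function(i) {
    g <- map$gene[i]; pr <- map$protein[i]
    mv <- cohort$values[, g]
    if (scale == "linear") mv <- back_transform(mv)
    m_rng <- range(mv)
    p_rng <- range(panel$values[, pr])
    if (m_rng[2L] <= m_rng[1L])
      stop("degenerate mRNA range for gene ", g, call. = FALSE)
    if (p_rng[2L] <= p_rng[1L])
      stop("degenerate protein range for ", pr, call. = FALSE)
    slope <- (p_rng[2L] - p_rng[1L]) / (m_rng[2L] - m_rng[1L])
    data.frame(protein = pr, gene = g,
               mrna_min = m_rng[1L], mrna_max = m_rng[2L],
               prot_min = p_rng[1L], prot_max = p_rng[2L],
               slope = slope, intercept = p_rng[1L] - slope * m_rng[1L],
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("interpolation_map", "data.frame"), scale = scale)
}

#' Estimate patient protein profiles from cohort mRNA
#'
#' Back-transforms each patient's mRNA values and evaluates the per-protein
#' standard curves, yielding estimated protein quantities on the training
#' panel's measurement scale. Estimates are clamped to the panel's protein
#' range (relevant only when a curve fitted on one cohort is deployed on
#' another); the number of clamped cells is reported via a message.
#'
#' @param cohort A [cohort_matrix()].
#' @param imap An [fit_interpolation()] map.
#' @param map The [gene_protein_map()] used to fit `imap`.
#' @return An [expression_panel()] of estimated protein quantities,
#'   patients in rows.
#' @export
estimate_profiles <- function(cohort, imap, map) {
  stopifnot(inherits(cohort, "cohort_matrix"),
            inherits(imap, "interpolation_map"),
            inherits(map, "gene_protein_map"))
  miss <- setdiff(imap$protein, map$protein)
  if (length(miss)) stop("gene map does not cover interpolation protein(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  log_scale <- identical(attr(imap, "scale"), "log")
  out <- matrix(NA_real_, nrow = length(cohort$patient_ids),
                ncol = nrow(imap),
                dimnames = list(cohort$patient_ids, imap$protein))
  clamped <- 0L
  for (i in seq_len(nrow(imap))) {
    mv <- cohort$values[, imap$gene[i]]
    if (!log_scale) mv <- back_transform(mv)
    est <- imap$intercept[i] + imap$slope[i] * mv
    lo <- imap$prot_min[i]; hi <- imap$prot_max[i]
    clamped <- clamped + sum(est < lo | est > hi)
    out[, i] <- pmin(pmax(est, lo), hi)
  }
  if (clamped > 0L)
    message(sprintf("estimate_profiles: %d estimate(s) clamped to the panel range",
                    clamped))
  expression_panel(out)
}

#' Run an in silico trial on a cohort
#'
#' Estimates every patient's protein profile from the cohort transcriptome
#' and positions it in the trained predictor's PC space; the fraction of
#' patients classified as synergistic responders is the predicted response
#' prevalence.
#'
#' @param model A trained [train_predictor()] model whose protein subset is
#'   covered by the interpolation map.
#' @param cohort A [cohort_matrix()].
#' @param imap An [fit_interpolation()] map.
#' @param map The matching [gene_protein_map()].
#' @return List with `predictions` (per-patient data frame from
#'   [predict.predictor_model()]), `n_responders`, `n_patients` and
#'   `prevalence`.
#' @export
run_trial <- function(model, cohort, imap, map) {
  stopifnot(inherits(model, "predictor_model"))
  miss <- setdiff(model$proteins, imap$protein)
  if (length(miss)) stop("interpolation map does not cover model protein(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  profiles <- estimate_profiles(cohort, imap, map)
  pred <- stats::predict(model, profiles)
  n_resp <- sum(pred$label == "synergistic")
  list(predictions = pred, n_responders = n_resp,
       n_patients = nrow(pred), prevalence = n_resp / nrow(pred))
}
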