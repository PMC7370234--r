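# Webb fractional-product synergy scoring of factorial dose-response grids
# and derivation of the two response classes.

#' Independence expectation under Webb's fractional product
#'
#' For two agents killing fractions `f_a` and `f_b` of cells when given
#' alone, the fraction expected to die under the combination if the agents
#' act independently is `f_a + f_b - f_a * f_b` (the fractional-product /
#' Bliss independence expectation on the fraction-affected scale). Observed
#' combination kill in excess of this expectation indicates synergy.
#'
#' @param f_a,f_b Fractions affected in `[0, 1]`; vectorized.
#' @return Expected fraction affected, in `[max(f_a, f_b), 1]`.
#' @export
#' @examples
#' webb_expected(0.4, 0.5)  # 0.70
webb_expected <- function(f_a, f_b) {
  if (any(!is.finite(f_a)) || any(!is.finite(f_b)) ||
      any(f_a < 0 | f_a > 1) || any(f_b < 0 | f_b > 1))
    stop("fractions affected must lie in [0, 1]", call. = FALSE)
  f_a + f_b - f_a * f_b
}

#' Construct a validated dose-response grid
#'
#' One grid per sample: fractions of dead cells measured over monotherapy
#' dose series of agent A (TRAIL-receptor agonist, nM) and agent B (IAP
#' antagonist, uM) plus their factorial combinations. Every combination
#' condition must have both monotherapy partners at matching doses so that
#' the independence expectation can be evaluated.
#'
#' @param sample_id Sample name.
#' @param conditions Data frame with columns `dose_a`, `dose_b`, `f_dead`.
#' @param replicate_count Number of replicates behind each mean fraction.
#' @return An object of class `"dose_response_grid"`.
#' @export
dose_response_grid <- function(sample_id, conditions, replicate_count = 1L) {
  conditions <- as.data.frame(conditions)
  need <- c("dose_a", "dose_b", "f_dead")
  miss <- setdiff(need, names(conditions))
  if (length(miss)) stop("conditions lack column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  conditions <- conditions[need]
  if (any(!is.finite(as.matrix(conditions))))
    stop("doses and fractions must be finite", call. = FALSE)
  if (any(conditions$dose_a < 0) || any(conditions$dose_b < 0))
    stop("doses must be non-negative", call. = FALSE)
  if (any(conditions$f_dead < 0 | conditions$f_dead > 1))
    stop("f_dead must lie in [0, 1]", call. = FALSE)
  if (anyDuplicated(conditions[c("dose_a", "dose_b")]))
    stop("duplicate treatment condition in grid", call. = FALSE)
  combo <- conditions$dose_a > 0 & conditions$dose_b > 0
  if (any(combo)) {
    key <- function(a, b) paste(sprintf("%.15g", a), sprintf("%.15g", b))
    have <- key(conditions$dose_a, conditions$dose_b)
    need_a <- key(conditions$dose_a[combo], 0)
    need_b <- key(0, conditions$dose_b[combo])
    if (!all(need_a %in% have) || !all(need_b %in% have))
      stop("combination condition without matching monotherapy entries",
           call. = FALSE)
  }
  structure(list(sample_id = as.character(sample_id),
                 conditions = conditions,
                 replicate_count = as.integer(replicate_count)),
            class = "dose_response_grid")
}

#' Read dose-response grids from delimited text
#'
#' Expects columns `sample`, `dose_a_nM`, `dose_b_uM`, `f_dead` (delimiter
#' sniffed; tab canonical).
#'
#' @param path Path to the grid file.
#' @return Named list of [dose_response_grid()] objects, one per sample.
#' @export
read_dose_grids <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample", "dose_a_nM", "dose_b_uM", "f_dead")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("grid file lacks column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  out <- lapply(split(df, df$sample), function(d)
    dose_response_grid(d$sample[1L],
                       data.frame(dose_a = d$dose_a_nM, dose_b = d$dose_b_uM,
                                  f_dead = d$f_dead)))
  out[unique(df$sample)]
}

#' Score a dose-response grid for synergy
#'
#' For every combination condition the observed fraction affected is
#' compared with the fractional-product expectation built from the matching
#' monotherapy entries; the synergy score is the excess
#' `f_obs - f_exp` (bounded in `[-1, 1]`). The per-sample summary is the
#' mean score over combination conditions. With
#' `control_correction = "normalize-to-control"` all fractions are first
#' corrected for spontaneous death via `(f - f_ctrl) / (1 - f_ctrl)` using
#' the untreated `(0, 0)` condition, then clipped to `[0, 1]` (replicate
#' noise can produce small negatives).
#'
#' @param grid A [dose_response_grid()].
#' @param control_correction `"none"` (default; the assay reports
#'   propidium-iodide positivity directly) or `"normalize-to-control"`.
#' @param score_type `"difference"` (default, `f_obs - f_exp`) or `"ratio"`
#'   (`f_obs / f_exp`).
#' @return An object of class `"synergy_result"`: list with `sample_id`,
#'   `records` (data frame `dose_a, dose_b, f_a, f_b, f_obs, f_exp, score`)
#'   and `mean_score`.
#' @export
score_grid <- function(grid, control_correction = c("none", "normalize-to-control"),
                       score_type = c("difference", "ratio")) {
  stopifnot(inherits(grid, "dose_response_grid"))
  control_correction <- match.arg(control_correction)
  score_type <- match.arg(score_type)
  cond <- grid$conditions
  if (control_correction == "normalize-to-control") {
    ctrl <- cond$dose_a == 0 & cond$dose_b == 0
    if (!any(ctrl)) stop("normalize-to-control requires a (0, 0) condition",
                         call. = FALSE)
    f_ctrl <- cond$f_dead[ctrl][1L]
    if (f_ctrl >= 1) stop("degenerate control: all cells dead untreated",
                          call. = FALSE)
    f <- (cond$f_dead - f_ctrl) / (1 - f_ctrl)
    if (any(f < 0)) warning("negative control-corrected fractions clipped to 0")
    cond$f_dead <- pmin(pmax(f, 0), 1)
  }
  combo <- which(cond$dose_a > 0 & cond$dose_b > 0)
  if (length(combo) == 0L)
    stop("grid has no combination conditions to score", call. = FALSE)
  key <- function(a, b) paste(sprintf("%.15g", a), sprintf("%.15g", b))
  have <- key(cond$dose_a, cond$dose_b)
  mono_a <- match(key(cond$dose_a[combo], 0), have)
  mono_b <- match(key(0, cond$dose_b[combo]), have)
  if (anyNA(mono_a) || anyNA(mono_b))
    stop("combination condition without matching monotherapy entries",
         call. = FALSE)
  f_a <- cond$f_dead[mono_a]
  f_b <- cond$f_dead[mono_b]
  f_obs <- cond$f_dead[combo]
  f_exp <- webb_expected(f_a, f_b)
  score <- if (score_type == "difference") f_obs - f_exp else f_obs / f_exp
  records <- data.frame(dose_a = cond$dose_a[combo], dose_b = cond$dose_b[combo],
                        f_a = f_a, f_b = f_b, f_obs = f_obs, f_exp = f_exp,
                        score = score)
  structure(list(sample_id = grid$sample_id, records = records,
                 mean_score = mean(score), score_type = score_type),
            class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf("synergy result for %s: %d combinations, mean score %.3f\n",
              x$sample_id, nrow(x$records), x$mean_score))
  invisible(x)
}

#' Derive the response class from a synergy result
#'
#' A sample is a `synergistic` responder when its mean synergy score over
#' combination conditions exceeds the threshold, otherwise a `low`
#' responder.
#'
#' @param result A [score_grid()] result.
#' @param threshold Minimum mean score for the synergistic call;
#'   default 0.1.
#' @return `"synergistic"` or `"low"`.
#' @export
classify_response <- function(result, threshold = 0.1) {
  stopifnot(inherits(result, "synergy_result"))
  if (nrow(result$records) < 1L)
    stop("synergy result has no combination records", call. = FALSE)
  if (result$mean_score > threshold) "synergistic" else "low"
}
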