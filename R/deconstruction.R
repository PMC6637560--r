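ci_bounds <- function(x, method) {
  n <- length(x)
  m <- mean(x)
  s <- stats::sd(x)
  half <- if (method == "normal_se") 1.96 * s / sqrt(n) else 2 * s
  c(mean = m, sd = s, ci_low = m - half, ci_high = m + half)
}

#' Per-cell score summary across facilities
#'
#' Mean normalized cell score with a confidence interval:
#' `"normal_se"` (default) gives mean +/- 1.96 * SD / sqrt(n);
#' `"two_sd"` gives mean +/- 2 * SD. For z-score-normalized scenarios the
#' means are 0 by construction, so the SD column carries the signal there.
#'
#' @param result A `composite_result` with >= 2 facilities.
#' @param method `"normal_se"` or `"two_sd"`.
#' @return Data frame: `scenario`, `cell_id`, `dimension`, `element`,
#'   `mean`, `sd`, `ci_low`, `ci_high`, `n`, `ci_method`.
#' @export
cell_summary <- function(result, method = c("normal_se", "two_sd")) {
  method <- match.arg(method)
  nrm <- result$cell_scores$normalized
  if (nrow(nrm) < 2L) qstop("cell_summary needs >= 2 facilities")
  parts <- strsplit(colnames(nrm), "_(?=[^_]+$)", perl = TRUE)
  rows <- lapply(seq_len(ncol(nrm)), function(j) {
    b <- ci_bounds(nrm[, j], method)
    data.frame(scenario = result$scenario, cell_id = colnames(nrm)[j],
               dimension = parts[[j]][1], element = parts[[j]][2],
               mean = b["mean"], sd = b["sd"],
               ci_low = b["ci_low"], ci_high = b["ci_high"],
               n = nrow(nrm), ci_method = method,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Element totals across the matrix
#'
#' For each Donabedian element, the sum of its cell means across the
#' active dimensions (range 0 to the number of dimensions under min-max
#' cell normalization). For additive scenarios the three element totals
#' sum exactly to the mean facility composite.
#'
#' @param result A `composite_result`.
#' @return Data frame: `scenario`, `element`, `mean_total`, `n_cells`.
#' @export
element_totals <- function(result) {
  nrm <- result$cell_scores$normalized
  el <- sub(".*_", "", colnames(nrm))
  rows <- lapply(qoc_elements(), function(e) {
    cols <- which(el == e)
    data.frame(scenario = result$scenario, element = e,
               mean_total = sum(colMeans(nrm[, cols, drop = FALSE])),
               n_cells = length(cols), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-facility element sub-scores
#'
#' @param result A `composite_result`.
#' @return Facility x element matrix of summed normalized cell scores.
#' @export
facility_element_scores <- function(result) {
  nrm <- result$cell_scores$normalized
  el <- sub(".*_", "", colnames(nrm))
  out <- vapply(qoc_elements(), function(e)
    rowSums(nrm[, el == e, drop = FALSE]),
    numeric(nrow(nrm)))
  rownames(out) <- rownames(nrm)
  out
}

#' Composite score summary
#'
#' @param scores Named numeric vector of composite scores (>= 2).
#' @param method `"normal_se"` or `"two_sd"`.
#' @return One-row data frame: `mean`, `sd`, `ci_low`, `ci_high`, `n`,
#'   `ci_method`.
#' @export
composite_summary <- function(scores, method = c("normal_se", "two_sd")) {
  method <- match.arg(method)
  if (length(scores) < 2L) qstop("composite_summary needs >= 2 facilities")
  b <- ci_bounds(as.numeric(scores), method)
  data.frame(mean = b["mean"], sd = b["sd"], ci_low = b["ci_low"],
             ci_high = b["ci_high"], n = length(scores),
             ci_method = method, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Indicator contributions to their cell scores
#'
#' Mean normalized indicator value times the indicator's weight share of
#' its cell — where each facility's quality composite actually comes from.
#'
#' @param result A `composite_result` (carries the normalized indicator
#'   matrix).
#' @param map The `indicator_map` used to build it.
#' @return Data frame: `indicator_id`, `cell_id`, `mean_value`,
#'   `weight_share`, `contribution`.
#' @export
indicator_contributions <- function(result, map) {
  by_cell <- Filter(length, map$matrix$indicators_by_cell)
  rows <- lapply(names(by_cell), function(cid) {
    ids <- by_cell[[cid]]
    w <- resolve_weights(result$config$indicator_weights, ids,
                         "indicator_weights")
    share <- w / sum(w)
    mv <- colMeans(result$indicator_values[, ids, drop = FALSE])
    data.frame(indicator_id = ids, cell_id = cid,
               mean_value = unname(mv), weight_share = unname(share),
               contribution = unname(mv * share),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
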