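#' Scenario configuration
#'
#' A scenario is the full set of construction choices: how non-binary
#' indicators are normalized, how indicators aggregate into cell scores,
#' how cell scores are normalized, and how cells aggregate into the
#' composite. Weights default to equal; user weight tables are normalized
#' so that equal weights reproduce plain sums (preserving the 0-12 scale).
#'
#' @param name Scenario label.
#' @param indicator_normalization `"binarize"` (cutoff rules) or `"minmax"`
#'   (empirical rescale of non-binary indicators to \[0,1\]).
#' @param indicator_aggregation `"additive"` (weighted sum) or
#'   `"geometric"` (product; any 0 gives 0).
#' @param cell_normalization `"minmax_theoretical"` (divide by the cell's
#'   possible maximum), `"minmax_empirical"`, or `"zscore"`.
#' @param cell_aggregation `"additive"` or `"geometric"`.
#' @param indicator_weights `"equal"` or a named numeric vector by
#'   indicator id.
#' @param cell_weights `"equal"` or a named numeric vector by cell id.
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(name,
                            indicator_normalization = "binarize",
                            indicator_aggregation = "additive",
                            cell_normalization = "minmax_theoretical",
                            cell_aggregation = "additive",
                            indicator_weights = "equal",
                            cell_weights = "equal") {
  check_weights <- function(w, what) {
    if (identical(w, "equal")) return(w)
    if (!is.numeric(w) || is.null(names(w)))
      qstop(what, " must be \"equal\" or a named numeric vector")
    if (any(w < 0) || all(w == 0))
      qstop(what, " must be non-negative with at least one positive entry")
    w
  }
  structure(list(
    name = as.character(name),
    indicator_normalization = match_enum(indicator_normalization,
                                         c("binarize", "minmax"),
                                         "indicator_normalization"),
    indicator_aggregation = match_enum(indicator_aggregation,
                                       c("additive", "geometric"),
                                       "indicator_aggregation"),
    cell_normalization = match_enum(cell_normalization,
                                    c("minmax_theoretical",
                                      "minmax_empirical", "zscore"),
                                    "cell_normalization"),
    cell_aggregation = match_enum(cell_aggregation,
                                  c("additive", "geometric"),
                                  "cell_aggregation"),
    indicator_weights = check_weights(indicator_weights, "indicator_weights"),
    cell_weights = check_weights(cell_weights, "cell_weights")
  ), class = "scenario_config")
}

#' Built-in scenario presets
#'
#' `base`: binarize, additive, theoretical min-max cells, additive.
#' Each alternative changes exactly one choice: `alt_a` min-max indicator
#' rescaling, `alt_b` geometric indicator aggregation, `alt_c` z-score
#' cell standardization, `alt_d` geometric cell aggregation.
#'
#' @param name Preset name.
#' @return A `scenario_config` ([scenario_preset()]) or named list of all
#'   five ([scenario_presets()]).
#' @export
scenario_preset <- function(name) {
  switch(match_enum(name, c("base", "alt_a", "alt_b", "alt_c", "alt_d"),
                    "preset"),
         base  = scenario_config("base"),
         alt_a = scenario_config("alt_a", indicator_normalization = "minmax"),
         alt_b = scenario_config("alt_b", indicator_aggregation = "geometric"),
         alt_c = scenario_config("alt_c", cell_normalization = "zscore"),
         alt_d = scenario_config("alt_d", cell_aggregation = "geometric"))
}

#' @rdname scenario_preset
#' @export
scenario_presets <- function() {
  nm <- c("base", "alt_a", "alt_b", "alt_c", "alt_d")
  stats::setNames(lapply(nm, scenario_preset), nm)
}

#' Orient an indicator column
#'
#' Higher-is-better columns pass through. Lower-is-better columns are
#' reflected (`max(x) - x`) ahead of min-max rescaling; binarization
#' instead handles direction through the cutoff comparator (see
#' [binarize_indicator()]), and lower-is-better binary indicators flip
#' 0 <-> 1.
#'
#' @param x Numeric column.
#' @param direction `"higher_better"` or `"lower_better"`.
#' @param var_type Variable type; binary columns flip, others reflect.
#' @return Oriented column.
#' @export
orient_indicator <- function(x, direction, var_type = "continuous") {
  match_enum(direction, qoc_directions(), "direction")
  if (direction == "higher_better") return(x)
  if (var_type == "binary") 1 - x else max(x) - x
}

#' Binarize a non-binary indicator at its cutoff
#'
#' Higher-is-better: 1 iff value >= cutoff. Lower-is-better (or an
#' explicit `fixed_le` rule): 1 iff value <= cutoff, so a median cutoff
#' always satisfies itself.
#'
#' @param x Numeric column.
#' @param cutoff Resolved numeric cutoff.
#' @param direction `"higher_better"` or `"lower_better"`.
#' @param comparator Optional override: `"ge"` or `"le"`.
#' @return 0/1 column.
#' @export
binarize_indicator <- function(x, cutoff, direction = "higher_better",
                               comparator = NULL) {
  if (is.na(cutoff)) qstop("binarize_indicator: cutoff did not resolve")
  cmp <- comparator %||%
    if (direction == "lower_better") "le" else "ge"
  if (cmp == "ge") as.numeric(x >= cutoff) else as.numeric(x <= cutoff)
}

# Resolve a parsed cutoff rule against the observed column.
resolve_cutoff <- function(def, x) {
  switch(def$cutoff_type,
         fixed = ,
         fixed_le = def$cutoff_value,
         median = {
           if (all(is.na(x)))
             qstop(sprintf("median cutoff for '%s': column is all missing",
                           def$indicator_id))
           stats::median(x, na.rm = TRUE)
         },
         none = qstop(sprintf("indicator '%s' has no cutoff rule",
                              def$indicator_id)))
}

#' Min-max rescale a column to \[0, 1\]
#'
#' With theoretical bounds `lo`/`hi` the transform is `(x - lo)/(hi - lo)`
#' and values must lie inside the bounds. Without bounds the observed
#' min/max are used; a constant column maps to 0.5 everywhere with a
#' degeneracy warning.
#'
#' @param x Numeric column (>= 2 values for empirical bounds).
#' @param lo,hi Optional theoretical bounds, `lo < hi`.
#' @return Column in \[0, 1\].
#' @export
minmax_rescale <- function(x, lo = NULL, hi = NULL) {
  if (!is.null(lo) || !is.null(hi)) {
    if (is.null(lo) || is.null(hi) || !(lo < hi))
      qstop("theoretical bounds require lo < hi")
    if (any(x < lo | x > hi, na.rm = TRUE))
      qstop(sprintf("value outside declared bounds [%g, %g]", lo, hi))
    return((x - lo) / (hi - lo))
  }
  if (length(x) < 2L) qstop("empirical min-max needs at least 2 values")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    qwarn("constant column under empirical min-max; mapped to 0.5")
    return(rep(0.5, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Z-score standardize a column
#'
#' Centers to mean 0 and scales to sample standard deviation 1 (n - 1
#' denominator). A constant column maps to all zeros with a warning.
#'
#' @param x Numeric column (>= 2 values).
#' @return Standardized column.
#' @export
zscore_standardize <- function(x) {
  if (length(x) < 2L) qstop("z-score needs at least 2 values")
  s <- stats::sd(x)
  if (s == 0) {
    qwarn("constant column under z-score; mapped to 0")
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

# Normalize all indicator columns for a scenario. Binary indicators pass
# through (flipped if lower_better); non-binary follow the scenario's
# choice of cutoff binarization or oriented empirical min-max.
normalize_indicators <- function(table, map, method) {
  ind <- map$indicators
  out <- table$values
  for (i in seq_len(nrow(ind))) {
    id <- ind$indicator_id[i]
    x <- out[, id]
    if (ind$var_type[i] == "binary") {
      out[, id] <- orient_indicator(x, ind$direction[i], "binary")
    } else if (method == "binarize") {
      cutoff <- resolve_cutoff(ind[i, ], x)
      cmp <- if (ind$cutoff_type[i] == "fixed_le") "le" else NULL
      out[, id] <- binarize_indicator(x, cutoff, ind$direction[i], cmp)
    } else {
      out[, id] <- minmax_rescale(orient_indicator(x, ind$direction[i],
                                                   ind$var_type[i]))
    }
  }
  out
}

# Normalize weights over the components they cover so they sum to the
# component count; "equal" becomes unit weights (plain sums).
resolve_weights <- function(spec, ids, what) {
  if (identical(spec, "equal")) return(stats::setNames(rep(1, length(ids)), ids))
  missing <- setdiff(ids, names(spec))
  if (length(missing))
    qstop(what, " missing for: ", paste(missing, collapse = ", "))
  w <- spec[ids]
  if (sum(w) == 0) qstop(what, ": all-zero weights for ", paste(ids, collapse = ","))
  w * length(ids) / sum(w)
}

#' Aggregate indicator columns into a raw cell score
#'
#' Additive: weighted sum (equal weights are plain sums, so binarized
#' indicators give integer cell scores with maximum = indicator count).
#' Geometric: plain product — any single 0 zeroes the cell
#' (non-compensability); requires non-negative inputs.
#'
#' @param x Facility x indicator matrix of normalized values.
#' @param method `"additive"` or `"geometric"`.
#' @param weights Numeric weights (already resolved), additive only.
#' @return Numeric cell score per facility.
#' @export
aggregate_indicators <- function(x, method = "additive",
                                 weights = rep(1, ncol(x))) {
  x <- as.matrix(x)
  if (method == "additive") return(drop(x %*% weights))
  if (any(x < 0))
    qstop("geometric aggregation requires non-negative values")
  apply(x, 1, prod)
}

# Normalize a facility x cell matrix of raw scores.
normalize_cells <- function(raw, method, cell_maxima) {
  out <- raw
  for (cid in colnames(raw)) {
    out[, cid] <- switch(method,
      minmax_theoretical = minmax_rescale(raw[, cid], lo = 0,
                                          hi = cell_maxima[cid]),
      minmax_empirical = minmax_rescale(raw[, cid]),
      zscore = zscore_standardize(raw[, cid]))
  }
  out
}

#' Aggregate normalized cell scores into the composite
#'
#' Additive: weighted sum — with equal weights and min-max cells the
#' composite ranges over \[0, number of cells\] (0-12 for the 4 x 3
#' matrix). Geometric: product of cell values, range \[0, 1\] for min-max
#' cells; any cell at 0 zeroes the composite. Geometric aggregation of
#' negative cell values (possible after z-scores) is an error.
#'
#' @param cells Facility x cell matrix of normalized scores.
#' @param method `"additive"` or `"geometric"`.
#' @param weights Resolved cell weights (additive only).
#' @return Named numeric composite per facility.
#' @export
aggregate_cells <- function(cells, method = "additive",
                            weights = rep(1, ncol(cells))) {
  cells <- as.matrix(cells)
  if (method == "additive") return(drop(cells %*% weights))
  if (any(cells < 0))
    qstop("geometric cell aggregation needs non-negative cell scores; ",
          "use a min-max cell normalization instead of z-scores")
  apply(cells, 1, prod)
}

#' Run one construction scenario
#'
#' Executes the full pipeline: orient -> indicator normalization ->
#' indicator aggregation into raw cell scores -> cell normalization ->
#' cell aggregation into the composite. Deterministic for fixed inputs.
#'
#' @param table Imputed [facility_table()].
#' @param map An `indicator_map` (only populated cells contribute).
#' @param config A [scenario_config()] or preset name.
#' @return A `composite_result`: list with `scenario`, `config`,
#'   `facility_scores` (named numeric), `cell_scores` (list `raw`,
#'   `normalized`, `cell_maxima`), `indicator_values` (normalized
#'   indicator matrix), and `scale_range` (numeric `c(lo, hi)` or the
#'   string `"unbounded"`).
#' @export
run_scenario <- function(table, map, config = scenario_preset("base")) {
  if (is.character(config)) config <- scenario_preset(config)
  if (!inherits(config, "scenario_config"))
    qstop("config must be a scenario_config or preset name")

  norm_ind <- normalize_indicators(table, map,
                                   config$indicator_normalization)
  by_cell <- Filter(length, map$matrix$indicators_by_cell)
  cells <- names(by_cell)
  facilities <- rownames(table$values)

  raw <- matrix(NA_real_, length(facilities), length(cells),
                dimnames = list(facilities, cells))
  cell_maxima <- stats::setNames(numeric(length(cells)), cells)
  for (cid in cells) {
    ids <- by_cell[[cid]]
    w <- resolve_weights(config$indicator_weights, ids, "indicator_weights")
    raw[, cid] <- aggregate_indicators(norm_ind[, ids, drop = FALSE],
                                       config$indicator_aggregation, w)
    # additive: maximum is the weight sum (= indicator count); geometric:
    # the product of all-1 inputs is 1 whatever the count
    cell_maxima[cid] <- if (config$indicator_aggregation == "additive")
      sum(w) else 1
  }

  normalized <- normalize_cells(raw, config$cell_normalization, cell_maxima)
  cw <- resolve_weights(config$cell_weights, cells, "cell_weights")
  composite <- aggregate_cells(normalized, config$cell_aggregation, cw)

  scale_range <- if (config$cell_normalization == "zscore") {
    "unbounded"
  } else if (config$cell_aggregation == "additive") {
    c(0, sum(cw))
  } else c(0, 1)

  structure(list(
    scenario = config$name,
    config = config,
    facility_scores = stats::setNames(as.numeric(composite), facilities),
    cell_scores = list(raw = raw, normalized = normalized,
                       cell_maxima = cell_maxima),
    indicator_values = norm_ind,
    scale_range = scale_range
  ), class = "composite_result")
}

#' @export
print.composite_result <- function(x, ...) {
  rng <- if (identical(x$scale_range, "unbounded")) "unbounded"
         else sprintf("%g-%g", x$scale_range[1], x$scale_range[2])
  cat(sprintf("composite_result '%s': %d facilities, %d cells, scale %s\n",
              x$scenario, length(x$facility_scores),
              ncol(x$cell_scores$raw), rng))
  print(round2(utils::head(sort(x$facility_scores, decreasing = TRUE), 5)))
  invisible(x)
}

#' Run the base construction and all four alternatives
#'
#' @inheritParams run_scenario
#' @return Named list of five `composite_result`s (`base`, `alt_a` ...
#'   `alt_d`), identical facility ordering.
#' @export
run_base_and_alternatives <- function(table, map) {
  lapply(scenario_presets(), function(cfg) run_scenario(table, map, cfg))
}

#' Export scenario scores as a tidy data frame
#'
#' One row per facility: composite, scale bounds, and the raw and
#' normalized score of every cell. Full precision (rounding is left to
#' reports).
#'
#' @param result A `composite_result`.
#' @return Data frame.
#' @export
scores_frame <- function(result) {
  raw <- result$cell_scores$raw
  nrm <- result$cell_scores$normalized
  lo <- if (identical(result$scale_range, "unbounded")) NA_real_
        else result$scale_range[1]
  hi <- if (identical(result$scale_range, "unbounded")) NA_real_
        else result$scale_range[2]
  df <- data.frame(facility_id = names(result$facility_scores),
                   scenario = result$scenario,
                   composite = unname(result$facility_scores),
                   scale_lo = lo, scale_hi = hi,
                   stringsAsFactors = FALSE)
  for (cid in colnames(raw)) df[[paste0("raw.", cid)]] <- raw[, cid]
  for (cid in colnames(nrm)) df[[paste0("norm.", cid)]] <- nrm[, cid]
  df
}
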