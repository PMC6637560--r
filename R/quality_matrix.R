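#' Quality-of-care matrix vocabulary
#'
#' The conceptual matrix crosses quality-of-care dimensions (effective,
#' efficient, accessible/timely, patient-centered/acceptable, equitable,
#' safe) with the Donabedian elements structure, process, and outcome.
#' Each indicator is assigned to exactly one (dimension, element) cell.
#'
#' @return Character vector of the closed enum values.
#' @export
qoc_dimensions <- function() {
  c("effective", "efficient", "accessible", "patient_centered",
    "equitable", "safe")
}

#' @rdname qoc_dimensions
#' @export
qoc_elements <- function() c("structure", "process", "outcome")

#' @rdname qoc_dimensions
#' @export
qoc_source_tools <- function() {
  c("inventory", "observation", "provider_interview", "exit_interview")
}

qoc_var_types <- function() c("binary", "ordinal", "continuous")
qoc_directions <- function() c("higher_better", "lower_better")

cell_id <- function(dimension, element) paste(dimension, element, sep = "_")

# Parse the serialized cutoff rule: "none", "median", "fixed:<x>",
# "fixed_le:<x>" (fixed cutoff with a <= comparator for lower-is-better).
parse_cutoff_rule <- function(rule, row = NA_integer_) {
  rule <- trimws(as.character(rule %||% "none"))
  if (rule == "" || is.na(rule)) rule <- "none"
  where <- if (is.na(row)) "" else sprintf(" (row %d)", row)
  if (rule %in% c("none", "median")) {
    return(list(type = rule, value = NA_real_))
  }
  m <- regmatches(rule, regexec("^(fixed|fixed_le):([-0-9.eE+]+)$", rule))[[1]]
  if (length(m) == 3L) {
    val <- suppressWarnings(as.numeric(m[3]))
    if (!is.na(val)) return(list(type = m[2], value = val))
  }
  qstop(sprintf(
    "invalid cutoff_rule '%s'%s: expected none, median, fixed:<x> or fixed_le:<x>",
    rule, where))
}

format_cutoff_rule <- function(type, value) {
  switch(type,
         none = "none",
         median = "median",
         fixed = sprintf("fixed:%g", value),
         fixed_le = sprintf("fixed_le:%g", value))
}

#' Build a quality matrix from an indicator table
#'
#' Enumerates the cross-product of the active dimensions with the three
#' Donabedian elements (elements major, dimensions minor, both in
#' declaration order) and assigns each indicator to its cell. Cells with
#' no indicator are flagged unpopulated rather than dropped; use
#' [drop_unpopulated_dimensions()] to shrink the matrix.
#'
#' @param indicators Validated indicator data frame (see
#'   [load_indicator_map()] for the schema).
#' @param active_dimensions Dimensions to enumerate; defaults to the full
#'   six-dimension vocabulary.
#' @return An object of class `quality_matrix`.
#' @export
build_quality_matrix <- function(indicators,
                                 active_dimensions = qoc_dimensions()) {
  active_dimensions <- vapply(active_dimensions, match_enum,
                              character(1), qoc_dimensions(), "dimension")
  cells <- expand.grid(dimension = active_dimensions,
                       element = qoc_elements(),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # elements major, dimensions minor
  cells <- cells[order(match(cells$element, qoc_elements()),
                       match(cells$dimension, active_dimensions)), ,
                 drop = FALSE]
  rownames(cells) <- NULL
  cells$cell_id <- cell_id(cells$dimension, cells$element)
  by_cell <- lapply(cells$cell_id, function(cid) {
    indicators$indicator_id[indicators$cell_id == cid]
  })
  names(by_cell) <- cells$cell_id
  structure(list(
    active_dimensions = active_dimensions,
    cells = cells,
    indicators_by_cell = by_cell,
    unpopulated = cells$cell_id[vapply(by_cell, length, 1L) == 0L]
  ), class = "quality_matrix")
}

#' @export
print.quality_matrix <- function(x, ...) {
  counts <- vapply(x$indicators_by_cell, length, 1L)
  cat(sprintf("quality_matrix: %d dimensions x 3 elements = %d cells, %d indicators\n",
              length(x$active_dimensions), nrow(x$cells), sum(counts)))
  grid <- matrix(counts[cell_id(rep(x$active_dimensions, each = 3),
                                 rep(qoc_elements(), length(x$active_dimensions)))],
                 nrow = length(x$active_dimensions), byrow = TRUE,
                 dimnames = list(x$active_dimensions, qoc_elements()))
  print(grid)
  if (length(x$unpopulated))
    cat("unpopulated cells:", paste(x$unpopulated, collapse = ", "), "\n")
  invisible(x)
}

validate_indicators <- function(df) {
  required <- c("indicator_id", "label", "dimension", "element", "source_tool",
                "var_type", "direction", "cutoff_rule", "proxy_id")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    qstop("indicator map is missing columns: ",
          paste(missing_cols, collapse = ", "))
  for (col in required) df[[col]] <- trimws(as.character(df[[col]]))
  df$proxy_id[df$proxy_id == "" | is.na(df$proxy_id)] <- NA_character_

  dup <- df$indicator_id[duplicated(df$indicator_id)]
  if (length(dup))
    qstop("duplicate indicator_id: ", paste(unique(dup), collapse = ", "))
  if (any(df$indicator_id == ""))
    qstop(sprintf("empty indicator_id at row %d",
                  which(df$indicator_id == "")[1]))

  for (i in seq_len(nrow(df))) {
    ctx <- sprintf("row %d, indicator '%s'", i, df$indicator_id[i])
    match_enum(df$dimension[i], qoc_dimensions(), "dimension", ctx)
    match_enum(df$element[i], qoc_elements(), "element", ctx)
    match_enum(df$source_tool[i], qoc_source_tools(), "source_tool", ctx)
    match_enum(df$var_type[i], qoc_var_types(), "var_type", ctx)
    match_enum(df$direction[i], qoc_directions(), "direction", ctx)
  }

  parsed <- lapply(seq_len(nrow(df)),
                   function(i) parse_cutoff_rule(df$cutoff_rule[i], i))
  df$cutoff_type <- vapply(parsed, `[[`, character(1), "type")
  df$cutoff_value <- vapply(parsed, `[[`, numeric(1), "value")

  bad_bin <- df$var_type == "binary" & df$cutoff_type != "none"
  if (any(bad_bin))
    qstop("binary indicators must have cutoff_rule 'none': ",
          paste(df$indicator_id[bad_bin], collapse = ", "))
  bad_nonbin <- df$var_type != "binary" & df$cutoff_type == "none"
  if (any(bad_nonbin))
    qstop("ordinal/continuous indicators need a cutoff_rule (median or fixed): ",
          paste(df$indicator_id[bad_nonbin], collapse = ", "))

  dangling <- !is.na(df$proxy_id) & !df$proxy_id %in% df$indicator_id
  if (any(dangling))
    qstop("proxy_id references unknown indicator: ",
          paste(df$proxy_id[dangling], collapse = ", "))
  self_proxy <- !is.na(df$proxy_id) & df$proxy_id == df$indicator_id
  if (any(self_proxy))
    qstop("indicator cannot be its own proxy: ",
          paste(df$indicator_id[self_proxy], collapse = ", "))

  df$cutoff_rule <- mapply(format_cutoff_rule, df$cutoff_type, df$cutoff_value)
  df$cell_id <- cell_id(df$dimension, df$element)
  rownames(df) <- NULL
  df
}

#' Load and validate an indicator map
#'
#' The indicator map is the input assigning each quality indicator to
#' exactly one matrix cell, together with its source tool, variable type,
#' direction, cutoff rule and optional proxy. Assignments are validated,
#' never recomputed: resolving ambiguous cell assignments is an upstream,
#' expert-judgment task.
#'
#' CSV columns (exact): `indicator_id,label,dimension,element,source_tool,`
#' `var_type,direction,cutoff_rule,proxy_id`. `cutoff_rule` is serialized
#' as `none`, `median`, `fixed:<number>` or `fixed_le:<number>`.
#'
#' @param path CSV file path, or a data frame with the same columns.
#' @return An object of class `indicator_map` with components `indicators`
#'   (validated data frame, plus parsed `cutoff_type`/`cutoff_value` and
#'   `cell_id` columns) and `matrix` (a [build_quality_matrix()] result over
#'   all six dimensions).
#' @export
load_indicator_map <- function(path) {
  df <- if (is.data.frame(path)) {
    path
  } else {
    if (!file.exists(path)) qstop("indicator map not found: ", path)
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = character())
  }
  indicators <- validate_indicators(df)
  map <- structure(list(
    indicators = indicators,
    matrix = build_quality_matrix(indicators)
  ), class = "indicator_map")
  assert_partition(map)
  map
}

#' @export
print.indicator_map <- function(x, ...) {
  cat(sprintf("indicator_map: %d indicators\n", nrow(x$indicators)))
  print(x$matrix)
  invisible(x)
}

# Partition property: every indicator in exactly one cell, union covers all.
assert_partition <- function(map) {
  assigned <- unlist(map$matrix$indicators_by_cell, use.names = FALSE)
  ids <- map$indicators$indicator_id
  if (anyDuplicated(assigned) ||
      !setequal(assigned, ids) ||
      length(assigned) != length(ids))
    qstop("internal error: indicator/cell assignment is not a partition")
  invisible(map)
}

#' Drop dimensions with no mapped indicators
#'
#' Removes dimensions whose three cells are all unpopulated (e.g. when the
#' available data cannot support the efficiency and equity dimensions,
#' shrinking a 6 x 3 matrix to 4 x 3 = 12 cells). Idempotent; removals are
#' logged via `message()`.
#'
#' @param map An `indicator_map` (or bare `quality_matrix`).
#' @return Object of the same class with empty dimensions removed.
#' @export
drop_unpopulated_dimensions <- function(map) {
  if (inherits(map, "indicator_map")) {
    qm <- map$matrix
  } else if (inherits(map, "quality_matrix")) {
    qm <- map
  } else qstop("expected an indicator_map or quality_matrix")

  counts <- vapply(qm$indicators_by_cell, length, 1L)
  keep <- vapply(qm$active_dimensions, function(d) {
    any(counts[cell_id(d, qoc_elements())] > 0L)
  }, logical(1))
  dropped <- qm$active_dimensions[!keep]
  if (length(dropped))
    message("dropping unpopulated dimensions: ",
            paste(dropped, collapse = ", "))
  kept <- qm$active_dimensions[keep]
  if (length(kept) == 0L)
    qstop("no dimension has any mapped indicator")
  if (length(kept) == 1L)
    qwarn("matrix reduced to a single dimension (3 cells)")

  if (inherits(map, "indicator_map")) {
    map$matrix <- build_quality_matrix(map$indicators, kept)
    assert_partition(map)
    map
  } else {
    # rebuild from the cell assignment alone
    ind <- data.frame(
      indicator_id = unlist(qm$indicators_by_cell, use.names = FALSE),
      cell_id = rep(names(qm$indicators_by_cell),
                    vapply(qm$indicators_by_cell, length, 1L)),
      stringsAsFactors = FALSE)
    build_quality_matrix(ind, kept)
  }
}

#' Write an indicator map to CSV
#'
#' @param map `indicator_map` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_indicator_map <- function(map, path) {
  cols <- c("indicator_id", "label", "dimension", "element", "source_tool",
            "var_type", "direction", "cutoff_rule", "proxy_id")
  df <- map$indicators[, cols]
  df$proxy_id[is.na(df$proxy_id)] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
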