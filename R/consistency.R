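#' Within-cell indicator pair correlations
#'
#' Screens every indicator pair inside each matrix cell for redundancy
#' using the Pearson product-moment correlation (equal to the phi
#' coefficient when both indicators are binary). Pairs involving a
#' zero-variance column get `NA` with `degenerate = TRUE` rather than an
#' error.
#'
#' @param table Imputed [facility_table()].
#' @param map An `indicator_map`.
#' @return Data frame: `cell_id`, `indicator_a`, `indicator_b`,
#'   `correlation`, `degenerate`.
#' @export
pairwise_cell_correlations <- function(table, map) {
  rows <- list()
  for (cid in names(map$matrix$indicators_by_cell)) {
    ids <- map$matrix$indicators_by_cell[[cid]]
    if (length(ids) < 2L) next
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq(i + 1L, length(ids))) {
        a <- table$values[, ids[i]]
        b <- table$values[, ids[j]]
        degen <- stats::sd(a) == 0 || stats::sd(b) == 0
        r <- if (degen) NA_real_ else stats::cor(a, b)
        rows[[length(rows) + 1L]] <- data.frame(
          cell_id = cid, indicator_a = ids[i], indicator_b = ids[j],
          correlation = r, degenerate = degen, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(cell_id = character(), indicator_a = character(),
                      indicator_b = character(), correlation = numeric(),
                      degenerate = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$degenerate))
    qwarn(sprintf("%d pairs involve a zero-variance indicator; excluded from flagging",
                  sum(out$degenerate)))
  out
}

#' Flag redundant indicator pairs for review
#'
#' Pairs with correlation strictly greater than the threshold are returned
#' for human review; nothing is merged automatically. The rule is
#' one-sided (r > threshold, sign preserved) by default; set
#' `absolute = TRUE` to flag |r| > threshold.
#'
#' @param flags Output of [pairwise_cell_correlations()].
#' @param threshold Correlation bound in (0, 1\]; default 0.7.
#' @param absolute Flag on absolute correlation instead.
#' @return The flagged subset, highest correlation first.
#' @export
flag_redundant <- function(flags, threshold = 0.7, absolute = FALSE) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    qstop("threshold must lie in (0, 1]")
  r <- if (absolute) abs(flags$correlation) else flags$correlation
  keep <- !flags$degenerate & !is.na(r) & r > threshold
  out <- flags[keep, , drop = FALSE]
  out[order(-if (absolute) abs(out$correlation) else out$correlation), ,
      drop = FALSE]
}

#' Read a reviewed merge map
#'
#' CSV columns: `survivor_id,absorbed_ids,combined_label`, with
#' `absorbed_ids` semicolon-separated.
#'
#' @param path CSV path or data frame.
#' @return A `merge_map`: list of entries (survivor_id, absorbed_ids,
#'   combined_label).
#' @export
read_merge_map <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("survivor_id", "absorbed_ids", "combined_label")
  if (!all(need %in% names(df)))
    qstop("merge map needs columns: ", paste(need, collapse = ", "))
  entries <- lapply(seq_len(nrow(df)), function(i) {
    list(survivor_id = trimws(df$survivor_id[i]),
         absorbed_ids = trimws(strsplit(df$absorbed_ids[i], ";")[[1]]),
         combined_label = df$combined_label[i])
  })
  structure(entries, class = "merge_map")
}

validate_merge_map <- function(merges, map) {
  ids <- map$indicators$indicator_id
  absorbed_all <- unlist(lapply(merges, `[[`, "absorbed_ids"))
  survivors <- vapply(merges, `[[`, character(1), "survivor_id")
  if (anyDuplicated(absorbed_all))
    qstop("indicator absorbed twice in merge map: ",
          paste(unique(absorbed_all[duplicated(absorbed_all)]), collapse = ", "))
  if (any(survivors %in% absorbed_all))
    qstop("a survivor is itself absorbed: ",
          paste(intersect(survivors, absorbed_all), collapse = ", "))
  unknown <- setdiff(c(survivors, absorbed_all), ids)
  if (length(unknown))
    qstop("merge map references unknown indicators: ",
          paste(unknown, collapse = ", "))
  cells <- stats::setNames(map$indicators$cell_id, ids)
  for (e in merges) {
    if (length(unique(cells[c(e$survivor_id, e$absorbed_ids)])) != 1L)
      qstop(sprintf("merge for '%s' crosses matrix cells", e$survivor_id))
  }
  invisible(merges)
}

#' Apply a reviewed merge map
#'
#' Each merge replaces the survivor column by the mean of the merged
#' columns, re-binarized at the 0.5 cutoff when all merged indicators are
#' binary; absorbed columns are removed from the table and the map, so
#' downstream cell maxima shrink accordingly. Merging across cells is an
#' error. An empty merge map is the identity.
#'
#' @param table Imputed [facility_table()].
#' @param map An `indicator_map`.
#' @param merges A [read_merge_map()] result (or equivalent list).
#' @return List with updated `table` and `map`.
#' @export
apply_merge_map <- function(table, map, merges) {
  if (!length(merges)) return(list(table = table, map = map))
  validate_merge_map(merges, map)
  ind <- map$indicators
  vals <- table$values
  drop_ids <- character()
  for (e in merges) {
    cols <- c(e$survivor_id, e$absorbed_ids)
    merged <- rowMeans(vals[, cols, drop = FALSE])
    types <- ind$var_type[match(cols, ind$indicator_id)]
    if (all(types == "binary"))
      merged <- as.numeric(binarize_share(merged))
    vals[, e$survivor_id] <- merged
    ind$label[ind$indicator_id == e$survivor_id] <- e$combined_label
    drop_ids <- c(drop_ids, e$absorbed_ids)
  }
  keep <- !colnames(vals) %in% drop_ids
  new_table <- facility_table(vals[, keep, drop = FALSE],
                              table$provenance[, keep, drop = FALSE],
                              table$pre_missing[keep])
  ind <- ind[!ind$indicator_id %in% drop_ids, , drop = FALSE]
  rownames(ind) <- NULL
  new_map <- structure(list(
    indicators = ind,
    matrix = build_quality_matrix(ind, map$matrix$active_dimensions)
  ), class = "indicator_map")
  assert_partition(new_map)
  list(table = new_table, map = new_map)
}
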