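#' Read one source dataset
#'
#' The four source tools are: `inventory` (facility-level, at most one row
#' per facility), and `observation`, `provider_interview`, `exit_interview`
#' (individual-level, any number of rows per facility, keyed by a mandatory
#' `facility_id` column). Missing values are empty fields.
#'
#' @param path CSV path or data frame.
#' @param tool One of [qoc_source_tools()].
#' @return A `source_recordset`: list with `tool`, `level`
#'   (`"facility"`/`"individual"`) and `records` (data frame).
#' @export
read_source_csv <- function(path, tool) {
  tool <- match_enum(tool, qoc_source_tools(), "source_tool")
  df <- if (is.data.frame(path)) path else {
    if (!file.exists(path)) qstop("source file not found: ", path)
    utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  }
  if (!"facility_id" %in% names(df))
    qstop(sprintf("%s data lacks the mandatory facility_id column", tool))
  df$facility_id <- as.character(df$facility_id)
  level <- if (tool == "inventory") "facility" else "individual"
  if (level == "facility" && anyDuplicated(df$facility_id))
    qstop("inventory has more than one row for facility: ",
          paste(unique(df$facility_id[duplicated(df$facility_id)]),
                collapse = ", "))
  structure(list(tool = tool, level = level, records = df),
            class = "source_recordset")
}

#' Aggregate individual-level records to facility level
#'
#' Each variable is averaged within facility, excluding missing entries
#' from the mean. Binary-source variables therefore become proportions in
#' \[0, 1\]; continuous variables become means. Facility-level recordsets
#' pass through unchanged. A variable with no observed value at a facility
#' is left missing (handled downstream by imputation or the completeness
#' filter).
#'
#' @param rs A `source_recordset` from [read_source_csv()].
#' @return Data frame: one row per facility, `facility_id` first.
#' @export
aggregate_to_facility <- function(rs) {
  if (!inherits(rs, "source_recordset"))
    qstop("expected a source_recordset")
  df <- rs$records
  if (rs$level == "facility") {
    rownames(df) <- NULL
    return(df)
  }
  vars <- setdiff(names(df), "facility_id")
  fac <- unique(df$facility_id)
  out <- data.frame(facility_id = fac, stringsAsFactors = FALSE)
  for (v in vars) {
    m <- tapply(df[[v]], df$facility_id, function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0L) NA_real_ else mean(x)
    })
    out[[v]] <- as.numeric(m[fac])
  }
  rownames(out) <- NULL
  out
}

#' Re-binarize a facility-level proportion
#'
#' Facility proportions obtained by averaging binary individual-level
#' observations are turned back into binary indicators with a 0.5 cutoff:
#' 0 for values below 0.5, 1 for 0.5 or greater.
#'
#' @param p Numeric vector in \[0, 1\]; `NA` passes through.
#' @return Integer vector of 0/1 (and `NA`).
#' @export
binarize_share <- function(p) {
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad))
    qstop("binarize_share: value outside [0,1]: ",
          paste(utils::head(p[bad], 3), collapse = ", "))
  out <- ifelse(is.na(p), NA_integer_, as.integer(p >= 0.5))
  out
}

#' Keep only facilities covered by all required tools
#'
#' A composite drawing on every data source is only meaningful for
#' facilities where every required tool was actually applied; others are
#' dropped (never imputed at whole-tool level).
#'
#' @param tables Named list of facility-level tables (one per tool, as from
#'   [aggregate_to_facility()]), names drawn from [qoc_source_tools()].
#' @param required_tools Tools a facility must have; defaults to all
#'   supplied tools.
#' @return Character vector of retained facility ids, with a `dropped`
#'   attribute (data frame of facility_id and missing tools).
#' @export
filter_complete_facilities <- function(tables,
                                       required_tools = names(tables)) {
  if (!length(tables) || is.null(names(tables)))
    qstop("tables must be a named list of per-tool facility tables")
  required_tools <- vapply(required_tools, match_enum, character(1),
                           qoc_source_tools(), "source_tool")
  all_fac <- unique(unlist(lapply(tables, function(t) t$facility_id)))
  if (!length(all_fac)) qstop("no facilities in any source table")
  has_tool <- vapply(required_tools, function(tl) {
    tab <- tables[[tl]]
    if (is.null(tab)) rep(FALSE, length(all_fac))
    else all_fac %in% tab$facility_id
  }, logical(length(all_fac)))
  if (is.null(dim(has_tool))) has_tool <- matrix(has_tool, nrow = 1)
  complete <- rowSums(!has_tool) == 0L
  dropped <- data.frame(
    facility_id = all_fac[!complete],
    missing_tools = apply(has_tool[!complete, , drop = FALSE], 1, function(r)
      paste(required_tools[!r], collapse = ";")),
    stringsAsFactors = FALSE)
  if (nrow(dropped))
    message(sprintf("dropping %d facilities lacking required tools: %s",
                    nrow(dropped),
                    paste(dropped$facility_id, collapse = ", ")))
  retained <- all_fac[complete]
  if (!length(retained))
    qstop("no facility has all required tools; cannot build a composite")
  structure(retained, dropped = dropped)
}

#' Imputation policy
#'
#' Controls how missing facility-level entries are filled. The default
#' matches the base construction: missing direct-observation tasks are
#' taken as not observed (zero fill); other binary gaps try a declared
#' proxy indicator first, then the sample mode; continuous (and ordinal,
#' whose facility values are already means) gaps take the sample mean.
#' Alternatives: `observation_missing = "one"` (benefit of the doubt) or
#' `"mode"`, and `binary_missing = "mode"` to skip proxies.
#'
#' @param observation_missing `"zero"`, `"one"`, or `"mode"`.
#' @param binary_missing `"proxy_then_mode"` or `"mode"`.
#' @param continuous_missing `"mean"` (the only supported strategy).
#' @return An `imputation_policy` object.
#' @export
imputation_policy <- function(observation_missing = "zero",
                              binary_missing = "proxy_then_mode",
                              continuous_missing = "mean") {
  structure(list(
    observation_missing = match_enum(observation_missing,
                                     c("zero", "one", "mode"),
                                     "observation_missing"),
    binary_missing = match_enum(binary_missing,
                                c("proxy_then_mode", "mode"),
                                "binary_missing"),
    continuous_missing = match_enum(continuous_missing, "mean",
                                    "continuous_missing")
  ), class = "imputation_policy")
}

#' Facility-by-indicator table
#'
#' Thin container for the facility x indicator value grid plus per-entry
#' provenance (`observed` or the imputation rule that filled it) and the
#' pre-imputation missing count per indicator.
#'
#' @param values Numeric matrix, rownames = facility ids, colnames =
#'   indicator ids.
#' @param provenance Optional character matrix of the same shape.
#' @param pre_missing Optional named integer vector (per indicator).
#' @return A `facility_table` object.
#' @export
facility_table <- function(values, provenance = NULL, pre_missing = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    qstop("facility_table values need facility rownames and indicator colnames")
  storage.mode(values) <- "double"
  if (is.null(provenance)) {
    provenance <- matrix("observed", nrow(values), ncol(values),
                         dimnames = dimnames(values))
  }
  if (is.null(pre_missing)) {
    pre_missing <- colSums(is.na(values))
  }
  structure(list(values = values, provenance = provenance,
                 pre_missing = pre_missing),
            class = "facility_table")
}

#' @export
print.facility_table <- function(x, ...) {
  cat(sprintf("facility_table: %d facilities x %d indicators, %d imputed entries\n",
              nrow(x$values), ncol(x$values),
              sum(x$provenance != "observed")))
  invisible(x)
}

# Assemble the facility x indicator grid from per-tool tables; each
# indicator's values come from its declared source tool.
build_facility_table <- function(tables, map, facilities) {
  ind <- map$indicators
  values <- matrix(NA_real_, length(facilities), nrow(ind),
                   dimnames = list(facilities, ind$indicator_id))
  for (i in seq_len(nrow(ind))) {
    tab <- tables[[ind$source_tool[i]]]
    if (is.null(tab))
      qstop(sprintf("no data supplied for tool '%s' (indicator '%s')",
                    ind$source_tool[i], ind$indicator_id[i]))
    if (!ind$indicator_id[i] %in% names(tab))
      qstop(sprintf("indicator '%s' not found in %s data",
                    ind$indicator_id[i], ind$source_tool[i]))
    idx <- match(facilities, tab$facility_id)
    values[, i] <- as.numeric(tab[[ind$indicator_id[i]]][idx])
  }
  facility_table(values)
}

# Re-binarize binary indicators whose facility-level values are shares.
rebinarize_binary <- function(table, map) {
  ind <- map$indicators
  for (i in which(ind$var_type == "binary")) {
    id <- ind$indicator_id[i]
    table$values[, id] <- as.numeric(binarize_share(table$values[, id]))
  }
  table
}

#' Impute missing facility-level entries
#'
#' Applied after whole-tool completeness filtering (whole-tool absence is
#' never imputed). Observation-tool gaps are filled per
#' `policy$observation_missing`; remaining binary gaps per
#' `policy$binary_missing` (a proxy value is copied from the same
#' facility's proxy indicator when available, else the sample mode, with
#' 0/1 mode ties resolving to 1); ordinal and continuous gaps take the
#' sample mean. Provenance is recorded for every filled entry.
#'
#' @param table A [facility_table()].
#' @param policy An [imputation_policy()].
#' @param map The `indicator_map` (supplies var_type, source_tool,
#'   proxy_id).
#' @return The imputed `facility_table`; no missing entries remain.
#' @export
impute_missing <- function(table, policy = imputation_policy(), map) {
  if (!inherits(policy, "imputation_policy"))
    qstop("policy must be an imputation_policy")
  ind <- map$indicators
  vals <- table$values
  prov <- table$provenance
  pre_missing <- colSums(is.na(vals))

  fill <- function(id, rows, replacement, tag) {
    vals[rows, id] <<- replacement
    prov[rows, id] <<- tag
  }

  for (i in seq_len(nrow(ind))) {
    id <- ind$indicator_id[i]
    miss <- which(is.na(vals[, id]))
    if (!length(miss)) next

    if (ind$source_tool[i] == "observation" &&
        policy$observation_missing != "mode") {
      v <- if (policy$observation_missing == "zero") 0 else 1
      fill(id, miss, v, paste0("imputed_", policy$observation_missing))
      next
    }

    if (ind$var_type[i] == "binary") {
      if (policy$binary_missing == "proxy_then_mode" &&
          !is.na(ind$proxy_id[i])) {
        proxy_vals <- vals[miss, ind$proxy_id[i]]
        ok <- !is.na(proxy_vals)
        if (any(ok)) fill(id, miss[ok], proxy_vals[ok], "imputed_proxy")
        miss <- miss[!ok]
      }
      if (length(miss)) {
        m <- sample_mode(vals[, id])
        if (is.na(m))
          qstop(sprintf(
            "cannot impute '%s': no observed value to take the mode from", id))
        fill(id, miss, m, "imputed_mode")
      }
    } else {
      m <- mean(vals[, id], na.rm = TRUE)
      if (is.nan(m))
        qstop(sprintf(
          "cannot impute '%s': no observed value to take the mean from", id))
      fill(id, miss, m, "imputed_mean")
    }
  }
  facility_table(vals, prov, pre_missing)
}

#' Descriptive screen of an imputed indicator table
#'
#' Per indicator: min/max/mean/SD, pre-imputation missing count, declared
#' direction, a degenerate flag for zero-variance columns and, for
#' non-binary indicators, the count of values outside
#' median +/- 1.5 * IQR.
#'
#' @param table Imputed [facility_table()].
#' @param map The `indicator_map`.
#' @return Data frame, one row per indicator.
#' @export
screen_indicators <- function(table, map) {
  ind <- map$indicators
  out <- lapply(seq_len(nrow(ind)), function(i) {
    id <- ind$indicator_id[i]
    x <- table$values[, id]
    s <- stats::sd(x)
    n_out <- NA_integer_
    if (ind$var_type[i] != "binary") {
      md <- stats::median(x)
      iqr <- stats::IQR(x)
      n_out <- sum(x < md - 1.5 * iqr | x > md + 1.5 * iqr)
    }
    data.frame(indicator_id = id, var_type = ind$var_type[i],
               direction = ind$direction[i],
               min = min(x), max = max(x), mean = mean(x), sd = s,
               n_missing_pre = unname(table$pre_missing[id]),
               degenerate = s == 0, n_outliers = n_out,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' End-to-end ingestion: sources to imputed facility table
#'
#' Aggregates each tool to facility level, drops facilities lacking any
#' required tool, assembles the facility x indicator grid, re-binarizes
#' binary-source proportions at the 0.5 cutoff, and imputes remaining
#' gaps.
#'
#' @param sources Named list (by tool) of `source_recordset`s, data frames,
#'   or CSV paths.
#' @param map An `indicator_map`.
#' @param policy An [imputation_policy()].
#' @param required_tools Tools facilities must have (default: all tools
#'   used by the map's indicators).
#' @return Imputed [facility_table()]; attribute `dropped` lists excluded
#'   facilities.
#' @export
ingest_study <- function(sources, map, policy = imputation_policy(),
                         required_tools = NULL) {
  recsets <- lapply(names(sources), function(tl) {
    s <- sources[[tl]]
    if (inherits(s, "source_recordset")) s else read_source_csv(s, tl)
  })
  names(recsets) <- names(sources)
  tables <- lapply(recsets, aggregate_to_facility)
  required_tools <- required_tools %||%
    intersect(names(tables), unique(map$indicators$source_tool))
  retained <- filter_complete_facilities(tables, required_tools)
  tab <- build_facility_table(tables, map, as.character(retained))
  tab <- rebinarize_binary(tab, map)
  tab <- impute_missing(tab, policy, map)
  attr(tab, "dropped") <- attr(retained, "dropped")
  tab
}
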