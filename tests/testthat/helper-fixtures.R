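# Shared in-code fixtures: a tiny two-cell indicator map, a matching
# 4-facility table, and an independent brute-force scoring oracle.

tiny_map_df <- function() {
  data.frame(
    indicator_id = c("es1", "es2", "es3", "ap1", "ap2", "ap3"),
    label = paste("item", 1:6),
    dimension = c(rep("effective", 3), rep("accessible", 3)),
    element = c(rep("structure", 3), rep("process", 3)),
    source_tool = c(rep("inventory", 3), rep("observation", 3)),
    var_type = c("binary", "binary", "binary",
                 "binary", "continuous", "continuous"),
    direction = c(rep("higher_better", 5), "lower_better"),
    cutoff_rule = c("none", "none", "none", "none", "fixed:3", "median"),
    proxy_id = c(NA, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
}

tiny_map <- function() load_indicator_map(tiny_map_df())

tiny_values <- function() {
  m <- matrix(c(
    # es1 es2 es3 ap1  ap2  ap3
       1,  1,  1,  1,   4,  10,
       1,  0,  1,  1,   3,  20,
       0,  1,  0,  0,   2,  25,
       0,  0,  0,  0,   1,  40),
    nrow = 4, byrow = TRUE,
    dimnames = list(paste0("f", 1:4),
                    c("es1", "es2", "es3", "ap1", "ap2", "ap3")))
  m
}

tiny_table <- function() facility_table(tiny_values())

# Independent oracle: recompute a scenario composite with explicit loops
# straight from the construction formulas, sharing no code with the
# package's pipeline.
oracle_scenario <- function(values, defs, ind_norm, ind_agg,
                            cell_norm, cell_agg) {
  n <- nrow(values)
  norm <- values
  for (j in seq_len(ncol(values))) {
    d <- defs[defs$indicator_id == colnames(values)[j], ]
    x <- values[, j]
    if (d$var_type == "binary") {
      norm[, j] <- if (d$direction == "lower_better") 1 - x else x
    } else if (ind_norm == "binarize") {
      cut <- if (grepl("^fixed", d$cutoff_rule))
        as.numeric(sub("^fixed(_le)?:", "", d$cutoff_rule))
      else median(x)
      norm[, j] <- if (d$direction == "lower_better" ||
                       grepl("^fixed_le", d$cutoff_rule))
        as.numeric(x <= cut) else as.numeric(x >= cut)
    } else {
      y <- if (d$direction == "lower_better") max(x) - x else x
      norm[, j] <- if (max(y) == min(y)) rep(0.5, n)
                   else (y - min(y)) / (max(y) - min(y))
    }
  }
  cells <- unique(paste(defs$dimension, defs$element, sep = "_"))
  raw <- matrix(0, n, length(cells), dimnames = list(rownames(values), cells))
  cmax <- numeric(length(cells))
  for (k in seq_along(cells)) {
    ids <- defs$indicator_id[paste(defs$dimension, defs$element,
                                   sep = "_") == cells[k]]
    for (i in seq_len(n)) {
      vals <- norm[i, ids]
      raw[i, k] <- if (ind_agg == "additive") sum(vals) else prod(vals)
    }
    cmax[k] <- if (ind_agg == "additive") length(ids) else 1
  }
  nc <- raw
  for (k in seq_along(cells)) {
    x <- raw[, k]
    nc[, k] <- switch(cell_norm,
      minmax_theoretical = x / cmax[k],
      minmax_empirical = if (max(x) == min(x)) rep(0.5, n)
                         else (x - min(x)) / (max(x) - min(x)),
      zscore = if (sd(x) == 0) rep(0, n) else (x - mean(x)) / sd(x))
  }
  comp <- numeric(n)
  for (i in seq_len(n)) {
    comp[i] <- if (cell_agg == "additive") sum(nc[i, ]) else prod(nc[i, ])
  }
  names(comp) <- rownames(values)
  comp
}

# A small complete synthetic study shared by several test files; cached
# so the suite builds it once.
shared_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressMessages(
        generate_study(simulation_config(seed = 2024)))
    }
    cache
  }
})

shared_ingest <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      s <- shared_study()
      cache <<- suppressMessages(ingest_study(s$sources, s$map))
    }
    cache
  }
})
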