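#' Simulation configuration
#'
#' Describes a synthetic multi-facility study with known latent quality.
#' Defaults emulate the scale of the motivating study: 26 facilities
#' (optionally 33 with whole-tool dropout), 85 indicators over a
#' 4-dimension x 3-element matrix (one 19-indicator cell, eleven
#' 6-indicator cells), and roughly 3 delivery observations, 3 provider
#' interviews and 8 exit interviews per facility (matching totals of
#' 82/81/204 over 26 facilities). Item missingness is MCAR at a low rate,
#' consistent with high observed data completeness.
#'
#' @param n_facilities Number of facilities (default 26).
#' @param indicators_per_cell Named integer vector (cell_id -> count);
#'   defaults to the 85-indicator layout above.
#' @param records_per_facility Named counts for the individual-level
#'   tools (`observation`, `provider_interview`, `exit_interview`).
#' @param quality_spread SD of latent facility quality on the logit scale
#'   (default 1; latent quality itself lies in (0, 1)).
#' @param signal Slope linking latent quality to item success log-odds
#'   (default 4; larger = less noise).
#' @param item_missing_rate MCAR probability per entry (default 0.02).
#' @param tool_dropout Number of facilities losing one whole tool
#'   (default 0).
#' @param seed Integer seed; all randomness in the package lives here.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_facilities = 26,
                              indicators_per_cell = NULL,
                              records_per_facility = c(
                                observation = 3,
                                provider_interview = 3,
                                exit_interview = 8),
                              quality_spread = 1,
                              signal = 4,
                              item_missing_rate = 0.02,
                              tool_dropout = 0,
                              seed = 1) {
  if (n_facilities < 2) qstop("need at least 2 facilities")
  if (item_missing_rate < 0 || item_missing_rate > 1)
    qstop("item_missing_rate must lie in [0, 1]")
  if (tool_dropout < 0 || tool_dropout > n_facilities)
    qstop("tool_dropout cannot exceed the number of facilities")
  if (any(records_per_facility < 1)) qstop("records_per_facility must be positive")
  if (quality_spread <= 0) qstop("quality_spread must be positive")
  structure(list(
    n_facilities = as.integer(n_facilities),
    indicators_per_cell = indicators_per_cell,
    records_per_facility = records_per_facility,
    quality_spread = quality_spread,
    signal = signal,
    item_missing_rate = item_missing_rate,
    tool_dropout = as.integer(tool_dropout),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# The default synthetic indicator map: 4 active dimensions x 3 elements,
# structure indicators from the facility inventory, process from delivery
# observations, outcome from provider/exit interviews. Includes one fixed-
# cutoff staffing count, one lower-is-better waiting time (median cutoff),
# one ordinal satisfaction rating (median cutoff), and one proxy pair, so
# every cutoff/imputation path is exercised.
synthetic_indicator_map <- function(indicators_per_cell = NULL) {
  dims <- c("effective", "accessible", "patient_centered", "safe")
  cells <- as.vector(t(outer(dims, qoc_elements(), cell_id)))
  default <- stats::setNames(rep(6L, length(cells)), cells)
  default["accessible_structure"] <- 19L
  counts <- indicators_per_cell %||% default
  if (is.null(names(counts))) {
    if (length(counts) != length(cells))
      qstop("indicators_per_cell needs one count per cell (or names)")
    counts <- stats::setNames(as.integer(counts), cells)
  }
  if (any(counts < 1)) qstop("every cell needs at least one indicator")

  tool_for <- function(dim, el) {
    switch(el,
           structure = "inventory",
           process = "observation",
           outcome = if (dim %in% c("effective", "safe"))
             "provider_interview" else "exit_interview")
  }
  rows <- list()
  for (cid in names(counts)) {
    dim <- sub("_(structure|process|outcome)$", "", cid)
    el <- sub(".*_", "", cid)
    ids <- sprintf("%s_%02d", cid, seq_len(counts[cid]))
    for (i in seq_along(ids)) {
      rows[[length(rows) + 1L]] <- data.frame(
        indicator_id = ids[i],
        label = sprintf("%s / %s item %d", dim, el, i),
        dimension = dim, element = el, source_tool = tool_for(dim, el),
        var_type = "binary", direction = "higher_better",
        cutoff_rule = "none", proxy_id = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)

  # non-binary exercises: staffing count (fixed cutoff >= 3), waiting time
  # (lower better, median cutoff), satisfaction rating (ordinal, median)
  special <- function(id, var_type, direction, rule, label) {
    i <- match(id, df$indicator_id)
    df$var_type[i] <<- var_type
    df$direction[i] <<- direction
    df$cutoff_rule[i] <<- rule
    df$label[i] <<- label
  }
  special("accessible_structure_01", "continuous", "higher_better",
          "fixed:3", "skilled birth attendants on staff")
  special("accessible_outcome_01", "continuous", "lower_better",
          "median", "waiting time from arrival to provider contact (min)")
  special("patient_centered_outcome_01", "ordinal", "higher_better",
          "median", "overall satisfaction rating (1-5)")
  # proxy pair within effective/process (two observation checklist items)
  df$proxy_id[df$indicator_id == "effective_process_01"] <-
    "effective_process_02"
  load_indicator_map(df)
}

#' Generate a synthetic multi-source facility study
#'
#' Draws a latent quality score per facility (logit-normal, so in (0, 1)),
#' then binary individual-level items with success probability
#' `plogis(a_cell + signal * (q - 0.5))` (cell-specific intercepts set
#' typical prevalence; the centered slope scales signal), inventory
#' items as Bernoulli(q), a lower-is-better waiting time, an ordinal
#' satisfaction rating, and a quality-linked staffing count. MCAR gaps and
#' whole-tool dropout are injected last. Fully reproducible from
#' `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List: `sources` (named list of four data frames in the dialect
#'   [read_source_csv()] reads), `map` (an `indicator_map`), `truth`
#'   (list `latent_quality`, `true_rank`), `config`.
#' @export
generate_study <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config"))
    qstop("config must be a simulation_config")
  set.seed(config$seed)
  n <- config$n_facilities
  facilities <- sprintf("F%02d", seq_len(n))
  q <- stats::plogis(stats::rnorm(n, 0, config$quality_spread))
  names(q) <- facilities

  map <- synthetic_indicator_map(config$indicators_per_cell)
  map <- drop_unpopulated_dimensions(map)
  ind <- map$indicators
  # cell-specific intercepts set each cell's typical item prevalence; the
  # slope is centered on q = 0.5 so raising the signal sharpens facility
  # separation without pushing whole items into floor/ceiling saturation
  cell_ids <- names(map$matrix$indicators_by_cell)
  a_cell <- stats::setNames(stats::runif(length(cell_ids), -0.5, 1.5),
                            cell_ids)

  draw_binary <- function(ids, fac_rep, q_rep) {
    out <- matrix(NA_real_, length(fac_rep), length(ids),
                  dimnames = list(NULL, ids))
    cid <- ind$cell_id[match(ids, ind$indicator_id)]
    for (j in seq_along(ids)) {
      p <- stats::plogis(a_cell[cid[j]] + config$signal * (q_rep - 0.5))
      out[, j] <- stats::rbinom(length(q_rep), 1, p)
    }
    out
  }

  make_tool <- function(tool) {
    ids <- ind$indicator_id[ind$source_tool == tool]
    if (tool == "inventory") {
      fac_rep <- facilities
      q_rep <- q
    } else {
      r <- config$records_per_facility[[tool]]
      fac_rep <- rep(facilities, each = r)
      q_rep <- rep(q, each = r)
    }
    bin_ids <- ids[ind$var_type[match(ids, ind$indicator_id)] == "binary"]
    df <- data.frame(facility_id = fac_rep, stringsAsFactors = FALSE)
    if (tool == "inventory" && length(bin_ids)) {
      for (id in bin_ids)
        df[[id]] <- stats::rbinom(length(q_rep), 1, q_rep)
    } else if (length(bin_ids)) {
      bm <- draw_binary(bin_ids, fac_rep, q_rep)
      for (id in bin_ids) df[[id]] <- bm[, id]
    }
    for (id in setdiff(ids, bin_ids)) {
      df[[id]] <- switch(id,
        accessible_structure_01 = stats::rpois(length(q_rep), 1 + 4 * q_rep),
        accessible_outcome_01 = pmax(
          1, round(stats::rnorm(length(q_rep), 45 - 40 * q_rep, 12))),
        patient_centered_outcome_01 = pmin(5, pmax(1, round(
          stats::rnorm(length(q_rep), 1.5 + 3.5 * q_rep, 0.8)))),
        qstop("no generator for indicator ", id))
    }
    # keep declared column order
    df[, c("facility_id", ids), drop = FALSE]
  }

  sources <- stats::setNames(
    lapply(qoc_source_tools(), make_tool), qoc_source_tools())

  # MCAR item missingness
  if (config$item_missing_rate > 0) {
    for (tool in names(sources)) {
      df <- sources[[tool]]
      for (v in setdiff(names(df), "facility_id")) {
        gap <- stats::runif(nrow(df)) < config$item_missing_rate
        df[[v]][gap] <- NA
      }
      sources[[tool]] <- df
    }
  }

  # whole-tool dropout: chosen facilities lose one randomly drawn tool
  if (config$tool_dropout > 0) {
    victims <- sample(facilities, config$tool_dropout)
    lost <- sample(qoc_source_tools(), config$tool_dropout, replace = TRUE)
    for (i in seq_along(victims)) {
      df <- sources[[lost[i]]]
      sources[[lost[i]]] <- df[df$facility_id != victims[i], , drop = FALSE]
    }
  }

  list(sources = sources, map = map,
       truth = list(latent_quality = q,
                    true_rank = rank_facilities(q)),
       config = config)
}

#' Write a generated study to disk
#'
#' Emits the CSV dialect [read_source_csv()] expects: `inventory.csv`,
#' `observations.csv`, `provider_interviews.csv`, `exit_interviews.csv`,
#' plus `indicator_map.csv`, `ground_truth.csv` and a `config.json` echo.
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(inventory = "inventory.csv", observation = "observations.csv",
             provider_interview = "provider_interviews.csv",
             exit_interview = "exit_interviews.csv")
  for (tool in names(files)) {
    utils::write.csv(study$sources[[tool]], file.path(dir, files[[tool]]),
                     row.names = FALSE, na = "")
  }
  write_indicator_map(study$map, file.path(dir, "indicator_map.csv"))
  utils::write.csv(
    data.frame(facility_id = names(study$truth$latent_quality),
               latent_quality = unname(study$truth$latent_quality),
               true_rank = unname(study$truth$true_rank)),
    file.path(dir, "ground_truth.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(study$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# md5 of the packaged published-score fixture; guards against silent edits
TABLE3_MD5 <- "372f5f6c6d05e1aa5ecea22af3e03a90"

#' Load the packaged published facility-score fixture
#'
#' Returns the 26 facilities (labeled A-Z in descending base-score order)
#' with their printed composite scores under the base construction and the
#' four alternatives, exactly as published. The file's checksum is
#' verified on load. Note the printed alternative-B column is rounded to
#' 2 decimals, which induces artificial ties.
#'
#' @param path Fixture path; defaults to the installed copy.
#' @return Data frame: `facility`, `base`, `alt_a`, `alt_b`, `alt_c`,
#'   `alt_d`.
#' @export
load_table3_fixture <- function(path = system.file(
    "extdata", "table3_scores.csv", package = "qocindex")) {
  if (!nzchar(path) || !file.exists(path))
    qstop("published score fixture not found")
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, TABLE3_MD5))
    qstop("published score fixture checksum mismatch: ", sum)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(identical(names(df),
                      c("facility", "base", "alt_a", "alt_b", "alt_c", "alt_d")),
            nrow(df) == 26L)
  df
}
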