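#' Rank facilities by score
#'
#' Rank 1 is the highest score (descending order, matching league-table
#' convention); tied scores receive the average of the spanned positions,
#' so ranks always sum to n(n+1)/2.
#'
#' @param scores Named numeric vector (facility -> score), >= 2 entries.
#' @return Named numeric rank vector in the same facility order.
#' @export
rank_facilities <- function(scores) {
  if (length(scores) < 2L) qstop("ranking needs at least 2 facilities")
  stats::setNames(rank(-as.numeric(scores), ties.method = "average"),
                  names(scores))
}

#' Spearman rank correlation between two rankings
#'
#' The tie-aware estimator: Pearson product-moment correlation of the two
#' rank vectors. Without ties this equals the classical
#' 1 - 6 * sum(d^2) / (n (n^2 - 1)); that formula is available as
#' `method = "classic"` for comparison. Accepts either rank vectors or raw
#' scores (`from_scores = TRUE` ranks them first).
#'
#' @param x,y Rank vectors over the same facilities, same order.
#' @param method `"pearson_ranks"` (default, tie-aware) or `"classic"`.
#' @param from_scores Rank the inputs (descending) before correlating.
#' @return Correlation in \[-1, 1\] at full precision; `NA` with a warning
#'   if either vector is all-tied.
#' @export
spearman_rho <- function(x, y, method = c("pearson_ranks", "classic"),
                         from_scores = FALSE) {
  method <- match.arg(method)
  if (length(x) != length(y))
    qstop("rank vectors differ in length")
  if (!is.null(names(x)) && !is.null(names(y)) &&
      !identical(names(x), names(y)))
    qstop("rank vectors cover different facilities or orders")
  if (from_scores) {
    x <- rank_facilities(x)
    y <- rank_facilities(y)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    qwarn("all-tied rank vector: Spearman rho undefined")
    return(NA_real_)
  }
  if (method == "pearson_ranks") return(stats::cor(x, y))
  n <- length(x)
  1 - 6 * sum((x - y)^2) / (n * (n^2 - 1))
}

# Pull a facility x scenario score matrix out of a list of
# composite_results or a data frame of score columns.
scores_matrix <- function(results) {
  if (is.data.frame(results)) {
    id_col <- intersect(c("facility_id", "facility"), names(results))[1]
    if (is.na(id_col)) qstop("score table needs a facility_id column")
    num <- vapply(results, is.numeric, logical(1))
    m <- as.matrix(results[, num, drop = FALSE])
    rownames(m) <- as.character(results[[id_col]])
    return(m)
  }
  if (!length(results)) qstop("no scenario results supplied")
  fac <- names(results[[1]]$facility_scores)
  cols <- lapply(results, function(r) {
    if (!identical(names(r$facility_scores), fac))
      qstop("scenario results cover different facility sets or orders")
    r$facility_scores
  })
  m <- do.call(cbind, cols)
  colnames(m) <- names(results)
  m
}

#' Compare facility rankings across scenarios
#'
#' For each scenario paired with the baseline (or all pairs), computes the
#' tie-aware Spearman rho, the largest absolute rank shift, and how many
#' facilities shift more than `k` positions. The shifted facility ids are
#' attached as attribute `shifted`.
#'
#' @param results Named list of `composite_result`s over identical
#'   facilities, or a data frame with `facility_id` plus one numeric score
#'   column per scenario.
#' @param baseline Scenario compared against (default `"base"`).
#' @param pairs `"baseline"` (default) or `"all"` pairwise.
#' @param k Rank-shift threshold for the shifted-facility count.
#' @return Data frame: `scenario_a`, `scenario_b`, `spearman_rho`,
#'   `max_abs_rank_shift`, `n_shifted_gt_k`, `k`.
#' @export
compare_scenarios <- function(results, baseline = "base",
                              pairs = c("baseline", "all"), k = 5) {
  pairs <- match.arg(pairs)
  m <- scores_matrix(results)
  if (ncol(m) < 2L) qstop("need at least 2 scenarios to compare")
  if (pairs == "baseline" && !baseline %in% colnames(m))
    qstop(sprintf("baseline scenario '%s' not among: %s", baseline,
                  paste(colnames(m), collapse = ", ")))
  ranks <- apply(m, 2, function(s) rank(-s, ties.method = "average"))
  combos <- if (pairs == "baseline") {
    lapply(setdiff(colnames(m), baseline), function(s) c(baseline, s))
  } else {
    utils::combn(colnames(m), 2, simplify = FALSE)
  }
  shifted_ids <- list()
  rows <- lapply(combos, function(p) {
    d <- ranks[, p[1]] - ranks[, p[2]]
    key <- paste(p, collapse = " vs ")
    shifted_ids[[key]] <<- rownames(m)[abs(d) > k]
    data.frame(scenario_a = p[1], scenario_b = p[2],
               spearman_rho = spearman_rho(ranks[, p[1]], ranks[, p[2]]),
               max_abs_rank_shift = max(abs(d)),
               n_shifted_gt_k = sum(abs(d) > k), k = k,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "shifted") <- shifted_ids
  out
}

#' Per-scenario rank table
#'
#' @inheritParams compare_scenarios
#' @return Data frame: `facility_id` plus one rank column per scenario
#'   (the data behind a rank parallel-coordinates plot).
#' @export
ranks_table <- function(results) {
  m <- scores_matrix(results)
  ranks <- apply(m, 2, function(s) rank(-s, ties.method = "average"))
  data.frame(facility_id = rownames(m), ranks, stringsAsFactors = FALSE,
             row.names = NULL, check.names = FALSE)
}

#' Relabel facilities by descending baseline rank
#'
#' League-table convention: facilities are labeled A, B, C, ... in
#' descending order of a reference score column (ties broken by current
#' id for determinism).
#'
#' @param scores Named numeric vector of the reference scenario's scores.
#' @return Named character vector: old id -> letter label.
#' @export
rank_labels <- function(scores) {
  ord <- order(-as.numeric(scores), names(scores))
  n <- length(scores)
  labs <- make.unique(rep(LETTERS, length.out = n), sep = "")
  stats::setNames(labs[order(ord)], names(scores))[names(scores)]
}
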