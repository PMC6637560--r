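test_that("binarization respects direction and cutoff comparators", {
  # waiting time, lower is better, cutoff 20: the median satisfies itself
  expect_equal(binarize_indicator(c(15, 25, 20), 20, "lower_better"),
               c(1, 0, 1))
  # staffing count, higher is better, fixed cutoff 3
  expect_equal(binarize_indicator(c(3, 2), 3, "higher_better"), c(1, 0))
  # explicit fixed_le comparator overrides direction
  expect_equal(binarize_indicator(c(15, 25), 20, "higher_better",
                                  comparator = "le"), c(1, 0))
  # ordinal column under the median rule
  x <- c(2, 3, 3, 4, 5)
  expect_equal(binarize_indicator(x, median(x), "higher_better"),
               c(0, 1, 1, 1, 1))
})

test_that("orientation reflects lower-is-better columns and flips binaries", {
  expect_equal(orient_indicator(c(10, 30), "higher_better"), c(10, 30))
  expect_equal(orient_indicator(c(10, 30), "lower_better"), c(20, 0))
  expect_equal(orient_indicator(c(1, 0), "lower_better", "binary"), c(0, 1))
})

test_that("min-max rescaling handles both bound modes and degeneracy", {
  expect_equal(minmax_rescale(3, lo = 0, hi = 6), 0.5)
  expect_equal(minmax_rescale(c(2, 4, 6)), c(0, 0.5, 1))
  expect_warning(out <- minmax_rescale(c(5, 5, 5)), "constant")
  expect_equal(out, c(0.5, 0.5, 0.5))
  expect_error(minmax_rescale(c(1, 7), lo = 0, hi = 6), "outside")
  expect_error(minmax_rescale(1:3, lo = 2, hi = 2), "lo < hi")
})

test_that("z-scores use the sample SD and map constants to zero", {
  expect_equal(zscore_standardize(c(1, 2, 3)), c(-1, 0, 1))
  expect_warning(out <- zscore_standardize(c(4, 4, 4)), "constant")
  expect_equal(out, c(0, 0, 0))
  set.seed(3)
  x <- rnorm(20)
  z <- zscore_standardize(x)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
})

test_that("indicator aggregation: additive sums, geometric zeroes on any 0", {
  m <- matrix(c(1, 0, 1), nrow = 1)
  expect_equal(aggregate_indicators(m, "additive", rep(1, 3)), 2)
  expect_equal(aggregate_indicators(m, "geometric"), 0)
  expect_equal(aggregate_indicators(matrix(1, 1, 3), "geometric"), 1)
  expect_error(aggregate_indicators(matrix(c(-1, 1), 1), "geometric"),
               "non-negative")
})

test_that("cell aggregation: scale maxima, zero-propagation, z-score guard", {
  cells <- matrix(1, 1, 12)
  expect_equal(aggregate_cells(cells, "additive", rep(1, 12)), 12)
  cells2 <- matrix(c(rep(1, 11), 0), 1)
  expect_equal(aggregate_cells(cells2, "geometric"), 0)
  expect_equal(aggregate_cells(matrix(0.9, 1, 12), "geometric"), 0.9^12)
  expect_error(aggregate_cells(matrix(c(-0.5, 1), 1), "geometric"),
               "min-max")
})

test_that("presets differ from base in exactly one field", {
  presets <- scenario_presets()
  expect_named(presets, c("base", "alt_a", "alt_b", "alt_c", "alt_d"))
  fields <- c("indicator_normalization", "indicator_aggregation",
              "cell_normalization", "cell_aggregation")
  base <- presets$base
  for (alt in presets[-1]) {
    diffs <- sum(vapply(fields, function(f)
      !identical(base[[f]], alt[[f]]), logical(1)))
    expect_equal(diffs, 1)
  }
  expect_equal(presets$alt_a$indicator_normalization, "minmax")
  expect_equal(presets$alt_b$indicator_aggregation, "geometric")
  expect_equal(presets$alt_c$cell_normalization, "zscore")
  expect_equal(presets$alt_d$cell_aggregation, "geometric")
})

test_that("run_scenario reports the documented scale ranges", {
  tab <- tiny_table()
  map <- suppressMessages(drop_unpopulated_dimensions(tiny_map()))
  base <- run_scenario(tab, map, "base")
  expect_equal(base$scale_range, c(0, 2))  # two populated cells
  expect_true(all(base$facility_scores >= 0 &
                  base$facility_scores <= 2))
  d <- run_scenario(tab, map, "alt_d")
  expect_equal(d$scale_range, c(0, 1))
  expect_true(all(d$facility_scores >= 0 & d$facility_scores <= 1))
  cz <- run_scenario(tab, map, "alt_c")
  expect_identical(cz$scale_range, "unbounded")
})

test_that("run_scenario matches the brute-force oracle on all presets", {
  tab <- tiny_table()
  map <- suppressMessages(drop_unpopulated_dimensions(tiny_map()))
  defs <- map$indicators
  grids <- list(
    base  = c("binarize", "additive", "minmax_theoretical", "additive"),
    alt_a = c("minmax", "additive", "minmax_theoretical", "additive"),
    alt_b = c("binarize", "geometric", "minmax_theoretical", "additive"),
    alt_c = c("binarize", "additive", "zscore", "additive"),
    alt_d = c("binarize", "additive", "minmax_theoretical", "geometric"))
  for (nm in names(grids)) {
    g <- grids[[nm]]
    got <- run_scenario(tab, map, scenario_preset(nm))$facility_scores
    want <- oracle_scenario(tiny_values(), defs, g[1], g[2], g[3], g[4])
    expect_equal(got, want, info = nm)
  }
  # and on a second, randomized instance
  set.seed(41)
  vals <- tiny_values()
  vals[, 1:4] <- rbinom(16, 1, 0.5)
  vals[, 5] <- sample(1:5, 4, replace = TRUE)
  vals[, 6] <- sample(5:50, 4)
  tab2 <- facility_table(vals)
  for (nm in names(grids)) {
    g <- grids[[nm]]
    got <- suppressWarnings(
      run_scenario(tab2, map, scenario_preset(nm))$facility_scores)
    want <- suppressWarnings(
      oracle_scenario(vals, defs, g[1], g[2], g[3], g[4]))
    expect_equal(got, want, info = paste("random", nm))
  }
})

test_that("perfect binary quality reaches the scale maximum everywhere", {
  df <- tiny_map_df()
  df$var_type <- "binary"; df$cutoff_rule <- "none"
  df$direction <- "higher_better"
  map <- suppressMessages(drop_unpopulated_dimensions(load_indicator_map(df)))
  vals <- matrix(1, 4, 6, dimnames = list(paste0("f", 1:4),
                                          df$indicator_id))
  tab <- facility_table(vals)
  for (nm in c("base", "alt_a", "alt_b")) {
    r <- run_scenario(tab, map, nm)
    expect_equal(unname(r$facility_scores), rep(2, 4), info = nm)
  }
  r <- run_scenario(tab, map, "alt_d")
  expect_equal(unname(r$facility_scores), rep(1, 4))
  # alt_c degenerates to all-zero cells on constant data, by the stated rule
  r <- suppressWarnings(run_scenario(tab, map, "alt_c"))
  expect_equal(unname(r$facility_scores), rep(0, 4))
})

test_that("base composite is monotone in every single indicator", {
  map <- suppressMessages(drop_unpopulated_dimensions(tiny_map()))
  set.seed(13)
  vals <- tiny_values()
  vals[, 1:4] <- rbinom(16, 1, 0.5)
  base <- run_scenario(facility_table(vals), map, "base")$facility_scores
  for (id in c("es1", "es2", "es3", "ap1")) {
    for (f in rownames(vals)) {
      if (vals[f, id] == 1) next
      up <- vals
      up[f, id] <- 1
      bumped <- run_scenario(facility_table(up), map, "base")$facility_scores
      expect_true(all(bumped - base >= -1e-12),
                  info = paste(id, f))
    }
  }
})

test_that("equal-weight additive composites are invariant to cell order", {
  map <- suppressMessages(drop_unpopulated_dimensions(tiny_map()))
  tab <- tiny_table()
  a <- run_scenario(tab, map, "base")$facility_scores
  # re-declare the map with dimensions in the opposite order
  df <- tiny_map_df()[c(4:6, 1:3), ]
  map2 <- suppressMessages(drop_unpopulated_dimensions(load_indicator_map(df)))
  b <- run_scenario(tab, map2, "base")$facility_scores
  expect_equal(a, b)
})

test_that("z-score cell columns have mean 0 and sample SD 1", {
  s <- shared_study()
  tab <- shared_ingest()
  r <- run_scenario(tab, s$map, "alt_c")
  nrm <- r$cell_scores$normalized
  expect_equal(unname(colMeans(nrm)), rep(0, ncol(nrm)))
  expect_equal(unname(apply(nrm, 2, sd)), rep(1, ncol(nrm)))
})

test_that("geometric <= min <= additive mean on [0,1] cell vectors", {
  set.seed(99)
  for (i in 1:50) {
    cells <- runif(12)
    geo <- aggregate_cells(matrix(cells, 1), "geometric")
    add_mean <- aggregate_cells(matrix(cells, 1), "additive",
                                rep(1, 12)) / 12
    expect_true(geo <= min(cells) + 1e-12)
    expect_true(min(cells) <= add_mean + 1e-12)
  }
})

test_that("custom weights are normalized so equal weights stay plain sums", {
  map <- suppressMessages(drop_unpopulated_dimensions(tiny_map()))
  tab <- tiny_table()
  w_ind <- stats::setNames(rep(2, 6), map$indicators$indicator_id)
  cfg <- scenario_config("wtest", indicator_weights = w_ind)
  expect_equal(run_scenario(tab, map, cfg)$facility_scores,
               run_scenario(tab, map, "base")$facility_scores)
  expect_error(scenario_config("bad", indicator_weights = c(a = -1)),
               "non-negative")
  cfg2 <- scenario_config("missing",
                          indicator_weights = c(es1 = 1))
  expect_error(run_scenario(tab, map, cfg2), "missing for")
})

test_that("scores_frame carries composite, bounds, and per-cell columns", {
  map <- suppressMessages(drop_unpopulated_dimensions(tiny_map()))
  df <- scores_frame(run_scenario(tiny_table(), map, "base"))
  expect_equal(nrow(df), 4)
  expect_true(all(c("facility_id", "scenario", "composite",
                    "scale_lo", "scale_hi",
                    "raw.effective_structure",
                    "norm.accessible_process") %in% names(df)))
  expect_equal(unique(df$scale_hi), 2)
})
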