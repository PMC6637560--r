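make_recordset <- function(df, tool = "observation") {
  read_source_csv(df, tool)
}

test_that("aggregation averages within facility, excluding missing", {
  df <- data.frame(
    facility_id = c("a", "a", "a", "a", "b", "b"),
    task = c(1, 0, 1, 1, NA, 1),
    wait = c(10, 30, NA, NA, 5, 15))
  agg <- aggregate_to_facility(make_recordset(df))
  expect_equal(agg$task[agg$facility_id == "a"], 0.75)
  expect_equal(agg$wait[agg$facility_id == "a"], 20)
  expect_equal(agg$task[agg$facility_id == "b"], 1)   # NA excluded
  # facility-level tools pass through unchanged
  inv <- data.frame(facility_id = c("a", "b"), beds = c(3, 7))
  expect_equal(aggregate_to_facility(make_recordset(inv, "inventory")), inv)
  # duplicate inventory rows are rejected
  expect_error(make_recordset(inv[c(1, 1), ], "inventory"),
               "more than one row")
})

test_that("binarize_share uses the 0.5-inclusive cutoff and guards its domain", {
  expect_equal(binarize_share(c(0.5, 0.49, 0, 1, NA)),
               c(1L, 0L, 0L, 1L, NA))
  expect_error(binarize_share(1.2), "outside")
  expect_error(binarize_share(-0.1), "outside")
})

test_that("aggregate + binarize is invariant to record order within facility", {
  set.seed(7)
  df <- data.frame(facility_id = rep(c("a", "b"), each = 10),
                   x = rbinom(20, 1, 0.6))
  out1 <- binarize_share(aggregate_to_facility(make_recordset(df))$x)
  df2 <- df[sample(nrow(df)), ]
  out2 <- binarize_share(aggregate_to_facility(make_recordset(df2))$x)
  expect_equal(out1, out2)
})

test_that("completeness filter drops facilities lacking required tools", {
  fac33 <- sprintf("F%02d", 1:33)
  tabs <- list(
    inventory = data.frame(facility_id = fac33),
    observation = data.frame(facility_id = fac33[1:29]),
    provider_interview = data.frame(facility_id = fac33[c(1:26, 30:33)]),
    exit_interview = data.frame(facility_id = fac33))
  kept <- suppressMessages(filter_complete_facilities(tabs))
  expect_length(kept, 26)
  expect_equal(nrow(attr(kept, "dropped")), 7)
  # all tools present -> identity
  all_there <- lapply(tabs["inventory"], identity)
  expect_length(filter_complete_facilities(all_there), 33)
  # judging on a tool subset
  kept_inv <- filter_complete_facilities(tabs, required_tools = "inventory")
  expect_length(kept_inv, 33)
  # zero retained is a hard error
  disjoint <- list(inventory = data.frame(facility_id = "a"),
                   observation = data.frame(facility_id = "b"))
  expect_error(suppressMessages(filter_complete_facilities(disjoint)),
               "no facility")
})

imputation_fixture <- function(vals) {
  df <- tiny_map_df()
  df$source_tool <- c("inventory", "inventory", "observation",
                      "observation", "inventory", "exit_interview")
  map <- load_indicator_map(df)
  list(map = map, table = facility_table(vals))
}

test_that("imputation follows the policy per tool and variable type", {
  vals <- tiny_values()
  vals["f1", "es3"] <- NA   # observation-tool binary (per fixture tools)
  vals["f2", "ap2"] <- NA   # continuous
  vals["f3", "es1"] <- NA   # inventory binary -> mode path
  fx <- imputation_fixture(vals)

  imp <- impute_missing(fx$table, imputation_policy(), fx$map)
  expect_equal(unname(imp$values["f1", "es3"]), 0)  # observation zero-fill
  expect_equal(imp$provenance["f1", "es3"], "imputed_zero")
  expect_equal(unname(imp$values["f2", "ap2"]), mean(c(4, 2, 1)))
  expect_equal(imp$provenance["f2", "ap2"], "imputed_mean")
  # es1 observed values are 1,1,0 -> mode 1
  expect_equal(unname(imp$values["f3", "es1"]), 1)
  expect_false(any(is.na(imp$values)))

  one <- impute_missing(fx$table,
                        imputation_policy(observation_missing = "one"),
                        fx$map)
  expect_equal(unname(one$values["f1", "es3"]), 1)
  expect_equal(one$provenance["f1", "es3"], "imputed_one")
})

test_that("binary mode imputation counts exhaustively and ties resolve to 1", {
  df <- tiny_map_df()[1:2, ]
  map <- load_indicator_map(df)
  vals <- matrix(c(1, 1, 0, NA,   # mode 1 by count
                   1, 0, NA, NA), # tie 1 vs 0 -> 1
                 ncol = 2, dimnames = list(paste0("f", 1:4), c("es1", "es2")))
  imp <- impute_missing(facility_table(vals), imputation_policy(), map)
  expect_equal(unname(imp$values["f4", "es1"]), 1)
  expect_equal(unname(imp$values[c("f3", "f4"), "es2"]), c(1, 1))
})

test_that("proxy imputation copies the same facility's proxy, then falls back", {
  df <- tiny_map_df()[c(1, 2), ]
  df$proxy_id[1] <- "es2"
  map <- load_indicator_map(df)
  vals <- matrix(c(NA, NA, 1, 0,
                   1, NA, 0, 0),
                 ncol = 2, dimnames = list(paste0("f", 1:4), c("es1", "es2")))
  imp <- impute_missing(facility_table(vals), imputation_policy(), map)
  expect_equal(unname(imp$values["f1", "es1"]), 1)  # copied from es2
  expect_equal(imp$provenance["f1", "es1"], "imputed_proxy")
  # f2's proxy is missing too -> mode of es1's observed (1, 0) -> tie -> 1
  expect_equal(unname(imp$values["f2", "es1"]), 1)
  expect_equal(imp$provenance["f2", "es1"], "imputed_mode")
  # pure mode policy ignores the proxy
  imp2 <- impute_missing(facility_table(vals),
                         imputation_policy(binary_missing = "mode"), map)
  expect_equal(imp2$provenance["f1", "es1"], "imputed_mode")
})

test_that("an all-missing column errors naming the indicator", {
  df <- tiny_map_df()[1:2, ]
  map <- load_indicator_map(df)
  vals <- matrix(c(NA, NA, 1, 0), ncol = 2,
                 dimnames = list(c("f1", "f2"), c("es1", "es2")))
  expect_error(impute_missing(facility_table(vals), imputation_policy(), map),
               "es1")
})

test_that("imputation on complete data is the identity under every policy", {
  fx <- imputation_fixture(tiny_values())
  policies <- list(
    imputation_policy(),
    imputation_policy(observation_missing = "one"),
    imputation_policy(observation_missing = "mode", binary_missing = "mode"))
  for (p in policies) {
    imp <- impute_missing(fx$table, p, fx$map)
    expect_equal(imp$values, fx$table$values)
    expect_true(all(imp$provenance == "observed"))
  }
})

test_that("zero-fill means are never above one-fill means", {
  set.seed(11)
  df <- tiny_map_df()[3:4, ]  # two observation-tool binaries
  df$var_type <- "binary"; df$cutoff_rule <- "none"
  map <- load_indicator_map(df)
  for (rep in 1:10) {
    vals <- matrix(rbinom(12, 1, 0.5), ncol = 2,
                   dimnames = list(paste0("f", 1:6), c("es3", "ap1")))
    vals[sample(12, 4)] <- NA
    if (all(is.na(vals[, 1])) || all(is.na(vals[, 2]))) next
    z <- impute_missing(facility_table(vals),
                        imputation_policy(observation_missing = "zero"), map)
    o <- impute_missing(facility_table(vals),
                        imputation_policy(observation_missing = "one"), map)
    expect_true(all(colMeans(z$values) <= colMeans(o$values)))
  }
})

test_that("indicator screening reports stats, degeneracy and IQR outliers", {
  df <- tiny_map_df()[c(1, 5), ]
  map <- load_indicator_map(df)
  vals <- matrix(c(1, 1, 1, 1, 1,
                   18, 19, 20, 21, 120),
                 ncol = 2, dimnames = list(paste0("f", 1:5), c("es1", "ap2")))
  tab <- facility_table(vals)
  rep <- screen_indicators(tab, map)
  es1 <- rep[rep$indicator_id == "es1", ]
  expect_equal(es1$sd, 0)
  expect_true(es1$degenerate)
  expect_true(is.na(es1$n_outliers))  # binary: no outlier scan
  ap2 <- rep[rep$indicator_id == "ap2", ]
  # median 20, IQR 2 -> fence [17, 23]: only 120 falls outside
  expect_equal(ap2$n_outliers, 1)
  expect_equal(ap2$n_missing_pre, 0)
})

test_that("ingest_study produces a complete binary-consistent table", {
  s <- shared_study()
  tab <- shared_ingest()
  expect_false(any(is.na(tab$values)))
  bin_ids <- s$map$indicators$indicator_id[s$map$indicators$var_type == "binary"]
  expect_true(all(tab$values[, bin_ids] %in% c(0, 1)))
  expect_equal(nrow(tab$values), 26)
  expect_equal(ncol(tab$values), 85)
  # no dropout configured -> every facility retained
  expect_equal(nrow(attr(tab, "dropped")), 0)
})
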