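make_panel <- function(n = 200, seed = 1, patterns = c(0.4, 0.3, 0.2, 0.1)) {
  suppressWarnings(generate_cohort(
    test_cohort_config(n = n, seed = seed, missing_patterns = patterns)))
}

test_that("changes are year-minus-baseline with missingness propagation", {
  p <- make_panel(120, seed = 2)
  ch <- compute_changes(p)
  d <- p$data
  ## spot-check: recompute one variable by explicit loop
  i <- which(d$year == 2)[5]
  pid <- d$participant[i]
  base <- d$csi[d$participant == pid & d$year == 0]
  expect_equal(ch$d_csi[ch$participant == pid & ch$year == 2],
               d$csi[i] - base)
  ## masked year value => masked change
  masked_rows <- which(p$mask[, "mood_emotions"] & d$year > 0)
  if (length(masked_rows)) {
    key <- paste(d$participant[masked_rows], d$year[masked_rows])
    chkey <- paste(ch$participant, ch$year)
    expect_true(all(is.na(ch$d_mood_emotions[chkey %in% key])))
  }
  ## identical values => zero change
  p0 <- p
  p0$data$bmi <- 5
  expect_true(all(compute_changes(p0)$d_bmi == 0))
  ## participant lacking a baseline row is a structural error
  pbad <- p
  drop <- which(pbad$data$participant == 1 & pbad$data$year == 0)
  pbad$data <- pbad$data[-drop, ]
  pbad$mask <- pbad$mask[-drop, ]
  expect_error(compute_changes(pbad), "baseline")
})

test_that("standardizer learns observed-cell moments and inverts exactly", {
  p <- make_panel(150, seed = 3)
  std <- fit_standardizer(p)
  ## hand-check one baseline column
  base_csi <- p$data$csi[p$data$year == 0]
  row <- std[std$column == "csi" & std$kind == "baseline", ]
  expect_equal(row$mean, mean(base_csi))
  expect_equal(row$sd, sd(base_csi))
  ## change column moments ignore masked cells (brute-force recompute)
  ch <- compute_changes(p)
  x <- ch$d_comm_cognition
  obs <- x[!is.na(x)]
  row2 <- std[std$column == "d_comm_cognition", ]
  expect_equal(row2$mean, mean(obs))
  expect_equal(row2$sd, sd(obs))
  ## restandardizing its own data gives mean 0, sd 1 on observed cells
  z <- (obs - row2$mean) / row2$sd
  expect_lt(abs(mean(z)), 1e-10)
  expect_lt(abs(sd(z) - 1), 1e-10)
  ## round-trip invertibility
  back <- z * row2$sd + row2$mean
  expect_equal(back, obs, tolerance = 1e-10)
  ## constant column rejected by name
  pc <- p
  pc$data$bmi <- 7
  expect_error(fit_standardizer(pc), "bmi")
})

test_that("three-point standardizer example", {
  ## minimal hand-built panel: 3 participants, 2 years, 1 scale, 1 medical
  d <- data.frame(participant = rep(1:3, each = 2), year = rep(0:1, 3),
                  age = rep(c(30, 40, 50), each = 2),
                  scale1 = c(1, 2, 2, 3, 3, 5), m1 = c(1, 1, 2, 3, 3, 6))
  p <- structure(list(
    data = d,
    mask = matrix(FALSE, 6, 1, dimnames = list(NULL, "scale1")),
    truth = matrix(d$scale1, 6, 1, dimnames = list(NULL, "scale1")),
    config = list(medical_params = data.frame(variable = "m1"))),
    class = "sw_panel")
  std <- fit_standardizer(p)
  row <- std[std$column == "m1" & std$kind == "baseline", ]
  expect_equal(row$mean, 2)   # baseline m1 values are {1, 2, 3}
  expect_equal(row$sd, 1)
  ## change column: differences are {0, 1, 3}
  rc <- std[std$column == "d_m1" & std$kind == "change", ]
  expect_equal(rc$mean, mean(c(0, 1, 3)))
  expect_equal(rc$sd, sd(c(0, 1, 3)))
})

test_that("missingness-tolerance filter keeps exactly the right participants", {
  p <- make_panel(800, seed = 5)
  counts <- missing_measurements(p)
  for (tol in c(0, 7, 14)) {
    kept <- filter_by_missingness(p, tol)
    expect_setequal(unique(kept$data$participant),
                    as.integer(names(counts))[counts <= tol])
  }
  ## tolerance 0 retains only fully observed participants
  k0 <- filter_by_missingness(p, 0)
  expect_equal(sum(k0$mask), 0)
  ## retained fraction matches the generator's pattern weights
  frac <- length(unique(filter_by_missingness(p, 14)$data$participant)) / 800
  expect_lt(abs(frac - 0.9), 3 * sqrt(0.9 * 0.1 / 800))
  ## nesting: tolerance 7 subset of tolerance 14
  expect_true(all(unique(filter_by_missingness(p, 7)$data$participant) %in%
                    unique(filter_by_missingness(p, 14)$data$participant)))
  expect_error(filter_by_missingness(p, 3), "tolerance")
})

test_that("design matrices restrict classes per covariate submodel", {
  p <- make_panel(200, seed = 6)
  std <- fit_standardizer(p)
  d_demo <- build_design(p, std, "demo")
  d_fab <- build_design(p, std, "demo+fab")
  d_med <- build_design(p, std, "demo+med")
  d_full <- build_design(p, std, "full")
  expect_equal(sum(d_demo$info$class %in% c("function", "medical")), 0)
  expect_equal(sum(d_fab$info$class == "medical"), 0)
  expect_equal(sum(d_med$info$class == "function"), 0)
  ## full columns = union of the pieces
  expect_equal(ncol(d_full$z),
               ncol(d_demo$z) +
                 sum(d_fab$info$class == "function") +
                 sum(d_med$info$class == "medical"))
  ## metadata covers every column exactly once
  expect_equal(d_full$info$name, colnames(d_full$z))
  ## no outcome rows at year 0; outcome aligned
  expect_true(all(d_full$year > 0))
  expect_true(all(d_full$y %in% 0:1))
  ## Community Mobility enters only via indicators
  expect_false(any(grepl("community", colnames(d_full$z))))
  expect_true(all(c("has_drive", "has_ride", "has_wheelchair") %in%
                    colnames(d_full$z)))
  ## indicator columns are 0/1 and never masked
  ind <- d_full$info$kind == "indicator"
  expect_true(all(d_full$z[, ind] %in% 0:1))
  expect_false(any(d_full$mask[, ind]))
  ## masked cells only in function or medical columns
  masked_cols <- unique(which(d_full$mask, arr.ind = TRUE)[, 2])
  expect_true(all(d_full$info$class[masked_cols] %in% c("function", "medical")))
  expect_error(build_design(p, std, "everything"), "covariate_set")
})

test_that("building then dropping a class equals building without it", {
  p <- make_panel(150, seed = 7)
  std <- fit_standardizer(p)
  full <- build_design(p, std, "full")
  fab <- build_design(p, std, "demo+fab")
  sub <- fabwork:::subset_design(full, c("demographic", "function"))
  expect_equal(sub$z, fab$z)
  expect_equal(sub$info, fab$info, ignore_attr = TRUE)
  expect_equal(sub$mask, fab$mask)
})

test_that("standardized observed function baselines center at zero", {
  p <- make_panel(300, seed = 8)
  std <- fit_standardizer(p)
  des <- build_design(p, std, "demo+fab")
  x <- des$z[, "comm_cognition"]
  m <- des$mask[, "comm_cognition"]
  ## the analysis standardizer is fit on baseline rows; design rows repeat
  ## each baseline up to 3 times, so the mean is near but not exactly 0
  expect_lt(abs(mean(x[!m])), 0.1)
  xc <- des$z[, "d_comm_cognition"]
  mc <- des$mask[, "d_comm_cognition"]
  expect_lt(abs(mean(xc[!mc])), 1e-10)
})
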