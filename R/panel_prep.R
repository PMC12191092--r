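## Columns that carry functional-scale values in a panel.
fab_cols <- function(panel) colnames(panel$mask)

## Medical-variable names (from config when present, else inferred).
med_cols <- function(panel) {
  cfg <- panel$config
  if (!is.null(cfg$medical_params)) return(cfg$medical_params$variable)
  setdiff(names(panel$data),
          c("participant", "year", "steady_work", "age", "baseline_working",
            "worked_past_2yr", "education", "race", "stable_housing",
            "vehicle_access", "arm", "has_drive", "has_ride", "has_wheelchair",
            fab_cols(panel)))
}

#' Change-from-baseline covariates
#'
#' For every functional scale and medical variable, computes the year-`t`
#' change `x_t - x_0` for each post-baseline person-year. A change is
#' missing whenever either side is missing.
#'
#' @param panel an `sw_panel`.
#' @return data frame with `participant`, `year` and one `d_<variable>`
#'   column per covariate, one row per post-baseline person-year.
#' @export
compute_changes <- function(panel) {
  d <- panel$data
  vars <- c(fab_cols(panel), med_cols(panel))
  base_rows <- which(d$year == 0)
  no_base <- setdiff(unique(d$participant), d$participant[base_rows])
  if (length(no_base))
    stop("participants lacking a baseline row: ",
         paste(utils::head(no_base, 10), collapse = ", "))
  post <- which(d$year > 0)
  bidx <- base_rows[match(d$participant[post], d$participant[base_rows])]
  ch <- as.matrix(d[post, vars, drop = FALSE]) -
    as.matrix(d[bidx, vars, drop = FALSE])
  colnames(ch) <- paste0("d_", vars)
  cbind(data.frame(participant = d$participant[post], year = d$year[post]), ch)
}

#' Filter participants by missing-measurement tolerance
#'
#' Keeps exactly the participants whose count of blanked
#' non-Community-Mobility scale scores is at most `tolerance`.
#'
#' @param panel an `sw_panel` with its missingness mask set.
#' @param tolerance one of 0, 7, 14.
#' @return the filtered `sw_panel`.
#' @export
filter_by_missingness <- function(panel, tolerance) {
  if (!length(tolerance) == 1 || !tolerance %in% c(0, 7, 14))
    stop("tolerance must be one of 0, 7, 14")
  counts <- missing_measurements(panel)
  keep_ids <- as.integer(names(counts))[counts <= tolerance]
  rows <- panel$data$participant %in% keep_ids
  panel$data <- panel$data[rows, , drop = FALSE]
  panel$mask <- panel$mask[rows, , drop = FALSE]
  panel$truth <- panel$truth[rows, , drop = FALSE]
  rownames(panel$data) <- NULL
  panel
}

#' Fit standardization parameters
#'
#' Learns, on observed cells only, the mean/SD of every baseline covariate
#' and the mean/SD of every change-from-baseline covariate, for reuse
#' across covariate submodels so effect sizes stay comparable.
#'
#' @param panel an `sw_panel` (typically after [filter_by_missingness()]).
#' @return an object of class `sw_standardizer`: a data frame with columns
#'   `column`, `kind` (`baseline`/`change`), `mean`, `sd`.
#' @export
fit_standardizer <- function(panel) {
  d <- panel$data
  base <- d[d$year == 0, , drop = FALSE]
  vars <- c("age", fab_cols(panel), med_cols(panel))
  ch <- compute_changes(panel)
  chvars <- grep("^d_", names(ch), value = TRUE)

  one <- function(x, name, kind) {
    x <- x[!is.na(x)]
    if (length(x) < 2) stop("column '", name, "' has fewer than 2 observed values")
    s <- stats::sd(x)
    if (s == 0) stop("column '", name, "' is constant; cannot standardize")
    data.frame(column = name, kind = kind, mean = mean(x), sd = s,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    do.call(rbind, lapply(vars, function(v) one(base[[v]], v, "baseline"))),
    do.call(rbind, lapply(chvars, function(v) one(ch[[v]], v, "change")))
  )
  rownames(out) <- NULL
  class(out) <- c("sw_standardizer", class(out))
  out
}

std_lookup <- function(params, name) {
  i <- match(name, params$column)
  if (is.na(i)) stop("no standardization parameters for column '", name, "'")
  params[i, ]
}

#' Build the model-ready design matrix
#'
#' Assembles one row per post-baseline person-year: the steady-work
#' outcome, standardized baseline and change covariates, Community
#' Mobility / wheelchair presence indicators, and demographic dummies.
#' Community Mobility scores never enter as values, only as presence
#' indicators. Covariate classes are restricted by submodel:
#' `demo`, `demo+fab` (function, no medical), `demo+med` (medical, no
#' function), `full`.
#'
#' @param panel an `sw_panel`.
#' @param params an `sw_standardizer` fitted on a compatible panel.
#' @param covariate_set one of `"demo"`, `"demo+fab"`, `"demo+med"`,
#'   `"full"`.
#' @return an object of class `sw_design`: list with outcome `y`, matrix
#'   `z` (masked cells `NA`), logical `mask`, column metadata `info`
#'   (`name`, `class`, `kind`), `year`, `participant`.
#' @export
build_design <- function(panel, params, covariate_set = "full") {
  sets <- c("demo", "demo+fab", "demo+med", "full")
  if (!covariate_set %in% sets)
    stop("unknown covariate_set '", covariate_set, "'; use one of: ",
         paste(sets, collapse = ", "))
  d <- panel$data
  post <- which(d$year > 0)
  ch <- compute_changes(panel)
  stopifnot(nrow(ch) == length(post))

  std <- function(x, name) {
    p <- std_lookup(params, name)
    (x - p$mean) / p$sd
  }

  blocks <- list(); info <- list()
  demo <- demographic_dummies(d[post, , drop = FALSE])
  demo[, "age"] <- std(demo[, "age"], "age")
  blocks$demo <- demo
  info$demo <- data.frame(name = colnames(demo), class = "demographic",
                          kind = c("baseline", rep("indicator", ncol(demo) - 1)))

  use_fab <- covariate_set %in% c("demo+fab", "full")
  use_med <- covariate_set %in% c("demo+med", "full")

  if (use_fab) {
    fv <- fab_cols(panel)
    bidx <- which(d$year == 0)[match(d$participant[post], d$participant[d$year == 0])]
    zb <- sapply(fv, function(v) std(d[[v]][bidx], v))
    zc <- sapply(fv, function(v) std(ch[[paste0("d_", v)]], paste0("d_", v)))
    colnames(zc) <- paste0("d_", fv)
    pres <- as.matrix(d[post, c("has_drive", "has_ride", "has_wheelchair")])
    blocks$fab <- cbind(zb, zc, pres)
    info$fab <- data.frame(
      name = colnames(blocks$fab), class = "function",
      kind = c(rep("baseline", length(fv)), rep("change", length(fv)),
               rep("indicator", 3)))
  }
  if (use_med) {
    mv <- med_cols(panel)
    bidx <- which(d$year == 0)[match(d$participant[post], d$participant[d$year == 0])]
    zb <- sapply(mv, function(v) std(d[[v]][bidx], v))
    zc <- sapply(mv, function(v) std(ch[[paste0("d_", v)]], paste0("d_", v)))
    colnames(zc) <- paste0("d_", mv)
    blocks$med <- cbind(zb, zc)
    info$med <- data.frame(
      name = colnames(blocks$med), class = "medical",
      kind = c(rep("baseline", length(mv)), rep("change", length(mv))))
  }

  z <- do.call(cbind, blocks)
  info <- do.call(rbind, info)
  rownames(info) <- NULL
  mask <- is.na(z)
  if (any(mask & matrix(info$kind == "indicator", nrow(z), ncol(z), byrow = TRUE)))
    stop("indicator columns must never be masked")

  structure(list(
    y = d$steady_work[post],
    z = z,
    mask = mask,
    info = info,
    year = d$year[post],
    participant = d$participant[post]
  ), class = "sw_design")
}

#' @export
print.sw_design <- function(x, ...) {
  cat(sprintf("Steady-work design: %d person-year rows, %d columns\n",
              nrow(x$z), ncol(x$z)))
  cls <- table(x$info$class)
  cat("  columns by class: ",
      paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n", sep = "")
  cat(sprintf("  outcome rate: %.3f; masked cells: %d (%.1f%%)\n",
              mean(x$y), sum(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

## Drop design columns by class, preserving metadata alignment.
subset_design <- function(design, keep_classes) {
  keep <- design$info$class %in% keep_classes
  design$z <- design$z[, keep, drop = FALSE]
  design$mask <- design$mask[, keep, drop = FALSE]
  design$info <- design$info[keep, , drop = FALSE]
  design
}
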