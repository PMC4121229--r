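#' Specification of a synthetic contaminated linear series
#'
#' Describes the study conditions of the validation design: a base line
#' (increasing, decreasing or constant), a fraction of positions replaced by
#' outliers, and optional missing regions.
#'
#' Non-Gaussian outliers are multiplicative: the value is scaled by a factor
#' whose magnitude is log-uniform between `factor_range[1]` and
#' `factor_range[2]` (default 1e-2 to 1e+2) with a random sign. Gaussian
#' outliers are additive normal perturbations with standard deviation
#' `gaussian_sd_frac` of the base-line value range (5% by default; for a
#' constant line, whose range is zero, 5% of the absolute intercept) — mild
#' symmetric contamination that produces no extreme points.
#'
#' The default line (`intercept` 1050, `slope` +/-1) keeps every base value
#' positive and away from zero for series up to 1000 elements, so a
#' multiplicative outlier never coincides with the line itself.
#'
#' @param n Number of grid positions (`0..n-1`).
#' @param trend `"increasing"`, `"decreasing"` or `"constant"`; sets the
#'   default slope (+1, -1, 0).
#' @param slope,intercept Line parameters `value = intercept + slope * index`;
#'   `NULL` means the trend default. A constant line must have a nonzero
#'   intercept.
#' @param outlier_fraction Fraction of present positions to contaminate, in
#'   `[0, 1)`. Default 0.5, the validated high-contamination setting.
#' @param outlier_mode `"non_gaussian"` (multiplicative, default) or
#'   `"gaussian"` (additive).
#' @param factor_range Magnitude range of the multiplicative factors.
#' @param gaussian_sd_frac Gaussian-mode sigma as a fraction of the value
#'   range.
#' @param protect_reference If `TRUE` (default) the first present position is
#'   never contaminated, matching the clean-reference study condition.
#' @param missing_regions List of `c(start, length)` pairs of grid positions
#'   to delete (disjoint, within `[0, n)`).
#' @param seed Optional integer seed; the generator is deterministic under it.
#' @return An object of class `simulation_spec`.
#' @examples
#' simulation_spec(n = 100, trend = "increasing", seed = 1)
#' @export
simulation_spec <- function(n = 100,
                            trend = c("increasing", "decreasing", "constant"),
                            slope = NULL, intercept = NULL,
                            outlier_fraction = 0.5,
                            outlier_mode = c("non_gaussian", "gaussian"),
                            factor_range = c(1e-2, 1e2),
                            gaussian_sd_frac = 0.05,
                            protect_reference = TRUE,
                            missing_regions = list(),
                            seed = NULL) {
  trend <- match.arg(trend)
  outlier_mode <- match.arg(outlier_mode)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 3,
            is.numeric(outlier_fraction), outlier_fraction >= 0,
            outlier_fraction < 1,
            is.numeric(factor_range), length(factor_range) == 2L,
            all(factor_range > 0), factor_range[1] <= factor_range[2],
            is.numeric(gaussian_sd_frac), gaussian_sd_frac > 0,
            is.logical(protect_reference), length(protect_reference) == 1L)
  n <- as.integer(n)
  if (is.null(slope)) {
    slope <- switch(trend, increasing = 1, decreasing = -1, constant = 0)
  }
  if (is.null(intercept)) intercept <- 1050
  if (trend == "constant" && intercept == 0) {
    stop("a constant line needs a nonzero intercept", call. = FALSE)
  }
  missing_regions <- lapply(missing_regions, function(r) {
    r <- as.integer(r)
    if (length(r) != 2L || r[1] < 0 || r[2] < 1 || r[1] + r[2] > n) {
      stop("each missing region must be c(start, length) within [0, n)",
           call. = FALSE)
    }
    r
  })
  miss <- unlist(lapply(missing_regions, function(r) r[1] + seq_len(r[2]) - 1L))
  if (anyDuplicated(miss)) {
    stop("missing regions must be disjoint", call. = FALSE)
  }
  structure(
    list(n = n, trend = trend, slope = slope, intercept = intercept,
         outlier_fraction = outlier_fraction, outlier_mode = outlier_mode,
         factor_range = factor_range, gaussian_sd_frac = gaussian_sd_frac,
         protect_reference = protect_reference,
         missing_regions = missing_regions, seed = seed),
    class = "simulation_spec"
  )
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf(
    "<simulation_spec> n = %d, %s line (value = %g %+g * index), %g%% %s outliers, %d missing region(s)\n",
    x$n, x$trend, x$intercept, x$slope, 100 * x$outlier_fraction,
    sub("_", "-", x$outlier_mode), length(x$missing_regions)))
  invisible(x)
}

#' Generate a contaminated linear series with ground truth
#'
#' Builds the base line `intercept + slope * index` on positions `0..n-1`,
#' deletes the missing regions, replaces a uniformly chosen set of
#' `floor(outlier_fraction * n_present)` present positions with outliers (see
#' [simulation_spec()] for the two contamination modes), and returns the
#' series together with the true labels.
#'
#' @param spec A [simulation_spec()].
#' @return A list with `series` (an [indexed_series()] of the present,
#'   possibly contaminated values) and `truth` (an [outlier_labels()] frame
#'   over `0..n-1` with levels `nonoutlier`, `outlier`, `missing`).
#' @examples
#' sim <- make_series(simulation_spec(n = 20, outlier_fraction = 0.25, seed = 7))
#' sim$series
#' table(sim$truth$label)
#' @export
make_series <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n
  grid <- 0:(n - 1L)
  base <- spec$intercept + spec$slope * grid
  miss <- unlist(lapply(spec$missing_regions,
                        function(r) r[1] + seq_len(r[2]) - 1L))
  present <- if (length(miss)) setdiff(grid, miss) else grid
  if (length(present) < 3L) {
    stop("missing regions leave fewer than 3 present elements", call. = FALSE)
  }
  ref <- present[1L]
  candidates <- if (spec$protect_reference) setdiff(present, ref) else present
  n_out <- floor(spec$outlier_fraction * length(present))
  if (length(present) - n_out < 3L) {
    stop("contamination leaves fewer than 3 clean points", call. = FALSE)
  }
  n_out <- min(n_out, length(candidates))
  out_pos <- if (n_out > 0L) sort(sample(candidates, n_out)) else integer()

  values <- base
  if (n_out > 0L) {
    at <- match(out_pos, grid)
    if (spec$outlier_mode == "non_gaussian") {
      lf <- stats::runif(n_out, log(spec$factor_range[1]),
                         log(spec$factor_range[2]))
      sgn <- sample(c(-1, 1), n_out, replace = TRUE)
      values[at] <- values[at] * sgn * exp(lf)
    } else {
      rng <- diff(range(base))
      sigma <- spec$gaussian_sd_frac * if (rng > 0) rng else abs(spec$intercept)
      values[at] <- values[at] + stats::rnorm(n_out, 0, sigma)
    }
  }

  lab <- rep("nonoutlier", n)
  lab[grid %in% miss] <- "missing"
  lab[grid %in% out_pos] <- "outlier"
  list(
    series = indexed_series(present, values[match(present, grid)],
                            reference = ref),
    truth = outlier_labels(grid, lab,
                           replace(values, grid %in% miss, NA_real_))
  )
}

#' Compare detected labels against ground truth
#'
#' Computes the four validation percentages: correctly and falsely detected
#' nonoutliers relative to the number of actual nonoutliers, and correctly
#' and falsely detected outliers relative to the total number of actual
#' outliers. Significant and nonsignificant flags both count as "outlier";
#' missing positions are excluded. A falsely detected nonoutlier is a true
#' outlier labelled nonoutlier; a falsely detected outlier is a true
#' nonoutlier that was flagged.
#'
#' @param labels,truth [outlier_labels()] frames over the same index set.
#' @return A one-row data frame with `correct_nonoutlier_pct`,
#'   `false_nonoutlier_pct`, `correct_outlier_pct`, `false_outlier_pct`
#'   (NA when the relevant denominator is zero) and the supporting counts
#'   `n_nonoutliers`, `n_outliers`, `n_false_flags`, `n_missed`.
#' @examples
#' sim <- make_series(simulation_spec(n = 50, seed = 3))
#' fit <- detect_outliers(sim$series, criteria_config(guard_endpoints = FALSE))
#' evaluate_labels(fit$labels, sim$truth)
#' @export
evaluate_labels <- function(labels, truth) {
  stopifnot(inherits(labels, "outlier_labels"),
            inherits(truth, "outlier_labels"))
  if (!identical(labels$index, truth$index)) {
    stop("label and truth index sets differ", call. = FALSE)
  }
  is_out <- function(l) l %in% c("outlier", "significant_outlier",
                                 "nonsignificant_outlier")
  keep <- truth$label != "missing" & labels$label != "missing"
  lo <- is_out(labels$label[keep])
  to <- is_out(truth$label[keep])
  n_non <- sum(!to)
  n_out <- sum(to)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  data.frame(
    correct_nonoutlier_pct = pct(sum(!to & !lo), n_non),
    false_nonoutlier_pct = pct(sum(to & !lo), n_non),
    correct_outlier_pct = pct(sum(to & lo), n_out),
    false_outlier_pct = pct(sum(!to & lo), n_out),
    n_nonoutliers = n_non,
    n_outliers = n_out,
    n_false_flags = sum(!to & lo),
    n_missed = sum(to & !lo)
  )
}

#' Run the synthetic validation grid
#'
#' Evaluates the two-phase detector over the Cartesian product of trends x
#' contamination modes x sizes x replicates, generating each series with
#' [make_series()], detecting with [detect_outliers()], and averaging the
#' [evaluate_labels()] percentages per cell. The default configuration turns
#' the endpoint guard off: the validation design guarantees a clean
#' reference, and an injected outlier that happens to fall on the last
#' position would otherwise (correctly, but uninformatively) trigger the
#' Bad-Detection termination.
#'
#' @param config A [criteria_config()]; default `k_mms = 0.5`,
#'   `k_emms = 0.01` without the endpoint guard.
#' @param sizes Integer vector of series lengths.
#' @param reps Replicates per cell.
#' @param seed Base seed; each run derives its own sub-seed deterministically.
#' @param trends,modes Subsets of the trend / contamination-mode grids.
#' @param outlier_fraction,missing_regions Passed to [simulation_spec()]
#'   (missing regions given as a function of `n`, or a fixed list, or `NULL`).
#' @return A data frame, one row per cell, with mean percentages, pooled
#'   counts and the mean number of MMS-phase removals.
#' @examples
#' run_validation_suite(sizes = c(10, 50), reps = 2, seed = 1)
#' @export
run_validation_suite <- function(config = criteria_config(guard_endpoints = FALSE),
                                 sizes = c(10, 100, 1000),
                                 reps = 5, seed = 1,
                                 trends = c("increasing", "decreasing",
                                            "constant"),
                                 modes = c("non_gaussian", "gaussian"),
                                 outlier_fraction = 0.5,
                                 missing_regions = NULL) {
  grid <- expand.grid(trend = trends, mode = modes, n = sizes,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cell <- grid[i, ]
    mr <- if (is.function(missing_regions)) missing_regions(cell$n) else
      if (is.null(missing_regions)) list() else missing_regions
    runs <- lapply(seq_len(reps), function(r) {
      sub_seed <- (seed * 10007L + i * 101L + r) %% .Machine$integer.max
      sim <- make_series(simulation_spec(
        n = cell$n, trend = cell$trend, outlier_mode = cell$mode,
        outlier_fraction = outlier_fraction, missing_regions = mr,
        seed = sub_seed))
      fit <- detect_outliers(sim$series, config)
      m <- evaluate_labels(fit$labels, sim$truth)
      m$mms_removals <- sum(fit$trace$phase == "mms" &
                              fit$trace$action == "remove")
      m
    })
    runs <- do.call(rbind, runs)
    data.frame(
      trend = cell$trend, mode = cell$mode, n = cell$n, reps = reps,
      correct_nonoutlier_pct = mean(runs$correct_nonoutlier_pct),
      false_nonoutlier_pct = mean(runs$false_nonoutlier_pct),
      correct_outlier_pct = mean(runs$correct_outlier_pct),
      false_outlier_pct = mean(runs$false_outlier_pct),
      n_false_flags = sum(runs$n_false_flags),
      n_missed = sum(runs$n_missed),
      n_outliers = sum(runs$n_outliers),
      mean_mms_removals = mean(runs$mms_removals)
    )
  })
  do.call(rbind, res)
}
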