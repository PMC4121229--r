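#' @keywords internal
LABEL_LEVELS <- c("nonoutlier", "significant_outlier",
                  "nonsignificant_outlier", "missing", "outlier")

#' Per-position label vector
#'
#' A classification of every position on the original index grid
#' (`0..max(index)`): `nonoutlier`, `significant_outlier` (flagged by the MMS
#' phase), `nonsignificant_outlier` (flagged by the EMMS phase) or `missing`
#' (absent from the input). The generic level `outlier` is permitted for
#' ground-truth vectors in which the significant/nonsignificant distinction
#' does not apply.
#'
#' @param index Integer positions (unique).
#' @param label Character or factor with levels among the label levels.
#' @param value Optional numeric values (NA where missing).
#' @return A data frame of class `outlier_labels` with columns `index`,
#'   `value`, `label`.
#' @export
outlier_labels <- function(index, label, value = NA_real_) {
  index <- as.integer(index)
  if (anyDuplicated(index)) stop("duplicate label indices", call. = FALSE)
  label <- as.character(label)
  bad <- setdiff(unique(label), LABEL_LEVELS)
  if (length(bad)) {
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(index = index,
                    value = rep_len(as.numeric(value), length(index)),
                    label = factor(label, levels = LABEL_LEVELS))
  out <- out[order(out$index), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("outlier_labels", "data.frame")
  out
}

# one trace row
.trace_row <- function(phase, iteration, n, scores, r_w, action, position,
                       reason) {
  data.frame(phase = phase, iteration = iteration, n = n,
             score_max = if (is.null(scores)) NA_real_ else scores$score_max,
             score_min = if (is.null(scores)) NA_real_ else scores$score_min,
             r_w = r_w, action = action,
             position = if (is.null(position) || is.na(position))
               NA_integer_ else as.integer(position),
             reason = reason)
}

#' Two-phase iterative outlier detection
#'
#' Runs the full detection procedure on a series expected to follow a linear
#' trend:
#'
#' * **Phase 1 (MMS, significant outliers):** the surviving elements are
#'   compacted by angular shifting ([compact_after_removals()]; initial
#'   missing values count as removals) and classified with
#'   [mms_classify()] at threshold `R_w = 2 * (1 + k_mms) / n` for the
#'   *current* window size `n`. Each flagged extreme is labelled a
#'   significant outlier and removed; the loop repeats until no score exceeds
#'   the threshold.
#' * **Phase 2 (EMMS, nonsignificant outliers):** the surviving elements, on
#'   their original indices, are classified with [emms_classify()] at
#'   `R_w = 2 * (1 + k_emms) / n`; flagged elements are labelled
#'   nonsignificant outliers and removed until no signal remains.
#'
#' No removed or missing value is ever imputed. With the endpoint guard on
#' (the default), flagging the first or last surviving element is a
#' contradiction — those positions are assumed nonoutliers — and terminates
#' both phases immediately (the Bad-Detection termination). When the
#' reference has been overridden to an interior element, the endpoint
#' assumption no longer holds and the guard reduces to the reference itself;
#' flagging the reference always terminates, since it is assumed clean by
#' construction. A phase with fewer than 3 surviving elements (or a widening
#' factor too large for the window) stops gracefully.
#'
#' @param series An [indexed_series()] with at least 3 present elements. Its
#'   `reference` anchors both repair strategies and is never removed.
#' @param config A [criteria_config()].
#' @param phase Which phases to run: `"both"` (default), `"mms"` only, or
#'   `"emms"` only. Running EMMS directly on heavily contaminated data is
#'   discouraged — its slope estimate is then biased — which is why the
#'   default order is MMS first.
#' @return An object of class `outlier_detection`: a list with
#'   `labels` (an [outlier_labels()] frame over positions `0..max(index)`),
#'   `trace` (a data frame of class `detection_trace`, one row per iteration
#'   with the scores, threshold, action, position and termination reason) and
#'   the `series` and `config` used.
#' @examples
#' s <- indexed_series(0:4, c(100, 101, 102, 103, 204))
#' fit <- detect_outliers(s)
#' fit$labels
#' fit$trace
#' @export
detect_outliers <- function(series, config = criteria_config(),
                            phase = c("both", "mms", "emms")) {
  stopifnot(inherits(series, "indexed_series"),
            inherits(config, "criteria_config"))
  phase <- match.arg(phase)
  if (length(series) < 3L) {
    stop("detection needs at least 3 present elements", call. = FALSE)
  }
  orig_idx <- series$indices
  orig_val <- series$values
  ref <- series$reference
  max_iter <- if (is.null(config$max_iterations)) length(series) else
    config$max_iterations

  # 0 = surviving, 1 = significant, 2 = nonsignificant
  status <- integer(length(orig_idx))
  rows <- list()
  terminated <- FALSE

  guard_hit <- function(pos, surv) {
    if (pos == ref) return("reference_flagged")
    if (config$guard_endpoints && ref == surv[1L] &&
        pos %in% c(surv[1L], surv[length(surv)])) {
      return("bad_detection_endpoint")
    }
    NA_character_
  }

  run_phase <- function(which_phase) {
    k <- if (which_phase == "mms") config$k_mms else config$k_emms
    iter <- 0L
    repeat {
      surv <- orig_idx[status == 0L]
      n <- length(surv)
      if (n < 3L || k > n / 2 - 1) {
        rows[[length(rows) + 1L]] <<- .trace_row(
          which_phase, iter, n, NULL, NA_real_, "stop", NA,
          "insufficient_elements")
        break
      }
      r_w <- detection_criterion(n, k)
      if (which_phase == "mms") {
        cs <- compact_after_removals(
          removal_ledger(series, removed = orig_idx[status != 0L]))
        v <- mms_classify(cs, r_w)
        pos <- if (is.na(v$position)) NA_integer_ else
          attr(cs, "original_indices")[match(v$position, cs$indices)]
      } else {
        sub <- indexed_series(surv, orig_val[status == 0L], reference = ref)
        v <- tryCatch(emms_classify(sub, r_w), error = function(e) e)
        if (inherits(v, "error")) {
          rows[[length(rows) + 1L]] <<- .trace_row(
            which_phase, iter, n, NULL, r_w, "stop", NA,
            "degenerate_geometry")
          break
        }
        pos <- v$position
      }
      iter <- iter + 1L
      if (v$type == "none") {
        reason <- if (is.na(v$scores$score_max)) "no_signal" else
          "below_threshold"
        rows[[length(rows) + 1L]] <<- .trace_row(
          which_phase, iter, n, v$scores, r_w, "stop", NA, reason)
        break
      }
      g <- guard_hit(pos, surv)
      if (!is.na(g)) {
        rows[[length(rows) + 1L]] <<- .trace_row(
          which_phase, iter, n, v$scores, r_w, "terminate", pos, g)
        terminated <<- TRUE
        break
      }
      status[match(pos, orig_idx)] <<- if (which_phase == "mms") 1L else 2L
      rows[[length(rows) + 1L]] <<- .trace_row(
        which_phase, iter, n, v$scores, r_w, "remove", pos, NA_character_)
      if (iter >= max_iter) {
        rows[[length(rows) + 1L]] <<- .trace_row(
          which_phase, iter, n - 1L, NULL, r_w, "stop", NA, "max_iterations")
        break
      }
    }
  }

  if (phase %in% c("both", "mms")) run_phase("mms")
  if (!terminated && phase %in% c("both", "emms")) run_phase("emms")

  trace <- do.call(rbind, rows)
  class(trace) <- c("detection_trace", "data.frame")

  full <- 0:max(orig_idx)
  lab <- rep("missing", length(full))
  val <- rep(NA_real_, length(full))
  at <- match(orig_idx, full)
  val[at] <- orig_val
  lab[at] <- c("nonoutlier", "significant_outlier",
               "nonsignificant_outlier")[status + 1L]
  structure(
    list(labels = outlier_labels(full, lab, val), trace = trace,
         series = series, config = config),
    class = "outlier_detection"
  )
}

#' @export
print.outlier_detection <- function(x, ...) {
  tab <- table(x$labels$label)
  cat("<outlier_detection>\n")
  cat(sprintf("  nonoutliers:             %d\n", tab[["nonoutlier"]]))
  cat(sprintf("  significant outliers:    %d\n", tab[["significant_outlier"]]))
  cat(sprintf("  nonsignificant outliers: %d\n",
              tab[["nonsignificant_outlier"]]))
  cat(sprintf("  missing positions:       %d\n", tab[["missing"]]))
  fin <- x$trace$reason[!is.na(x$trace$reason)]
  if (length(fin)) {
    cat("  termination:", paste(fin, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Was a detection run terminated by the Bad-Detection guard?
#' @param x An `outlier_detection` object.
#' @return `TRUE` if any phase ended via the endpoint guard or a flagged
#'   reference element.
#' @export
bad_detection <- function(x) {
  stopifnot(inherits(x, "outlier_detection"))
  any(x$trace$reason %in% c("bad_detection_endpoint", "reference_flagged"))
}

#' Detection with multiple candidate reference elements
#'
#' The method presumes the reference element is not an outlier. When no
#' position is known to be clean, detection can be attempted from several
#' candidate references and the best fitting run kept. Runs that ended in a
#' Bad-Detection termination (a contradiction between the flags and the
#' clean-reference assumption) rank below cleanly terminated runs; among the
#' remainder the run labelling the most elements nonoutlier wins, with ties
#' going to the earliest candidate.
#'
#' @inheritParams detect_outliers
#' @param candidate_references Integer vector of present indices to try.
#' @return The winning `outlier_detection` object, with an extra element
#'   `candidate_summary`: a data frame of per-candidate nonoutlier counts and
#'   termination status.
#' @examples
#' s <- indexed_series(0:4, c(1, 101, 102, 103, 104))
#' fit <- detect_multi_reference(s, candidate_references = c(0, 1))
#' fit$candidate_summary
#' @export
detect_multi_reference <- function(series, config = criteria_config(),
                                   candidate_references,
                                   phase = c("both", "mms", "emms")) {
  stopifnot(inherits(series, "indexed_series"))
  phase <- match.arg(phase)
  candidate_references <- as.integer(candidate_references)
  if (length(candidate_references) == 0L) {
    stop("`candidate_references` must not be empty", call. = FALSE)
  }
  if (!all(candidate_references %in% series$indices)) {
    stop("all candidate references must be present indices", call. = FALSE)
  }
  runs <- lapply(candidate_references, function(r) {
    detect_outliers(
      indexed_series(series$indices, series$values, reference = r),
      config = config, phase = phase)
  })
  nonout <- vapply(runs, function(f)
    sum(f$labels$label == "nonoutlier"), integer(1))
  bad <- vapply(runs, bad_detection, logical(1))
  pick <- order(bad, -nonout, seq_along(runs))[1L]
  best <- runs[[pick]]
  best$candidate_summary <- data.frame(
    reference = candidate_references,
    nonoutliers = nonout,
    bad_detection = bad,
    selected = seq_along(runs) == pick
  )
  best
}
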