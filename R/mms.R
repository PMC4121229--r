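#' Min-max-sum (MMS) scores for significant outliers
#'
#' The MMS scores compare the spread of a series against its sum in a form
#' that is safe for negative values. For any arithmetic progression both
#' scores equal exactly `2/n`; a score strictly above the threshold
#' [detection_criterion()] implicates the corresponding extreme element as a
#' significant outlier.
#'
#' `mms_max()` evaluates `(a_max - a_min) / (S_n - a_min * n)`: values above
#' `2/n` implicate the maximum. `mms_min()` evaluates
#' `(a_max - a_min) / (a_max * n - S_n)`, the same score on the complemented
#' series ([series_complement()]): values above `2/n` implicate the minimum.
#'
#' Both scores use only the multiset of present values and the count `n`;
#' index gaps are irrelevant at this level (positional repair is the job of
#' [compact_after_removals()]).
#'
#' On a constant series both numerator and denominator vanish; the score is
#' then the `NO_SIGNAL` sentinel (`NA_real_`), meaning "no outlier detectable
#' here", not an error. Equality with the range floor is taken relative to the
#' value scale (tolerance 1e-9).
#'
#' @param series An [indexed_series()] with at least 2 present elements.
#' @return A single numeric score in `(0, 1]`, or `NA_real_` (NO_SIGNAL) for
#'   a constant series.
#' @examples
#' s <- indexed_series(0:4, c(100, 101, 102, 103, 204))
#' mms_max(s)  # 0.945: the maximum is far off the line
#' mms_min(s)  # 0.254
#' @export
mms_max <- function(series) {
  stopifnot(inherits(series, "indexed_series"))
  v <- series$values
  n <- length(v)
  if (n < 2L) stop("MMS scores need at least 2 elements", call. = FALSE)
  rng <- max(v) - min(v)
  if (rng <= .DEGENERACY_TOL * .value_scale(v)) return(NA_real_)
  rng / (sum(v) - min(v) * n)
}

#' @rdname mms_max
#' @export
mms_min <- function(series) {
  stopifnot(inherits(series, "indexed_series"))
  v <- series$values
  n <- length(v)
  if (n < 2L) stop("MMS scores need at least 2 elements", call. = FALSE)
  rng <- max(v) - min(v)
  if (rng <= .DEGENERACY_TOL * .value_scale(v)) return(NA_real_)
  rng / (max(v) * n - sum(v))
}

#' Paired MMS scores with implicated positions
#'
#' Convenience wrapper returning both MMS scores together with the original
#' indices of the implicated extremes. Ties among several elements equal to
#' the maximum (or minimum) resolve to the earliest position, keeping the
#' procedure deterministic.
#'
#' @inheritParams mms_max
#' @return A list of class `score_pair` with elements `score_max`,
#'   `score_min`, `argmax_position`, `argmin_position`. Scores are `NA_real_`
#'   (NO_SIGNAL) on a constant series.
#' @examples
#' mms_scores(indexed_series(0:4, c(1, 101, 102, 103, 104)))
#' @export
mms_scores <- function(series) {
  v <- series$values
  structure(
    list(score_max = mms_max(series),
         score_min = mms_min(series),
         argmax_position = series$indices[which.max(v)],
         argmin_position = series$indices[which.min(v)]),
    class = "score_pair"
  )
}

#' @export
print.score_pair <- function(x, ...) {
  fmt <- function(s) if (is.na(s)) "NO_SIGNAL" else sprintf("%.6g", s)
  cat(sprintf("<score_pair> max = %s (position %s), min = %s (position %s)\n",
              fmt(x$score_max), x$argmax_position,
              fmt(x$score_min), x$argmin_position))
  invisible(x)
}

#' Single-step MMS classification
#'
#' Compares both MMS scores against a threshold `r_w` (from
#' [detection_criterion()]). A score must strictly exceed `r_w` to flag;
#' equality is consistent with the linear border. When both scores exceed the
#' threshold the greater one wins; an exact tie prefers the maximum side
#' (arbitrary but fixed, recorded in the detection trace by the pipeline).
#'
#' @inheritParams mms_max
#' @param r_w Detection threshold, normally [detection_criterion()] at the
#'   current window size.
#' @return A list with `type` (`"none"`, `"max_outlier"` or `"min_outlier"`),
#'   `position` (original index of the implicated element, `NA` for none) and
#'   `scores` (the [mms_scores()] pair).
#' @examples
#' s <- indexed_series(0:4, c(100, 101, 102, 103, 204))
#' mms_classify(s, detection_criterion(5, 0))
#' @export
mms_classify <- function(series, r_w) {
  stopifnot(is.numeric(r_w), length(r_w) == 1L, is.finite(r_w))
  sp <- mms_scores(series)
  if (is.na(sp$score_max)) {
    return(list(type = "none", position = NA_integer_, scores = sp))
  }
  flag_max <- sp$score_max > r_w
  flag_min <- sp$score_min > r_w
  if (flag_max && (!flag_min || sp$score_max >= sp$score_min)) {
    list(type = "max_outlier", position = sp$argmax_position, scores = sp)
  } else if (flag_min) {
    list(type = "min_outlier", position = sp$argmin_position, scores = sp)
  } else {
    list(type = "none", position = NA_integer_, scores = sp)
  }
}
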