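#' Enhanced MMS (EMMS) scores for nonsignificant outliers
#'
#' The MMS scores can only implicate the current maximum or minimum; an
#' interior outlier that is neither extreme drives them into "Bad Detection".
#' EMMS fixes this by scoring the [constant_transform()] of the series
#' instead: on the transformed values `y_TT` (absolute residuals around the
#' reference-anchored mean-slope line) every outlier *becomes* the maximum.
#' Since the minimum of `y_TT` is identically 0 (at the reference), the
#' scores simplify to
#' `EMMS_max = max(y_TT) / S_TT` and
#' `EMMS_min = max(y_TT) / (max(y_TT) * n - S_TT)` with `S_TT = sum(y_TT)`.
#'
#' The transform is recomputed from the currently present elements on their
#' original indices, so EMMS is inherently missing-value robust and needs no
#' compaction.
#'
#' When the transform is (numerically) all zero the series is a perfect line:
#' both scores are the `NO_SIGNAL` sentinel (`NA_real_`). The zero test is
#' relative to the scale of the centred values (tolerance 1e-9).
#'
#' @param series An [indexed_series()] with at least 3 present elements.
#' @return A `score_pair` list: `score_max`, `score_min`, `argmax_position`
#'   (original index of the largest residual; earliest on ties) and
#'   `argmin_position` (the reference, whose residual is exactly 0).
#' @examples
#' s <- indexed_series(0:4, c(100, 101, 102, 103.6, 104))
#' emms_scores(s)  # max 0.5, min 1/3, implicating position 3
#' @export
emms_scores <- function(series) {
  stopifnot(inherits(series, "indexed_series"))
  if (length(series) < 3L) {
    stop("EMMS needs at least 3 elements", call. = FALSE)
  }
  ytt <- constant_transform(series)
  n <- length(ytt)
  a_max <- max(ytt)
  scale <- .value_scale(series$values - reference_value(series))
  if (a_max <= .DEGENERACY_TOL * scale) {
    return(structure(
      list(score_max = NA_real_, score_min = NA_real_,
           argmax_position = NA_integer_,
           argmin_position = series$reference),
      class = "score_pair"
    ))
  }
  s_tt <- sum(ytt)
  structure(
    list(score_max = a_max / s_tt,
         score_min = a_max / (a_max * n - s_tt),
         argmax_position = series$indices[which.max(ytt)],
         argmin_position = series$reference),
    class = "score_pair"
  )
}

#' Single-step EMMS classification
#'
#' Outliers are present whenever *either* EMMS score strictly exceeds the
#' threshold. The removable element is always the one with the largest
#' transformed residual (the point farthest from the reference-anchored
#' fitted line): the minimum of the transform is the reference itself, a
#' point *on* the line, so the minimum-side score can signal contamination
#' but never implicates a different element. An `EMMS_min`-only signal
#' (`EMMS_min > r_w >= EMMS_max`) typically arises when many comparable
#' residuals remain — heavy contamination with no single dominant outlier —
#' and removing the largest residual is still the correct move there.
#'
#' @inheritParams emms_scores
#' @param r_w Detection threshold, normally [detection_criterion()] with the
#'   EMMS widening factor at the current window size.
#' @return A list with `type` (`"none"` or `"outlier"`), `position`
#'   (original index of the implicated element, `NA` unless `"outlier"`) and
#'   `scores` (the [emms_scores()] pair).
#' @examples
#' s <- indexed_series(0:4, c(100, 101, 102, 103.6, 104))
#' emms_classify(s, detection_criterion(5, 0.01))  # flags position 3
#' @export
emms_classify <- function(series, r_w) {
  stopifnot(is.numeric(r_w), length(r_w) == 1L, is.finite(r_w))
  sp <- emms_scores(series)
  if (is.na(sp$score_max)) {
    return(list(type = "none", position = NA_integer_, scores = sp))
  }
  if (sp$score_max > r_w || sp$score_min > r_w) {
    list(type = "outlier", position = sp$argmax_position, scores = sp)
  } else {
    list(type = "none", position = NA_integer_, scores = sp)
  }
}
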