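#' Indexed numeric series with missing-value support
#'
#' The central data object: an ordered set of (index, value) pairs describing
#' a series that is expected to follow a linear trend. Indices are 0-based
#' integer positions on the original sampling grid; missing values are
#' represented by absent indices, never by placeholder numerics, so the
#' element count `n` always refers to present elements only.
#'
#' @param indices Integer vector of non-negative, strictly increasing
#'   positions. May contain gaps (missing values).
#' @param values Numeric vector of series values, one per index. Must be
#'   finite.
#' @param reference Optional index (one of `indices`) designating the
#'   reference element — the point assumed *not* to be an outlier, anchoring
#'   angular shifting and the constant-value transform. Defaults to the first
#'   present index.
#'
#' @return An object of class `indexed_series`: a list with elements
#'   `indices`, `values` and `reference`.
#'
#' @examples
#' s <- indexed_series(0:4, c(100, 101, 102, 103, 204))
#' s
#' ap_ratio(s)
#'
#' # a gap at position 2:
#' indexed_series(c(0, 1, 3), c(100, 101, 103))
#' @export
indexed_series <- function(indices, values, reference = NULL) {
  if (length(indices) != length(values)) {
    stop("`indices` and `values` must have the same length", call. = FALSE)
  }
  if (length(indices) == 0L) {
    stop("a series needs at least one element", call. = FALSE)
  }
  if (any(!is.finite(indices)) || any(indices < 0) ||
      any(indices != trunc(indices))) {
    stop("`indices` must be finite non-negative integers", call. = FALSE)
  }
  indices <- as.integer(indices)
  if (is.unsorted(indices, strictly = TRUE)) {
    ord <- order(indices)
    indices <- indices[ord]
    values <- values[ord]
    if (anyDuplicated(indices)) {
      stop("`indices` must be unique (one value per index)", call. = FALSE)
    }
  }
  values <- as.numeric(values)
  if (any(!is.finite(values))) {
    stop("`values` must be finite; encode missing values as absent indices",
         call. = FALSE)
  }
  if (is.null(reference)) {
    reference <- indices[1L]
  } else {
    reference <- as.integer(reference)
    if (length(reference) != 1L || !(reference %in% indices)) {
      stop("`reference` must be a single present index", call. = FALSE)
    }
  }
  structure(
    list(indices = indices, values = values, reference = reference),
    class = "indexed_series"
  )
}

#' @export
length.indexed_series <- function(x) length(x$values)

#' @export
print.indexed_series <- function(x, ...) {
  n <- length(x)
  span <- max(x$indices) - x$indices[1L] + 1L
  cat(sprintf(
    "<indexed_series> %d element%s over positions %d..%d (%d missing), reference at %d\n",
    n, if (n == 1L) "" else "s", x$indices[1L], max(x$indices),
    span - n, x$reference
  ))
  show <- min(n, 10L)
  df <- data.frame(index = x$indices[seq_len(show)],
                   value = x$values[seq_len(show)])
  print(df, row.names = FALSE)
  if (n > show) cat(sprintf("... and %d more\n", n - show))
  invisible(x)
}

#' @export
as.data.frame.indexed_series <- function(x, ...) {
  data.frame(index = x$indices, value = x$values)
}

#' Value at the reference element
#' @param series An [indexed_series()].
#' @return The numeric value stored at the reference index.
#' @export
reference_value <- function(series) {
  stopifnot(inherits(series, "indexed_series"))
  series$values[match(series$reference, series$indices)]
}

# relative scale of a value vector, for degeneracy floors
.value_scale <- function(v) max(abs(v), 1)

# relative tolerance below which a range / transform maximum counts as zero
.DEGENERACY_TOL <- 1e-9

#' Raw arithmetic-progression ratio
#'
#' For a finite arithmetic progression (a series without outliers) the ratio
#' of the sum of the extreme elements to the sum of all elements is exactly
#' `2/n`. Any departure from `2/n` implies outliers: a ratio above `2/n`
#' implicates the maximum, a ratio below `2/n` the minimum. The raw ratio is
#' fragile (its sign breaks down with negative values and its denominator can
#' vanish); the MMS forms ([mms_max()], [mms_min()]) are the robust versions.
#'
#' @param series An [indexed_series()] with at least 2 elements.
#' @return `(min + max) / sum` of the present values.
#' @seealso [mms_max()], [mms_min()], [detection_criterion()]
#' @examples
#' ap_ratio(indexed_series(0:4, c(100, 101, 102, 103, 104)))  # exactly 2/5
#' ap_ratio(indexed_series(0:4, c(100, 101, 102, 103, 204)))  # > 2/5: max suspect
#' @export
ap_ratio <- function(series) {
  stopifnot(inherits(series, "indexed_series"))
  v <- series$values
  n <- length(v)
  if (n < 2L) stop("ap_ratio() needs at least 2 elements", call. = FALSE)
  s <- sum(v)
  if (s == 0) {
    stop("zero series sum: the raw AP ratio is unusable (use the MMS scores)",
         call. = FALSE)
  }
  (min(v) + max(v)) / s
}

#' Outlier-detection threshold R_w
#'
#' The exact-line indicator `2/n` widened by a non-negative factor `k`:
#' `R_w = (2/n) * (1 + k)`. Elements scoring strictly above `R_w` are flagged.
#' `k = 0` tolerates only a perfect line; larger `k` widens the linear border.
#' `k` must not exceed `n/2 - 1`, which keeps `R_w` at or below the score
#' ceiling of 1.
#'
#' @param n Number of present elements in the window (`>= 2`).
#' @param k Non-negative widening factor; `k <= n/2 - 1`.
#' @return The threshold `2 * (1 + k) / n`, guaranteed in `[2/n, 1]`.
#' @examples
#' detection_criterion(5, 0)     # 0.4, the exact-line indicator
#' detection_criterion(10, 0.5)  # 0.3
#' @export
detection_criterion <- function(n, k) {
  if (length(n) != 1L || !is.finite(n) || n < 2 || n != trunc(n)) {
    stop("`n` must be a single integer >= 2", call. = FALSE)
  }
  if (length(k) != 1L || !is.finite(k) || k < 0) {
    stop("`k` must be a single non-negative number", call. = FALSE)
  }
  if (k > n / 2 - 1) {
    stop(sprintf("`k` = %g exceeds n/2 - 1 = %g: threshold would exceed 1",
                 k, n / 2 - 1), call. = FALSE)
  }
  2 * (1 + k) / n
}

#' Complement of a series
#'
#' Maps every value to `(max + min) - value`, swapping the roles of maximum
#' and minimum while preserving the element geometry. The complement underlies
#' the minimum-side MMS score: the minimum of the original series becomes the
#' maximum of the complement, so a single maximum-side score suffices for both
#' extremes. The operation is an involution and leaves indices untouched.
#'
#' @param series An [indexed_series()].
#' @return The complemented [indexed_series()].
#' @examples
#' s <- indexed_series(0:4, c(1, 101, 102, 103, 104))
#' series_complement(s)$values  # 104, 4, 3, 2, 1
#' @export
series_complement <- function(series) {
  stopifnot(inherits(series, "indexed_series"))
  v <- series$values
  series$values <- (max(v) + min(v)) - v
  series
}

#' Detection configuration for the two-phase pipeline
#'
#' @param k_mms Widening factor for the significant-outlier (MMS) phase.
#'   Default 0.5, the validated setting for synthetic linear data; the `field`
#'   preset uses 0.2.
#' @param k_emms Widening factor for the nonsignificant-outlier (EMMS) phase.
#'   Default 0.01 (`field` preset: 0.1).
#' @param guard_endpoints If `TRUE` (default), flagging the first or last
#'   surviving element terminates detection: when the window endpoints are
#'   assumed nonoutliers, such a flag is a contradiction signalling the
#'   Bad-Detection level. Turn off only with prior knowledge about where
#'   outliers can occur.
#' @param max_iterations Defensive cap on removals per phase; `NULL` means the
#'   series length (one cannot remove more than everything).
#' @param preset Either `"validation"` (defaults above) or `"field"`
#'   (`k_mms = 0.2`, `k_emms = 0.1`), applied before the explicit arguments.
#' @return An object of class `criteria_config`.
#' @examples
#' criteria_config()
#' criteria_config(preset = "field")
#' @export
criteria_config <- function(k_mms = NULL, k_emms = NULL,
                            guard_endpoints = TRUE, max_iterations = NULL,
                            preset = c("validation", "field")) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    validation = list(k_mms = 0.5, k_emms = 0.01),
    field      = list(k_mms = 0.2, k_emms = 0.1)
  )
  if (is.null(k_mms)) k_mms <- defaults$k_mms
  if (is.null(k_emms)) k_emms <- defaults$k_emms
  stopifnot(is.numeric(k_mms), length(k_mms) == 1L, is.finite(k_mms),
            k_mms >= 0,
            is.numeric(k_emms), length(k_emms) == 1L, is.finite(k_emms),
            k_emms >= 0,
            is.logical(guard_endpoints), length(guard_endpoints) == 1L)
  if (!is.null(max_iterations)) {
    stopifnot(is.numeric(max_iterations), length(max_iterations) == 1L,
              max_iterations >= 1)
    max_iterations <- as.integer(max_iterations)
  }
  structure(
    list(k_mms = k_mms, k_emms = k_emms,
         guard_endpoints = guard_endpoints,
         max_iterations = max_iterations),
    class = "criteria_config"
  )
}

#' @export
print.criteria_config <- function(x, ...) {
  cat(sprintf(
    "<criteria_config> k_mms = %g, k_emms = %g, endpoint guard %s, max iterations %s\n",
    x$k_mms, x$k_emms, if (x$guard_endpoints) "on" else "off",
    if (is.null(x$max_iterations)) "= n" else format(x$max_iterations)
  ))
  invisible(x)
}
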