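#' Angular-shift recalculation of a single value
#'
#' When an element is removed (or was missing from the start), the elements
#' behind it slide toward the gap. A plain horizontal shift would change their
#' relationship to the series; shifting *along the ray through the reference
#' element* preserves it. The recalculated value keeps the element's angle to
#' the reference:
#' `new = ref + (original - ref) * new_offset / original_offset`.
#'
#' Offsets are distances from the reference element on the index grid.
#' Recalculation must always start from the element's *original* value, never
#' from a previously recalculated one; [compact_after_removals()] enforces
#' this. Offsets may be negative for elements before an interior reference
#' (then `|new_offset| <= |original_offset|` with matching signs).
#'
#' @param reference_value Value of the reference element.
#' @param original_value The element's original (never recalculated) value.
#' @param original_offset Signed index distance from the reference in the
#'   original series; nonzero.
#' @param new_offset Signed distance after gap compaction; same sign as
#'   `original_offset`, nonzero, and not larger in magnitude.
#' @return The recalculated value.
#' @examples
#' # a point on the line y = 2x through the reference stays on it:
#' angular_shift_value(0, 10, 5, 4)     # 8
#' angular_shift_value(100, 102, 2, 1)  # 101, line y = 100 + x
#' @export
angular_shift_value <- function(reference_value, original_value,
                                original_offset, new_offset) {
  stopifnot(is.numeric(reference_value), is.numeric(original_value),
            length(original_offset) == length(new_offset))
  if (any(new_offset == 0)) {
    stop("`new_offset` of 0 would collapse an element onto the reference",
         call. = FALSE)
  }
  if (any(original_offset == 0)) {
    stop("`original_offset` must be nonzero", call. = FALSE)
  }
  if (any(sign(new_offset) != sign(original_offset)) ||
      any(abs(new_offset) > abs(original_offset))) {
    stop("`new_offset` must keep the sign of `original_offset` and not exceed it in magnitude",
         call. = FALSE)
  }
  reference_value + (original_value - reference_value) *
    (new_offset / original_offset)
}

#' Removal ledger: a frozen series plus its removed positions
#'
#' Book-keeping for iterative removal. The ledger freezes the original series
#' so every recalculation reads original values, and tracks which original
#' indices have been removed. The reference element can never be removed.
#'
#' @param series The original [indexed_series()] (frozen; initial missing
#'   values are simply absent indices and are treated exactly like removals).
#' @param removed Integer vector of removed original indices (subset of the
#'   series' present indices, excluding the reference).
#' @return An object of class `removal_ledger`.
#' @seealso [compact_after_removals()]
#' @export
removal_ledger <- function(series, removed = integer()) {
  stopifnot(inherits(series, "indexed_series"))
  removed <- as.integer(removed)
  if (anyDuplicated(removed)) {
    stop("duplicate removed positions", call. = FALSE)
  }
  if (!all(removed %in% series$indices)) {
    stop("removed positions must be present indices of the original series",
         call. = FALSE)
  }
  if (series$reference %in% removed) {
    stop("the reference element cannot be removed", call. = FALSE)
  }
  structure(list(original = series, removed = sort(removed)),
            class = "removal_ledger")
}

#' @export
print.removal_ledger <- function(x, ...) {
  cat(sprintf("<removal_ledger> %d of %d elements removed (reference at %d)\n",
              length(x$removed), length(x$original), x$original$reference))
  invisible(x)
}

#' Compact a series after removals by angular shifting
#'
#' Re-indexes the surviving elements contiguously and recalculates each value
#' by [angular_shift_value()]: the new offset from the reference is the
#' original offset minus the number of removed-or-missing grid positions
#' between the reference and the element (equivalently, the element's
#' surviving rank counted from the reference). Original values are always
#' used, so compaction is independent of removal order. Elements before an
#' interior reference are handled symmetrically with negative offsets. Any
#' element on a line through the reference lands exactly on that line at its
#' new offset, so a clean linear series survives compaction unchanged.
#'
#' @param ledger A [removal_ledger()] (or an [indexed_series()], taken as a
#'   ledger with no removals, compacting only its initial gaps).
#' @return An [indexed_series()] with contiguous indices `0..n_surviving - 1`
#'   and recalculated values; its reference is the reference element's new
#'   position. The original indices of the surviving elements are attached as
#'   attribute `"original_indices"`.
#' @examples
#' s <- indexed_series(0:4, c(100, 101, 102, 103, 104))
#' compact_after_removals(removal_ledger(s, removed = 2))$values
#' # 100 101 102 103 -- still on the original line
#' @export
compact_after_removals <- function(ledger) {
  if (inherits(ledger, "indexed_series")) {
    ledger <- removal_ledger(ledger)
  }
  stopifnot(inherits(ledger, "removal_ledger"))
  orig <- ledger$original
  keep <- !(orig$indices %in% ledger$removed)
  idx <- orig$indices[keep]
  val <- orig$values[keep]
  if (length(idx) < 2L) {
    stop("fewer than 2 elements survive the removals", call. = FALSE)
  }
  ref_pos <- match(ledger$original$reference, idx)
  ref_val <- val[ref_pos]
  # new offset = signed surviving rank from the reference
  new_off <- seq_along(idx) - ref_pos
  old_off <- idx - idx[ref_pos]
  shifted <- val
  mv <- new_off != 0L
  shifted[mv] <- angular_shift_value(ref_val, val[mv], old_off[mv], new_off[mv])
  out <- indexed_series(seq_along(idx) - 1L, shifted, reference = ref_pos - 1L)
  attr(out, "original_indices") <- idx
  out
}

#' Constant-value transform of a linear series
#'
#' Transforms a series expected to be linear into the absolute residuals
#' around the line through the reference element with the mean slope
#' `m = sum(value - ref_value) / sum(index - ref_index)` (sums over present
#' elements): `y_TT = |(value - ref_value) - (index - ref_index) * m|`.
#'
#' A perfect line maps to all zeros regardless of which values are missing --
#' the transform is the imputation-free answer to gaps, and the substrate of
#' the EMMS scores. The reference element always maps to exactly 0, and the
#' output is invariant under adding any linear trend `c * index + d` to the
#' values.
#'
#' @param series An [indexed_series()] with at least 2 present elements whose
#'   index sum (relative to the reference) is nonzero.
#' @return Numeric vector of non-negative transformed values, aligned with
#'   `series$indices`.
#' @examples
#' s <- indexed_series(0:4, c(100, 101, 102, 103.6, 104))
#' constant_transform(s)  # 0 0.06 0.12 0.42 0.24
#' @export
constant_transform <- function(series) {
  stopifnot(inherits(series, "indexed_series"))
  n <- length(series)
  if (n < 2L) stop("constant_transform() needs at least 2 elements",
                   call. = FALSE)
  x_t <- series$indices - series$reference
  y_t <- series$values - reference_value(series)
  gx <- sum(x_t)
  if (gx == 0) {
    stop("zero index sum relative to the reference: slope is undefined",
         call. = FALSE)
  }
  m <- sum(y_t) / gx
  abs(y_t - x_t * m)
}
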