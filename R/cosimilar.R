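# Cosimilar pair-value coding: maximal runs of equal values become
# (U = value, V = count) pairs, flattened to the interleaved sequence
# S = U1,V1,U2,V2,... Both steps invert exactly. Real wavelet coefficients
# are bridged to the integer pair coder by uniform scalar quantization.

#' Construct a pair sequence
#'
#' @param values Integer run values (U).
#' @param counts Integer run counts (V), all `>= 1`.
#' @param order Scan order tag, `"row"` (row-major raster, default) or
#'   `"column"`.
#' @param maximal If `TRUE` (default) enforce maximal runs: consecutive
#'   values must differ. Decoders may carry non-maximal runs (e.g. after
#'   lossy value reconstruction), so this can be relaxed.
#' @return An object of class `sbpn_pairs` with fields `values`, `counts`,
#'   `total` and `order`.
#' @export
pair_sequence <- function(values, counts, order = "row", maximal = TRUE) {
  if (length(values) != length(counts)) {
    stop_argument("values and counts must have equal length")
  }
  if (length(values) == 0L) stop_argument("pair sequence must be nonempty")
  counts <- as.numeric(counts)
  if (anyNA(counts) || any(counts < 1) || any(counts != floor(counts))) {
    stop_corrupt("run counts must be integers >= 1")
  }
  values <- as.numeric(values)
  if (anyNA(values) || any(values != floor(values))) {
    stop_argument("run values must be integers")
  }
  if (maximal && length(values) > 1L &&
      any(values[-1L] == values[-length(values)])) {
    stop_argument("runs must be maximal: consecutive pair values must differ")
  }
  if (!order %in% c("row", "column")) stop_argument("unknown scan order '%s'", order)
  structure(list(values = values, counts = counts, total = sum(counts),
                 order = order),
            class = "sbpn_pairs")
}

#' @export
print.sbpn_pairs <- function(x, ...) {
  cat(sprintf("<sbpn_pairs> %d pairs covering %d elements (%s-major scan)\n",
              length(x$values), x$total, x$order))
  invisible(x)
}

scan_vector <- function(mat, order) {
  if (order == "row") as.vector(t(mat)) else as.vector(mat)
}

unscan_matrix <- function(vec, dims, order) {
  if (order == "row") {
    matrix(vec, nrow = dims[1], ncol = dims[2], byrow = TRUE)
  } else {
    matrix(vec, nrow = dims[1], ncol = dims[2])
  }
}

#' Encode a matrix as cosimilar (value, count) run pairs
#'
#' Scans the matrix in the declared order and collapses each maximal run of
#' equal values into one pair — the redundancy-suppression stage of the
#' codec.
#'
#' @param mat Integer matrix (pixels or quantized coefficients).
#' @param order Scan order, `"row"` (default) or `"column"`.
#' @return An [pair_sequence] whose counts sum to `length(mat)`.
#' @examples
#' p <- encode_pairs(matrix(c(5, 5, 5, 5), 2, 2))
#' cbind(p$values, p$counts)  # one run of four
#' @export
encode_pairs <- function(mat, order = "row") {
  if (!is.matrix(mat) || length(mat) == 0L) {
    stop_argument("matrix must be nonempty")
  }
  v <- as.numeric(scan_vector(mat, order))
  if (anyNA(v) || any(v != floor(v))) stop_argument("matrix entries must be integers")
  r <- rle(v)
  pair_sequence(r$values, r$lengths, order = order)
}

#' Decode run pairs back to a matrix
#'
#' Exact inverse of [encode_pairs()] for the same scan order.
#'
#' @param p An `sbpn_pairs` object.
#' @param dims Target dims `c(m, n)`; `sum(p$counts)` must equal `m * n`.
#' @return An integer matrix.
#' @export
decode_pairs <- function(p, dims) {
  if (!inherits(p, "sbpn_pairs")) stop_argument("not an sbpn_pairs object")
  dims <- as.integer(dims)
  if (p$total != prod(dims)) {
    stop_corrupt("pair counts sum to %d but target dims %dx%d need %d elements",
                 p$total, dims[1], dims[2], prod(dims))
  }
  vec <- rep(p$values, p$counts)
  unscan_matrix(vec, dims, p$order)
}

#' Flatten pairs to the interleaved sequence order
#'
#' `S = U1, V1, U2, V2, ...`: odd positions are run values, even positions
#' run counts. [unflatten()] inverts it.
#'
#' @param p An `sbpn_pairs` object.
#' @return A numeric vector of length `2 * length(p$values)`.
#' @export
flatten <- function(p) {
  if (!inherits(p, "sbpn_pairs")) stop_argument("not an sbpn_pairs object")
  s <- as.vector(rbind(p$values, p$counts))
  attr(s, "order") <- p$order
  s
}

#' @rdname flatten
#' @param s Numeric vector in interleaved sequence order (even length).
#' @param order Scan order tag for the rebuilt pair sequence.
#' @param maximal Passed to [pair_sequence()].
#' @export
unflatten <- function(s, order = NULL, maximal = TRUE) {
  if (length(s) == 0L || length(s) %% 2L != 0L) {
    stop_corrupt("flat sequence must have nonzero even length, got %d", length(s))
  }
  if (is.null(order)) order <- attr(s, "order") %||% "row"
  idx <- seq(1L, length(s), by = 2L)
  pair_sequence(s[idx], s[idx + 1L], order = order, maximal = maximal)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Uniform scalar quantization of a coefficient plane
#'
#' Rounds `x / step` to the nearest integer (ties away from zero);
#' [dequantize_plane()] returns `q * step`. The reconstruction error is at
#' most `step / 2` per coefficient. This bridges real-valued wavelet
#' coefficients to the integer pair coder: two coefficients are cosimilar
#' when they quantize to the same index.
#'
#' @param plane Numeric matrix of coefficients.
#' @param step Positive quantizer step.
#' @return `quantize_plane`: an integer-valued matrix of quantizer indices;
#'   `dequantize_plane`: a numeric matrix.
#' @export
quantize_plane <- function(plane, step) {
  if (!is.numeric(step) || length(step) != 1L || is.na(step) || step <= 0) {
    stop_argument("quantizer step must be a positive real")
  }
  round_half_away(plane / step)
}

#' @rdname quantize_plane
#' @param q Integer matrix of quantizer indices.
#' @export
dequantize_plane <- function(q, step) {
  if (!is.numeric(step) || length(step) != 1L || is.na(step) || step <= 0) {
    stop_argument("quantizer step must be a positive real")
  }
  q * step
}
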