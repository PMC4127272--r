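# Pyramidal 2-D discrete wavelet transform.
#
# Orthonormal filter pairs applied as a periodized two-channel filter bank:
# the analysis operator is orthogonal, so synthesis is its transpose and
# reconstruction is exact to floating precision. Odd-length axes are
# extended by half-sample replication of the last row/column before
# filtering; the original dims are recorded so reconstruction can crop,
# which keeps the round trip exact for odd sizes too.

dwt_filters <- function(wavelet) {
  switch(wavelet,
    haar = {
      lo <- c(1, 1) / sqrt(2)
      list(lo = lo, hi = c(1, -1) / sqrt(2))
    },
    db2 = {
      s3 <- sqrt(3)
      lo <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
      # quadrature mirror: reversed low-pass with alternating signs
      list(lo = lo, hi = rev(lo) * c(1, -1, 1, -1))
    },
    stop_argument("unknown wavelet '%s' (supported: haar, db2)", wavelet)
  )
}

# One analysis step along rows of X (i.e. down each column), periodized.
# X must have an even number of rows. Returns list(lo, hi), each N/2 rows.
dwt_step_rows <- function(X, filt) {
  N <- nrow(X)
  half <- N %/% 2L
  A <- matrix(0, half, ncol(X))
  D <- matrix(0, half, ncol(X))
  base <- 2L * (seq_len(half) - 1L)
  for (i in seq_along(filt$lo)) {
    idx <- (base + (i - 1L)) %% N + 1L
    A <- A + filt$lo[i] * X[idx, , drop = FALSE]
    D <- D + filt$hi[i] * X[idx, , drop = FALSE]
  }
  list(lo = A, hi = D)
}

# Transpose of dwt_step_rows: exact inverse for orthonormal filters.
idwt_step_rows <- function(A, D, filt) {
  half <- nrow(A)
  N <- 2L * half
  X <- matrix(0, N, ncol(A))
  base <- 2L * (seq_len(half) - 1L)
  for (i in seq_along(filt$lo)) {
    # stride-2 shifts mod even N: indices are distinct within each tap
    idx <- (base + (i - 1L)) %% N + 1L
    X[idx, ] <- X[idx, ] + filt$lo[i] * A + filt$hi[i] * D
  }
  X
}

pad_even_rows <- function(X) {
  if (nrow(X) %% 2L == 1L) rbind(X, X[nrow(X), , drop = FALSE]) else X
}

# Single-level 2-D analysis. Returns the four subband planes.
dwt2_once <- function(X, filt) {
  X <- pad_even_rows(X)
  X <- t(pad_even_rows(t(X)))
  rows <- dwt_step_rows(X, filt)                 # filter along row index
  L <- rows$lo; H <- rows$hi                     # H: high-pass across rows
  Lc <- dwt_step_rows(t(L), filt)                # then along column index
  Hc <- dwt_step_rows(t(H), filt)
  list(
    approx = t(Lc$lo),        # LL
    horizontal = t(Hc$lo),    # high-pass across rows: horizontal edges
    vertical = t(Lc$hi),      # high-pass across cols: vertical edges
    diagonal = t(Hc$hi)       # HH
  )
}

idwt2_once <- function(planes, filt, out_dim) {
  tL <- idwt_step_rows(t(planes$approx), t(planes$vertical), filt)
  tH <- idwt_step_rows(t(planes$horizontal), t(planes$diagonal), filt)
  X <- idwt_step_rows(t(tL), t(tH), filt)
  X[seq_len(out_dim[1]), seq_len(out_dim[2]), drop = FALSE]
}

#' Pyramidal wavelet decomposition into subbands
#'
#' Decomposes an image (or any real matrix) into the multiresolution
#' subbands of a discrete wavelet transform: at each level the three detail
#' planes — horizontal, vertical and diagonal — plus, at the deepest level,
#' the approximate (low-pass) plane. Filtering is recursive on the
#' approximate plane.
#'
#' @param img A [gray_image] or numeric matrix.
#' @param levels Number of decomposition levels, `>= 1`; limited by
#'   `2^levels <= min(dim(img))`.
#' @param wavelet `"haar"` (default) or `"db2"` (Daubechies-4).
#' @return An object of class `sbpn_subbands` with elements `levels`,
#'   `wavelet`, `dim` (original dims), `detail` (a list per level with
#'   matrices `horizontal`, `vertical`, `diagonal`) and `approx` (the level-L
#'   low-pass plane).
#' @examples
#' sb <- decompose(gray_image(matrix(128L, 8, 8)), levels = 1)
#' max(abs(sb$detail[[1]]$diagonal))  # 0: constant image has no detail
#' @export
decompose <- function(img, levels = 1L, wavelet = "haar") {
  X <- if (inherits(img, "gray_image")) as_gray_matrix(img) else as.matrix(img)
  storage.mode(X) <- "double"
  if (!is_count(levels)) stop_argument("levels must be a positive integer")
  levels <- as.integer(levels)
  maxL <- floor(log2(min(dim(X))))
  if (2^levels > min(dim(X))) {
    stop_argument("levels = %d too deep for a %dx%d image (max admissible level: %d)",
                  levels, nrow(X), ncol(X), maxL)
  }
  filt <- dwt_filters(wavelet)
  detail <- vector("list", levels)
  dims <- vector("list", levels)
  A <- X
  for (l in seq_len(levels)) {
    dims[[l]] <- dim(A)
    planes <- dwt2_once(A, filt)
    detail[[l]] <- planes[c("horizontal", "vertical", "diagonal")]
    A <- planes$approx
  }
  structure(
    list(levels = levels, wavelet = wavelet, dim = dim(X),
         level_dims = dims, detail = detail, approx = A),
    class = "sbpn_subbands"
  )
}

#' @export
print.sbpn_subbands <- function(x, ...) {
  cat(sprintf("<sbpn_subbands> %dx%d, %d level(s), wavelet=%s, approx %dx%d\n",
              x$dim[1], x$dim[2], x$levels, x$wavelet,
              nrow(x$approx), ncol(x$approx)))
  invisible(x)
}

check_subbands <- function(sb) {
  if (!inherits(sb, "sbpn_subbands")) stop_argument("not an sbpn_subbands object")
  d <- sb$dim
  for (l in seq_len(sb$levels)) {
    expect <- ceiling(sb$level_dims[[l]] / 2)
    for (nm in c("horizontal", "vertical", "diagonal")) {
      pl <- sb$detail[[l]][[nm]]
      if (!all(dim(pl) == expect)) {
        stop_shape("level-%d %s plane is %dx%d, expected %dx%d",
                   l, nm, nrow(pl), ncol(pl), expect[1], expect[2])
      }
    }
  }
  if (!all(dim(sb$approx) == ceiling(sb$level_dims[[sb$levels]] / 2))) {
    stop_shape("approximate plane dims inconsistent with pyramid")
  }
  invisible(sb)
}

#' Inverse pyramidal wavelet reconstruction
#'
#' Exact inverse of [decompose()]: returns a real matrix of the original
#' dimensions, equal to the source within floating tolerance.
#'
#' @param sb An `sbpn_subbands` object.
#' @return A numeric matrix of the original image dimensions.
#' @export
reconstruct <- function(sb) {
  check_subbands(sb)
  filt <- dwt_filters(sb$wavelet)
  A <- sb$approx
  for (l in rev(seq_len(sb$levels))) {
    planes <- sb$detail[[l]]
    planes$approx <- A
    A <- idwt2_once(planes, filt, sb$level_dims[[l]])
  }
  A
}
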