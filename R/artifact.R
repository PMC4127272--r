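# The ".sbpn" container: a bespoke little-endian binary format.
#
# Layout:
#   magic "SBPN" | version u8 | mode u8 | m u32 | n u32 | levels u8 |
#   wavelet u8 | n_streams u16 | stream blocks...
# Each stream block:
#   label u8 | level u8 | rows u32 | cols u32 | step f64 | s_max f64 |
#   signed u8 | vmin f64 | vmax f64 | chunk_n u16 | k u16 | pad u16 |
#   n_pairs u32 | counts_len u32 | values_len u32 | hidden_len u32 |
#   wdec_len u32 | counts bytes | values bytes | hidden bytes | wdec bytes
# Counts and values are LEB128-style varints (values zigzag-mapped so
# negative quantized coefficients are representable); hidden codes are one
# byte per coefficient; decode weights are 32-bit floats. The header fully
# determines how to parse the payload, and the serialized length is a
# deterministic function of the artifact — it is the codec's "compressed
# size" for all rate metrics.

SBPN_MAGIC <- charToRaw("SBPN")
SBPN_VERSION <- 1L
SBPN_MODES <- c(lossless = 0L, direct = 1L, spectral = 2L)
SBPN_WAVELETS <- c(haar = 0L, db2 = 1L)
SBPN_LABELS <- c(pixels = 0L, approx = 1L, horizontal = 2L, vertical = 3L,
                 diagonal = 4L)

# ---- varints ----------------------------------------------------------------

# Unsigned LEB128, vectorized. Values must be non-negative and < 2^53.
varint_encode <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0L) return(raw(0))
  if (anyNA(x) || any(x < 0) || any(x != floor(x))) {
    stop_argument("varint values must be non-negative integers")
  }
  nbits <- ifelse(x < 1, 1, floor(log2(x)) + 1)
  ng <- pmax(1, ceiling(nbits / 7))
  vi <- rep(seq_along(x), ng)
  gi <- sequence(ng) - 1
  byte <- (x[vi] %/% 128^gi) %% 128
  cont <- gi < ng[vi] - 1
  as.raw(byte + 128 * cont)
}

varint_decode <- function(bytes, expected_n = NULL) {
  b <- as.integer(bytes)
  if (length(b) == 0L) {
    if (!is.null(expected_n) && expected_n > 0L) {
      stop_corrupt("varint block empty, expected %d values", expected_n)
    }
    return(numeric(0))
  }
  last <- b < 128L
  if (!last[length(b)]) stop_corrupt("truncated varint at end of block")
  ends <- which(last)
  lens <- diff(c(0L, ends))
  if (any(lens > 8L)) stop_corrupt("varint longer than 8 bytes")
  vi <- rep(seq_along(ends), lens)
  gi <- sequence(lens) - 1
  vals <- as.numeric(rowsum((b %% 128L) * 128^gi, vi))
  if (!is.null(expected_n) && length(vals) != expected_n) {
    stop_corrupt("varint block holds %d values, expected %d",
                 length(vals), expected_n)
  }
  vals
}

# Zigzag map so signed integers use small varints: 0,-1,1,-2,2 -> 0,1,2,3,4.
zigzag <- function(v) ifelse(v >= 0, 2 * v, -2 * v - 1)
unzigzag <- function(z) ifelse(z %% 2 == 0, z / 2, -(z + 1) / 2)

# ---- artifact construction --------------------------------------------------

# Canonical stream record; both the compressor and the deserializer build
# streams through this so that round-tripped artifacts compare identical().
new_artifact_stream <- function(label, level, rows, cols, step, counts,
                                values = NULL, chunk_n = 0L, k = 0L,
                                pad = 0L, s_max = 0, signed = FALSE,
                                vmin = 0, vmax = 0, hidden_q = raw(0),
                                W_dec = NULL) {
  if (!label %in% names(SBPN_LABELS)) stop_argument("unknown stream label '%s'", label)
  list(
    label = label,
    level = as.integer(level),
    rows = as.integer(rows),
    cols = as.integer(cols),
    step = as.numeric(step),
    counts = as.numeric(counts),
    values = if (is.null(values)) NULL else as.numeric(values),
    chunk_n = as.integer(chunk_n),
    k = as.integer(k),
    pad = as.integer(pad),
    s_max = as.numeric(s_max),
    signed = isTRUE(signed),
    vmin = as.numeric(vmin),
    vmax = as.numeric(vmax),
    hidden_q = as.raw(hidden_q),
    W_dec = if (is.null(W_dec)) NULL else float32_snap(W_dec)
  )
}

new_artifact <- function(mode, dim, levels, wavelet, streams,
                         version = SBPN_VERSION) {
  if (!mode %in% names(SBPN_MODES)) stop_argument("unknown mode '%s'", mode)
  if (!wavelet %in% names(SBPN_WAVELETS)) stop_argument("unknown wavelet '%s'", wavelet)
  structure(
    list(
      version = as.integer(version),
      mode = mode,
      dim = as.integer(dim),
      levels = as.integer(levels),
      wavelet = wavelet,
      streams = streams
    ),
    class = "sbpn_artifact"
  )
}

#' @export
print.sbpn_artifact <- function(x, ...) {
  cat(sprintf("<sbpn_artifact> mode=%s %dx%d levels=%d wavelet=%s streams=%d (%d bytes)\n",
              x$mode, x$dim[1], x$dim[2], x$levels, x$wavelet,
              length(x$streams), length(serialize_artifact(x))))
  invisible(x)
}

# ---- serialization ----------------------------------------------------------

#' Serialize a compressed artifact to bytes
#'
#' The returned raw vector is the `.sbpn` container; its length is the
#' compressed size used by all compression-ratio metrics. Serialization is
#' deterministic (no timestamps or padding) and
#' `deserialize_artifact(serialize_artifact(a))` is structurally identical
#' to `a`.
#'
#' @param a An artifact produced by [compress()] or [deserialize_artifact()].
#' @return A raw vector.
#' @export
serialize_artifact <- function(a) {
  if (!inherits(a, "sbpn_artifact")) stop_argument("not an sbpn_artifact")
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con), add = TRUE)
  w_u8 <- function(x) writeBin(as.raw(x), con)
  w_u16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_u32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_f64 <- function(x) writeBin(as.numeric(x), con, size = 8L, endian = "little")

  writeBin(SBPN_MAGIC, con)
  w_u8(a$version)
  w_u8(SBPN_MODES[[a$mode]])
  w_u32(a$dim[1]); w_u32(a$dim[2])
  w_u8(a$levels)
  w_u8(SBPN_WAVELETS[[a$wavelet]])
  w_u16(length(a$streams))

  for (s in a$streams) {
    counts_b <- varint_encode(s$counts)
    values_b <- if (is.null(s$values)) raw(0) else varint_encode(zigzag(s$values))
    wdec_b <- if (is.null(s$W_dec)) raw(0) else
      writeBin(as.numeric(s$W_dec), raw(), size = 4L, endian = "little")
    w_u8(SBPN_LABELS[[s$label]])
    w_u8(s$level)
    w_u32(s$rows); w_u32(s$cols)
    w_f64(s$step); w_f64(s$s_max)
    w_u8(as.integer(s$signed))
    w_f64(s$vmin); w_f64(s$vmax)
    w_u16(s$chunk_n); w_u16(s$k); w_u16(s$pad)
    w_u32(length(s$counts))
    w_u32(length(counts_b)); w_u32(length(values_b))
    w_u32(length(s$hidden_q)); w_u32(length(wdec_b))
    writeBin(counts_b, con)
    writeBin(values_b, con)
    writeBin(s$hidden_q, con)
    writeBin(wdec_b, con)
  }
  rawConnectionValue(con)
}

#' Deserialize a compressed artifact from bytes
#'
#' @param b Raw vector holding an `.sbpn` container.
#' @return An `sbpn_artifact`.
#' @export
deserialize_artifact <- function(b) {
  if (!is.raw(b)) stop_argument("expected a raw vector")
  pos <- 0L
  need <- function(nb, what) {
    if (nb == 0L) return(raw(0))
    if (pos + nb > length(b)) {
      stop_corrupt("corrupt container: truncated while reading %s at byte offset %d (need %d, have %d)",
                   what, pos, nb, length(b) - pos)
    }
    chunk <- b[(pos + 1L):(pos + nb)]
    pos <<- pos + nb
    chunk
  }
  r_u8 <- function(what) as.integer(need(1L, what))
  r_u16 <- function(what) readBin(need(2L, what), "integer", size = 2L,
                                  signed = FALSE, endian = "little")
  r_u32 <- function(what) readBin(need(4L, what), "integer", size = 4L,
                                  endian = "little")
  r_f64 <- function(what) readBin(need(8L, what), "numeric", size = 8L,
                                  endian = "little")

  magic <- need(4L, "magic")
  if (!identical(magic, SBPN_MAGIC)) {
    stop_corrupt("corrupt container: bad magic bytes at offset 0")
  }
  version <- r_u8("version")
  if (version != SBPN_VERSION) {
    stop_corrupt("unsupported container version %d at byte offset 4", version)
  }
  mode_i <- r_u8("mode")
  if (!mode_i %in% SBPN_MODES) stop_corrupt("unknown mode tag %d at byte offset 5", mode_i)
  mode <- names(SBPN_MODES)[match(mode_i, SBPN_MODES)]
  m <- r_u32("rows"); n <- r_u32("cols")
  levels <- r_u8("levels")
  wav_i <- r_u8("wavelet")
  if (!wav_i %in% SBPN_WAVELETS) stop_corrupt("unknown wavelet tag %d", wav_i)
  wavelet <- names(SBPN_WAVELETS)[match(wav_i, SBPN_WAVELETS)]
  n_streams <- r_u16("stream count")

  streams <- vector("list", n_streams)
  for (i in seq_len(n_streams)) {
    label_i <- r_u8("stream label")
    if (!label_i %in% SBPN_LABELS) stop_corrupt("unknown stream label %d at byte offset %d", label_i, pos - 1L)
    label <- names(SBPN_LABELS)[match(label_i, SBPN_LABELS)]
    level <- r_u8("stream level")
    rows <- r_u32("stream rows"); cols <- r_u32("stream cols")
    step <- r_f64("quantizer step"); s_max <- r_f64("scale")
    signed <- r_u8("signed flag") != 0L
    vmin <- r_f64("vmin"); vmax <- r_f64("vmax")
    chunk_n <- r_u16("chunk length"); k <- r_u16("hidden size")
    pad <- r_u16("pad count")
    n_pairs <- r_u32("pair count")
    counts_len <- r_u32("counts length")
    values_len <- r_u32("values length")
    hidden_len <- r_u32("hidden length")
    wdec_len <- r_u32("weights length")
    counts <- varint_decode(need(counts_len, "run counts"), expected_n = n_pairs)
    values <- if (values_len > 0L) {
      unzigzag(varint_decode(need(values_len, "run values"), expected_n = n_pairs))
    } else NULL
    hidden_q <- need(hidden_len, "hidden codes")
    W_dec <- NULL
    if (wdec_len > 0L) {
      if (wdec_len != 4L * chunk_n * k) {
        stop_corrupt("decode-weight block length %d inconsistent with n=%d, k=%d",
                     wdec_len, chunk_n, k)
      }
      W_dec <- matrix(readBin(need(wdec_len, "decode weights"), "numeric",
                              n = chunk_n * k, size = 4L, endian = "little"),
                      nrow = chunk_n, ncol = k)
    }
    streams[[i]] <- new_artifact_stream(
      label = label, level = level, rows = rows, cols = cols, step = step,
      counts = counts, values = values, chunk_n = chunk_n, k = k, pad = pad,
      s_max = s_max, signed = signed, vmin = vmin, vmax = vmax,
      hidden_q = hidden_q, W_dec = W_dec
    )
  }
  if (pos != length(b)) {
    stop_corrupt("corrupt container: %d trailing bytes after byte offset %d",
                 length(b) - pos, pos)
  }
  new_artifact(mode, c(m, n), levels, wavelet, streams, version = version)
}

#' Write / read an artifact to a file
#'
#' Thin convenience wrappers over [serialize_artifact()] and
#' [deserialize_artifact()].
#'
#' @param a An `sbpn_artifact`.
#' @param path File path (conventionally `.sbpn`).
#' @return `write_artifact` returns `path` invisibly; `read_artifact`
#'   returns the artifact.
#' @export
write_artifact <- function(a, path) {
  writeBin(serialize_artifact(a), path)
  invisible(path)
}

#' @rdname write_artifact
#' @export
read_artifact <- function(path) {
  if (!file.exists(path)) stop_io("cannot read artifact: no such file '%s'", path)
  deserialize_artifact(readBin(path, "raw", n = file.size(path)))
}
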