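# Rate/distortion/time evaluation harness.

#' Peak signal-to-noise ratio between two 8-bit images
#'
#' `10 * log10(255^2 / MSE)` in decibels; `Inf` when the images are
#' identical. The peak is fixed at 255 because the whole pipeline is 8-bit.
#'
#' @param a,b [gray_image]s (or integer matrices) of equal dimensions.
#' @return PSNR in dB (possibly `Inf`).
#' @examples
#' x <- gray_image(matrix(100L, 4, 4))
#' psnr(x, gray_image(matrix(116L, 4, 4)))  # 10*log10(255^2/256) ~ 24.05
#' @export
psnr <- function(a, b) {
  a <- if (inherits(a, "gray_image")) as_gray_matrix(a) else as.matrix(a)
  b <- if (inherits(b, "gray_image")) as_gray_matrix(b) else as.matrix(b)
  if (!all(dim(a) == dim(b))) {
    stop_argument("images must have equal dims (%dx%d vs %dx%d)",
                  nrow(a), ncol(a), nrow(b), ncol(b))
  }
  mse <- mean((as.numeric(a) - as.numeric(b))^2)
  if (mse == 0) return(Inf)
  10 * log10(255^2 / mse)
}

#' Compression ratio
#'
#' Original byte count divided by compressed byte count; values above 1
#' mean the artifact is smaller than the source.
#'
#' @param original_bytes,compressed_bytes Positive byte counts.
#' @return The dimensionless ratio.
#' @export
compression_ratio <- function(original_bytes, compressed_bytes) {
  if (!is.numeric(original_bytes) || !is.numeric(compressed_bytes) ||
      any(original_bytes <= 0) || any(compressed_bytes <= 0)) {
    stop_argument("byte counts must be positive")
  }
  original_bytes / compressed_bytes
}

#' Built-in codec plug-ins for the evaluation suite
#'
#' A suite codec is a list with a `name` and two functions:
#' `compress(img) -> raw` and `decompress(raw) -> gray_image`. This
#' constructor wraps the package's own codec for a given configuration;
#' external baselines (e.g. a JPEG2000 implementation) can be benchmarked
#' by supplying the same interface.
#'
#' @param cfg A [codec_config()].
#' @param name Codec label in the results (defaults to the mode).
#' @return A suite codec list.
#' @export
suite_codec <- function(cfg, name = cfg$mode) {
  list(
    name = name,
    compress = function(img) serialize_artifact(compress(img, cfg)),
    decompress = function(bytes) decompress(deserialize_artifact(bytes))
  )
}

#' Run a codec comparison suite
#'
#' One record per (image, codec): original and compressed bytes,
#' compression ratio, PSNR, and wall-clock encode/decode times. Original
#' size is the raw 8-bit pixel count (`m * n` bytes). A codec failure on a
#' sample is recorded (`status` column) and the suite continues. Timing
#' fields are hardware-dependent and excluded from every correctness
#' contract.
#'
#' @param images List of [gray_image]s (named or not).
#' @param codecs List of suite codecs (see [suite_codec()]).
#' @return A data frame of metric records (class `sbpn_metrics`).
#' @export
run_suite <- function(images, codecs) {
  if (length(images) < 1L || length(codecs) < 1L) {
    stop_argument("need at least one image and one codec")
  }
  sample_ids <- names(images) %||% NULL
  if (is.null(sample_ids) || any(sample_ids == "")) {
    sample_ids <- sprintf("Q%d", seq_along(images))
  }
  rows <- list()
  for (i in seq_along(images)) {
    img <- images[[i]]
    orig <- prod(dim(img))
    for (cd in codecs) {
      rec <- tryCatch({
        t0 <- proc.time()[["elapsed"]]
        bytes <- cd$compress(img)
        t1 <- proc.time()[["elapsed"]]
        out <- cd$decompress(bytes)
        t2 <- proc.time()[["elapsed"]]
        data.frame(
          sample = sample_ids[i], codec = cd$name,
          original_bytes = orig, compressed_bytes = length(bytes),
          ratio = compression_ratio(orig, length(bytes)),
          psnr = psnr(img, out),
          encode_ms = (t1 - t0) * 1000, decode_ms = (t2 - t1) * 1000,
          status = "ok", stringsAsFactors = FALSE
        )
      }, error = function(e) {
        data.frame(
          sample = sample_ids[i], codec = cd$name,
          original_bytes = orig, compressed_bytes = NA_real_,
          ratio = NA_real_, psnr = NA_real_,
          encode_ms = NA_real_, decode_ms = NA_real_,
          status = paste("failed:", conditionMessage(e)),
          stringsAsFactors = FALSE
        )
      })
      rows[[length(rows) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sbpn_metrics", class(out))
  out
}

#' Per-metric comparison table
#'
#' Reshapes suite records into one samples-by-codecs table per metric
#' (compression ratio, PSNR, encode/decode time), mirroring the usual
#' side-by-side comparison layout.
#'
#' @param records Output of [run_suite()].
#' @param metric One of `"ratio"`, `"psnr"`, `"encode_ms"`, `"decode_ms"`.
#' @return A data frame, samples as rows and codecs as columns.
#' @export
metrics_table <- function(records, metric = c("ratio", "psnr", "encode_ms",
                                              "decode_ms")) {
  metric <- match.arg(metric)
  samples <- unique(records$sample)
  codecs <- unique(records$codec)
  tab <- sapply(codecs, function(cd) {
    sapply(samples, function(sm) {
      v <- records[records$sample == sm & records$codec == cd, metric]
      if (length(v)) v[1] else NA_real_
    })
  })
  tab <- matrix(tab, nrow = length(samples), ncol = length(codecs),
                dimnames = list(samples, codecs))
  as.data.frame(tab)
}

#' Export suite records as CSV
#'
#' @param records Output of [run_suite()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}
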