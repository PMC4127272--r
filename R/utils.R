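# Internal helpers shared across the codec.

# Classed conditions so callers can distinguish bad arguments from corrupt
# streams or I/O failures.
sbpn_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "sbpn_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_argument <- function(fmt, ...) sbpn_stop("sbpn_argument_error", fmt, ...)
stop_corrupt  <- function(fmt, ...) sbpn_stop("sbpn_corrupt_error", fmt, ...)
stop_io       <- function(fmt, ...) sbpn_stop("sbpn_io_error", fmt, ...)
stop_shape    <- function(fmt, ...) sbpn_stop("sbpn_shape_error", fmt, ...)
stop_training <- function(fmt, ...) sbpn_stop("sbpn_training_error", fmt, ...)

# Run `code` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Round to nearest integer, ties away from zero (sign-symmetric, unlike R's
# banker's rounding).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Snap doubles through IEEE single precision; container weights are stored
# as 32-bit floats and in-memory artifacts must equal their round trip.
float32_snap <- function(x) {
  d <- dim(x)
  y <- readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
               "numeric", n = length(x), size = 4L, endian = "little")
  dim(y) <- d
  y
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == floor(x) && x >= 1
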