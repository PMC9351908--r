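# small shared helpers, internal only

`%||%` <- function(a, b) if (is.null(a)) b else a

rms <- function(x) sqrt(mean(x^2))

#' Centered moving average with symmetric edge padding
#' @noRd
moving_average <- function(x, k) {
  k <- as.integer(k)
  if (k <= 1L) return(x)
  if (k %% 2L == 0L) k <- k + 1L  # force odd so the window is centered
  n <- length(x)
  pad <- k %/% 2L
  if (pad >= n) stop("moving-average window longer than signal")
  xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  cs <- c(0, cumsum(xp))
  (cs[(k + 1L):(k + n)] - cs[seq_len(n)]) / k
}

# canonical lead label: upper case, whitespace stripped ("v1 " -> "V1")
canonical_lead <- function(x) toupper(gsub("\\s", "", as.character(x)))

# run code with a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# derive a child seed from a parent seed and an index, staying in 32-bit range
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1103L + 7919 * as.double(k)) %% 2147483629)
}

stop_fw <- function(code, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(code, "fibwave_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}
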