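# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. `seed = NULL` leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-stream child seed from a master seed, kept within 32-bit range.
child_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 48271 + as.numeric(i) * 16807) %% 2147483629
}

abort_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

# Quartiles by linear interpolation between order statistics (stats type 7),
# the convention used everywhere a quartile or IQR is reported.
quartiles <- function(x) {
  stats::quantile(x, probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
}

iqr_of <- function(x) {
  q <- quartiles(x)
  q[3] - q[1]
}

# Moving maximum over a centered-ish window using the two-pass block
# cummax trick (van Herk); O(n), no loops over window width.
moving_max <- function(x, w) {
  n <- length(x)
  if (w <= 1L) return(x)
  if (w >= n) return(rep(max(x), n))
  nblk <- ceiling(n / w)
  pad <- nblk * w - n
  xp <- c(x, rep(-Inf, pad))
  m <- matrix(xp, nrow = w)
  fwd <- apply(m, 2, cummax)
  bwd <- apply(m[w:1, , drop = FALSE], 2, cummax)[w:1, , drop = FALSE]
  fwd <- as.vector(fwd); bwd <- as.vector(bwd)
  # window covering positions i..i+w-1
  out <- pmax(bwd[seq_len(n - w + 1L)], fwd[seq(w, n)])
  out
}

# Moving range (max - min) over windows of length w; returns n - w + 1 values,
# value j summarising samples j..j+w-1.
moving_range <- function(x, w) {
  moving_max(x, w) + moving_max(-x, w)
}
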