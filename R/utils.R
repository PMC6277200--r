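# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

vec_norm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# fold an undirected-axis angle into [0, 90] degrees
fold_angle <- function(deg) {
  deg <- abs(deg) %% 180
  ifelse(deg > 90, 180 - deg, deg)
}

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name))
  invisible(x)
}

as_point3 <- function(p, name = "point") {
  p <- as.numeric(p)
  if (length(p) != 3L || any(!is.finite(p)))
    stop(sprintf("'%s' must be a finite numeric vector of length 3", name))
  p
}

# centered moving average with window shrinking at the edges, so the smoothed
# series has the same length and spans the same time range as the input
moving_average <- function(x, window) {
  n <- length(x)
  window <- as.integer(window)
  if (window < 1L) stop("smoothing window must be >= 1")
  if (window > n) stop("smoothing window larger than series")
  if (window == 1L) return(x)
  half <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}
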