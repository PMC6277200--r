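# shared fixtures: small synthetic configurations built in code

small_config <- function(seed = 7L, ...) {
  sim_config(rng_seed = seed, n_cells = 60L, n_frames = 20L, ...)
}

# ring table (one event) -> time/area series
ring_series <- function(rings) {
  fr <- split(rings, rings$frame)
  areas <- vapply(fr, function(s)
    ring_area(as.matrix(s[order(s$vertex_index), c("x_um", "y_um", "z_um")])),
    numeric(1L))
  t_min <- vapply(fr, function(s) s$t_min[1L], numeric(1L))
  o <- order(t_min)
  list(t_min = unname(t_min[o]), area = unname(areas[o]))
}

# independent fan-triangulation oracle (direct re-summation)
fan_area_oracle <- function(v) {
  ctr <- colMeans(v)
  tot <- 0
  n <- nrow(v)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- v[i, ] - ctr
    b <- v[j, ] - ctr
    cr <- c(a[2] * b[3] - a[3] * b[2],
            a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
    tot <- tot + sqrt(sum(cr^2)) / 2
  }
  tot
}

# a regular n-gon of circumradius rho in the z = 0 plane
regular_polygon <- function(n, rho, phase = 0) {
  ang <- phase + 2 * pi * (seq_len(n) - 1L) / n
  cbind(rho * cos(ang), rho * sin(ang), 0)
}

rigid_motion <- function() {
  # random rotation (QR of a Gaussian matrix) + translation
  qr_m <- qr(matrix(rnorm(9), 3, 3))
  rot <- qr.Q(qr_m)
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  list(rot = rot, shift = rnorm(3, 0, 20))
}

apply_motion <- function(points, m) {
  sweep(points %*% t(m$rot), 2, -m$shift)
}
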