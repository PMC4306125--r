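# Shared fixtures: tiny phantoms are regenerated on the fly (cheap,
# deterministic) instead of being stored as binary fixtures.

small_phantom <- function(seed = 1, ...) {
  phantom_generate(phantom_spec(size = 64, r_endo = 10, r_epi = 18,
                                frames = 8, seed = seed, ...))
}

# central-difference gradient-magnitude edge map (x along columns)
edge_map_of <- function(img) {
  sh <- function(m, dr, dc) {
    ri <- pmin(pmax(seq_len(nrow(m)) + dr, 1L), nrow(m))
    ci <- pmin(pmax(seq_len(ncol(m)) + dc, 1L), ncol(m))
    m[ri, ci, drop = FALSE]
  }
  fx <- (sh(img, 0, 1) - sh(img, 0, -1)) / 2
  fy <- (sh(img, 1, 0) - sh(img, -1, 0)) / 2
  sqrt(fx^2 + fy^2)
}

# circle contour sampled at n points (y-down pixel coordinates)
circle_points <- function(r, center = c(0, 0), n = 64L, phase = 0) {
  th <- phase + seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}
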