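# programmatic fixtures shared across test files

# straight axial tube through a volume, by exact capsule rasterization
make_tube <- function(shape = c(32L, 33L, 33L), radius = 3,
                      center = c(17, 17)) {
  v <- array(FALSE, shape)
  rasterize_capsule(v, c(1, center[1], center[2]),
                    c(shape[1], center[1], center[2]), radius)
}

# small, fast phantom + degradation configs used by several suites
small_phantom_cfg <- function() phantom_config(shape = c(16L, 32L, 32L), n_vessels = 2L)

# a frame that is pure line-wise stripes over a uniform background plus a
# faint blurred vessel band
stripe_frame <- function(ny = 48L, nx = 48L, amplitude = 0.3, period = 8,
                         background = 0.1, vessel = NULL) {
  s <- amplitude * sin(2 * pi * seq_len(ny) / period)
  fr <- matrix(background, ny, nx) + matrix(s, ny, nx)
  if (!is.null(vessel)) fr <- fr + vessel
  pmax(fr, 0)
}
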