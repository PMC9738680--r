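# Shared fixtures, built once per test run. Small frame sizes keep the suite
# fast; the printed output-size constants (100/400/64) do not depend on the
# input resolution and are asserted explicitly where they matter.

fixture_env <- new.env()

# a clean, static clip: no jitter, no noise, strong pulse
static_clip <- function() {
  if (is.null(fixture_env$static)) {
    fixture_env$static <- generate_clip(scene_config(
      width = 160, height = 120, fps = 30, duration = 3, heart_rate = 72,
      pulse_amplitude = 0.05, noise_sigma = 0, jitter_step = 0, seed = 7))
  }
  fixture_env$static
}

# small extractor config used when output-size constants are not under test
small_extractor <- function(...) {
  extractor_config(eye_out = 20, mouth_out = 40, distortion_strength = 0, ...)
}

# numeric gradient of scalar function f at array p
num_grad <- function(f, p, eps = 1e-6) {
  g <- array(0, dim(p) %||% length(p))
  for (i in seq_along(p)) {
    p1 <- p; p1[i] <- p1[i] + eps
    p2 <- p; p2[i] <- p2[i] - eps
    g[i] <- (f(p1) - f(p2)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
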