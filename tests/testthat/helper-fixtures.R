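# Shared fixtures, generated in code at test time.

# A small, fast phantom: modest volume, 1 mm spacing.
tiny_phantom <- function(archetype = "solid_isolated", seed = 42, ...) {
  generate_phantom(phantom_spec(archetype = archetype, seed = seed, ...))
}

# A reduced-width model configuration for fast network tests.
tiny_model_config <- function(preset = NULL, base_channels = 2L, ...) {
  model_config(preset = preset, base_channels = base_channels, ...)
}

# Random binary mask pair of a given shape.
random_mask <- function(shape, p = 0.3) {
  array(rbinom(prod(shape), 1, p), dim = shape)
}

# Finite-difference gradient of a scalar-valued function at x[idx].
numeric_grad <- function(f, x, idx, eps = 1e-6) {
  xp <- x; xp[idx] <- xp[idx] + eps
  xm <- x; xm[idx] <- xm[idx] - eps
  (f(xp) - f(xm)) / (2 * eps)
}
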