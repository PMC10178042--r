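# shared fixtures: built in code at test time, never stored on disk

sphere <- function(x) sum(x^2)

# small, fast synthetic population for pipeline-level tests
tiny_config <- function(seed = 1L, ...) {
  spectra_config(n_per_class = 12L, n_channels = 30L, seed = seed, ...)
}

# noiseless, scatter-free variant: rows within a class are identical
noiseless_config <- function(seed = 1L, ...) {
  spectra_config(n_per_class = 4L, n_channels = 60L, noise_sd = 0,
                 scatter_slope_range = c(1, 1),
                 scatter_offset_range = c(0, 0), seed = seed, ...)
}

# smooth non-constant reference spectrum for MSC tests
msc_ref_curve <- function(n = 50) 0.5 + 0.3 * sin(seq(0, 2 * pi, length.out = n))
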