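# Fixture builders used across test files. Everything is generated in code;
# nothing is stored on disk.

# image whose intensity equals the 0-based row index (a vertical ramp)
make_row_ramp <- function(nr = 20, nc = 10) {
  gray_image(matrix(0:(nr - 1), nr, nc), bit_depth = 32L)
}

# image whose intensity equals the 0-based column index
make_col_ramp <- function(nr = 10, nc = 20) {
  gray_image(matrix(0:(nc - 1), nr, nc, byrow = TRUE), bit_depth = 32L)
}

make_constant <- function(value = 7, nr = 12, nc = 12, bit_depth = 32L) {
  gray_image(matrix(value, nr, nc), bit_depth = bit_depth)
}

# a slope_result with just the fields aggregation needs
fake_line <- function(raw, norm, valid = TRUE) {
  structure(list(raw_slope = raw, normalized_slope = norm, valid = valid),
            class = "slope_result")
}

# small, fast phantom geometry for unit tests (full-size runs live in the
# acceptance suite)
small_geometry <- list(nrow = 200L, ncol = 180L, thickness = 120,
                       wave_amp = 5, wave_len = 120)

small_phantom_spec <- function(...) {
  args <- utils::modifyList(small_geometry, list(...))
  do.call(phantom_spec, args)
}

small_cohort <- function(preset, n_samples, base_seed, extra = list(), ...) {
  generate_cohort(preset, n_samples = n_samples, base_seed = base_seed,
                  spec_overrides = utils::modifyList(small_geometry, extra),
                  ...)
}
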