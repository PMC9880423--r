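# Shared fixtures built in code.  Everything is deterministic under the
# seeds written here.

# one rendered scene per magnification group, cached for the session
fixture_scene <- local({
  cache <- list()
  function(seed = 7L, group = 1L) {
    key <- paste(seed, group)
    if (is.null(cache[[key]])) {
      sp <- generate_plant_spec(seed, c(1L, 12L), group)
      cache[[key]] <<- render_scene(sp)
    }
    cache[[key]]
  }
})

# a small pool of random pooled-resolution inputs for the tiny backbone
# (image content is irrelevant for contract tests; 56 x 56 x 3 columns)
fixture_pixel_matrix <- function(n, seed = 1L) {
  withr::with_seed(seed, matrix(runif(3 * 56 * 56 * n), ncol = n))
}

expect_white <- function(px) expect_equal(unname(px), c(1, 1, 1))
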