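# Shared synthetic bundles, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, maker) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- maker()
  .fixture_cache[[key]]
}

# Default planted study (the generator's stated study conditions).
default_bundle <- function() {
  cached_fixture("default", function() {
    generate_dataset(sim_config(seed = 7),
                     dir = file.path(tempdir(), "itb_fix_default"))
  })
}

# Noiseless configuration for exact end-to-end recovery.
noiseless_bundle <- function() {
  cached_fixture("noiseless", function() {
    generate_dataset(noiseless_config(seed = 3),
                     dir = file.path(tempdir(), "itb_fix_noiseless"))
  })
}

# Null bundle at the calibration scale (2 types x 200 nuclei, 2000 peaks).
null_bundle <- function() {
  cached_fixture("null", function() {
    generate_null(sim_config(n_celltypes = 2, celltypes = c("A", "B"),
                             n_nuclei_per_type = 200, n_peaks = 2000,
                             seed = 11),
                  dir = file.path(tempdir(), "itb_fix_null"))
  })
}

# Small hand-built count matrix: 3 peaks x 4 nuclei, two cell types.
toy_count_matrix <- function() {
  counts <- matrix(c(3, 0, 1,
                     0, 2, 1,
                     4, 0, 0,
                     1, 1, 2), nrow = 3)
  peaks <- peak_set(rep("chr1", 3), c(0, 1000, 2000), c(400, 1400, 2400),
                    c("pkA", "pkB", "pkC"))
  count_matrix(counts, peaks, paste0("bc", 1:4), c("T1", "T1", "T2", "T2"))
}
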