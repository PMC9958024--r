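# Shared coarse phantom (2 mm spacing) memoized across test files; unit
# tests that only need geometry reuse it instead of regenerating.
phantom_cache <- new.env(parent = emptyenv())

coarse_phantom <- function(noise = TRUE) {
  key <- if (noise) "noisy" else "clean"
  if (is.null(phantom_cache[[key]])) {
    spec <- phantom_spec(spacing = 2, noise_sd = if (noise) 20 else 0)
    phantom_cache[[key]] <- phantom_generate(spec)
  }
  phantom_cache[[key]]
}

coarse_mask <- function() {
  if (is.null(phantom_cache[["mask"]])) {
    phantom_cache[["mask"]] <- segment_skull(coarse_phantom()$volume)
  }
  phantom_cache[["mask"]]
}
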