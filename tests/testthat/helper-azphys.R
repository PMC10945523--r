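# shared fixtures for the suite; everything is generated in code

# small imaging scene used by several pipeline tests (kept modest so the
# default suite stays fast; the acceptance tests use larger scenes)
small_scene <- function(...) {
  image_scene_params(field_px = 512, n_terminals = 1,
                     n_small_terminals = 1, az_per_terminal = 8, ...)
}

# scene sized for the WT/KO recovery study: ~11 gated AZs per field
recovery_scene <- function(...) {
  image_scene_params(field_px = 512, n_terminals = 1,
                     n_small_terminals = 1, terminal_area_um2 = 5,
                     az_per_terminal = 12, ...)
}

# ground-truth nearest-neighbor distances of a rendered field
gt_nnd <- function(field) {
  tc <- field$ground_truth$clusters
  unlist(lapply(unique(tc$az_id), function(a) {
    f <- tc[tc$az_id == a & tc$channel == "cav", ]
    m <- tc[tc$az_id == a & tc$channel == "munc13", ]
    vapply(seq_len(nrow(f)), function(k)
      min(sqrt((m$x_nm - f$x_nm[k])^2 + (m$y_nm - f$y_nm[k])^2)), 0)
  }))
}

# one field rendered once and reused across read-only tests
shared_field <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- render_sted_field(small_scene(), "WT",
                                                    seed = 42)
    cache
  }
})

expect_rel <- function(x, target, tol) {
  expect_lt(abs(x - target) / abs(target), tol)
}
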