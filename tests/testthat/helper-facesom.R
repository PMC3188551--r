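# Shared fixtures, built in code.

# A toy configuration small enough for per-test training: 8x8 sheets,
# 64-pixel images, a 5x5 stimulus grid, and afferent counts feasible for
# the 67% convergence on an 8x8 torus.
toy_config <- function(n_identity = 5L, n_expression = 5L) {
  cfg <- default_config("desk")
  cfg$stimuli$size <- 64L
  cfg$stimuli$n_identity <- n_identity
  cfg$stimuli$n_expression <- n_expression
  cfg$training$epochs <- c(2L, 2L, 2L, 2L)
  for (l in 1:4) {
    cfg$layers[[l]]$dims <- c(8L, 8L)
    cfg$layers[[l]]$radius <- if (l == 1L) 6 else 2.5
    if (l > 1L) cfg$layers[[l]]$n_connections <- 12L
  }
  cfg$layers[[1L]]$n_connections <- 40L
  cfg$layers[[1L]]$freq_connections <-
    c("0.5" = 25L, "0.25" = 10L, "0.125" = 3L, "0.0625" = 2L)
  cfg
}

# retina codes for a toy stimulus list (memoised per session)
.toy_env <- new.env(parent = emptyenv())

toy_retina <- function(i, e, cfg = toy_config()) {
  key <- sprintf("rc_%d_%d_%d", i, e, cfg$stimuli$size)
  if (is.null(.toy_env[[key]])) {
    st <- cfg$stimuli
    img <- render_face(i, e, "complete", st$size, st$n_identity,
                       st$n_expression)
    .toy_env[[key]] <- apply_filterbank(img)
  }
  .toy_env[[key]]
}

expect_unit_norms <- function(syn, tol = 1e-9) {
  norms <- sqrt(rowSums(syn$w^2))
  expect_lt(max(abs(norms - 1)), tol)
}
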