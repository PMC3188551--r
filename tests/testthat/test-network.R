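test_that("connectivity matches the configured counts and frequency split", {
  cfg <- default_config("full")
  set.seed(11)
  syn <- sample_connectivity(cfg, 1)
  expect_identical(ncol(syn$idx), 272L)
  expect_unit_norms(syn, 1e-12)
  # afferents are distinct within each neuron
  expect_true(all(apply(syn$idx, 1, anyDuplicated) == 0L))
  # frequency-group counts 201/50/13/8 for every neuron
  sp <- filter_specs()
  px <- 128L * 128L
  for (neuron in c(1L, 500L, 1024L)) {
    ch <- (syn$idx[neuron, ] - 1L) %/% px + 1L
    counts <- table(factor(sp$frequency[ch], levels = c(0.5, 0.25, 0.125, 0.0625)))
    expect_identical(unname(c(counts)), c(201L, 50L, 13L, 8L))
  }
})

test_that("the stated radius captures ~67% of sampled afferents", {
  frac_within <- function(syn, cfg, l) {
    n <- cfg$layers[[l]]$dims[1]
    r <- cfg$layers[[l]]$radius
    if (l == 1L) {
      size <- cfg$stimuli$size
      mean(vapply(seq_len(n * n), function(i) {
        pr <- (i - 1) %% n + 1; pc <- (i - 1) %/% n + 1
        cy <- (pr - 0.5) * size / n + 0.5; cx <- (pc - 0.5) * size / n + 0.5
        pix <- (syn$idx[i, ] - 1) %% (size * size)
        py <- pix %% size + 1; px <- pix %/% size + 1
        mean((py - cy)^2 + (px - cx)^2 <= r^2)
      }, numeric(1)))
    } else {
      mean(vapply(seq_len(n * n), function(i) {
        pr <- (i - 1) %% n + 1; pc <- (i - 1) %/% n + 1
        qr <- (syn$idx[i, ] - 1) %% n + 1; qc <- (syn$idx[i, ] - 1) %/% n + 1
        dr <- pmin((qr - pr) %% n, (pr - qr) %% n)
        dc <- pmin((qc - pc) %% n, (pc - qc) %% n)
        mean(dr^2 + dc^2 <= r^2)
      }, numeric(1)))
    }
  }
  set.seed(21)
  for (preset in c("desk", "full")) {
    cfg <- default_config(preset)
    for (l in c(1L, 2L, 4L)) {
      syn <- sample_connectivity(cfg, l)
      expect_gt(frac_within(syn, cfg, l), 0.64)
      expect_lt(frac_within(syn, cfg, l), 0.70)
    }
  }
  cfg <- default_config("desk")
  cfg$layers[[2]]$radius <- -1
  expect_error(sample_connectivity(cfg, 2), "radius")
  cfg$layers[[2]]$radius <- 0.2   # too few candidate positions
  expect_error(sample_connectivity(cfg, 2), "infeasible|distinct")
})

test_that("activation equals the brute-force per-neuron sum", {
  set.seed(3)
  cfg <- toy_config()
  syn <- sample_connectivity(cfg, 2)
  y <- runif(64) * rbinom(64, 1, 0.3)
  h <- compute_activations(y, syn)
  h_loop <- vapply(seq_len(nrow(syn$idx)), function(i)
    sum(syn$w[i, ] * y[syn$idx[i, ]]), numeric(1))
  expect_equal(h, h_loop, tolerance = 1e-12)
  expect_identical(compute_activations(numeric(64), syn), numeric(64))
  # single active input: h_i = w_ij for every neuron containing j
  j <- syn$idx[5, 7]
  y1 <- numeric(64); y1[j] <- 1
  h1 <- compute_activations(y1, syn)
  expect_equal(h1[5], syn$w[5, 7])
  expect_error(compute_activations(numeric(10), syn), "shorter")
})

test_that("lateral filter matches direct kernel evaluation and Table values", {
  p1 <- default_config("full")$layers[[1]]$lateral
  k <- facesom:::.lateral_kernel(p1)
  h <- (nrow(k) - 1) / 2
  expect_equal(k[h + 1, h + 1], 5.35 - 1.5)
  expect_identical(max(abs(lateral_filter(matrix(0, 16, 16), p1))), 0)
  # impulse response on the torus equals the wrapped kernel
  n <- 16L
  imp <- matrix(0, n, n); imp[5, 9] <- 1
  got <- lateral_filter(imp, p1)
  want <- matrix(0, n, n)
  for (a in -h:h) for (b in -h:h)
    want[(5 - 1 + a) %% n + 1, (9 - 1 + b) %% n + 1] <-
      want[(5 - 1 + a) %% n + 1, (9 - 1 + b) %% n + 1] + k[a + h + 1, b + h + 1]
  expect_equal(got, want, tolerance = 1e-10)
  # clipped variant: impulse in the centre reproduces the kernel directly
  imp2 <- matrix(0, 33, 33); imp2[17, 17] <- 1
  got2 <- lateral_filter(imp2, p1, wrap = FALSE)
  expect_equal(got2[17 + (-h:h), 17 + (-h:h)], k, tolerance = 1e-10)
  expect_error(lateral_filter(imp, list(sigma_E = -1, delta_E = 1,
                                        sigma_I = 2, delta_I = 1)), "positive")
})

test_that("percentile sigmoid: midpoint, monotonicity, sparseness", {
  # the cell sitting exactly at the percentile point fires at 0.5
  r100 <- matrix(sample(100), 10, 10)
  y100 <- apply_sigmoid(r100, 95, beta = 190)
  expect_identical(y100[r100 == 95], 0.5)
  expect_identical(sum(y100 > 0.5), 5L)
  set.seed(9)
  r <- matrix(rnorm(1024), 32, 32)
  y <- apply_sigmoid(r, 95, beta = 190)
  expect_identical(dim(y), dim(r))
  expect_true(all(y >= 0 & y <= 1))
  frac <- mean(y > 0.5)
  expect_gte(frac, 0.04); expect_lte(frac, 0.06)
  # monotone in r, strictly so away from floating-point saturation
  o <- order(r)
  expect_true(all(diff(y[o]) >= 0))
  mid <- abs(y[o] - 0.5) < 0.499
  strict <- diff(r[o]) > 1e-12 & mid[-1] & mid[-length(mid)]
  expect_true(all(diff(y[o])[strict] > 0))
  expect_warning(apply_sigmoid(matrix(1, 4, 4), 95, 2), "degenerate")
  expect_error(apply_sigmoid(matrix(c(1, NA), 2, 2)), "finite")
})

test_that("hebbian update scales, normalises, and leaves silent neurons alone", {
  set.seed(4)
  cfg <- toy_config()
  syn <- sample_connectivity(cfg, 3)
  y_pre <- runif(64)
  y_post <- runif(64); y_post[c(2, 10)] <- 0
  before <- syn$w
  syn2 <- hebbian_update(y_pre, y_post, syn, rate = 0.1)
  expect_unit_norms(syn2)
  expect_equal(syn2$w[2, ], before[2, ])
  expect_equal(syn2$w[10, ], before[10, ])
  expect_error(hebbian_update(y_pre, y_post, syn, rate = -0.1), "non-negative")
  # 3-4-5 triangle: raw updated vector (3,4) normalises to (0.6, 0.8)
  toy <- list(idx = matrix(c(1L, 2L), 1), w = matrix(c(3, 4), 1), n_pre = 2L)
  out <- hebbian_update(c(0, 0), 0, toy, rate = 0.1)
  expect_equal(out$w, matrix(c(0.6, 0.8), 1))
})

test_that("models round-trip through save/load with a metadata sidecar", {
  cfg <- toy_config()
  model <- init_network(cfg, seed = 19)
  dir <- withr::local_tempdir()
  save_model(model, dir)
  expect_true(file.exists(file.path(dir, "model.json")))
  back <- load_model(dir)
  expect_identical(back, model)
  meta <- jsonlite::fromJSON(file.path(dir, "model.json"))
  expect_identical(meta$seed, 19L)
  expect_equal(meta$weight_sums,
               vapply(model$synapses, function(s) sum(s$w), numeric(1)))
})

test_that("forward pass is pure, bounded, and prefix-consistent", {
  cfg <- toy_config()
  model <- init_network(cfg, seed = 8)
  rc <- toy_retina(1, 1, cfg)
  a <- forward_pass(rc, model)
  b <- forward_pass(rc, model)
  expect_identical(a, b)
  for (l in 1:4) expect_true(all(a[[l]] >= 0 & a[[l]] <= 1))
  pre <- forward_pass(rc, model, up_to_layer = 3)
  expect_identical(a[1:3], pre)
  expect_error(forward_pass(numeric(10), model), "elements")
})
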