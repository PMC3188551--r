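test_that("cell classification follows the region-counting rule", {
  flat <- rep(0, 40)
  plateau <- function(at) { v <- rep(0, 40); v[at] <- 1; v }
  expect_identical(classify_cell(plateau(10:15), flat), "identity_selective")
  expect_identical(classify_cell(flat, plateau(3:9)), "expression_selective")
  expect_identical(classify_cell(plateau(1:4), plateau(30:40)), "dual")
  expect_identical(classify_cell(plateau(c(1:4, 20:24)), flat), "multi_region")
  expect_identical(classify_cell(flat, plateau(c(1:2, 39:40))), "multi_region")
  expect_identical(classify_cell(flat, flat), "unresponsive")
  # single supra-threshold bins are noise, not regions
  expect_identical(classify_cell(plateau(7), flat), "unresponsive")
  expect_error(classify_cell(rep(2, 40), flat))
})

test_that("preference labels follow the stronger isolated response", {
  curves <- structure(list(
    identity = rbind(c(0.9, 0, 0), c(0.2, 0.1, 0), c(0.4, 0.4, 0.4),
                     c(0.7, 0, 0)),
    expression = rbind(c(0.2, 0, 0), c(0.3, 0.9, 0), c(0.1, 0, 0),
                       c(0.7, 0, 0))), class = "tuning_curves")
  pm <- preference_map(curves, c(2, 2))
  expect_identical(as.vector(pm),
                   c("identity", "expression", "unresponsive", "dual"))
})

test_that("join-count statistic separates dispersion from clustering", {
  checker <- outer(1:8, 1:8, function(r, c) ifelse((r + c) %% 2 == 0, "a", "b"))
  set.seed(31)
  res <- clustering_statistic(checker, n_perm = 199)
  expect_identical(res$statistic, 0)
  expect_gt(res$p_value, 0.95)
  halves <- matrix(rep(c("a", "b"), each = 32), 8, 8)
  res2 <- clustering_statistic(halves, n_perm = 999)
  expect_gt(res2$statistic, 0.85)
  expect_lte(res2$p_value, 0.001)
  expect_warning(res3 <- clustering_statistic(matrix("a", 4, 4), 99),
                 "single-class")
  expect_identical(res3$p_value, 1)
})

test_that("permutation p-values are calibrated under random labels", {
  set.seed(77)
  ps <- replicate(120, {
    lab <- matrix(sample(c("a", "b"), 64, TRUE), 8, 8)
    clustering_statistic(lab, n_perm = 99)$p_value
  })
  # roughly uniform: no mass concentration at small p
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_lt(mean(ps < 0.1), 0.25)
})

test_that("complete-face testing fills the grid and mutates nothing", {
  cfg <- toy_config()
  model <- train_network(cfg, seed = 14)
  w_before <- lapply(model$synapses, `[[`, "w")
  rmat <- test_complete_faces(model)
  expect_identical(dim(rmat), c(64L, 5L, 5L))
  expect_true(all(rmat >= 0 & rmat <= 1))
  # one entry recomputed by a standalone forward pass
  rc <- toy_retina(4, 2, cfg)
  y <- forward_pass(rc, model)[["layer4"]]
  expect_equal(rmat[, 4, 2], as.vector(y), tolerance = 1e-12)
  curves <- test_isolated_spaces(model)
  expect_identical(dim(curves$identity), c(64L, 5L))
  expect_identical(lapply(model$synapses, `[[`, "w"), w_before)
  # purity: repeat run identical
  expect_identical(curves, test_isolated_spaces(model))
})

test_that("a cell wired to the nose region responds to identity only", {
  # constructed-weights oracle: layer-1 neurons receive weight only from
  # high-frequency channels over the nose band, which identity-only images
  # drive and expression-only images cannot reach
  cfg <- toy_config()
  model <- init_network(cfg, seed = 22)
  syn <- model$synapses[[1]]
  size <- cfg$stimuli$size
  px <- size * size
  sp <- filter_specs()
  pix <- (syn$idx - 1L) %% px
  row <- pix %% size + 1L
  ch <- (syn$idx - 1L) %/% px + 1L
  # nose band at size 64 is rows 33..44; stay >= 4 rows (the f = 0.5 kernel
  # reach) away from the nearest expression feature (mouth top ~44.7)
  hot <- sp$frequency[ch] == 0.5 & row >= 35 & row <= 39
  w <- ifelse(hot, 1, 0)
  nrm <- sqrt(rowSums(w^2))
  syn$w <- w / ifelse(nrm > 0, nrm, 1)   # cells with no nose afferent stay silent
  model$synapses[[1]] <- syn
  st <- cfg$stimuli
  layer1_curve <- function(mode, n) vapply(seq_len(n), function(k) {
    img <- if (mode == "identity_only")
      render_face(k, 1, mode, st$size, st$n_identity, st$n_expression)
    else render_face(1, k, mode, st$size, st$n_identity, st$n_expression)
    max(forward_pass(apply_filterbank(img), model, 1)[[1]])
  }, numeric(1))
  suppressWarnings({
    idc <- layer1_curve("identity_only", st$n_identity)
    exc <- layer1_curve("expression_only", st$n_expression)
  })
  expect_true(any(idc > 0.5))
  expect_true(all(exc <= 0.5))
})
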