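test_that("quantisation produces contiguous blocks with declared centrals", {
  q <- quantise_space(40, 5)
  expect_identical(q$block_size, 8L)
  expect_identical(q$blocks[[1]], 1L:8L)
  expect_identical(q$central, c(4L, 12L, 20L, 28L, 36L))
  expect_equal(log2(q$n_blocks), 2.3219, tolerance = 1e-4)
  # degenerate: every transform its own block
  q40 <- quantise_space(40, 40)
  expect_identical(q40$block_size, 1L)
  expect_identical(q40$central, 1:40)
  # blocks disjoint and covering for every divisor of 40
  for (nb in c(1, 2, 4, 5, 8, 10, 20, 40)) {
    qq <- quantise_space(40, nb)
    expect_identical(sort(unlist(qq$blocks)), 1:40)
    expect_identical(anyDuplicated(unlist(qq$blocks)), 0L)
  }
  expect_error(quantise_space(40, 7), "divide")
})

test_that("response tables are shaped (cell, stimulus, transform)", {
  q <- quantise_space(40, 5)
  resp <- matrix(runif(3 * 200), 3, 200)
  tab <- build_response_table(resp, q)
  expect_identical(dim(tab), c(3L, 5L, 40L))
  expect_identical(length(tab[1, , ]), 200L)
  # column (s-1)*40 + t maps to [cell, s, t]
  expect_identical(tab[2, 3, 17], as.integer(ceiling(resp[2, 2 * 40 + 17] * 2)))
  expect_error(build_response_table(resp * 2, q), "\\[0, 1\\]")
  # constant cell occupies a single bin
  tabc <- build_response_table(matrix(0.2, 1, 200), q)
  expect_identical(unique(as.vector(tabc)), 1L)
})

test_that("a perfectly selective binary cell attains log2(5) bits", {
  q <- quantise_space(40, 5)
  resp <- matrix(0, 1, 200)
  resp[1, (3 - 1) * 40 + 1:40] <- 1    # fires for all transforms of stimulus 3
  tab <- build_response_table(resp, q)
  expect_equal(stimulus_specific_information(tab, 1, 3), log2(5),
               tolerance = 1e-12)
  expect_equal(single_cell_information(tab, 1), log2(5), tolerance = 1e-12)
  # responses independent of the stimulus carry zero information
  const <- build_response_table(matrix(1, 1, 200), q)
  expect_identical(single_cell_information(const, 1), 0)
})

test_that("information matches a brute-force oracle on random tables", {
  # independent oracle: direct expansion of the definition from raw counts
  oracle <- function(r_by_s) {
    all_r <- unlist(r_by_s)
    vals <- sort(unique(all_r))
    p_r <- vapply(vals, function(v) mean(all_r == v), numeric(1))
    vapply(r_by_s, function(rs) {
      p_rs <- vapply(vals, function(v) mean(rs == v), numeric(1))
      sum(ifelse(p_rs > 0, p_rs * log2(p_rs / p_r), 0))
    }, numeric(1))
  }
  set.seed(123)
  q <- quantise_space(8, 4)   # 4 stimuli x 8 transforms keeps the oracle cheap
  for (rep in 1:1000) {
    n_bins <- sample(2:4, 1)
    resp <- matrix(runif(32), 1, 32)
    tab <- build_response_table(resp, q, n_bins = n_bins)
    r_by_s <- lapply(1:4, function(s) tab[1, s, ])
    want <- oracle(r_by_s)
    got <- vapply(1:4, function(s)
      stimulus_specific_information(tab, 1, s), numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(single_cell_information(tab, 1), max(want),
                 tolerance = 1e-12)
    expect_true(all(got >= -1e-15 & got <= log2(4) + 1e-9))
  }
})

test_that("ranked profile is a sorted permutation bounded by the ceiling", {
  cfg <- toy_config()
  model <- init_network(cfg, seed = 15)
  # toy grid is 5x5: quantise into 5 singleton-ish blocks
  prof <- ranked_information_profile(model, "identity")
  expect_length(prof$information, 64L)
  expect_true(all(diff(prof$information) <= 0))
  expect_true(all(prof$information >= 0 &
                  prof$information <= prof$ceiling + 1e-9))
  expect_identical(sort(prof$order), 1:64)
  # profile is reproducible
  prof2 <- ranked_information_profile(model, "identity")
  expect_identical(prof$information, prof2$information)
})
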