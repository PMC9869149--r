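test_that("the activation-count rule rounds as specified", {
  expect_equal(sdm_activation_count(125, 1000, "A1"), 2L)
  expect_equal(sdm_activation_count(2000, 1000, "A1"), 13L)  # 2000/(4e6)^(1/3) = 12.6
  expect_equal(sdm_activation_count(368, 1000, "A2"), 5L)    # 4.08 -> nearest odd
  expect_equal(sdm_activation_count(97, 1000, "A2"), 1L)     # 1.68 -> nearest odd
  expect_equal(sdm_activation_count(31, 1000, "A4"), 1L)     # 0.78 -> minimum 1
  expect_true(sdm_activation_count(10, 5, "A2") %% 2 == 1)
  expect_error(sdm_activation_count(0, 10), "positive")
})

test_that("activation selects the nearest labels deterministically", {
  sdm <- sdm_memory(20, 64, "A1", seed = 1, m_a = 20)
  addr <- hv_random(64, "binary", seed = 2)
  expect_setequal(sdm_activate(sdm, addr), 1:20)

  sdm1 <- sdm_memory(20, 64, "A1", seed = 1, m_a = 1)
  lab <- hypervector(sdm1$addresses[7, ], "binary")
  expect_equal(sdm_activate(sdm1, lab), 7L)

  sdm5 <- sdm_memory(50, 64, "A1", seed = 3, m_a = 5)
  for (case in 1:30) {
    a <- unclass(hv_random(64, "binary", seed = 500 + case))
    expect_identical(sdm_activate(sdm5, a),
                     naive_top_ma(sdm5$addresses, a, 5))
  }
  # identical address, identical set
  a <- hv_random(64, "binary", seed = 4)
  expect_identical(sdm_activate(sdm5, a), sdm_activate(sdm5, a))
  expect_error(sdm_activate(sdm5, hv_random(32, "binary", seed = 5)), "width")
  expect_error(sdm_activate(sdm5, hv_random(64, "bipolar", seed = 6)), "domain")
})

test_that("storing writes +/-1 data into exactly the activated rows", {
  sdm <- sdm_memory(12, 32, "A1", seed = 7, m_a = 3)
  addr <- hv_random(32, "binary", seed = 8)
  data <- hv_random(32, "binary", seed = 9)
  s1 <- sdm_store(sdm, addr, data)
  rows <- sdm_activate(sdm, addr)
  nz <- which(rowSums(s1$contents != 0) > 0)
  expect_setequal(nz, rows)
  for (r in rows) expect_equal(s1$contents[r, ], 2L * comps(data) - 1L)
  s2 <- sdm_store(s1, addr, data)
  for (r in rows) expect_equal(s2$contents[r, ], 2L * (2L * comps(data) - 1L))

  # 20 pairs against a from-scratch loop
  m <- 10; n_c <- 16; m_a <- 2
  sdmk <- sdm_memory(m, n_c, "A1", seed = 10, m_a = m_a)
  ref <- matrix(0, m, n_c)
  set.seed(11)
  for (i in 1:20) {
    a <- sample(0:1, n_c, replace = TRUE)
    d <- sample(0:1, n_c, replace = TRUE)
    sdmk <- sdm_store(sdmk, hypervector(a, "binary"), hypervector(d, "binary"))
    for (r in naive_top_ma(sdmk$addresses, a, m_a)) {
      ref[r, ] <- pmin(127, pmax(-127, ref[r, ] + (2 * d - 1)))
    }
  }
  expect_equal(unname(sdmk$contents), unname(ref))
})

test_that("binarization keeps signs and flips a fair coin on zeros", {
  sdm <- sdm_memory(2, 3, "A2", seed = 12, m_a = 1)
  sdm$contents <- matrix(c(5L, -2L, 0L, 1L, 0L, -7L), 2, 3, byrow = TRUE)
  b <- sdm_binarize(sdm)
  expect_equal(b$contents[1, 1:2], c(1L, -1L))
  expect_true(all(b$contents %in% c(-1L, 1L)))
  expect_error(sdm_binarize(b), "already")

  allpos <- sdm_memory(2, 3, "A3", seed = 13, m_a = 1)
  allpos$contents <- matrix(3L, 2, 3)
  expect_true(all(sdm_binarize(allpos)$contents == 1L))

  # ~1e5 zero counters: the coin is fair
  z <- sdm_memory(200, 512, "A2", seed = 14, m_a = 1)
  zb <- sdm_binarize(z)
  expect_lt(abs(mean(zb$contents == 1L) - 0.5), 0.005)

  expect_error(sdm_binarize(sdm_memory(4, 8, "A1", seed = 15, m_a = 1)), "A2 and A3")
})

test_that("a single stored pair is recalled exactly by every variant", {
  for (v in c("A1", "A2", "A3", "A4")) {
    domain <- if (v %in% c("A1", "A2")) "binary" else "bipolar"
    im <- item_memory(15, 64, domain, seed = 16)
    m_a <- if (v == "A2") 3 else 2
    sdm <- sdm_memory(25, 64, v, seed = 17, m_a = m_a)
    addr <- hv_random(64, domain, seed = 18)
    sdm <- sdm_store(sdm, addr, im_entry(im, 9))
    if (v %in% c("A2", "A3")) sdm <- sdm_binarize(sdm)
    r <- sdm_recall(sdm, addr, im)
    expect_equal(r$best_index, 9)
    # Hamming readout recovers the data exactly; the raw-sum readout's
    # dot grows with the number of summed rows
    expect_equal(r$best_distance, if (v %in% c("A1", "A2")) 0 else m_a * 64)
  }
})

test_that("recall refuses an inconsistent binarization state", {
  sdm <- sdm_memory(10, 32, "A2", seed = 19, m_a = 1)
  addr <- hv_random(32, "binary", seed = 20)
  sdm <- sdm_store(sdm, addr, hv_random(32, "binary", seed = 21))
  expect_error(sdm_read(sdm, addr), "binarize")
  expect_error(sdm_store(sdm_binarize(sdm), addr, hv_random(32, "binary", seed = 22)),
               "binariz")
})

test_that("odd activation counts give zero-free pre-threshold sums for A2", {
  # after binarization each counter is +/-1, so a sum of an odd number of
  # rows is odd and never zero
  rep <- run_recall_experiment("A2", 30, trials = 2, seed = 23,
                               num_states = 20, num_inputs = 5, n_c = 64,
                               m_a = 3)
  expect_true(rep$n_recalls == 200)
  sdm <- sdm_memory(30, 64, "A2", seed = 24, m_a = 3)
  for (i in 1:20) {
    sdm <- sdm_store(sdm, hv_random(64, "binary", seed = 600 + i),
                     hv_random(64, "binary", seed = 700 + i))
  }
  sdm <- sdm_binarize(sdm)
  for (i in 1:50) {
    rows <- sdm_activate(sdm, hv_random(64, "binary", seed = 800 + i))
    sums <- colSums(sdm$contents[rows, , drop = FALSE])
    expect_true(all(sums != 0))
  }
})

test_that("one-row SDM with thresholded readout reproduces S1", {
  # m = 1, m_a = 1: the single row of counters is the superposition
  # vector; thresholding at zero is S1's binarization when k is odd
  width <- 128; k <- 5
  sdm <- sdm_memory(1, width, "A1", seed = 25, m_a = 1)
  sm <- superposition_memory(width, "S1")
  for (i in seq_len(k)) {
    key <- hv_random(width, "binary", seed = 900 + i)
    val <- hv_random(width, "binary", seed = 950 + i)
    sdm <- sdm_store(sdm, key, hv_bind(key, val))
    sm <- sm_store(sm, key, val)
  }
  sm <- sm_finalize(sm)
  probe <- hv_random(width, "binary", seed = 999)
  expect_identical(comps(sdm_read(sdm, probe)), sm$binarized)
})

test_that("the batched harness agrees with the object API, pair by pair", {
  seed <- 31
  # SDM side
  fsa <- random_fsa(5, 2, child_seed(seed, "fsa", 1))
  cb <- fsa_codebooks(fsa, 32, "binary", child_seed(seed, "codebooks", 1))
  sdm <- sdm_memory(8, 32, "A1", seed = child_seed(seed, "memory", 1), m_a = 3)
  tr <- hdmem:::transition_index(fsa)
  for (i in seq_along(tr$si)) {
    enc <- encode_transition_sdm(cb, tr$si[i], tr$pj[i], tr$sk[i])
    sdm <- sdm_store(sdm, enc$address, enc$data)
  }
  errors <- 0; match_d <- numeric(length(tr$si))
  for (i in seq_along(tr$si)) {
    enc <- encode_transition_sdm(cb, tr$si[i], tr$pj[i], tr$sk[i])
    noisy <- hv_permute(hv_bind(sdm_read(sdm, enc$address), enc$address), -1)
    mr <- im_nearest(cb$state_memory, noisy, "hamming")
    if (mr$is_tie || mr$best_index != tr$sk[i]) errors <- errors + 1
    match_d[i] <- sum(comps(noisy) != cb$state_memory$vectors[tr$sk[i], ])
  }
  rep <- run_recall_experiment("A1", 8, trials = 1, seed = seed,
                               num_states = 5, num_inputs = 2, n_c = 32, m_a = 3)
  expect_equal(rep$n_errors, errors)
  expect_equal(rep$match_d, match_d)

  # superposition side (k = 10 is even: the tie-break vector engages)
  cb2 <- fsa_codebooks(fsa, 64, "binary", child_seed(seed, "codebooks", 1))
  sm <- superposition_memory(64, "S1",
                             tiebreak_seed = child_seed(child_seed(seed, "memory", 1),
                                                        "tiebreak"))
  for (i in seq_along(tr$si)) {
    key <- hv_bind(im_entry(cb2$state_memory, tr$si[i]),
                   im_entry(cb2$input_memory, tr$pj[i]))
    sm <- sm_store(sm, key, hv_permute(im_entry(cb2$state_memory, tr$sk[i]), 1))
  }
  sm <- sm_finalize(sm)
  errors2 <- 0; match_d2 <- numeric(length(tr$si))
  for (i in seq_along(tr$si)) {
    key <- hv_bind(im_entry(cb2$state_memory, tr$si[i]),
                   im_entry(cb2$input_memory, tr$pj[i]))
    noisy <- hv_permute(sm_read(sm, key), -1)
    mr <- im_nearest(cb2$state_memory, noisy, "hamming")
    if (mr$is_tie || mr$best_index != tr$sk[i]) errors2 <- errors2 + 1
    match_d2[i] <- sum(comps(noisy) != cb2$state_memory$vectors[tr$sk[i], ])
  }
  rep2 <- run_recall_experiment("S1", 64, trials = 1, seed = seed,
                                num_states = 5, num_inputs = 2)
  expect_equal(rep2$n_errors, errors2)
  expect_equal(rep2$match_d, match_d2)
})
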