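test_that("random hypervectors are reproducible and uniform", {
  a <- hv_random(8, "binary", seed = 5)
  b <- hv_random(8, "binary", seed = 5)
  expect_identical(unclass(a), unclass(b))
  expect_true(all(unclass(a) %in% c(0L, 1L)))
  expect_false(identical(unclass(a), unclass(hv_random(8, "binary", seed = 6))))

  # law of large numbers: bipolar mean ~ 0
  v <- hv_random(1e5, "bipolar", seed = 7)
  expect_lt(abs(mean(unclass(v))), 0.01)

  # two independent 512-bit vectors sit near Hamming distance 256
  x <- hv_random(512, "binary", seed = 8)
  y <- hv_random(512, "binary", seed = 9)
  expect_lt(abs(hv_hamming(x, y) - 256), 4 * sqrt(0.25 * 512))

  expect_error(hv_random(0, "binary"), "positive")
})

test_that("binding is a self-inverse XOR / product", {
  a <- hypervector(c(0, 1, 1, 0), "binary")
  b <- hypervector(c(0, 1, 0, 1), "binary")
  expect_equal(comps(hv_bind(a, b)), c(0L, 0L, 1L, 1L))
  expect_equal(comps(hv_bind(a, a)), rep(0L, 4))
  expect_identical(unclass(hv_bind(hv_bind(a, b), b)), unclass(a))

  p <- hv_random(64, "bipolar", seed = 1)
  q <- hv_random(64, "bipolar", seed = 2)
  expect_equal(comps(hv_bind(p, p)), rep(1L, 64))
  expect_identical(unclass(hv_bind(hv_bind(p, q), q)), unclass(p))

  expect_error(hv_bind(a, hypervector(c(0, 1), "binary")), "width")
  expect_error(hv_bind(a, p), "domain|width")
})

test_that("permutation is an invertible shift that distributes over bind", {
  a <- hv_random(33, "binary", seed = 3)
  b <- hv_random(33, "binary", seed = 4)
  expect_identical(hv_permute(a, 0), a)
  for (t in -8:8) {
    expect_identical(unclass(hv_permute(hv_permute(a, t), -t)), unclass(a))
  }
  expect_identical(unclass(hv_permute(hv_bind(a, b), 1)),
                   unclass(hv_bind(hv_permute(a, 1), hv_permute(b, 1))))
  # shift by one: component i comes from component i - 1
  expect_identical(comps(hv_permute(a, 1)), comps(a)[c(33, 1:32)])
})

test_that("distance measures match their definitions", {
  a <- hypervector(c(0, 1, 1, 0), "binary")
  b <- hypervector(c(0, 1, 0, 1), "binary")
  expect_equal(hv_hamming(a, a), 0)
  expect_equal(hv_hamming(a, b), 2)
  expect_equal(hv_hamming(hypervector(c(1, -1, -1), "bipolar"),
                          hypervector(c(1, 1, -1), "bipolar")), 1)
  v <- hv_random(64, "bipolar", seed = 10)
  expect_equal(hv_dot(v, v), 64)
  expect_equal(hv_dot(rep(0, 64), v), 0)
  expect_equal(hv_dot(c(3, -2, 0), hypervector(c(1, -1, 1), "bipolar")), 5)

  # distances between random pairs follow Binomial(n, 1/2)
  n <- 256; pairs <- 1e4
  x <- hdmem:::random_bit_matrix(pairs, n, "binary", 11)
  y <- hdmem:::random_bit_matrix(pairs, n, "binary", 12)
  d <- rowSums(x != y)
  expect_lt(abs(mean(d) - n / 2), 3 * sqrt(n / 4 / pairs))
  expect_lt(abs(var(d) - n / 4), 3 * (n / 4) * sqrt(2 / (pairs - 1)))
})

test_that("nearest-neighbour lookup matches an exhaustive oracle", {
  im <- item_memory(10, 64, "binary", seed = 13)
  q <- im$vectors[4, ]
  r <- im_nearest(im, q, "hamming")
  expect_equal(r$best_index, 4)
  expect_equal(r$best_distance, 0)
  expect_false(r$is_tie)

  # duplicate entries force a reported tie
  im2 <- im
  im2$vectors[7, ] <- im2$vectors[4, ]
  expect_true(im_nearest(im2, q, "hamming")$is_tie)

  for (case in 1:20) {
    imc <- item_memory(10, 64, "binary", seed = 100 + case)
    qc <- unclass(hv_random(64, "binary", seed = 200 + case))
    got <- im_nearest(imc, qc, "hamming")
    want <- naive_nearest(imc$vectors, qc, "hamming")
    expect_equal(got$best_index, want$best_index)
    expect_equal(got$best_distance, want$best_distance)
    expect_equal(got$is_tie, want$is_tie)
  }
  imd <- item_memory(10, 64, "bipolar", seed = 14)
  qd <- c(unclass(hv_random(64, "bipolar", seed = 15))) * sample(1:3, 64, TRUE)
  got <- im_nearest(imd, qd, "dot")
  want <- naive_nearest(imd$vectors, qd, "dot")
  expect_equal(got$best_index, want$best_index)
  expect_equal(got$best_distance, want$best_distance)

  expect_error(im_nearest(im, q[-1], "hamming"), "width")
  expect_error(im_nearest(imd, qd, "hamming"), "bipolar")
})

test_that("hamming and dot ranking agree across the binary/bipolar map", {
  # a binarized query matched by Hamming against a binary codebook ranks
  # entries identically to the dot product after mapping {0,1} -> {-1,+1}
  for (case in 1:10) {
    imb <- item_memory(20, 128, "binary", seed = 300 + case)
    q <- unclass(hv_random(128, "binary", seed = 400 + case))
    rh <- im_nearest(imb, q, "hamming")
    imp <- imb
    imp$vectors <- 2L * imp$vectors - 1L
    imp$domain <- "bipolar"
    rd <- im_nearest(imp, 2 * q - 1, "dot")
    if (!rh$is_tie) expect_equal(rd$best_index, rh$best_index)
    expect_equal(rd$best_distance, 128 - 2 * rh$best_distance)
  }
})
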