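# Sparse Distributed Memory with four readout variants.
#
# m hard locations, each a fixed random address label (one row of the
# address matrix) plus a row of saturating 8-bit counters. An address
# activates the m_a locations whose labels are nearest in Hamming
# distance; storing adds the +/-1 data vector into the activated rows;
# recall sums the activated rows column-wise. Variants differ in whether
# the contents are binarized first (A2, A3) and whether the column sums
# are thresholded at zero for a Hamming match (A1, A2) or kept raw for a
# dot-product match (A3, A4).

sdm_variants <- c("A1", "A2", "A3", "A4")

sdm_address_domain <- function(variant) {
  if (variant %in% c("A1", "A2")) "binary" else "bipolar"
}

#' Optimal number of activated hard locations
#'
#' `m_a = round(m / (2 k m)^(1/3))`, the activation count that maximizes
#' recall fidelity for a thresholded-sum readout, rounded to the nearest
#' positive integer -- or to the nearest positive *odd* integer for
#' variant A2, whose recalled vector is a superposition of `m_a` bipolar
#' rows and benefits from never summing to zero.
#'
#' @param m Number of hard locations (rows).
#' @param k Number of items to be stored.
#' @param variant SDM readout variant, `"A1"`..`"A4"`.
#' @return A positive integer activation count.
#' @examples
#' sdm_activation_count(125, 1000, "A1")  # 2
#' sdm_activation_count(368, 1000, "A2")  # 5
#' @export
sdm_activation_count <- function(m, k, variant = "A1") {
  variant <- match.arg(variant, sdm_variants)
  if (!all(m >= 1) || !all(k >= 1)) stop("m and k must be positive")
  x <- m / (2 * k * m)^(1 / 3)
  if (variant == "A2") {
    lo <- 2 * floor((x - 1) / 2) + 1  # nearest odd integers bracketing x
    ma <- ifelse(x - lo <= (lo + 2) - x, lo, lo + 2)
  } else {
    ma <- round(x)
  }
  as.integer(pmax(1, ma))
}

#' Create a Sparse Distributed Memory
#'
#' @param m Number of hard locations.
#' @param n_c Row width (default 512: wide enough for clean codebook
#'   separation without inflating the item memory).
#' @param variant Readout variant `"A1"`..`"A4"`. A1/A2 use binary
#'   address labels, A3/A4 bipolar ones.
#' @param seed Seed for the random address matrix (and, via a child
#'   seed, for the coin used on zero counters at binarization).
#' @param m_a Activation count; defaults to [sdm_activation_count()]
#'   when `k` is given.
#' @param k Planned number of stored items, used only to derive `m_a`.
#' @return An object of class `"sdm_memory"`: address matrix
#'   (`m x n_c`), contents counter matrix (`m x n_c`, confined to
#'   `[-127, 127]`), `m`, `n_c`, `m_a`, `variant`, `seed`,
#'   `contents_binarized`.
#' @export
sdm_memory <- function(m, n_c = 512L, variant = c("A1", "A2", "A3", "A4"),
                       seed = NULL, m_a = NULL, k = NULL) {
  variant <- match.arg(variant)
  stopifnot(m >= 1, n_c >= 1)
  m <- as.integer(m); n_c <- as.integer(n_c)
  if (is.null(m_a)) {
    if (is.null(k)) stop("supply either m_a or k")
    m_a <- sdm_activation_count(m, k, variant)
  }
  m_a <- as.integer(m_a)
  if (m_a < 1L || m_a > m) stop("m_a must lie in [1, m]")
  if (variant == "A2" && m_a %% 2L == 0L) stop("variant A2 requires odd m_a")
  addr <- random_bit_matrix(m, n_c, sdm_address_domain(variant),
                            if (is.null(seed)) NULL else child_seed(seed, "addresses"))
  structure(list(addresses = addr,
                 contents = matrix(0L, m, n_c),
                 m = m, n_c = n_c, m_a = m_a, variant = variant,
                 seed = seed, k_stored = 0L, contents_binarized = FALSE),
            class = "sdm_memory")
}

#' @export
print.sdm_memory <- function(x, ...) {
  cat(sprintf("<sdm_memory %s> m = %d, n_c = %d, m_a = %d, %d item(s) stored%s\n",
              x$variant, x$m, x$n_c, x$m_a, x$k_stored,
              if (x$contents_binarized) ", contents binarized" else ""))
  invisible(x)
}

#' Hard locations activated by an address
#'
#' Returns the indices of the `m_a` rows whose labels have the smallest
#' Hamming distance to the address, ordered by increasing distance with
#' ties broken by lowest row index. The selection is deterministic: the
#' same address always activates the same set.
#'
#' @param sdm An `"sdm_memory"`.
#' @param address Address hypervector of width `n_c` in the variant's
#'   address domain.
#' @return Integer vector of `m_a` distinct row indices.
#' @export
sdm_activate <- function(sdm, address) {
  if (length(address) != sdm$n_c) stop("address width mismatch")
  d <- hv_domain(address)
  if (!is.null(d) && d != sdm_address_domain(sdm$variant))
    stop("address domain must be ", sdm_address_domain(sdm$variant),
         " for variant ", sdm$variant)
  h <- as.vector(rowSums(sdm$addresses != rep(as.integer(unclass(address)),
                                              each = sdm$m)))
  # radix order is stable: equal distances keep ascending row index
  order(h, method = "radix")[seq_len(sdm$m_a)]
}

#' Store an address-data pair
#'
#' Adds the data vector (as +/-1) into the counters of every activated
#' row, saturating at +/-127.
#'
#' @inheritParams sdm_activate
#' @param data Data hypervector of width `n_c` (binary for A1/A2,
#'   bipolar for A3/A4).
#' @return The updated memory.
#' @export
sdm_store <- function(sdm, address, data) {
  if (sdm$contents_binarized) stop("cannot store after binarizing the contents")
  if (length(data) != sdm$n_c) stop("data width mismatch")
  pm <- as.integer(unclass(data))
  if (sdm$variant %in% c("A1", "A2")) {
    if (!all(pm == 0L | pm == 1L)) stop("variant ", sdm$variant,
                                        " stores binary data vectors")
    pm <- 2L * pm - 1L
  } else if (!all(pm == -1L | pm == 1L)) {
    stop("variant ", sdm$variant, " stores bipolar data vectors")
  }
  rows <- sdm_activate(sdm, address)
  add <- matrix(pm, length(rows), sdm$n_c, byrow = TRUE)
  sdm$contents[rows, ] <- clamp_counters(sdm$contents[rows, , drop = FALSE] + add)
  sdm$k_stored <- sdm$k_stored + 1L
  sdm
}

#' Binarize the contents matrix (variants A2 and A3)
#'
#' Collapses every counter to its sign in `{-1, +1}`; zero counters get
#' a fair coin drawn from a child seed of the memory's seed, so the
#' operation replays exactly.
#'
#' @param sdm An `"sdm_memory"` of variant A2 or A3.
#' @return The updated memory with `contents_binarized = TRUE`.
#' @export
sdm_binarize <- function(sdm) {
  if (!sdm$variant %in% c("A2", "A3"))
    stop("binarization applies to variants A2 and A3 only")
  if (sdm$contents_binarized) stop("contents already binarized")
  s <- sign(sdm$contents)
  zeros <- which(s == 0L)
  if (length(zeros)) {
    seed <- child_seed(sdm$seed %||% 0, "binarize")
    coin <- with_seed(seed, sample(c(-1L, 1L), length(zeros), replace = TRUE))
    s[zeros] <- coin
  }
  storage.mode(s) <- "integer"
  sdm$contents <- s
  sdm$contents_binarized <- TRUE
  sdm
}

#' Read the noisy data vector for an address
#'
#' Sums the counters of the activated rows column-wise. A1/A2 threshold
#' the sums at zero (sum > 0 gives bit 1, otherwise bit 0) and return a
#' binary vector; A3/A4 return the raw integer sums.
#'
#' @inheritParams sdm_activate
#' @return Binary `"hypervector"` (A1/A2) or integer vector of column
#'   sums (A3/A4).
#' @export
sdm_read <- function(sdm, address) {
  if (sdm$variant %in% c("A2", "A3") && !sdm$contents_binarized)
    stop("binarize the contents before recall with variant ", sdm$variant)
  if (sdm$variant %in% c("A1", "A4") && sdm$contents_binarized)
    stop("variant ", sdm$variant, " reads raw counters")
  rows <- sdm_activate(sdm, address)
  sums <- colSums(sdm$contents[rows, , drop = FALSE])
  if (sdm$variant %in% c("A1", "A2")) {
    hypervector(as.integer(sums > 0), "binary")
  } else {
    as.integer(sums)
  }
}

#' Recall a data vector and clean it up against an item memory
#'
#' @inheritParams sdm_read
#' @param im `"item_memory"` of candidate data vectors (binary for
#'   A1/A2, bipolar for A3/A4).
#' @return A `"match_result"` (Hamming match for A1/A2, dot for A3/A4).
#' @export
sdm_recall <- function(sdm, address, im) {
  r <- sdm_read(sdm, address)
  im_nearest(im, r, mode = if (sdm$variant %in% c("A1", "A2")) "hamming" else "dot")
}
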