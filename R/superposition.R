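# Superposition-vector memories.
#
# Key-value pairs are bound (XOR / multiplication) and bundled into one
# row of saturating 8-bit counters. Variant S1 binarizes the counters
# and reads out with the Hamming distance; variant S2 keeps the integer
# counters and reads out with the dot product.

COUNTER_MAX <- 127L

clamp_counters <- function(x) pmin.int(COUNTER_MAX, pmax.int(-COUNTER_MAX, x))

#' Create a superposition-vector memory
#'
#' @param width Counter row width `n_s`.
#' @param variant `"S1"` (binary vectors, XOR binding, binarized counters,
#'   Hamming readout) or `"S2"` (bipolar vectors, multiplicative binding,
#'   raw counters, dot-product readout).
#' @param tiebreak_seed Seed for the extra random vector S1 adds when an
#'   even number of vectors were stored; recorded so runs replay exactly.
#' @return An object of class `"superposition_memory"` with fields
#'   `counters` (integers confined to `[-127, 127]`), `variant`,
#'   `k_stored`, `finalized`, `tiebreak_seed` and (after finalizing an S1
#'   memory) `binarized`.
#' @seealso [sm_store()], [sm_finalize()], [sm_recall()]
#' @export
superposition_memory <- function(width, variant = c("S1", "S2"),
                                 tiebreak_seed = NULL) {
  variant <- match.arg(variant)
  stopifnot(width >= 1)
  structure(list(counters = integer(as.integer(width)), variant = variant,
                 k_stored = 0L, finalized = FALSE,
                 tiebreak_seed = tiebreak_seed, binarized = NULL),
            class = "superposition_memory")
}

#' @export
print.superposition_memory <- function(x, ...) {
  cat(sprintf("<superposition_memory %s> width %d, %d pair(s) stored%s\n",
              x$variant, length(x$counters), x$k_stored,
              if (x$finalized) ", finalized" else ""))
  invisible(x)
}

sm_domain <- function(mem) if (mem$variant == "S1") "binary" else "bipolar"

#' Store a key-value pair in a superposition memory
#'
#' Binds the key and value and adds the result (as a +/-1 vector) to the
#' counters, saturating at +/-127.
#'
#' @param mem A `"superposition_memory"` that has not been finalized.
#' @param key,value Hypervectors of the memory's width, binary for S1 and
#'   bipolar for S2.
#' @return The updated memory.
#' @export
sm_store <- function(mem, key, value) {
  if (mem$finalized) stop("cannot store into a finalized memory")
  if (length(key) != length(mem$counters) || length(value) != length(mem$counters))
    stop("key/value width mismatch")
  want <- sm_domain(mem)
  for (v in list(key, value)) {
    d <- hv_domain(v)
    if (!is.null(d) && d != want)
      stop(mem$variant, " stores ", want, " vectors")
  }
  bound <- unclass(hv_bind(hypervector(key, want), hypervector(value, want)))
  pm <- if (mem$variant == "S1") 2L * bound - 1L else bound
  mem$counters <- clamp_counters(mem$counters + pm)
  mem$k_stored <- mem$k_stored + 1L
  mem
}

#' Finalize a superposition memory for recall
#'
#' For S1: if an even number of vectors were stored, one extra random
#' +/-1 vector (drawn from `tiebreak_seed`) is added so the effective
#' count is odd, then each counter collapses to bit 1 if positive and 0
#' otherwise. For S2 the counters are kept as they are.
#'
#' @param mem A `"superposition_memory"`.
#' @return The updated memory with `finalized = TRUE`.
#' @export
sm_finalize <- function(mem) {
  if (mem$finalized) stop("memory already finalized")
  if (mem$variant == "S1") {
    if (mem$k_stored %% 2L == 0L) {
      seed <- mem$tiebreak_seed %||% stop("tiebreak_seed required to finalize ",
                                          "an even number of stored vectors")
      tb <- 2L * unclass(hv_random(length(mem$counters), "binary", seed)) - 1L
      mem$counters <- clamp_counters(mem$counters + tb)
    }
    # an odd effective count makes a zero counter impossible (saturation
    # aside); > 0 maps to bit 1, everything else to bit 0
    mem$binarized <- as.integer(mem$counters > 0L)
  }
  mem$finalized <- TRUE
  mem
}

#' Read the noisy value for a key from a superposition memory
#'
#' S1 returns `XOR(key, binarized superposition)`, a binary vector; S2
#' returns the component-wise product of the key with the counters, an
#' integer vector. The result approximates the stored value plus
#' crosstalk noise from the other stored pairs.
#'
#' @param mem A finalized `"superposition_memory"`.
#' @param key The key hypervector.
#' @return Noisy value: a binary `"hypervector"` (S1) or integer vector (S2).
#' @export
sm_read <- function(mem, key) {
  if (!mem$finalized) stop("finalize the memory before recall")
  if (length(key) != length(mem$counters)) stop("key width mismatch")
  if (mem$variant == "S1") {
    hypervector((unclass(key) + mem$binarized) %% 2L, "binary")
  } else {
    as.integer(unclass(key)) * mem$counters
  }
}

#' Recall a value and clean it up against an item memory
#'
#' Reads the noisy value for `key` and matches it against `im`:
#' Hamming distance for S1, dot product for S2.
#'
#' @inheritParams sm_read
#' @param im The `"item_memory"` holding the candidate values.
#' @return A `"match_result"`.
#' @export
sm_recall <- function(mem, key, im) {
  r <- sm_read(mem, key)
  im_nearest(im, r, mode = if (mem$variant == "S1") "hamming" else "dot")
}
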