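# Deterministic seed plumbing.
#
# Every stochastic object in the package (codebook, automaton, tie-break
# vector, address matrix, trial) is generated from a child seed derived
# from a single master seed by a fixed arithmetic rule, so whole
# experiments replay bit-for-bit from one integer.

#' Derive a child seed from a master seed
#'
#' Maps `(seed, tag, index)` to an integer in `[1, 2^31 - 2]` by a fixed
#' polynomial hash of the tag string and index. The rule is deterministic
#' and documented so that experiment logs stating a master seed fully
#' determine every random draw.
#'
#' @param seed Master seed (single number).
#' @param tag Character label naming the component (e.g. `"states"`).
#' @param index Integer index distinguishing repeated components (trials).
#' @return A single integer seed.
#' @examples
#' child_seed(1, "states")
#' child_seed(1, "states", 2)
#' @export
child_seed <- function(seed, tag, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  # modulus is the largest prime below 2^31 - 58; arithmetic stays exact in
  # doubles (values < 2^31 * 131 << 2^53)
  p <- 2147483587
  h <- abs(as.double(seed)) %% p
  for (code in utf8ToInt(paste0(tag, ":", format(index, scientific = FALSE)))) {
    h <- (h * 131 + code) %% p
  }
  as.integer(h) + 1L
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library code never disturbs user
# simulations.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
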