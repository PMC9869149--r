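# Dimension search: the smallest-granularity dimension whose predicted
# recall error is closest (in log10) to a requested target rate.

#' Find the memory dimension for a target error rate
#'
#' Bracketing binary search over the integer dimension (`n_s` for
#' S1/S2, hard-location count `m` for the SDM variants) using the
#' variant's analytic predictor, refined to unit granularity; of the two
#' final bracket ends the one whose predicted error is nearest the
#' target in log10 is returned. For SDM variants the activation count
#' `m_a` is recomputed from the activation rule at every probe.
#'
#' @param variant `"S1"`, `"S2"`, `"A1"`..`"A4"` (A3 routes to the A1
#'   predictor).
#' @param target_error Desired recall error rate, in (0, 1).
#' @param k Number of stored pairs.
#' @param distractors Competing codebook entries.
#' @param n_c SDM row width.
#' @param exact_delta Use the exact binomial per-bit error for S1.
#' @param overlap_model SDM overlap model (see [predict_error_sdm()]).
#' @return A list: `variant`, `dimension`, `m_a` (`NA` for S1/S2),
#'   `predicted_error`.
#' @examples
#' find_dimension("S2", 1e-1)$dimension   # 15221
#' @export
find_dimension <- function(variant, target_error, k = 1000L, distractors = 99L,
                           n_c = 512L, exact_delta = FALSE,
                           overlap_model = c("geometry", "hypergeometric")) {
  variant <- match.arg(variant, c("S1", "S2", sdm_variants))
  if (!is.numeric(target_error) || target_error <= 0 || target_error >= 1)
    stop("target_error must lie in (0, 1)")
  perr <- function(d) predict_error(variant, d, k = k, distractors = distractors,
                                    n_c = n_c, exact_delta = exact_delta,
                                    overlap_model = overlap_model)$p_err

  lo <- 1L
  hi <- if (variant %in% c("S1", "S2")) 1024L else 8L
  while (perr(hi) > target_error) {
    lo <- hi
    hi <- hi * 2L
    if (hi > 2^26) stop("target error unreachable within search range")
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (perr(mid) > target_error) lo <- mid else hi <- mid
  }
  cand <- unique(c(lo, hi))
  gap <- vapply(cand, function(d) abs(log10(max(perr(d), 1e-300)) -
                                      log10(target_error)), numeric(1))
  dim <- cand[which.min(gap)]
  list(variant = variant, dimension = dim,
       m_a = if (variant %in% sdm_variants)
         sdm_activation_count(dim, k, variant) else NA_integer_,
       predicted_error = perr(dim))
}
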