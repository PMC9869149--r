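# Analytic recall-error predictors.
#
# Shared framework: a recall succeeds when the noisy vector read from
# the memory is closer to the correct codebook entry (the match) than to
# every one of the i - 1 distractors,
#
#   p_corr = Integral  p(D(r, I_m) = h) * [ p(D(r, I_d) beaten by h) ]^(i-1) dh,
#
# evaluated numerically with normal approximations to the match and
# distractor distance distributions. Each memory variant supplies its
# own pair of distributions; the SDM variants derive theirs from the
# distribution of how often other stored items land on the activated
# hard locations.

#' Expected per-bit error of a binarized superposition (S1)
#'
#' Probability that one bit recalled from a binarized superposition of
#' `k` vectors (k odd) disagrees with the stored bit: the chance that
#' fewer than `(k-1)/2` of the other `k-1` added vectors match the
#' stored value. Exactly the binomial CDF of `B(k-1, 1/2)` at
#' `(k-1)/2 - 1`; the closed-form approximation is
#' `0.5 - 0.4 / sqrt(k - 0.44)`.
#'
#' @param k Odd number of stored vectors. Callers storing an even count
#'   adjust to `k + 1` for the tie-break vector.
#' @param exact Use the exact binomial CDF (`TRUE`) or the closed-form
#'   approximation (`FALSE`, the default used by the dimension search).
#' @return Per-bit error probability in `[0, 0.5)`.
#' @examples
#' delta_s(5, exact = TRUE)   # 5/16 = 0.3125
#' delta_s(5, exact = FALSE)  # 0.3127
#' @export
delta_s <- function(k, exact = FALSE) {
  if (any(k %% 2 == 0)) stop("k must be odd (add the tie-break vector first)")
  if (exact) {
    stats::pbinom((k - 1) / 2 - 1, k - 1, 0.5)
  } else {
    pmin(pmax(0.5 - 0.4 / sqrt(k - 0.44), 0), 0.5 - 1e-12)
  }
}

# Numeric core: p_err for a normal match distribution against i1
# independent normal distractors. `beats = "smaller"` means a distractor
# wins with a smaller value (Hamming); `"larger"` means it wins with a
# larger one (dot product). The distractor CCDF/CDF power is accumulated
# in log space so error rates down to ~1e-300 do not underflow; the
# integrand uses -expm1 so p_err keeps full relative precision when
# small. Trapezoid rule over the match mean +/- 8 combined standard
# deviations, 4001 nodes.
perr_two_normals <- function(mu_m, sd_m, mu_d, sd_d, i1,
                             beats = c("smaller", "larger"), nodes = 4001L) {
  beats <- match.arg(beats)
  lower_tail <- beats == "larger"   # distractor loses when below h
  if (sd_m == 0) {
    lp <- stats::pnorm(mu_m, mu_d, sd_d, lower.tail = lower_tail, log.p = TRUE)
    return(min(max(-expm1(i1 * lp), 0), 1))
  }
  span <- 8 * (sd_m + sd_d)
  h <- seq(mu_m - span, mu_m + span, length.out = nodes)
  fm <- stats::dnorm(h, mu_m, sd_m)
  lp <- stats::pnorm(h, mu_d, sd_d, lower.tail = lower_tail, log.p = TRUE)
  integrand <- fm * (-expm1(i1 * lp))
  p <- sum((integrand[-1L] + integrand[-nodes]) / 2) * (h[2L] - h[1L])
  min(max(p, 0), 1)
}

# Hamming-match p_err with per-bit error d: match ~ N(dn, d(1-d)n),
# distractor ~ N(n/2, n/4). Internal version accepts any d in [0, 1).
perr_hamming_normal <- function(n, d, i1) {
  perr_two_normals(d * n, sqrt(d * (1 - d) * n), 0.5 * n, sqrt(0.25 * n),
                   i1, beats = "smaller")
}

#' Predicted recall error for a Hamming-distance memory
#'
#' Given the per-bit error probability of the recalled vector, models
#' the match Hamming distance as `Normal(bit_error * n,
#' bit_error (1 - bit_error) n)` and each distractor distance as
#' `Normal(n/2, n/4)` (two random binary vectors), and integrates the
#' probability that the match beats all `distractors` competitors.
#' A distractor also wins on a tie, matching the strict inequality of
#' the success criterion.
#'
#' @param n Vector width.
#' @param bit_error Per-bit error probability, in `[0, 0.5)`; at 0.5 the
#'   recalled vector carries no information and the prediction is refused.
#' @param distractors Number of competing codebook entries (`i - 1`).
#' @return An object of class `"hd_prediction"`: `p_err`, `p_corr`,
#'   `bit_error`, `match_dist`, `distractor_dist`.
#' @examples
#' predict_error_hamming(10000, delta_s(5), distractors = 99)
#' @export
predict_error_hamming <- function(n, bit_error, distractors) {
  stopifnot(n >= 1, distractors >= 1)
  if (bit_error < 0 || bit_error >= 0.5)
    stop("bit_error must lie in [0, 0.5): at 0.5 the recalled vector carries no information")
  p <- perr_hamming_normal(n, bit_error, distractors)
  hd_prediction(p, bit_error = bit_error,
                match_dist = dist_desc("normal", bit_error * n,
                                       bit_error * (1 - bit_error) * n),
                distractor_dist = dist_desc("normal", n / 2, n / 4))
}

#' Predicted recall error for the integer-counter memory (S2)
#'
#' Dot-product readout of a superposition of `k` bipolar bound pairs:
#' summing independent per-component contributions gives a match dot
#' product approximately `Normal(n, n (k - 1))` and a distractor dot
#' product `Normal(0, n k)`; the success probability integrates the
#' match density against the distractor CDF raised to the number of
#' competitors (a tie counts as a loss).
#'
#' @param n Vector width.
#' @param k Number of stored pairs.
#' @param distractors Number of competing codebook entries.
#' @return An `"hd_prediction"`.
#' @export
predict_error_dot <- function(n, k, distractors) {
  stopifnot(n >= 1, k >= 1, distractors >= 1)
  p <- perr_two_normals(n, sqrt(n * (k - 1)), 0, sqrt(n * k),
                        distractors, beats = "larger")
  hd_prediction(p, bit_error = NA_real_,
                match_dist = dist_desc("normal", n, n * (k - 1)),
                distractor_dist = dist_desc("normal", 0, n * k))
}

dist_desc <- function(family, mean, var) list(family = family, mean = mean, var = var)

hd_prediction <- function(p_err, bit_error, match_dist, distractor_dist) {
  structure(list(p_err = p_err, p_corr = 1 - p_err, bit_error = bit_error,
                 match_dist = match_dist, distractor_dist = distractor_dist),
            class = "hd_prediction")
}

#' @export
print.hd_prediction <- function(x, ...) {
  cat(sprintf("<hd_prediction> p_err = %.4g%s\n", x$p_err,
              if (!is.na(x$bit_error))
                sprintf(" (per-bit error %.4g)", x$bit_error) else ""))
  invisible(x)
}

# ---- SDM overlap machinery ---------------------------------------------

# Exact word-error summation for a Hamming readout of width n with
# per-bit error d: match ~ Binom(n, d), distractor ~ Binom(n, 1/2).
# Affordable (and noticeably more accurate than the normal
# approximation) at SDM row widths, where one lattice step is a
# non-negligible fraction of the distance spread.
perr_hamming_exact <- function(n, d, i1) {
  h <- 0:n
  lcc <- stats::pbinom(h, n, 0.5, lower.tail = FALSE, log.p = TRUE)
  p <- sum(stats::dbinom(h, n, d) * (-expm1(i1 * lcc)))
  min(max(p, 0), 1)
}

# pmf of the overlap of one other item onto the target's m_a activated
# rows: hypergeometric (draw m_a of m rows, m_a of them marked)
overlap_item_pmf <- function(m, m_a) {
  stats::dhyper(0:m_a, m_a, m - m_a, m_a)
}

# Activation-geometry sampler. The closed-form overlap model treats
# every item's activated set as an independent uniform m_a-subset; in a
# real memory the sets are determined by nearest-label geometry, which
# correlates them (labels that happen to lie close to each other
# co-activate, and the index tie-break slightly favours early rows).
# This sampler measures the overlap structure directly: it draws a
# random address matrix and k random addresses, activates them by the
# memory's own rule, and tabulates, for each address, how many other
# items overlap its activated set in 1, 2, ... rows and how loaded each
# of its rows is. Seeds are fixed functions of the configuration, so
# the resulting predictor is deterministic. Results are cached.
.geometry_cache <- new.env(parent = emptyenv())

sample_overlap_geometry <- function(m, m_a, k, n_c, reps = NULL) {
  if (is.null(reps)) reps <- max(30L, ceiling(30000 / k))
  key <- paste(m, m_a, k, n_c, reps, sep = "/")
  if (!is.null(.geometry_cache[[key]])) return(.geometry_cache[[key]])
  base <- child_seed(k, sprintf("overlap-geometry-%d-%d-%d", m, m_a, n_c))
  # the canonical workload binds a state and an input codebook into each
  # address; that structure slightly tempers load variance relative to
  # fully independent addresses, so it is reproduced here when k fits it
  shape <- if (k %% 10L == 0L && k >= 20L) c(k %/% 10L, 10L) else NULL
  comp <- vector("list", reps)
  loads <- vector("list", reps)
  shared <- vector("list", reps * k)
  for (rep in seq_len(reps)) {
    Qb <- if (is.null(shape)) {
      random_bit_matrix(k, n_c, "binary", child_seed(base, "queries", rep))
    } else {
      S <- random_bit_matrix(shape[1], n_c, "binary",
                             child_seed(base, "states", rep))
      P <- random_bit_matrix(shape[2], n_c, "binary",
                             child_seed(base, "inputs", rep))
      (S[rep(seq_len(shape[1]), shape[2]), , drop = FALSE] +
       P[rep(seq_len(shape[2]), each = shape[1]), , drop = FALSE]) %% 2L
    }
    A <- random_bit_matrix(m, n_c, "binary", child_seed(base, "addresses", rep))
    H <- matrix(as.integer(round((n_c - (2 * Qb - 1) %*% t(2 * A - 1)) / 2)), k, m)
    act <- matrix(vapply(seq_len(k),
                         function(i) order(H[i, ], method = "radix")[seq_len(m_a)],
                         integer(m_a)), nrow = m_a)
    Z <- matrix(0, k, m)
    Z[cbind(rep(seq_len(k), each = m_a), as.vector(act))] <- 1
    OV <- Z %*% t(Z)                 # |act_i intersect act_j|
    diag(OV) <- 0
    cnt <- matrix(0L, k, m_a)
    for (o in seq_len(m_a)) cnt[, o] <- as.integer(rowSums(OV == o))
    comp[[rep]] <- cnt
    row_load <- colSums(Z)
    loads[[rep]] <- matrix(row_load[act], nrow = m_a) - 1  # others on my rows
    if (m_a > 1L) {
      multi <- which(OV >= 2, arr.ind = TRUE)    # items sharing >= 2 rows
      if (nrow(multi)) {
        for (r in seq_len(nrow(multi))) {
          i <- multi[r, 1L]; j <- multi[r, 2L]
          pos <- which(act[, i] %in% act[, j])   # row slots shared with item j
          gi <- (rep - 1L) * k + i
          shared[[gi]] <- c(shared[[gi]], list(pos))
        }
      }
    }
  }
  out <- list(comp = do.call(rbind, comp),       # (reps*k) x m_a counts by overlap size
              row_loads = do.call(cbind, loads), # m_a x (reps*k) per-row counts
              shared = shared)                   # per query: row slots of multi items
  .geometry_cache[[key]] <- out
  out
}

# Exact bit error of the thresholded-sum readout given the overlap
# composition `counts` (counts[o] = number of items sharing o of the
# target's rows): the column noise is sum_o o * (2 B_o - counts[o]),
# B_o ~ Binom(counts[o], 1/2); a stored 1 is lost when the noise
# reaches -m_a and a stored 0 when it exceeds +m_a.
a1_bit_error_comp <- function(counts, m_a) {
  tvals <- 0; tprobs <- 1
  for (o in seq_along(counts)[-1]) {            # multi-row overlap terms
    n <- counts[o]
    if (n == 0L) next
    v <- o * (2 * (0:n) - n)
    p <- stats::dbinom(0:n, n, 0.5)
    ag <- rowsum(as.vector(outer(tprobs, p, "*")),
                 as.vector(outer(tvals, v, "+")))
    tvals <- as.numeric(rownames(ag)); tprobs <- as.vector(ag)
  }
  n1 <- counts[1]
  ple <- function(t) stats::pbinom(floor((t + n1) / 2), n1, 0.5)
  sum(tprobs * 0.5 * (ple(-m_a - tvals) + (1 - ple(m_a - tvals))))
}

# pmf of the sum of n i.i.d. copies of a small pmf (support starting at
# 0), by FFT convolution with exponentiation by squaring; trailing mass
# below 1e-15 cumulative is trimmed to keep lengths bounded
pmf_power <- function(pmf, n) {
  trim <- function(p) {
    p <- pmax(p, 0)
    keep <- max(which(rev(cumsum(rev(p))) > 1e-15), 1L)
    p[seq_len(keep)] / sum(p[seq_len(keep)])
  }
  conv <- function(a, b) trim(stats::convolve(a, rev(b), type = "open"))
  out <- c(1)
  base <- pmf
  while (n > 0) {
    if (n %% 2 == 1) out <- conv(out, base)
    n <- n %/% 2
    if (n > 0) base <- conv(base, base)
  }
  trim(out)
}

# P(recalled bit wrong | total overlap w) for the thresholded-sum
# readout: counter sum = m_a * (stored +/-1) + w i.i.d. +/-1 terms; the
# threshold maps sum > 0 to bit 1 and sum <= 0 to bit 0, so a stored 1
# is lost when the noise reaches -m_a and a stored 0 when it exceeds +m_a.
a1_bit_error_given_w <- function(w, m_a) {
  0.5 * (stats::pbinom(floor((w - m_a) / 2), w, 0.5) +
         stats::pbinom(floor((w + m_a) / 2), w, 0.5, lower.tail = FALSE))
}

# Per-row sign-channel error for binarized contents: one row's counter is
# (stored +/-1) + w other +/-1 contributions; binarization keeps the
# sign, tossing a fair coin on zero.
a2_row_error_given_w <- function(w) {
  e <- stats::pbinom(floor((w - 2) / 2), w, 0.5)
  odd <- w %% 2 == 1
  e[odd] <- e[odd] + 0.5 * stats::dbinom((w[odd] - 1) / 2, w[odd], 0.5)
  e
}

#' Predicted recall error for the SDM variants
#'
#' Overlap-distribution predictor. Each of the other `k - 1` stored
#' items activates its own `m_a` of the `m` hard locations; the recall
#' noise is governed by how often those sets land on the target's
#' activated rows. The overlap structure is a property of the
#' activation geometry, shared by all `n_c` columns of one recall, so
#' the predicted error is a *mixture* over it:
#'
#' * **A1** (raw counters, thresholded sums, Hamming match): given the
#'   overlap composition, the column sum is `m_a * (stored bit)` plus
#'   one `o * (+/-1)` term per item overlapping in `o` rows; the exact
#'   per-bit error feeds an exact binomial match-vs-distractor
#'   summation.
#' * **A2** (binarized counters, thresholded sums): each activated row
#'   is a sign channel whose error depends on that row's own load; the
#'   recalled bit is a majority vote of `m_a` (odd) such rows.
#' * **A4** (raw counters, raw sums, dot match): given a composition
#'   with squared overlap `V = sum o^2`, the match dot product is
#'   `Normal(n_c m_a, n_c V)` and a distractor
#'   `Normal(0, n_c (m_a^2 + V))`.
#' * **A3** is predicted by the A1 model: empirically the two track each
#'   other closely, and no separate analysis is used.
#'
#' Two models of the overlap structure are available.
#' `"hypergeometric"` treats every item's activated set as an
#' independent uniform `m_a`-subset, giving a closed-form convolution
#' for the total overlap. `"geometry"` (the default) measures the
#' overlap composition from the activation rule itself on seeded random
#' address matrices; it captures the correlations the independence
#' model misses -- address labels that happen to lie close together
#' co-activate, inflating multi-row overlaps and the overlap variance
#' -- and validates noticeably better against simulation. Both are
#' deterministic for a given configuration.
#'
#' @param variant `"A1"`..`"A4"`.
#' @param m Number of hard locations.
#' @param m_a Activation count; default [sdm_activation_count()].
#' @param n_c Row width.
#' @param k Number of stored items.
#' @param distractors Number of competing codebook entries.
#' @param overlap_model `"geometry"` or `"hypergeometric"` (see above).
#' @return An `"hd_prediction"`; `bit_error` is the mixture-averaged
#'   per-bit error for A1/A2 (`NA` for A4).
#' @examples
#' predict_error_sdm("A1", m = 86, k = 1000, distractors = 99)
#' @export
predict_error_sdm <- function(variant, m, m_a = NULL, n_c = 512L, k,
                              distractors = 99L,
                              overlap_model = c("geometry", "hypergeometric")) {
  variant <- match.arg(variant, sdm_variants)
  overlap_model <- match.arg(overlap_model)
  if (variant == "A3") variant <- "A1"
  stopifnot(m >= 1, k >= 1, n_c >= 1, distractors >= 1)
  if (is.null(m_a)) m_a <- sdm_activation_count(m, k, variant)
  if (m_a > m) stop("m_a cannot exceed m")
  i1 <- distractors
  if (k == 1) {                                   # no other items: noiseless
    p0 <- if (variant %in% c("A1", "A2")) {
      perr_hamming_exact(n_c, 0, i1)
    } else {
      perr_two_normals(n_c * m_a, 0, 0, sqrt(n_c * m_a^2), i1, beats = "larger")
    }
    return(hd_prediction(p0, bit_error = if (variant == "A4") NA_real_ else 0,
                         match_dist = dist_desc("degenerate", 0, 0),
                         distractor_dist = dist_desc("normal", n_c / 2, n_c / 4)))
  }

  if (overlap_model == "geometry") {
    geo <- sample_overlap_geometry(m, m_a, k, n_c)
    if (variant == "A1") {
      comp <- geo$comp
      keys <- apply(comp, 1L, paste, collapse = ",")
      tab <- table(keys)
      uniq <- comp[match(names(tab), keys), , drop = FALSE]
      pbits <- vapply(seq_len(nrow(uniq)),
                      function(i) a1_bit_error_comp(uniq[i, ], m_a), numeric(1))
      wts <- as.numeric(tab) / sum(tab)
      p <- sum(wts * vapply(pbits, function(e) perr_hamming_exact(n_c, e, i1),
                            numeric(1)))
      bit <- sum(wts * pbits)
      return(hd_prediction(p, bit_error = bit,
                           match_dist = dist_desc("binomial mixture (geometry)",
                                                  n_c * bit, NA_real_),
                           distractor_dist = dist_desc("binomial", n_c / 2, n_c / 4)))
    }
    if (variant == "A2") {
      eps <- matrix(a2_row_error_given_w(geo$row_loads), nrow = nrow(geo$row_loads))
      ecol <- majority_error(eps)
      # items overlapping several of the target's rows write the same bit
      # into each, correlating the sign channels: redo those queries exactly
      has <- which(!vapply(geo$shared, is.null, logical(1)))
      for (qi in has) {
        ecol[qi] <- a2_query_error(geo$row_loads[, qi], geo$shared[[qi]], m_a)
      }
      atoms <- bin_atoms(ecol, rep(1, length(ecol)))
      p <- sum(atoms$p * vapply(atoms$e, function(e) perr_hamming_exact(n_c, e, i1),
                                numeric(1))) / sum(atoms$p)
      bit <- mean(ecol)
      return(hd_prediction(p, bit_error = bit,
                           match_dist = dist_desc("binomial mixture (geometry)",
                                                  n_c * bit, NA_real_),
                           distractor_dist = dist_desc("binomial", n_c / 2, n_c / 4)))
    }
    # A4: mixture over the squared-overlap statistic V
    V <- as.vector(geo$comp %*% (seq_len(ncol(geo$comp))^2))
    tab <- table(V)
    vvals <- as.numeric(names(tab)); wts <- as.numeric(tab) / sum(tab)
    pvals <- vapply(vvals, function(v) {
      perr_two_normals(n_c * m_a, sqrt(n_c * v), 0, sqrt(n_c * (m_a^2 + v)),
                       i1, beats = "larger")
    }, numeric(1))
    return(hd_prediction(sum(wts * pvals), bit_error = NA_real_,
                         match_dist = dist_desc("normal mixture (geometry)",
                                                n_c * m_a, n_c * mean(V)),
                         distractor_dist = dist_desc("normal mixture (geometry)", 0,
                                                     n_c * (m_a^2 + mean(V)))))
  }

  # closed-form hypergeometric overlap model
  if (variant == "A1") {
    wpmf <- pmf_power(overlap_item_pmf(m, m_a), k - 1)
    w <- seq_along(wpmf) - 1
    pw <- a1_bit_error_given_w(w, m_a)
    keep <- wpmf > 1e-14
    p <- sum(wpmf[keep] * vapply(pw[keep],
                                 function(e) perr_hamming_exact(n_c, e, i1),
                                 numeric(1)))
    bit <- sum(wpmf * pw)
    return(hd_prediction(min(max(p, 0), 1), bit_error = bit,
                         match_dist = dist_desc("binomial mixture over W",
                                                n_c * bit, NA_real_),
                         distractor_dist = dist_desc("binomial", n_c / 2, n_c / 4)))
  }

  if (variant == "A2") {
    # marginal overlap count of one activated row: Binom(k-1, m_a/m)
    wmax <- max(stats::qbinom(1 - 1e-12, k - 1, m_a / m), 2)
    w <- 0:wmax
    pr <- stats::dbinom(w, k - 1, m_a / m)
    eps <- a2_row_error_given_w(w)
    if (m_a == 1L) {
      atoms <- list(e = eps, p = pr)
    } else {
      atoms <- a2_pattern_mixture(eps, pr, m_a)
    }
    keep <- atoms$p > 1e-14
    p <- sum(atoms$p[keep] * vapply(atoms$e[keep],
                                    function(e) perr_hamming_exact(n_c, e, i1),
                                    numeric(1))) / sum(atoms$p[keep])
    bit <- sum(atoms$p * atoms$e) / sum(atoms$p)
    return(hd_prediction(min(max(p, 0), 1), bit_error = bit,
                         match_dist = dist_desc("binomial mixture over row pattern",
                                                n_c * bit, NA_real_),
                         distractor_dist = dist_desc("binomial", n_c / 2, n_c / 4)))
  }

  # A4
  wpmf <- pmf_power(overlap_item_pmf(m, m_a), k - 1)
  w <- seq_along(wpmf) - 1
  keep <- wpmf > 1e-14
  pvals <- vapply(w[keep], function(wi) {
    perr_two_normals(n_c * m_a, sqrt(n_c * wi), 0, sqrt(n_c * (m_a^2 + wi)),
                     i1, beats = "larger")
  }, numeric(1))
  p <- sum(wpmf[keep] * pvals)
  hd_prediction(min(max(p, 0), 1), bit_error = NA_real_,
                match_dist = dist_desc("normal mixture over W", n_c * m_a,
                                       n_c * sum(wpmf * w)),
                distractor_dist = dist_desc("normal mixture over W", 0,
                                            n_c * (m_a^2 + sum(wpmf * w))))
}

# Sign-channel error of one binarized row holding `s` independent other
# contributions plus a fixed offset `off` from shared multi-row items:
# counter = 1 + off + (2B - s), binarized by sign with a fair coin at 0.
a2_row_error_offset <- function(s, off) {
  ple <- stats::pbinom(floor((s - 2 - off) / 2), s, 0.5)
  idx <- s - 1 - off
  pm <- numeric(length(ple))
  ok <- idx %% 2 == 0 & idx >= 0 & idx <= 2 * s
  if (any(ok)) pm[ok] <- stats::dbinom(idx[ok] / 2, rep_len(s, length(ok))[ok], 0.5)
  ple + 0.5 * pm
}

# Exact per-column error for one query whose activated rows share
# `items` (each an index vector of row slots written by one multi-row
# item): enumerate the shared items' bits; rows are conditionally
# independent given those.
a2_query_error <- function(wr, items, m_a) {
  cover <- integer(m_a)
  for (it in items) cover[it] <- cover[it] + 1L
  singles <- pmax(wr - cover, 0L)
  g <- length(items)
  tot <- 0
  for (mask in 0:(2^g - 1)) {
    signs <- ifelse(bitwAnd(mask, 2^(seq_len(g) - 1)) > 0, 1L, -1L)
    off <- integer(m_a)
    for (t in seq_len(g)) off[items[[t]]] <- off[items[[t]]] + signs[t]
    tot <- tot + majority_error(matrix(a2_row_error_offset(singles, off),
                                       ncol = 1))
  }
  tot / 2^g
}

# P(majority of the rows are wrong) for a matrix of per-row error
# probabilities (rows = the m_a sign channels, columns = samples);
# m_a is odd, so no vote ties occur.
majority_error <- function(eps) {
  m_a <- nrow(eps)
  if (m_a == 1L) return(as.vector(eps))
  need <- (m_a + 1) / 2
  n <- ncol(eps)
  out <- numeric(n)
  for (mask in 0:(2^m_a - 1)) {
    inset <- bitwAnd(mask, 2^(seq_len(m_a) - 1)) > 0
    if (sum(inset) < need) next
    term <- rep(1, n)
    for (r in seq_len(m_a)) {
      term <- term * if (inset[r]) eps[r, ] else 1 - eps[r, ]
    }
    out <- out + term
  }
  out
}

# Aggregate (value, weight) atoms into narrow bins with weighted-mean
# values, to bound the number of downstream integrals.
bin_atoms <- function(e, p, nb = 400L) {
  rng <- range(e)
  if (diff(rng) == 0) return(list(e = rng[1], p = sum(p)))
  bins <- findInterval(e, seq(rng[1], rng[2], length.out = nb + 1L),
                       rightmost.closed = TRUE)
  psum <- rowsum(p, bins)
  esum <- rowsum(p * e, bins)
  list(e = as.vector(esum / psum), p = as.vector(psum))
}

# Distribution of the per-column error of an m_a-row majority vote when
# each row's sign-channel error is drawn i.i.d. from (eps, pr) atoms.
# Exact enumeration over row patterns; for larger m_a the row atoms are
# first merged to keep the pattern count near 2e6. Returns aggregated
# (e, p) atoms binned for the downstream mixture integral.
a2_pattern_mixture <- function(eps, pr, m_a, max_patterns = 2e6) {
  natoms <- max(2L, floor(max_patterns^(1 / m_a)))
  if (length(eps) > natoms) {
    grp <- ceiling(seq_along(eps) / (length(eps) / natoms))
    pg <- as.vector(rowsum(pr, grp))
    eg <- as.vector(rowsum(pr * eps, grp)) / pmax(pg, 1e-300)
    keep <- pg > 0
    eps <- eg[keep]; pr <- pg[keep]
  }
  s <- length(eps)
  n <- s^m_a
  idx <- 0:(n - 1)
  emat <- matrix(0, n, m_a)
  pvec <- rep(1, n)
  for (r in seq_len(m_a)) {
    a <- (idx %/% s^(r - 1)) %% s + 1
    emat[, r] <- eps[a]
    pvec <- pvec * pr[a]
  }
  # majority-wrong probability per pattern (Poisson-binomial over subsets)
  need <- (m_a + 1) / 2
  ecol <- numeric(n)
  for (mask in 0:(2^m_a - 1)) {
    inset <- which(bitwAnd(mask, 2^(seq_len(m_a) - 1)) > 0)
    if (length(inset) < need) next
    term <- rep(1, n)
    for (r in seq_len(m_a)) {
      term <- term * if (r %in% inset) emat[, r] else 1 - emat[, r]
    }
    ecol <- ecol + term
  }
  # aggregate into narrow bins, weighted-mean error per bin
  nb <- 400L
  rng <- range(ecol)
  if (diff(rng) == 0) return(list(e = rng[1], p = 1))
  bins <- findInterval(ecol, seq(rng[1], rng[2], length.out = nb + 1L),
                       rightmost.closed = TRUE)
  psum <- rowsum(pvec, bins)
  esum <- rowsum(pvec * ecol, bins)
  list(e = as.vector(esum / psum), p = as.vector(psum))
}

#' Dispatch the analytic predictor for any memory variant
#'
#' @param variant `"S1"`, `"S2"`, `"A1"`..`"A4"`.
#' @param dimension `n_s` (S1/S2) or `m` (SDM).
#' @param k Number of stored pairs (S1 odd-adjusts internally: an even
#'   count gains the tie-break vector as a genuine extra noise term).
#' @param distractors Competing codebook entries (default 99: recall is
#'   cleaned up against the 100-entry state codebook).
#' @param n_c SDM row width.
#' @param m_a SDM activation count override.
#' @param exact_delta Use the exact binomial per-bit error for S1.
#' @param overlap_model SDM overlap model (see [predict_error_sdm()]).
#' @return An `"hd_prediction"`.
#' @export
predict_error <- function(variant, dimension, k = 1000L, distractors = 99L,
                          n_c = 512L, m_a = NULL, exact_delta = FALSE,
                          overlap_model = c("geometry", "hypergeometric")) {
  variant <- match.arg(variant, c("S1", "S2", sdm_variants))
  switch(variant,
    S1 = {
      k_odd <- if (k %% 2 == 0) k + 1 else k
      predict_error_hamming(dimension, delta_s(k_odd, exact = exact_delta),
                            distractors)
    },
    S2 = predict_error_dot(dimension, k, distractors),
    predict_error_sdm(variant, dimension, m_a = m_a, n_c = n_c, k = k,
                      distractors = distractors, overlap_model = overlap_model))
}

#' Exact per-bit interference error of small superpositions
#'
#' Exhaustive enumeration of the per-bit recall error of a binarized
#' superposition in three structural cases:
#'
#' * `"independent"` -- one stored target bit plus four independent fair
#'   `+/-1` overlaps (three other stored vectors and the tie-break): the
#'   bit is lost when at most one overlap matches it, probability
#'   `5/16 = 0.3125`.
#' * `"eq2_turnstile"` -- the four turnstile transitions share their
#'   constituent vectors, so the four bound terms are *dependent*:
#'   enumerating all sign assignments of the participating components
#'   (plus the fair tie-break) gives `3/8 = 0.375`.
#' * `"single_term"` -- a single stored vector: no noise, error 0.
#'
#' @param structure Which dependency structure to evaluate.
#' @return The exact per-bit error probability.
#' @examples
#' interference_bit_error("independent")    # 0.3125
#' interference_bit_error("eq2_turnstile")  # 0.375
#' @export
interference_bit_error <- function(structure = c("independent", "eq2_turnstile",
                                                 "single_term")) {
  structure <- match.arg(structure)
  if (structure == "single_term") return(0)
  if (structure == "independent") {
    # stored bit +1; enumerate the 2^4 sign patterns of the overlaps
    overlaps <- as.matrix(expand.grid(rep(list(c(-1, 1)), 4)))
    s <- 1 + rowSums(overlaps)          # odd total: never zero
    return(mean(s < 0))
  }
  # turnstile: component j of the superposition involves the component-j
  # values of the input vectors (p, t), the state vectors (l, u) and the
  # component-(j-1) values of the permuted states (lp, up). Recall the
  # Token-from-Locked transition: key t o l, stored next-state bit up.
  g <- expand.grid(p = c(-1, 1), t = c(-1, 1), l = c(-1, 1), u = c(-1, 1),
                   lp = c(-1, 1), up = c(-1, 1))
  a <- with(g, p * l * lp + t * l * up + p * u * lp + t * u * up)
  recalled_nonzero <- sign(a) * g$t * g$l          # tie-break cannot flip |a| >= 2
  err <- ifelse(a == 0, 0.5, as.numeric(recalled_nonzero != g$up))
  mean(err)
}
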