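# Batched storage/recall experiments.
#
# run_recall_experiment() measures recall error rates for a memory
# variant on randomly generated automata. Each trial draws a fresh
# automaton and fresh codebooks from child seeds, stores the complete
# transition table, recalls every transition, and pools errors across
# trials. Internally the trials are vectorized over whole transition
# batches (matrix binds, one matrix product per distance computation);
# the semantics are identical to storing/recalling pair by pair with the
# object API, which the test suite verifies on small cases.

#' Run a storage/recall experiment on random automata
#'
#' Stores all `num_states * num_inputs` transitions of a random
#' finite-state automaton in the requested memory variant and recalls
#' every transition, comparing the cleaned-up result to the state
#' codebook. A recall counts as an error when the best match is wrong
#' *or* tied -- a tie is an error even if the correct state is among the
#' tied entries, mirroring the strict inequality in the analytic
#' predictors. Two estimators are reported: the direct count error rate,
#' and the PMF error rate obtained by recombining the pooled empirical
#' distributions of the match distance and the closest-distractor
#' distance (treated as independent between recalls).
#'
#' @param variant One of `"S1"`, `"S2"` (superposition) or
#'   `"A1"`..`"A4"` (SDM).
#' @param dimension Memory dimension: the vector width `n_s` for S1/S2,
#'   the number of hard locations `m` for the SDM variants.
#' @param trials Number of independent (automaton, codebook) trials.
#' @param seed Master seed; every trial derives child seeds from it.
#' @param num_states,num_inputs Automaton size (defaults 100 x 10, i.e.
#'   1,000 stored transitions and a 110-entry item memory).
#' @param n_c SDM row width (ignored for S1/S2).
#' @param m_a SDM activation count; defaults to
#'   [sdm_activation_count()] at `k = num_states * num_inputs`.
#' @return An object of class `"error_report"`; see
#'   [pmf_error_rate()] and [error_ci()].
#' @examples
#' run_recall_experiment("A1", dimension = 51, trials = 2, seed = 1)
#' @export
run_recall_experiment <- function(variant, dimension, trials = 1L, seed = 1L,
                                  num_states = 100L, num_inputs = 10L,
                                  n_c = 512L, m_a = NULL) {
  variant <- match.arg(variant, c("S1", "S2", sdm_variants))
  stopifnot(trials >= 1, dimension >= 1)
  k <- as.integer(num_states) * as.integer(num_inputs)
  sdm <- variant %in% sdm_variants
  if (sdm && is.null(m_a)) m_a <- sdm_activation_count(dimension, k, variant)

  per_trial <- vector("list", trials)
  for (t in seq_len(trials)) {
    fsa <- random_fsa(num_states, num_inputs, child_seed(seed, "fsa", t))
    cb_seed <- child_seed(seed, "codebooks", t)
    mem_seed <- child_seed(seed, "memory", t)
    per_trial[[t]] <- if (sdm) {
      sdm_trial(variant, dimension, m_a, n_c, fsa, cb_seed, mem_seed)
    } else {
      superposition_trial(variant, dimension, fsa, cb_seed, mem_seed)
    }
  }

  match_d <- unlist(lapply(per_trial, `[[`, "match_d"))
  distr_d <- unlist(lapply(per_trial, `[[`, "distr_d"))
  errors <- vapply(per_trial, `[[`, integer(1), "errors")
  mode <- if (variant %in% c("S1", "A1", "A2")) "hamming" else "dot"
  structure(list(variant = variant, dimension = as.integer(dimension),
                 m_a = if (sdm) as.integer(m_a) else NA_integer_,
                 n_c = if (sdm) as.integer(n_c) else NA_integer_,
                 k = k, trials = as.integer(trials), seed = seed,
                 mode = mode,
                 n_recalls = k * trials, n_errors = sum(errors),
                 count_error_rate = sum(errors) / (k * trials),
                 pmf_error_rate = pmf_error_rate(match_d, distr_d, mode),
                 per_trial = data.frame(trial = seq_len(trials),
                                        errors = errors, recalls = k),
                 match_d = match_d, distr_d = distr_d),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf(paste0("<error_report %s> dimension %d%s, %d trials x %d recalls\n",
                     "  count error rate %.3g (%d/%d), PMF error rate %.3g\n"),
              x$variant, x$dimension,
              if (!is.na(x$m_a)) sprintf(" (m_a = %d)", x$m_a) else "",
              x$trials, x$k, x$count_error_rate, x$n_errors, x$n_recalls,
              x$pmf_error_rate))
  invisible(x)
}

#' PMF estimator of the recall error rate
#'
#' Recombines the empirical probability mass function of the match
#' distance with the empirical distribution of the closest-distractor
#' distance, assuming the two do not change between recalls: the error
#' probability is the chance that an independently drawn closest
#' distractor beats *or ties* the match (smaller Hamming distance, or
#' larger dot product). Ties count toward error. This estimator resolves
#' error rates far below 1/n_recalls, where direct counting runs out of
#' events.
#'
#' @param match_d Match distances, one per recall.
#' @param distr_d Closest-distractor distances, one per recall.
#' @param mode `"hamming"` (smaller beats) or `"dot"` (larger beats).
#' @return The estimated error probability.
#' @export
pmf_error_rate <- function(match_d, distr_d, mode = c("hamming", "dot")) {
  mode <- match.arg(mode)
  sd_ <- sort(distr_d)
  n <- length(sd_)
  if (mode == "hamming") {
    mean(findInterval(match_d, sd_) / n)          # P(d <= h)
  } else {
    mean((n - findInterval(match_d - 0.5, sd_)) / n)  # P(d >= h), integer dots
  }
}

#' Confidence interval for the count error rate
#'
#' Clopper-Pearson interval on the pooled error count.
#'
#' @param report An `"error_report"`.
#' @param level Confidence level.
#' @return Numeric vector `c(lower, upper)`.
#' @export
error_ci <- function(report, level = 0.95) {
  as.numeric(stats::binom.test(report$n_errors, report$n_recalls,
                               conf.level = level)$conf.int)
}

# ---- internal batched trials -------------------------------------------

# transitions in column-major order over the next-state table
transition_index <- function(fsa) {
  list(si = rep(seq_len(fsa$num_states), fsa$num_inputs),
       pj = rep(seq_len(fsa$num_inputs), each = fsa$num_states),
       sk = as.vector(fsa$next_state))
}

rho_cols <- function(n) c(n, seq_len(n - 1L))      # column index for rho
rho_inv_cols <- function(n) c(seq(2L, n), 1L)      # and for rho^-1

# One superposition trial: store all transitions, recall all transitions.
superposition_trial <- function(variant, n_s, fsa, cb_seed, mem_seed) {
  n <- as.integer(n_s)
  domain <- if (variant == "S1") "binary" else "bipolar"
  cb <- fsa_codebooks(fsa, n, domain, cb_seed)
  S <- cb$state_memory$vectors
  P <- cb$input_memory$vectors
  Sro <- S[, rho_cols(n), drop = FALSE]
  tr <- transition_index(fsa)
  k <- length(tr$si)

  counters <- integer(n)
  for (i in seq_len(k)) {
    pm <- if (variant == "S1") {
      2L * ((S[tr$si[i], ] + P[tr$pj[i], ] + Sro[tr$sk[i], ]) %% 2L) - 1L
    } else {
      S[tr$si[i], ] * P[tr$pj[i], ] * Sro[tr$sk[i], ]
    }
    counters <- clamp_counters(counters + pm)
  }
  if (variant == "S1") {
    if (k %% 2L == 0L) {
      tb <- 2L * unclass(hv_random(n, "binary", child_seed(mem_seed, "tiebreak"))) - 1L
      counters <- clamp_counters(counters + tb)
    }
    sbin <- as.integer(counters > 0L)
  }

  St <- t(if (domain == "binary") 2 * S - 1 else S)  # n x num_states
  errors <- 0L
  match_d <- distr_d <- numeric(k)
  inv <- rho_inv_cols(n)
  chunks <- split(seq_len(k), ceiling(seq_len(k) / 256L))
  for (idx in chunks) {
    if (variant == "S1") {
      Q <- (S[tr$si[idx], , drop = FALSE] + P[tr$pj[idx], , drop = FALSE]) %% 2L
      flip <- which(sbin == 1L)
      noisy <- Q
      noisy[, flip] <- 1L - noisy[, flip]
      r <- noisy[, inv, drop = FALSE]
      D <- (2 * r - 1) %*% St               # agreement score: n - 2*hamming
      dist_of <- function(score) (n - score) / 2
    } else {
      Q <- S[tr$si[idx], , drop = FALSE] * P[tr$pj[idx], , drop = FALSE]
      noisy <- Q * rep(counters, each = length(idx))
      r <- noisy[, inv, drop = FALSE]
      D <- r %*% St                          # dot products
      dist_of <- identity
    }
    res <- score_matches(D, tr$sk[idx])
    errors <- errors + res$errors
    match_d[idx] <- dist_of(res$match_score)
    distr_d[idx] <- dist_of(res$distr_score)
  }
  list(errors = errors, n = k, match_d = match_d, distr_d = distr_d)
}

# One SDM trial.
sdm_trial <- function(variant, m, m_a, n_c, fsa, cb_seed, mem_seed) {
  m <- as.integer(m); n_c <- as.integer(n_c); m_a <- as.integer(m_a)
  binary <- variant %in% c("A1", "A2")
  domain <- if (binary) "binary" else "bipolar"
  cb <- fsa_codebooks(fsa, n_c, domain, cb_seed)
  S <- cb$state_memory$vectors
  P <- cb$input_memory$vectors
  Sro <- S[, rho_cols(n_c), drop = FALSE]
  tr <- transition_index(fsa)
  k <- length(tr$si)

  A <- random_bit_matrix(m, n_c, domain, child_seed(mem_seed, "addresses"))
  Q <- if (binary) {
    (S[tr$si, , drop = FALSE] + P[tr$pj, , drop = FALSE]) %% 2L
  } else {
    S[tr$si, , drop = FALSE] * P[tr$pj, , drop = FALSE]
  }
  Dat <- if (binary) (Q + Sro[tr$sk, , drop = FALSE]) %% 2L else Q * Sro[tr$sk, , drop = FALSE]

  # activation: m_a nearest labels per address, ties to the lowest index
  Qpm <- if (binary) 2 * Q - 1 else Q
  Apm <- t(if (binary) 2 * A - 1 else A)
  H <- matrix(as.integer(round((n_c - Qpm %*% Apm) / 2)), k, m)
  act <- matrix(vapply(seq_len(k),
                       function(i) order(H[i, ], method = "radix")[seq_len(m_a)],
                       integer(m_a)),
                nrow = m_a)                        # m_a x k

  # store: counters held transposed (n_c x m) so column updates recycle
  contents <- matrix(0L, n_c, m)
  pm_dat <- if (binary) 2L * Dat - 1L else Dat
  for (i in seq_len(k)) {
    cols <- act[, i]
    contents[, cols] <- clamp_counters(contents[, cols, drop = FALSE] + pm_dat[i, ])
  }

  if (variant %in% c("A2", "A3")) {
    sg <- sign(contents)
    zeros <- which(sg == 0L)
    if (length(zeros)) {
      coin <- with_seed(child_seed(mem_seed, "binarize"),
                        sample(c(-1L, 1L), length(zeros), replace = TRUE))
      sg[zeros] <- coin
    }
    contents <- sg
  }

  Z <- matrix(0, k, m)
  Z[cbind(rep(seq_len(k), each = m_a), as.vector(act))] <- 1
  sums <- Z %*% t(contents)                        # k x n_c column sums

  inv <- rho_inv_cols(n_c)
  St <- t(if (binary) 2 * S - 1 else S)
  if (binary) {
    bits <- (sums > 0) + 0L                        # threshold at zero
    r <- ((bits + Q) %% 2L)[, inv, drop = FALSE]   # release address, rho^-1
    D <- (2 * r - 1) %*% St
    dist_of <- function(score) (n_c - score) / 2
  } else {
    r <- (sums * Qpm)[, inv, drop = FALSE]
    D <- r %*% St
    dist_of <- identity
  }
  res <- score_matches(D, tr$sk)
  list(errors = res$errors, n = k,
       match_d = dist_of(res$match_score), distr_d = dist_of(res$distr_score))
}

# Given a score matrix (higher = closer) and the correct column per row,
# count errors (wrong best or tie) and extract match / best-distractor scores.
score_matches <- function(D, correct) {
  n <- nrow(D)
  b1 <- max.col(D, ties.method = "first")
  b2 <- max.col(D, ties.method = "last")
  tie <- b1 != b2
  errors <- sum(tie | b1 != correct)
  match_score <- D[cbind(seq_len(n), correct)]
  D[cbind(seq_len(n), correct)] <- -Inf
  distr_score <- D[cbind(seq_len(n), max.col(D, ties.method = "first"))]
  list(errors = errors, match_score = match_score, distr_score = distr_score)
}

#' Monte Carlo bit-error of the binarized superposition on the turnstile
#'
#' Runs the complete S1 pipeline on the four-transition turnstile
#' automaton -- fresh codebooks per trial, all four transitions stored,
#' the fair tie-break vector added (four is even), every transition
#' recalled -- and measures the fraction of recalled bits that mismatch
#' the stored next-state vector. Because the four bound transition
#' vectors share their constituent state/input vectors, this rate is
#' elevated above the independent-overlap value; compare with
#' [interference_bit_error()].
#'
#' @param width Codebook width per trial (bits sampled per transition).
#' @param trials Number of independent trials.
#' @param seed Master seed.
#' @return List with `rate` (pooled bit-error fraction), `n_bits`,
#'   `per_trial` rates, and `se` (standard error across trials).
#' @export
interference_monte_carlo <- function(width = 1000L, trials = 250L, seed = 1L) {
  fsa <- turnstile_fsa()
  tr <- transition_index(fsa)
  rate <- numeric(trials)
  for (t in seq_len(trials)) {
    cb <- fsa_codebooks(fsa, width, "binary", child_seed(seed, "cb", t))
    mem <- superposition_memory(width, "S1",
                                tiebreak_seed = child_seed(seed, "tb", t))
    for (i in seq_along(tr$si)) {
      key <- hv_bind(im_entry(cb$state_memory, tr$si[i]),
                     im_entry(cb$input_memory, tr$pj[i]))
      mem <- sm_store(mem, key, hv_permute(im_entry(cb$state_memory, tr$sk[i]), 1L))
    }
    mem <- sm_finalize(mem)
    wrong <- 0L
    for (i in seq_along(tr$si)) {
      key <- hv_bind(im_entry(cb$state_memory, tr$si[i]),
                     im_entry(cb$input_memory, tr$pj[i]))
      r <- hv_permute(sm_read(mem, key), -1L)
      wrong <- wrong + hv_hamming(r, im_entry(cb$state_memory, tr$sk[i]))
    }
    rate[t] <- wrong / (4 * width)
  }
  list(rate = mean(rate), n_bits = 4 * width * trials, per_trial = rate,
       se = stats::sd(rate) / sqrt(trials))
}

# Per-bit recall error of S1 with k random stored pairs (development /
# validation oracle for the delta_s predictor).
s1_bit_error_mc <- function(k, width, seed = 1L, memories = 1L) {
  wrong <- 0L
  for (t in seq_len(memories)) {
    base <- child_seed(seed, "mem", t)
    K <- random_bit_matrix(k, width, "binary", child_seed(base, "keys"))
    V <- random_bit_matrix(k, width, "binary", child_seed(base, "values"))
    counters <- integer(width)
    for (i in seq_len(k)) {
      counters <- clamp_counters(counters + (2L * ((K[i, ] + V[i, ]) %% 2L) - 1L))
    }
    if (k %% 2L == 0L) {
      tb <- 2L * unclass(hv_random(width, "binary", child_seed(base, "tb"))) - 1L
      counters <- clamp_counters(counters + tb)
    }
    sbin <- as.integer(counters > 0L)
    recalled <- (K[1L, ] + sbin) %% 2L
    wrong <- wrong + sum(recalled != V[1L, ])
  }
  wrong / (width * memories)
}
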