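# Resource accounting: storage (bits) and recall operation counts for
# every memory variant, as functions of the memory dimension, the
# fraction of fixed bits physically present, and the per-component cost
# of the similarity computation.

#' Bundled reference dimension table
#'
#' Estimated dimensions (vector width `n_s` for S1/S2; hard-location
#' count `m` and activation count `m_a` for A1-A4) at which each memory
#' variant stores 1,000 automaton transitions with a 110-entry codebook
#' at recall error rates `10^-1` .. `10^-9`. These are the bundled
#' reference values the resource comparisons are anchored to;
#' [find_dimension()] recomputes the S1/S2 columns from the analytic
#' predictors (and the test suite checks the agreement).
#'
#' @return A data frame with columns `variant`, `error_exponent`
#'   (r in the rate `10^-r`), `dimension`, `m_a` (`NA` for S1/S2).
#' @export
reference_dimensions <- function() {
  s1 <- c(24002, 40503, 55649, 70239, 84572, 98790, 112965, 127134, 141311)
  s2 <- c(15221, 25717, 35352, 44633, 53750, 62795, 71812, 80825, 89843)
  a1 <- c(51, 86, 125, 168, 196, 238, 285, 311, 357)
  a1ma <- c(1, 2, 2, 2, 3, 3, 3, 4, 4)
  a2 <- c(50, 97, 158, 208, 262, 322, 368, 425, 486)
  a2ma <- c(1, 1, 3, 3, 3, 3, 5, 5, 5)
  a4 <- c(31, 57, 82, 101, 129, 160, 177, 205, 238)
  a4ma <- c(1, 1, 1, 2, 2, 2, 3, 3, 3)
  data.frame(
    variant = rep(c("S1", "S2", "A1", "A2", "A3", "A4"), each = 9L),
    error_exponent = rep(1:9, 6L),
    dimension = c(s1, s2, a1, a2, a1, a4),
    m_a = c(rep(NA_integer_, 18L), a1ma, a2ma, a1ma, a4ma))
}

counter_bits <- function(variant) {
  # 1 bit per component for binarized memories, 8 for integer counters
  switch(variant, S1 = 1, S2 = 8, A1 = 8, A2 = 1, A3 = 1, A4 = 8,
         stop("unknown variant ", variant))
}

match_cost_q <- function(variant) {
  # per-component cost of the codebook match: 1 for a Hamming
  # comparison, 3.4 (measured multiply/XOR cost ratio) for a dot product
  if (variant %in% c("S1", "A1", "A2")) 1 else 3.4
}

#' Storage required by a memory variant
#'
#' Total bits, splitting "fixed bits" (codebooks, and the SDM address
#' matrix) from counter bits. Only a fraction `f_imp` of the fixed bits
#' is physically present; the remainder is assumed regenerated on
#' demand from seeds. Superposition memories occupy
#' `n_s (f_imp i_t + b_c)` bits; SDM variants occupy
#' `m n_c (b_c + f_imp) + i_t f_imp n_c` bits, where `b_c` is the bits
#' per counter (1 binarized, 8 integer).
#'
#' @param variant Memory variant.
#' @param dimension `n_s` (S1/S2) or `m` (SDM).
#' @param f_imp Fraction of fixed bits physically present, in `[0, 1]`.
#' @param n_c SDM row width.
#' @param i_t Total codebook entries (states + inputs).
#' @param b_c Bits per counter; defaults to the variant's convention.
#' @return Storage in bits.
#' @examples
#' storage_bits("S1", 98790, f_imp = 1)   # 10965690
#' @export
storage_bits <- function(variant, dimension, f_imp = 1, n_c = 512L,
                         i_t = 110L, b_c = NULL) {
  variant <- match.arg(variant, c("S1", "S2", sdm_variants))
  if (any(f_imp < 0 | f_imp > 1)) stop("f_imp must lie in [0, 1]")
  if (is.null(b_c)) b_c <- counter_bits(variant)
  if (variant %in% c("S1", "S2")) {
    dimension * (f_imp * i_t + b_c)
  } else {
    dimension * n_c * (b_c + f_imp) + i_t * f_imp * n_c
  }
}

#' Serial operation count for one recall
#'
#' Number of scalar operations to recall a vector and find its best
#' codebook match with every step serialized: release and permute, the
#' distance computation against the `i_s` state entries (cost factor
#' `q` per component for the similarity), and the final selection scan.
#' Superposition: `n_s (3 + i_s (q + 1)) + i_s`. SDM: address bind,
#' Hamming to all `m` labels, top-`m_a` selection, column sums, release,
#' inverse permutation, match:
#' `n_c (3 + m + m_a + i_s (q + 1)) + m m_a + i_s`.
#'
#' @param variant Memory variant.
#' @param dimension `n_s` or `m`.
#' @param m_a SDM activation count (required for SDM variants unless
#'   derivable via `k`).
#' @param n_c SDM row width.
#' @param i_s State-codebook entries compared at match time.
#' @param q Per-component cost of the similarity computation; defaults
#'   to 1 (Hamming) or 3.4 (dot) by variant.
#' @param k Stored-item count used to derive a default `m_a`.
#' @return Operation count.
#' @examples
#' serial_ops("S1", 24002)                      # 4872506
#' serial_ops("A1", 51, m_a = 1)                # 130711
#' @export
serial_ops <- function(variant, dimension, m_a = NULL, n_c = 512L,
                       i_s = 100L, q = NULL, k = 1000L) {
  variant <- match.arg(variant, c("S1", "S2", sdm_variants))
  if (is.null(q)) q <- match_cost_q(variant)
  if (variant %in% c("S1", "S2")) {
    dimension * (3 + i_s * (q + 1)) + i_s
  } else {
    if (is.null(m_a)) m_a <- sdm_activation_count(dimension, k, variant)
    n_c * (3 + dimension + m_a + i_s * (q + 1)) + dimension * m_a + i_s
  }
}

#' Parallel operation count for one recall
#'
#' As [serial_ops()], but operations applied across a group of vectors
#' (the codebook match, the label scan, the column sums) count as one
#' vector's worth. Superposition: `n_s (4 + q) + i_s`. SDM:
#' `n_c (5 + q) + m_a (m + 1) + i_s`.
#'
#' @inheritParams serial_ops
#' @return Operation count.
#' @export
parallel_ops <- function(variant, dimension, m_a = NULL, n_c = 512L,
                         i_s = 100L, q = NULL, k = 1000L) {
  variant <- match.arg(variant, c("S1", "S2", sdm_variants))
  if (is.null(q)) q <- match_cost_q(variant)
  if (variant %in% c("S1", "S2")) {
    dimension * (4 + q) + i_s
  } else {
    if (is.null(m_a)) m_a <- sdm_activation_count(dimension, k, variant)
    n_c * (5 + q) + m_a * (dimension + 1) + i_s
  }
}

#' Fixed-bit fraction at which two variants need equal storage
#'
#' Storage is affine in `f_imp` for every variant; this solves
#' `storage_a(f) = storage_b(f)` for `f`. Returns `NA` (with a message
#' in the `reason` attribute) when the lines are parallel or the
#' crossing lies outside `[0, 1]`.
#'
#' @param variant_a,variant_b Memory variants.
#' @param dim_a,dim_b Their dimensions.
#' @param n_c,i_t As in [storage_bits()].
#' @return The crossing fraction, or `NA` if there is none in `[0, 1]`.
#' @examples
#' crossover_fimp("S1", "A1", 98790, 238)   # ~0.082
#' @export
crossover_fimp <- function(variant_a, variant_b, dim_a, dim_b,
                           n_c = 512L, i_t = 110L) {
  s <- function(v, d, f) storage_bits(v, d, f_imp = f, n_c = n_c, i_t = i_t)
  int_a <- s(variant_a, dim_a, 0); slope_a <- s(variant_a, dim_a, 1) - int_a
  int_b <- s(variant_b, dim_b, 0); slope_b <- s(variant_b, dim_b, 1) - int_b
  if (slope_a == slope_b) {
    return(structure(NA_real_, reason = "no crossover: equal slopes"))
  }
  f <- (int_b - int_a) / (slope_a - slope_b)
  if (f < 0 || f > 1) {
    return(structure(NA_real_, reason = sprintf(
      "no crossover in [0, 1] (solution f = %.4g)", f)))
  }
  f
}

#' Storage and operation-count comparison tables
#'
#' Evaluates the storage and operation-count models for every variant
#' over a grid of error rates and fixed-bit fractions, producing the
#' data behind the dimension table, the storage-versus-`f_imp` curves
#' and the serial/parallel operation comparisons.
#'
#' @param error_exponents Error-rate exponents r (rates `10^-r`).
#' @param f_imp_grid Fixed-bit fractions to tabulate storage at.
#' @param dims `"reference"` uses the bundled [reference_dimensions()]
#'   table; `"search"` recomputes every dimension with
#'   [find_dimension()] (slower).
#' @param k,n_c,i_t,i_s Model constants.
#' @return A list of four data frames: `table2` (variant, exponent,
#'   dimension, m_a), `storage` (bits per variant/exponent/f_imp),
#'   `ops` (serial and parallel counts), `ratios` (each variant's
#'   storage and ops relative to the smallest variant at the same
#'   grid point).
#' @export
build_comparison_report <- function(error_exponents = 1:9,
                                    f_imp_grid = seq(0, 1, by = 0.1),
                                    dims = c("reference", "search"),
                                    k = 1000L, n_c = 512L, i_t = 110L,
                                    i_s = 100L) {
  dims <- match.arg(dims)
  variants <- c("S1", "S2", sdm_variants)
  tab <- if (dims == "reference") {
    reference_dimensions()
  } else {
    do.call(rbind, lapply(variants, function(v) {
      do.call(rbind, lapply(error_exponents, function(r) {
        fd <- find_dimension(v, 10^(-r), k = k, n_c = n_c)
        data.frame(variant = v, error_exponent = r,
                   dimension = fd$dimension, m_a = fd$m_a)
      }))
    }))
  }
  tab <- tab[tab$error_exponent %in% error_exponents, ]

  storage <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    data.frame(variant = row$variant, error_exponent = row$error_exponent,
               f_imp = f_imp_grid,
               bits = storage_bits(row$variant, row$dimension,
                                   f_imp = f_imp_grid, n_c = n_c, i_t = i_t))
  }))

  ops <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    ma <- if (is.na(row$m_a)) NULL else row$m_a
    data.frame(variant = row$variant, error_exponent = row$error_exponent,
               serial_ops = serial_ops(row$variant, row$dimension, m_a = ma,
                                       n_c = n_c, i_s = i_s, k = k),
               parallel_ops = parallel_ops(row$variant, row$dimension, m_a = ma,
                                           n_c = n_c, i_s = i_s, k = k))
  }))

  storage_min <- stats::aggregate(bits ~ error_exponent + f_imp, storage, min)
  names(storage_min)[names(storage_min) == "bits"] <- "min_bits"
  sr <- merge(storage, storage_min)
  sr$storage_ratio <- sr$bits / sr$min_bits
  ops_min <- stats::aggregate(cbind(serial_ops, parallel_ops) ~ error_exponent,
                              ops, min)
  names(ops_min) <- c("error_exponent", "min_serial", "min_parallel")
  orat <- merge(ops, ops_min)
  orat$serial_ratio <- orat$serial_ops / orat$min_serial
  orat$parallel_ratio <- orat$parallel_ops / orat$min_parallel
  ratios <- merge(sr[, c("variant", "error_exponent", "f_imp", "storage_ratio")],
                  orat[, c("variant", "error_exponent", "serial_ratio",
                           "parallel_ratio")],
                  by = c("variant", "error_exponent"))
  ratios <- ratios[order(ratios$variant, ratios$error_exponent, ratios$f_imp), ]
  rownames(ratios) <- NULL

  list(table2 = tab, storage = storage, ops = ops, ratios = ratios)
}
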