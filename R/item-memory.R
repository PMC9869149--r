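# Item memory (codebook / cleanup memory): the stored set of defined
# hypervectors against which noisy recalled vectors are matched.

#' Create an item memory (codebook)
#'
#' An ordered codebook of i.i.d. random hypervectors of common width and
#' domain, generated from a recorded seed, with nearest-neighbour lookup
#' by Hamming distance or dot product.
#'
#' @param n_items Number of entries.
#' @param width Vector width.
#' @param domain `"binary"` or `"bipolar"`.
#' @param seed Integer seed recorded in the object.
#' @param labels Optional character labels, one per entry.
#' @return An object of class `"item_memory"` with fields `vectors`
#'   (an `n_items x width` integer matrix, one entry per row), `labels`,
#'   `domain` and `seed`.
#' @examples
#' im <- item_memory(10, 64, "binary", seed = 1)
#' im_nearest(im, im$vectors[3, ], mode = "hamming")
#' @export
item_memory <- function(n_items, width, domain = c("binary", "bipolar"),
                        seed = NULL, labels = NULL) {
  domain <- match.arg(domain)
  stopifnot(n_items >= 1, width >= 1)
  n_items <- as.integer(n_items); width <- as.integer(width)
  m <- random_bit_matrix(n_items, width, domain, seed)
  if (is.null(labels)) labels <- as.character(seq_len(n_items))
  stopifnot(length(labels) == n_items)
  structure(list(vectors = m, labels = labels, domain = domain, seed = seed),
            class = "item_memory")
}

# n x width matrix of i.i.d. uniform components; rows are codebook entries
random_bit_matrix <- function(n, width, domain, seed = NULL) {
  draw <- function() matrix(sample(c(0L, 1L), n * width, replace = TRUE), n, width)
  m <- if (is.null(seed)) draw() else with_seed(seed, draw())
  if (domain == "bipolar") m <- 2L * m - 1L
  m
}

#' @export
print.item_memory <- function(x, ...) {
  cat(sprintf("<item_memory> %d %s entries of width %d (seed %s)\n",
              nrow(x$vectors), x$domain, ncol(x$vectors),
              if (is.null(x$seed)) "unset" else format(x$seed)))
  invisible(x)
}

#' Extract one entry of an item memory as a hypervector
#'
#' @param im An `"item_memory"`.
#' @param i Entry index.
#' @return A `"hypervector"`.
#' @export
im_entry <- function(im, i) {
  hypervector(im$vectors[i, ], im$domain)
}

#' Nearest-neighbour lookup in an item memory
#'
#' Finds the codebook entry that minimises the Hamming distance
#' (`mode = "hamming"`) or maximises the dot product (`mode = "dot"`)
#' to the query. Ties are reported, not resolved: `is_tie` is `TRUE`
#' when two or more entries attain the extremum, and the caller decides
#' whether a tie counts as a recall error (the automaton experiments
#' count it as one).
#'
#' @param im An `"item_memory"`.
#' @param query Numeric vector of the codebook width. For
#'   `mode = "hamming"` the query must take values in the codebook's
#'   two-valued domain; for `mode = "dot"` it may hold arbitrary
#'   integers (counter sums) and the codebook must be bipolar.
#' @param mode Similarity used for the match.
#' @return A list of class `"match_result"`: `best_index`,
#'   `best_distance` (Hamming count or dot product) and `is_tie`.
#' @export
im_nearest <- function(im, query, mode = c("hamming", "dot")) {
  mode <- match.arg(mode)
  m <- im$vectors
  if (nrow(m) < 1L) stop("empty item memory")
  if (length(query) != ncol(m)) stop("query width mismatch")
  q <- as.numeric(unclass(query))
  if (mode == "hamming") {
    dom <- if (im$domain == "binary") c(0, 1) else c(-1, 1)
    if (!all(q %in% dom))
      stop("hamming lookup requires a ", im$domain, "-valued query")
    d <- as.vector(rowSums(m != rep(q, each = nrow(m))))
    best <- min(d)
  } else {
    if (im$domain != "bipolar") stop("dot lookup requires a bipolar item memory")
    d <- as.vector(m %*% q)
    best <- max(d)
  }
  hits <- which(d == best)
  structure(list(best_index = hits[1L], best_distance = best,
                 is_tie = length(hits) > 1L),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> index %d, distance %g%s\n",
              x$best_index, x$best_distance, if (x$is_tie) " (tie)" else ""))
  invisible(x)
}
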