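# Hypervector primitives: the atomic representation of hyperdimensional
# computing. A hypervector is a fixed-width vector with components in
# {0, 1} (binary) or {-1, +1} (bipolar). Binding is XOR (binary) or
# component-wise multiplication (bipolar); the permutation used to mark
# sequence position is the cyclic shift by one.

#' Construct a hypervector
#'
#' @param components Integer vector of components, all in `{0, 1}` for
#'   `domain = "binary"` or `{-1, +1}` for `domain = "bipolar"`.
#' @param domain Component domain.
#' @return An object of class `"hypervector"`: an integer vector with a
#'   `domain` attribute.
#' @export
hypervector <- function(components, domain = c("binary", "bipolar")) {
  domain <- match.arg(domain)
  x <- as.integer(components)
  if (length(x) < 1L) stop("hypervector width must be >= 1")
  ok <- if (domain == "binary") all(x == 0L | x == 1L) else all(x == -1L | x == 1L)
  if (!ok) stop("components outside the ", domain, " domain")
  structure(x, domain = domain, class = "hypervector")
}

#' @export
print.hypervector <- function(x, ...) {
  n <- length(x)
  shown <- paste(utils::head(unclass(x), 16L), collapse = " ")
  cat(sprintf("<hypervector> %s, width %d\n  %s%s\n",
              hv_domain(x), n, shown, if (n > 16L) " ..." else ""))
  invisible(x)
}

hv_domain <- function(a) attr(a, "domain", exact = TRUE)

check_pair <- function(a, b) {
  if (length(a) != length(b)) stop("hypervector width mismatch")
  da <- hv_domain(a); db <- hv_domain(b)
  if (!is.null(da) && !is.null(db) && da != db) stop("hypervector domain mismatch")
}

#' Generate a random hypervector
#'
#' Components are drawn i.i.d. uniform over the domain. The same
#' `width`, `domain` and `seed` always reproduce the same vector; the
#' caller's RNG state is left untouched.
#'
#' @inheritParams hypervector
#' @param width Number of components (positive integer).
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG.
#' @return A `"hypervector"`.
#' @examples
#' hv_random(8, "binary", seed = 1)
#' @export
hv_random <- function(width, domain = c("binary", "bipolar"), seed = NULL) {
  domain <- match.arg(domain)
  if (!is.numeric(width) || length(width) != 1L || width < 1)
    stop("width must be a positive integer")
  width <- as.integer(width)
  bits <- if (is.null(seed)) {
    sample(c(0L, 1L), width, replace = TRUE)
  } else {
    with_seed(seed, sample(c(0L, 1L), width, replace = TRUE))
  }
  if (domain == "bipolar") bits <- 2L * bits - 1L
  structure(bits, domain = domain, class = "hypervector")
}

#' Bind two hypervectors
#'
#' Component-wise XOR in the binary domain, component-wise product in the
#' bipolar domain. Binding is self-inverse: `hv_bind(hv_bind(a, b), b)`
#' returns `a` exactly, which is what makes key-value release possible.
#'
#' @param a,b Hypervectors of equal width and domain.
#' @return A `"hypervector"` in the common domain.
#' @export
hv_bind <- function(a, b) {
  check_pair(a, b)
  domain <- hv_domain(a) %||% hv_domain(b)
  out <- if (identical(domain, "binary")) {
    (unclass(a) + unclass(b)) %% 2L
  } else {
    unclass(a) * unclass(b)
  }
  structure(as.integer(out), domain = domain, class = "hypervector")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Permute (cyclically shift) a hypervector
#'
#' The permutation operation is the cyclic shift by one position, applied
#' `times` times; negative `times` applies the inverse shift. The cyclic
#' shift is invertible and distributes over binding and component-wise
#' addition, which is all the sequence-role encoding requires.
#'
#' @param a A hypervector (or any vector; attributes are preserved).
#' @param times Integer number of shifts; may be negative or zero.
#' @return The shifted vector.
#' @export
hv_permute <- function(a, times = 1L) {
  n <- length(a)
  s <- as.integer(times) %% n
  if (s == 0L) return(a)
  idx <- c((n - s + 1L):n, seq_len(n - s))  # result[i] = a[i - s]
  out <- unclass(a)[idx]
  attributes(out) <- attributes(a)
  out
}

#' Hamming distance between two vectors
#'
#' Number of positions at which the components differ. Defined for
#' binary/binary and bipolar/bipolar pairs alike (a disagreement count),
#' which is how bipolar address labels are matched to bipolar queries.
#'
#' @param a,b Vectors of equal width.
#' @return Non-negative integer count.
#' @export
hv_hamming <- function(a, b) {
  check_pair(a, b)
  sum(unclass(a) != unclass(b))
}

#' Dot product similarity
#'
#' `sum(a * b)`. `a` may hold arbitrary integers (e.g. counter sums read
#' from a memory); `b` is typically a bipolar codebook entry.
#'
#' @param a Numeric vector (counter sums or a hypervector).
#' @param b A bipolar hypervector of the same width.
#' @return The integer-valued dot product.
#' @export
hv_dot <- function(a, b) {
  if (length(a) != length(b)) stop("hypervector width mismatch")
  sum(as.numeric(a) * as.numeric(b))
}
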