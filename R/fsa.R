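# Finite-state automata: the benchmark workload. A random automaton's
# complete transition table (state, input) -> next state is encoded one
# transition per stored vector into either memory family.

#' Generate a random finite-state automaton
#'
#' The transition table is complete (one next state per state-input
#' pair) with next states drawn i.i.d. uniform over the states, so
#' self-loops and repeated targets are allowed.
#'
#' @param num_states Number of states (default 100).
#' @param num_inputs Number of input symbols (default 10).
#' @param seed Integer seed; the same seed reproduces the same table.
#' @return An object of class `"fsa"` with fields `num_states`,
#'   `num_inputs`, `next_state` (a `num_states x num_inputs` integer
#'   matrix of 1-based state indices) and `seed`.
#' @examples
#' fsa <- random_fsa(100, 10, seed = 1)
#' dim(fsa$next_state)        # 100 x 10: 1000 transitions
#' @export
random_fsa <- function(num_states = 100L, num_inputs = 10L, seed = NULL) {
  if (num_states < 1 || num_inputs < 1) stop("sizes must be positive")
  num_states <- as.integer(num_states); num_inputs <- as.integer(num_inputs)
  draw <- function() matrix(sample.int(num_states, num_states * num_inputs,
                                       replace = TRUE),
                            num_states, num_inputs)
  nxt <- if (is.null(seed)) draw() else with_seed(seed, draw())
  structure(list(num_states = num_states, num_inputs = num_inputs,
                 next_state = nxt, seed = seed,
                 state_labels = as.character(seq_len(num_states)),
                 input_labels = as.character(seq_len(num_inputs))),
            class = "fsa")
}

#' The two-state turnstile automaton
#'
#' The classic turnstile controller: states Locked/Unlocked, inputs
#' Push/Token; a token unlocks, a push locks (and passes through when
#' unlocked). Its four transitions are the smallest workload in which
#' the bound-transition terms of a superposition memory are *not*
#' independent, which makes it the standard fixture for the
#' interference analysis (see [interference_bit_error()]).
#'
#' @return An `"fsa"` with 2 states and 2 inputs.
#' @export
turnstile_fsa <- function() {
  # rows: Locked, Unlocked; cols: Push, Token
  nxt <- matrix(c(1L, 1L,   # Push  -> Locked from either state
                  2L, 2L),  # Token -> Unlocked from either state
                nrow = 2, ncol = 2)
  structure(list(num_states = 2L, num_inputs = 2L, next_state = nxt,
                 seed = NULL,
                 state_labels = c("Locked", "Unlocked"),
                 input_labels = c("Push", "Token")),
            class = "fsa")
}

#' @export
print.fsa <- function(x, ...) {
  cat(sprintf("<fsa> %d states x %d inputs (%d transitions)\n",
              x$num_states, x$num_inputs, x$num_states * x$num_inputs))
  invisible(x)
}

#' Codebooks for encoding an automaton
#'
#' Two item memories -- one vector per state and one per input symbol --
#' of common width and domain, generated from child seeds of `seed`.
#'
#' @param fsa An `"fsa"`.
#' @param width Vector width (`n_s` for a superposition memory, `n_c`
#'   for an SDM).
#' @param domain `"binary"` (S1/A1/A2) or `"bipolar"` (S2/A3/A4).
#' @param seed Master seed for both codebooks.
#' @return An object of class `"fsa_codebooks"` with fields
#'   `state_memory`, `input_memory`, `width`, `domain`.
#' @export
fsa_codebooks <- function(fsa, width, domain = c("binary", "bipolar"),
                          seed = NULL) {
  domain <- match.arg(domain)
  sm <- item_memory(fsa$num_states, width, domain,
                    seed = if (is.null(seed)) NULL else child_seed(seed, "states"),
                    labels = fsa$state_labels)
  pm <- item_memory(fsa$num_inputs, width, domain,
                    seed = if (is.null(seed)) NULL else child_seed(seed, "inputs"),
                    labels = fsa$input_labels)
  structure(list(state_memory = sm, input_memory = pm,
                 width = as.integer(width), domain = domain, seed = seed),
            class = "fsa_codebooks")
}

#' Encode one transition for a superposition memory
#'
#' The transition (state `s_i`, input `p_j`) -> `s_k` is represented as
#' `state_i o input_j o rho(state_k)`: the permutation marks `s_k` as
#' playing the next-state role. Recall releases the key `s_i o p_j`
#' from the superposition and applies the inverse permutation.
#'
#' @param cb An `"fsa_codebooks"`.
#' @param s_i,p_j,s_k 1-based state, input, and next-state indices.
#' @return The bound transition `"hypervector"`.
#' @export
encode_transition_superposition <- function(cb, s_i, p_j, s_k) {
  si <- im_entry(cb$state_memory, s_i)
  pj <- im_entry(cb$input_memory, p_j)
  sk <- im_entry(cb$state_memory, s_k)
  hv_bind(hv_bind(si, pj), hv_permute(sk, 1L))
}

#' Encode one transition for an SDM
#'
#' The address is the key `a_ij = state_i o input_j`; the data vector is
#' `a_ij o rho(state_k)`. Binding the address into the data decorrelates
#' occurrences of the same next state stored under different keys, which
#' reduces interference in the contents matrix.
#'
#' @inheritParams encode_transition_superposition
#' @return A list with hypervectors `address` and `data`.
#' @export
encode_transition_sdm <- function(cb, s_i, p_j, s_k) {
  si <- im_entry(cb$state_memory, s_i)
  pj <- im_entry(cb$input_memory, p_j)
  sk <- im_entry(cb$state_memory, s_k)
  address <- hv_bind(si, pj)
  list(address = address, data = hv_bind(address, hv_permute(sk, 1L)))
}
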