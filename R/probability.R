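# False-positive calibration for the scanner: exact per-window match
# probability under an i.i.d. base model.

#' Exact window match probability under an i.i.d. base model
#'
#' Computes the probability that a random window of the descriptor's fixed
#' length satisfies every sequence constraint and every helix pairing
#' constraint, assuming bases are drawn i.i.d. For each unpaired constrained
#' position the factor is `P(base in allowed set)`; for each helix position
#' pair the factor is the joint probability that the 5' base matches its
#' pattern, the 3' base matches its pattern, and the two pair under
#' `rules` — the joint constraint cannot be factorized per position.
#'
#' The expected number of hits on a random genome of length `L` scanned on
#' both strands is approximately `2 * (L - win + 1) * p`.
#'
#' @param descriptor A `rose_descriptor` with all mismatch allowances 0.
#' @param rules A [pairing_rules()] object.
#' @param base_freq Base frequencies (A, C, G, U), default uniform.
#' @return A single probability.
#' @examples
#' d <- roseg_descriptors()$restrictive
#' match_probability(d)  # about 4.7e-11
#' @export
match_probability <- function(descriptor, rules = pairing_rules(),
                              base_freq = rep(0.25, 4)) {
  stopifnot(inherits(descriptor, "rose_descriptor"))
  if (any(vapply(descriptor$elements, `[[`, 1L, "mismatch_allowance") > 0L)) {
    stop("match_probability requires zero mismatch allowances", call. = FALSE)
  }
  stopifnot(length(base_freq) == 4, all(base_freq >= 0),
            abs(sum(base_freq) - 1) < 1e-8)
  sm <- descriptor$structure_map
  p <- 1
  for (id in names(descriptor$elements)) {
    e <- descriptor$elements[[id]]
    if (e$kind == "strand") {
      m <- iupac_matrix(e$pattern5)[1:4, , drop = FALSE]
      p <- p * prod(colSums(m * base_freq))
    } else {
      m5 <- iupac_matrix(e$pattern5)[1:4, , drop = FALSE]
      m3 <- iupac_matrix(e$pattern3)[1:4, , drop = FALSE]
      L <- ncol(m5)
      for (i in seq_len(L)) {
        a_ok <- m5[, i]
        b_ok <- m3[, L - i + 1L]  # antiparallel partner
        joint <- outer(base_freq * a_ok, base_freq * b_ok) *
          rules$matrix[1:4, 1:4]
        p <- p * sum(joint)
      }
    }
  }
  p
}

#' Expected descriptor hit count on a random sequence
#'
#' @param descriptor A `rose_descriptor` (zero allowances).
#' @param seq_len Sequence length in nt.
#' @param rules A [pairing_rules()] object.
#' @param both_strands Count windows on both strands (default `TRUE`).
#' @inheritParams match_probability
#' @return Expected number of matching windows.
#' @export
expected_hits <- function(descriptor, seq_len, rules = pairing_rules(),
                          both_strands = TRUE, base_freq = rep(0.25, 4)) {
  nw <- max(0L, seq_len - descriptor$win_len + 1L)
  (if (both_strands) 2 else 1) * nw *
    match_probability(descriptor, rules, base_freq)
}
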