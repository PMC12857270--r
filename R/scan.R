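# Fixed-window descriptor scanner.
#
# The descriptor is compiled once into flat constraint tables (per-element
# degenerate-code membership at window offsets, plus antiparallel pairing
# offset pairs), then every window start is tested with vectorized lookups.
# Mismatch allowances relax sequence-pattern violations per element; helix
# pairing is never relaxed.

# compiled-table cache: scanning many sequences with the same descriptor
# and rules (genome sets, simulations) should not re-derive the tables
.compile_cache <- new.env(parent = emptyenv())

# compile a descriptor + rules into scan tables (window offsets are 0-based)
#' @keywords internal
compile_descriptor <- function(descriptor, rules) {
  key <- paste(c(descriptor$name, format_descriptor(descriptor), rules$pairs),
               collapse = "\r")
  hit <- .compile_cache[[key]]
  if (!is.null(hit)) return(hit)
  cd <- .compile_descriptor_impl(descriptor, rules)
  .compile_cache[[key]] <- cd
  cd
}

.compile_descriptor_impl <- function(descriptor, rules) {
  sm <- descriptor$structure_map
  elems <- list()
  pairs5 <- integer(0)
  pairs3 <- integer(0)
  for (id in names(descriptor$elements)) {
    e <- descriptor$elements[[id]]
    offs <- integer(0)
    allow <- NULL
    row5 <- sm[sm$element == id & !sm$primed, ]
    m5 <- iupac_matrix(e$pattern5)
    offs <- row5$offset + seq_len(row5$length) - 1L
    allow <- m5
    if (e$kind == "helix") {
      row3 <- sm[sm$element == id & sm$primed, ]
      m3 <- iupac_matrix(e$pattern3)
      offs <- c(offs, row3$offset + seq_len(row3$length) - 1L)
      allow <- cbind(allow, m3)
      L <- row5$length
      pairs5 <- c(pairs5, row5$offset + seq_len(L) - 1L)
      pairs3 <- c(pairs3, row3$offset + L - seq_len(L))  # antiparallel partner
    }
    # drop unconstrained (any-base) positions
    constrained <- colSums(allow[1:4, , drop = FALSE]) < 4L
    elems[[id]] <- list(offs = offs[constrained],
                        allow = allow[, constrained, drop = FALSE],
                        m = e$mismatch_allowance)
  }
  pairvec <- as.vector(t(rules$matrix))  # code (a-1)*5 + b
  list(win = descriptor$win_len, elems = elems,
       pairs5 = pairs5, pairs3 = pairs3, pairvec = pairvec)
}

# 0-based window starts where the compiled descriptor matches an int-coded
# sequence
#' @keywords internal
scan_int <- function(s, cd) {
  nw <- length(s) - cd$win + 1L
  if (nw < 1L) return(integer(0))
  idx0 <- seq_len(nw)
  ok <- rep(TRUE, nw)
  for (el in cd$elems) {
    if (!length(el$offs)) next
    viol <- integer(nw)
    for (j in seq_along(el$offs)) {
      viol <- viol + !el$allow[s[idx0 + el$offs[j]], j]
    }
    ok <- ok & (viol <= el$m)
  }
  for (j in seq_along(cd$pairs5)) {
    a <- s[idx0 + cd$pairs5[j]]
    b <- s[idx0 + cd$pairs3[j]]
    ok <- ok & cd$pairvec[(a - 1L) * 5L + b]
  }
  which(ok) - 1L
}

#' Scan a nucleotide sequence for descriptor matches
#'
#' Slides the descriptor's fixed window along the sequence (and, for the
#' minus strand, along its reverse complement) and reports every window
#' where all per-element sequence constraints hold within their mismatch
#' allowances and all helix positions form admissible base pairs. `T` is
#' normalized to `U`; `N` in the input matches only unconstrained pattern
#' positions and never forms a pair.
#'
#' @param descriptor A `rose_descriptor` from [parse_descriptor()].
#' @param sequence A single DNA/RNA string (or `Biostrings` XString).
#' @param rules A [pairing_rules()] object.
#' @param strand `"+"`, `"-"` or `"both"`.
#' @param seq_id Identifier carried into the matches.
#' @return A `motif_match_list`: list of matches, each with `seq_id`,
#'   `strand`, 0-based half-open `span` on the forward reference,
#'   `element_spans` (forward coordinates; helix 3' strands keyed with a
#'   trailing `'`), `matched_rna` (the hit read 5'->3' in motif orientation)
#'   and the descriptor window layout. Sorted by (seq_id, start, strand).
#' @examples
#' d <- roseg_descriptors()$restrictive
#' hit <- scan_sequence(d, roseg_example_hit())
#' length(hit)           # 1
#' hit[[1]]$span         # 0 48
#' @export
scan_sequence <- function(descriptor, sequence, rules = pairing_rules(),
                          strand = c("both", "+", "-"), seq_id = "seq") {
  strand <- match.arg(strand)
  stopifnot(inherits(descriptor, "rose_descriptor"))
  sequence <- as.character(sequence)
  if (length(sequence) != 1L) stop("scan_sequence takes a single sequence; see scan_set()",
                                   call. = FALSE)
  s <- seq_to_int(sequence)
  cd <- compile_descriptor(descriptor, rules)
  L <- length(s)
  out <- list()
  if (strand %in% c("both", "+")) {
    for (st in scan_int(s, cd)) {
      out[[length(out) + 1L]] <- .make_match(descriptor, s, st, "+", L, seq_id)
    }
  }
  if (strand %in% c("both", "-")) {
    rc <- revcomp_int(s)
    for (st in scan_int(rc, cd)) {
      out[[length(out) + 1L]] <- .make_match(descriptor, rc, st, "-", L, seq_id)
    }
  }
  if (length(out) > 1L) {
    o <- order(vapply(out, function(m) m$span[1], 1L),
               vapply(out, function(m) m$strand, ""))
    out <- out[o]
  }
  structure(out, class = "motif_match_list", descriptor = descriptor$name)
}

# build a motif_match; s is the oriented (already reverse-complemented for
# minus strand) int sequence, st the 0-based window start on that orientation
.make_match <- function(descriptor, s, st, strand, L, seq_id) {
  sm <- descriptor$structure_map
  win <- descriptor$win_len
  if (strand == "+") {
    fstart <- st
  } else {
    fstart <- L - (st + win)
  }
  spans <- matrix(0L, nrow(sm), 2, dimnames = list(sm$ref, c("start", "end")))
  for (i in seq_len(nrow(sm))) {
    a <- sm$offset[i]
    b <- a + sm$length[i]
    if (strand == "+") {
      spans[i, ] <- c(fstart + a, fstart + b)
    } else {
      spans[i, ] <- c(fstart + win - b, fstart + win - a)
    }
  }
  structure(list(
    seq_id = seq_id,
    strand = strand,
    span = c(fstart, fstart + win),
    element_spans = spans,
    matched_rna = int_to_rna(s[(st + 1L):(st + win)]),
    layout = sm
  ), class = "motif_match")
}

#' @export
print.motif_match <- function(x, ...) {
  cat(sprintf("<motif_match> %s:%d-%d(%s) %s\n", x$seq_id, x$span[1],
              x$span[2], x$strand, x$matched_rna))
  invisible(x)
}

#' @export
print.motif_match_list <- function(x, ...) {
  cat("<motif_match_list> ", length(x), " match(es) [descriptor: ",
      attr(x, "descriptor"), "]\n", sep = "")
  if (length(x)) print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.motif_match_list <- function(x, ...) {
  if (!length(x)) {
    return(data.frame(seq_id = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      matched_rna = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    seq_id = vapply(x, `[[`, "", "seq_id"),
    strand = vapply(x, `[[`, "", "strand"),
    start = vapply(x, function(m) m$span[1], 1L),
    end = vapply(x, function(m) m$span[2], 1L),
    matched_rna = vapply(x, `[[`, "", "matched_rna"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' @export
`[.motif_match_list` <- function(x, i) {
  structure(unclass(x)[i], class = "motif_match_list",
            descriptor = attr(x, "descriptor"))
}

#' Scan a set of sequences
#'
#' Applies [scan_sequence()] to every record of a named sequence set and
#' concatenates the matches, deduplicated by (seq_id, strand, span) and
#' sorted by (seq_id, start, strand).
#'
#' @param descriptor A `rose_descriptor`.
#' @param seqs Named character vector or `Biostrings::DNAStringSet` /
#'   `RNAStringSet`.
#' @inheritParams scan_sequence
#' @return A `motif_match_list`.
#' @export
scan_set <- function(descriptor, seqs, rules = pairing_rules(),
                     strand = c("both", "+", "-")) {
  strand <- match.arg(strand)
  if (methods::is(seqs, "XStringSet")) {
    nm <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- nm
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  out <- list()
  for (id in names(seqs)) {
    m <- scan_sequence(descriptor, seqs[[id]], rules, strand, seq_id = id)
    out <- c(out, unclass(m))
  }
  # deduplicate and order independently of record order
  if (length(out)) {
    key <- vapply(out, function(m) {
      paste(m$seq_id, m$strand, m$span[1], m$span[2])
    }, "")
    out <- out[!duplicated(key)]
    o <- order(vapply(out, `[[`, "", "seq_id"),
               vapply(out, function(m) m$span[1], 1L),
               vapply(out, `[[`, "", "strand"))
    out <- out[o]
  }
  structure(out, class = "motif_match_list", descriptor = descriptor$name)
}

#' The worked 48-nt ROSE-G example sequence
#'
#' A constructed sequence matching the restrictive ROSE-G descriptor in a
#' single window: a CUGCU core paired across a purine-rich
#' Shine-Dalgarno-side strand with two opposing bulged G residues, ending in
#' an AUG start codon.
#'
#' @return A 48-character RNA string.
#' @export
roseg_example_hit <- function() {
  "AAAGCCACUGCUGGUGUCCCUAACACCAGGAGUGGCACAUCACAAAUG"
}
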