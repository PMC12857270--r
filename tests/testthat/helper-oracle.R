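# Independent brute-force oracle for the descriptor scanner, deliberately
# separate from the package's compiled scan path: every window is checked
# position by position with the oracle's own IUPAC and pairing tables. The
# descriptor's patterns are flattened once per call (plain string splitting,
# no package internals); the per-window logic is a straight double loop.

.ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), W = c("A", "U"), S = c("C", "G"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "U"), `*` = c("A", "C", "G", "U")
)

oracle_chars <- function(sequence) {
  ch <- strsplit(toupper(sequence), "")[[1]]
  ch[ch == "T"] <- "U"
  ch
}

oracle_revcomp <- function(chars) {
  rev(unname(c(A = "U", C = "G", G = "C", U = "A", N = "N")[chars]))
}

oracle_pair_set <- function(wobble = TRUE) {
  ps <- c("AU", "UA", "CG", "GC")
  if (wobble) ps <- c(ps, "GU", "UG")
  ps
}

# flatten the descriptor into per-element position/allowed-set lists and
# helix partner offsets (1-based within-window offsets). Any-base positions
# can never mismatch and are dropped; allowed sets become named logical
# vectors for O(1) lookup.
oracle_flatten <- function(descriptor) {
  sm <- descriptor$structure_map
  bases <- c("A", "C", "G", "U", "N")
  as_lut <- function(set) {
    l <- stats::setNames(bases %in% set, bases)  # N never satisfies a constraint
    l["N"] <- FALSE
    l
  }
  elems <- list()
  for (id in names(descriptor$elements)) {
    e <- descriptor$elements[[id]]
    offs <- integer(0)
    sets <- list()
    for (r in which(sm$element == id)) {
      pat <- if (sm$primed[r]) e$pattern3 else e$pattern5
      pat_ch <- strsplit(pat, "")[[1]]
      for (k in seq_along(pat_ch)) {
        allowed <- .ORACLE_IUPAC[[pat_ch[k]]]
        if (length(allowed) == 4L) next   # any base: cannot mismatch
        offs <- c(offs, sm$offset[r] + k)
        sets[[length(sets) + 1L]] <- as_lut(allowed)
      }
    }
    pair5 <- pair3 <- integer(0)
    if (e$kind == "helix") {
      r5 <- which(sm$element == id & !sm$primed)
      r3 <- which(sm$element == id & sm$primed)
      L <- sm$length[r5]
      pair5 <- sm$offset[r5] + seq_len(L)
      pair3 <- sm$offset[r3] + (L - seq_len(L) + 1L)
    }
    elems[[id]] <- list(offs = offs, sets = sets, m = e$mismatch_allowance,
                        pair5 = pair5, pair3 = pair3)
  }
  elems
}

# named logical pair lookup matrix from the oracle's pair set
oracle_pair_lut <- function(pair_set) {
  bases <- c("A", "C", "G", "U", "N")
  m <- matrix(FALSE, 5, 5, dimnames = list(bases, bases))
  for (p in pair_set) m[substr(p, 1, 1), substr(p, 2, 2)] <- TRUE
  m
}

oracle_window_ok_flat <- function(chars, start, elems, pair_lut) {
  for (el in elems) {
    mism <- 0L
    offs <- el$offs
    sets <- el$sets
    for (k in seq_along(offs)) {
      if (!sets[[k]][[chars[start + offs[k]]]]) {
        mism <- mism + 1L
        if (mism > el$m) return(FALSE)
      }
    }
    p5 <- el$pair5
    p3 <- el$pair3
    for (k in seq_along(p5)) {
      if (!pair_lut[chars[start + p5[k]], chars[start + p3[k]]]) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# kept for single-window checks on raw descriptors
oracle_window_ok <- function(chars, start, descriptor, pair_set) {
  oracle_window_ok_flat(chars, start, oracle_flatten(descriptor),
                        oracle_pair_lut(pair_set))
}

# forward-strand 0-based match starts
oracle_starts <- function(descriptor, chars, pair_set,
                          elems = oracle_flatten(descriptor),
                          pair_lut = oracle_pair_lut(pair_set)) {
  win <- descriptor$win_len
  n <- length(chars) - win + 1L
  if (n < 1L) return(integer(0))
  starts <- integer(0)
  for (s in 0:(n - 1L)) {
    if (oracle_window_ok_flat(chars, s, elems, pair_lut)) {
      starts <- c(starts, s)
    }
  }
  starts
}

# full both-strand oracle as a data frame comparable to
# as.data.frame(scan_sequence(...))
oracle_scan <- function(descriptor, sequence, wobble = TRUE, seq_id = "seq") {
  ps <- oracle_pair_set(wobble)
  plut <- oracle_pair_lut(ps)
  elems <- oracle_flatten(descriptor)
  chars <- oracle_chars(sequence)
  win <- descriptor$win_len
  L <- length(chars)
  rows <- list()
  for (s in oracle_starts(descriptor, chars, ps, elems, plut)) {
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = seq_id, strand = "+", start = s, end = s + win,
      matched_rna = paste(chars[(s + 1L):(s + win)], collapse = ""),
      stringsAsFactors = FALSE)
  }
  rc <- oracle_revcomp(chars)
  for (s in oracle_starts(descriptor, rc, ps, elems, plut)) {
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = seq_id, strand = "-", start = L - (s + win), end = L - s,
      matched_rna = paste(rc[(s + 1L):(s + win)], collapse = ""),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(seq_id = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      matched_rna = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exact window-match probability by exhaustive enumeration (tiny windows)
oracle_enumeration_probability <- function(descriptor, wobble = TRUE) {
  win <- descriptor$win_len
  stopifnot(win <= 8)
  ps <- oracle_pair_set(wobble)
  plut <- oracle_pair_lut(ps)
  elems <- oracle_flatten(descriptor)
  bases <- c("A", "C", "G", "U")
  grid <- do.call(expand.grid, c(rep(list(bases), win),
                                 stringsAsFactors = FALSE))
  hits <- 0L
  for (i in seq_len(nrow(grid))) {
    chars <- as.character(unlist(grid[i, ]))
    if (oracle_window_ok_flat(chars, 0L, elems, plut)) hits <- hits + 1L
  }
  hits / 4^win
}

# random sequence with the given GC fraction
random_seq <- function(n, gc = 0.5, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# plant a string inside a random background at a given 0-based position
plant_in <- function(background, instance, at) {
  paste0(substr(background, 1, at),
         instance,
         substr(background, at + nchar(instance) + 1, nchar(background)))
}

# random single-base substitution of a motif instance (may or may not
# destroy the match)
perturb_instance <- function(inst) {
  p <- sample(nchar(inst), 1)
  b <- sample(c("A", "C", "G", "U"), 1)
  substr(inst, p, p) <- b
  inst
}
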