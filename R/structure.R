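# Descriptor-implied secondary structure, base-pair inventory, and
# construct mutations.

#' Derive the descriptor-implied secondary structure of a hit
#'
#' Brackets the two nested helices of the terminal hairpin and dots all
#' single strands, in motif orientation (5'->3' of the hit). Named regions
#' are attached as 0-based position sets: `P2` (all helix positions), `L2`
#' (the apical loop, element s3), `SD_side` (the Shine-Dalgarno-side strand:
#' h2' through h1', including the bulged s4) and `ROSEG_core` (the 5-nt
#' core across h1-end/s2/h2-start). Additional regions (e.g. `P1`, `L1` of
#' a longer construct) may be supplied externally.
#'
#' @param match A `motif_match` with the s1 h1 s2 h2 s3 h2' s4 h1' s5 layout.
#' @param extra_regions Optional named list of 0-based integer position
#'   vectors merged into `regions`.
#' @return A `secondary_structure`: list with `dot_bracket`, `pairs`
#'   (n x 2 matrix of 0-based paired positions, 5' column first), `regions`
#'   (named list of 0-based position vectors), `length` and `bulges` (the
#'   0-based positions of the two opposing single-base bulges s2 and s4).
#' @examples
#' d <- roseg_descriptors()$restrictive
#' m <- scan_sequence(d, roseg_example_hit())[[1]]
#' to_dot_bracket(m)$dot_bracket
#' @export
to_dot_bracket <- function(match, extra_regions = NULL) {
  stopifnot(inherits(match, "motif_match"))
  .expect_layout(match, c("s1", "h1", "s2", "h2", "s3", "s4", "s5"))
  lay <- match$layout
  n <- sum(lay$length)
  db <- rep(".", n)
  pairs <- NULL
  for (id in unique(lay$element[duplicated(lay$element)])) {
    # helices appear twice (unprimed + primed)
    r5 <- lay[lay$element == id & !lay$primed, ]
    r3 <- lay[lay$element == id & lay$primed, ]
    L <- r5$length
    p5 <- r5$offset + seq_len(L) - 1L
    p3 <- r3$offset + L - seq_len(L)
    db[p5 + 1L] <- "("
    db[p3 + 1L] <- ")"
    pairs <- rbind(pairs, cbind(p5, p3))
  }
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  colnames(pairs) <- c("pos5", "pos3")
  span0 <- function(ref) {
    i <- which(lay$ref == ref)
    lay$offset[i] + seq_len(lay$length[i]) - 1L
  }
  regions <- list(
    P2 = sort(c(span0("h1"), span0("h2"), span0("h2'"), span0("h1'"))),
    L2 = span0("s3"),
    SD_side = seq.int(min(span0("h2'")), max(span0("h1'"))),
    ROSEG_core = seq.int(max(span0("h1")) - 1L, min(span0("h2")) + 1L)
  )
  if (!is.null(extra_regions)) regions <- c(regions, extra_regions)
  structure(list(
    dot_bracket = paste(db, collapse = ""),
    pairs = pairs,
    regions = regions,
    length = n,
    bulges = c(s2 = span0("s2")[1], s4 = span0("s4")[1])
  ), class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat("<secondary_structure> ", x$length, " nt, ", nrow(x$pairs),
      " pairs\n  ", x$dot_bracket, "\n", sep = "")
  invisible(x)
}

#' Inventory base pairs by identity
#'
#' Counts the paired positions of a structure by unordered base identity:
#' canonical C-G and A-U pairs and G·U wobble pairs. Paired positions whose
#' bases form none of these are counted separately under `other` and
#' reported, not silently dropped.
#'
#' @param structure A `secondary_structure`.
#' @param sequence The RNA string the structure refers to.
#' @return A `pair_counts` list: `gc`, `au`, `gu`, `other`, plus
#'   `other_pairs` (base combinations of any non-canonical pairs).
#' @export
pair_inventory <- function(structure, sequence) {
  stopifnot(inherits(structure, "secondary_structure"))
  sequence <- chartr("Tt", "Uu", toupper(as.character(sequence)))
  if (nchar(sequence) < structure$length) {
    stop("sequence shorter than structure", call. = FALSE)
  }
  counts <- list(gc = 0L, au = 0L, gu = 0L, other = 0L,
                 other_pairs = character(0))
  if (nrow(structure$pairs)) {
    for (i in seq_len(nrow(structure$pairs))) {
      a <- substr(sequence, structure$pairs[i, 1] + 1L, structure$pairs[i, 1] + 1L)
      b <- substr(sequence, structure$pairs[i, 2] + 1L, structure$pairs[i, 2] + 1L)
      key <- paste(sort(c(a, b)), collapse = "")
      if (key == "CG") counts$gc <- counts$gc + 1L
      else if (key == "AU") counts$au <- counts$au + 1L
      else if (key == "GU") counts$gu <- counts$gu + 1L
      else {
        counts$other <- counts$other + 1L
        counts$other_pairs <- c(counts$other_pairs, key)
      }
    }
  }
  class(counts) <- "pair_counts"
  counts
}

#' @export
print.pair_counts <- function(x, ...) {
  cat(sprintf("pairs: %d C-G, %d A-U, %d G.U wobble", x$gc, x$au, x$gu))
  if (x$other > 0L) {
    cat(sprintf(", %d non-canonical (%s)", x$other,
                paste(x$other_pairs, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Parse a mutation string
#'
#' Accepts substitutions like `"G32C"` (1-based position 32, `G` replaced
#' by `C`) and single-base deletions written `"ΔU36"` or `"dU36"`.
#'
#' @param x Character vector of mutation strings, or a list of already
#'   parsed specs (returned unchanged).
#' @return List of mutation specs: `kind`, `position` (1-based),
#'   `ref_base`, `alt_base`.
#' @export
parse_mutations <- function(x) {
  if (is.list(x)) return(x)
  lapply(x, function(s) {
    s0 <- s
    s <- chartr("Tt", "Uu", toupper(trimws(s)))
    s <- sub("^\u0394", "D", s)
    if (grepl("^D[ACGU][0-9]+$", s)) {
      list(kind = "deletion",
           position = as.integer(sub("^D[ACGU]", "", s)),
           ref_base = substr(s, 2, 2), alt_base = NA_character_)
    } else if (grepl("^[ACGU][0-9]+[ACGU]$", s)) {
      n <- nchar(s)
      list(kind = "substitution",
           position = as.integer(substr(s, 2, n - 1)),
           ref_base = substr(s, 1, 1), alt_base = substr(s, n, n))
    } else {
      stop("cannot parse mutation '", s0,
           "' (expected e.g. G32C, U36C, \u0394U36 or dU36)", call. = FALSE)
    }
  })
}

#' Apply substitutions and deletions to a construct sequence
#'
#' Positions are 1-based on the supplied construct sequence. Specs are
#' applied right to left so earlier positions stay valid when deletions
#' shorten the sequence; each spec's reference base is checked against the
#' sequence and a mismatch is an error (it signals the wrong construct).
#'
#' @param sequence RNA/DNA string (T normalized to U).
#' @param specs Mutation strings or parsed specs (see [parse_mutations()]).
#' @return The mutated RNA string.
#' @examples
#' apply_mutations("AAGAU", "G3C")   # "AACAU"
#' apply_mutations("AAGAU", "dU5")   # "AAGA"
#' @export
apply_mutations <- function(sequence, specs) {
  s <- chartr("Tt", "Uu", toupper(as.character(sequence)))
  specs <- parse_mutations(specs)
  if (!length(specs)) return(s)
  pos <- vapply(specs, `[[`, 1L, "position")
  specs <- specs[order(pos, decreasing = TRUE)]
  for (sp in specs) {
    p <- sp$position
    if (p < 1L || p > nchar(s)) {
      stop("mutation position ", p, " out of range (length ", nchar(s), ")",
           call. = FALSE)
    }
    have <- substr(s, p, p)
    if (have != sp$ref_base) {
      stop("reference base mismatch at position ", p, ": sequence has ",
           have, ", spec expects ", sp$ref_base,
           " (wrong construct sequence?)", call. = FALSE)
    }
    if (sp$kind == "substitution") {
      substr(s, p, p) <- sp$alt_base
    } else {
      s <- paste0(substr(s, 1L, p - 1L), substr(s, p + 1L, nchar(s)))
    }
  }
  s
}

#' Close the opposing bulges of a hit's structure
#'
#' Local re-pairing check for stabilizing mutations: if the two opposing
#' single-base bulges (the motif bulge s2 and the Shine-Dalgarno-side bulge
#' s4) can pair under the given rules — as after the bulged-G-to-C
#' substitution — the pair is added and the bracket string updated. No
#' thermodynamic folding is attempted; this only re-derives pairing at the
#' bulge.
#'
#' @param structure A `secondary_structure` carrying `bulges`.
#' @param sequence The (possibly mutated) RNA string.
#' @param rules A [pairing_rules()] object.
#' @return The structure, with `bulges_closed = TRUE` and the extra pair if
#'   the bulge bases pair; otherwise unchanged with `bulges_closed = FALSE`.
#' @export
close_bulges <- function(structure, sequence, rules = pairing_rules()) {
  stopifnot(inherits(structure, "secondary_structure"))
  sequence <- chartr("Tt", "Uu", toupper(as.character(sequence)))
  b <- structure$bulges
  a <- seq_to_int(substr(sequence, b[1] + 1L, b[1] + 1L))
  c_ <- seq_to_int(substr(sequence, b[2] + 1L, b[2] + 1L))
  if (rules$matrix[a, c_]) {
    db <- strsplit(structure$dot_bracket, "")[[1]]
    db[b[1] + 1L] <- "("
    db[b[2] + 1L] <- ")"
    structure$dot_bracket <- paste(db, collapse = "")
    pr <- rbind(structure$pairs, c(b[1], b[2]))
    structure$pairs <- pr[order(pr[, 1]), , drop = FALSE]
    structure$bulges_closed <- TRUE
  } else {
    structure$bulges_closed <- FALSE
  }
  structure
}
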