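# Internal nucleotide encoding: A=1, C=2, G=3, U=4, N=5 (unknown).
# T is silently normalized to U everywhere.

.BASES <- c("A", "C", "G", "U")

# lookup table from UTF-8 code point to internal code
.base_lut <- local({
  lut <- rep(NA_integer_, 127L)
  set <- function(chars, v) {
    for (ch in chars) lut[utf8ToInt(ch)] <<- v
  }
  set(c("A", "a"), 1L)
  set(c("C", "c"), 2L)
  set(c("G", "g"), 3L)
  set(c("U", "u", "T", "t"), 4L)
  set(c("N", "n"), 5L)
  lut
})

#' @keywords internal
seq_to_int <- function(x) {
  cp <- utf8ToInt(x)
  if (any(cp > 127L)) {
    stop("sequence contains non-ASCII characters", call. = FALSE)
  }
  v <- .base_lut[cp]
  if (anyNA(v)) {
    bad <- unique(substring(x, which(is.na(v)), which(is.na(v))))
    stop("invalid sequence character(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  v
}

#' @keywords internal
int_to_rna <- function(v) {
  paste(c(.BASES, "N")[v], collapse = "")
}

# reverse complement on internal codes (N stays N)
#' @keywords internal
revcomp_int <- function(v) {
  rev(c(4L, 3L, 2L, 1L, 5L)[v])
}

#' @keywords internal
revcomp_rna <- function(x) int_to_rna(revcomp_int(seq_to_int(x)))

# IUPAC degenerate codes -> logical membership over A,C,G,U.
# "*" is the descriptor dialect's any-base wildcard, synonymous with N.
.IUPAC <- list(
  A = c(TRUE, FALSE, FALSE, FALSE), C = c(FALSE, TRUE, FALSE, FALSE),
  G = c(FALSE, FALSE, TRUE, FALSE), U = c(FALSE, FALSE, FALSE, TRUE),
  R = c(TRUE, FALSE, TRUE, FALSE),  Y = c(FALSE, TRUE, FALSE, TRUE),
  W = c(TRUE, FALSE, FALSE, TRUE),  S = c(FALSE, TRUE, TRUE, FALSE),
  K = c(FALSE, FALSE, TRUE, TRUE),  M = c(TRUE, TRUE, FALSE, FALSE),
  B = c(FALSE, TRUE, TRUE, TRUE),   D = c(TRUE, FALSE, TRUE, TRUE),
  H = c(TRUE, TRUE, FALSE, TRUE),   V = c(TRUE, TRUE, TRUE, FALSE),
  N = c(TRUE, TRUE, TRUE, TRUE),    `*` = c(TRUE, TRUE, TRUE, TRUE)
)

#' @keywords internal
iupac_matrix <- function(pattern) {
  ch <- strsplit(pattern, "", fixed = TRUE)[[1]]
  m <- vapply(ch, function(c) {
    set <- .IUPAC[[c]]
    if (is.null(set)) stop("illegal pattern character: ", c, call. = FALSE)
    set
  }, logical(4))
  # rows = A,C,G,U membership; extra N row: an unknown input base never
  # satisfies a constrained position
  rbind(m, FALSE)
}

#' Base-pairing rules for helix elements
#'
#' Defines which unordered base pairs are admissible inside descriptor
#' helices. The default is Watson-Crick plus the G·U wobble pair, the set
#' consistent with validated thermometer stems; strict Watson-Crick is
#' available via `wobble = FALSE` or an explicit pair list.
#'
#' @param pairs Character vector of unordered pairs, e.g. `c("AU","CG","GU")`.
#' @param wobble If `pairs` is missing, include G·U wobble (default `TRUE`).
#' @return An object of class `pairing_rules` wrapping a 4x4 logical matrix.
#' @examples
#' pairing_rules()                 # WC + wobble
#' pairing_rules(wobble = FALSE)   # strict WC
#' @export
pairing_rules <- function(pairs = NULL, wobble = TRUE) {
  if (is.null(pairs)) {
    pairs <- if (wobble) c("AU", "CG", "GU") else c("AU", "CG")
  }
  m <- matrix(FALSE, 5, 5, dimnames = list(c(.BASES, "N"), c(.BASES, "N")))
  for (p in pairs) {
    p <- chartr("T", "U", toupper(p))
    if (nchar(p) != 2L) stop("pair must be two bases: ", p, call. = FALSE)
    a <- seq_to_int(substr(p, 1, 1)); b <- seq_to_int(substr(p, 2, 2))
    if (a == 5L || b == 5L) stop("N cannot appear in a pairing rule", call. = FALSE)
    m[a, b] <- TRUE
    m[b, a] <- TRUE
  }
  if (!any(m)) stop("pairing rules must allow at least one pair", call. = FALSE)
  structure(list(matrix = m, pairs = sort(unique(pairs))),
            class = "pairing_rules")
}

#' @export
print.pairing_rules <- function(x, ...) {
  cat("pairing rules:", paste(x$pairs, collapse = ", "), "\n")
  invisible(x)
}
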