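# Structural descriptor parsing.
#
# Dialect: first non-comment line is a whitespace-separated structure map,
# e.g. "s1 h1 s2 h2 s3 h2' s4 h1' s5"; a primed reference (h1') is the 3'
# strand of helix h1. Each following line defines one element:
#   strand:  <id> <mismatch or mismatch:insertion> <pattern>
#   helix:   <id> <mismatch:insertion> <pattern5>:<pattern3>
# Both helix strand patterns are written 5'->3'; pairing is antiparallel
# (pattern5[i] against pattern3[L-1-i]). "#" starts a comment. This subset
# is fixed-length: helix strands must have equal length and
# insertion allowances must be 0.

# normalize typographic characters the dialect is printed with
.normalize_descriptor_text <- function(text) {
  text <- gsub("\u2217", "*", text)            # asterisk operator
  text <- gsub("[\u2032\u2019]", "'", text)    # prime / right quote
  text
}

#' Parse a structural motif descriptor
#'
#' Reads the descriptor dialect used for thermometer motif searches: an
#' ordered structure map of single-stranded and helical elements, each with
#' degenerate-nucleotide sequence constraints and a per-element mismatch
#' allowance. `T` in patterns is normalized to `U`; `*` and `N` both match
#' any base (kept distinct for round-trip fidelity).
#'
#' @param text Descriptor source: a single string (possibly multi-line) or a
#'   character vector of lines.
#' @param name Optional descriptor name.
#' @return An object of class `rose_descriptor` with fields `name`,
#'   `structure_map` (data frame of element references with window offsets),
#'   `elements` (named list of element specs) and `win_len` (fixed window
#'   length in nt).
#' @examples
#' d <- parse_descriptor(c(
#'   "s1 h1 s2",
#'   "s1 0 NN",
#'   "h1 0:0 GC:GC",
#'   "s2 0 AUG"))
#' d$win_len  # 9
#' @export
parse_descriptor <- function(text, name = "descriptor") {
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  text <- .normalize_descriptor_text(text)
  text <- sub("#.*$", "", text)
  text <- trimws(text)
  text <- sub("\\.$", "", text)    # tolerate a sentence-final period
  lines <- text[nzchar(text)]
  if (length(lines) < 2L) {
    stop("descriptor needs a structure map line and at least one element definition",
         call. = FALSE)
  }

  refs <- strsplit(lines[1], "\\s+")[[1]]
  defs <- lines[-1]

  elements <- list()
  for (ln in defs) {
    tok <- strsplit(ln, "\\s+")[[1]]
    if (length(tok) != 3L) {
      stop("malformed element definition: '", ln, "'", call. = FALSE)
    }
    id <- tok[1]
    allow <- strsplit(tok[2], ":", fixed = TRUE)[[1]]
    if (!all(grepl("^[0-9]+$", allow)) || length(allow) > 2L) {
      stop("malformed allowance '", tok[2], "' for element ", id, call. = FALSE)
    }
    mismatch <- as.integer(allow[1])
    insertion <- if (length(allow) == 2L) as.integer(allow[2]) else 0L
    if (insertion > 0L) {
      stop("insertion allowances are not supported in this dialect subset (element ",
           id, ")", call. = FALSE)
    }
    pat <- chartr("Tt", "Uu", toupper(tok[3]))
    if (grepl(":", pat, fixed = TRUE)) {
      halves <- strsplit(pat, ":", fixed = TRUE)[[1]]
      if (length(halves) != 2L || !all(nzchar(halves))) {
        stop("helix ", id, " must have two ':'-separated strand patterns",
             call. = FALSE)
      }
      if (nchar(halves[1]) != nchar(halves[2])) {
        stop("helix ", id, " strands have unequal length (",
             nchar(halves[1]), " vs ", nchar(halves[2]), ")", call. = FALSE)
      }
      .check_pattern_chars(halves[1], id)
      .check_pattern_chars(halves[2], id)
      elements[[id]] <- list(id = id, kind = "helix",
                             mismatch_allowance = mismatch,
                             insertion_allowance = insertion,
                             pattern5 = halves[1], pattern3 = halves[2])
    } else {
      .check_pattern_chars(pat, id)
      elements[[id]] <- list(id = id, kind = "strand",
                             mismatch_allowance = mismatch,
                             insertion_allowance = insertion,
                             pattern5 = pat, pattern3 = NULL)
    }
  }

  base <- sub("'$", "", refs)
  primed <- grepl("'$", refs)
  missing <- setdiff(unique(base), names(elements))
  if (length(missing)) {
    stop("structure map references undefined element(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unused <- setdiff(names(elements), base)
  if (length(unused)) {
    stop("element(s) defined but absent from structure map: ",
         paste(unused, collapse = ", "), call. = FALSE)
  }
  for (id in names(elements)) {
    hits <- which(base == id)
    if (elements[[id]]$kind == "helix") {
      if (sum(!primed[hits]) != 1L || sum(primed[hits]) != 1L) {
        stop("helix ", id, " must appear exactly once unprimed and once primed",
             call. = FALSE)
      }
      if (which(base == id & !primed) > which(base == id & primed)) {
        stop("helix ", id, " has its primed strand before its unprimed strand",
             call. = FALSE)
      }
    } else {
      if (length(hits) != 1L || any(primed[hits])) {
        stop("strand ", id, " must appear exactly once, unprimed", call. = FALSE)
      }
    }
  }
  # proper nesting of helix intervals (positions in the structure map)
  helices <- names(elements)[vapply(elements, function(e) e$kind, "") == "helix"]
  iv <- cbind(
    open  = vapply(helices, function(h) which(base == h & !primed), 1L),
    close = vapply(helices, function(h) which(base == h & primed), 1L)
  )
  if (length(helices) > 1L) {
    for (i in seq_along(helices)) {
      for (j in seq_along(helices)) {
        if (i == j) next
        crossing <- iv[i, 1] < iv[j, 1] && iv[j, 1] < iv[i, 2] && iv[i, 2] < iv[j, 2]
        if (crossing) {
          stop("helices ", helices[i], " and ", helices[j],
               " cross (pseudoknots are not supported)", call. = FALSE)
        }
      }
    }
  }

  len <- vapply(seq_along(refs), function(i) {
    nchar(elements[[base[i]]]$pattern5)
  }, 1L)
  off <- c(0L, cumsum(len))[seq_along(refs)]
  structure_map <- data.frame(
    ref = refs, element = base, primed = primed,
    offset = off, length = len, stringsAsFactors = FALSE
  )

  structure(list(name = name, structure_map = structure_map,
                 elements = elements,
                 win_len = sum(len)),
            class = "rose_descriptor")
}

.check_pattern_chars <- function(pat, id) {
  ok <- strsplit("ACGUNRYWSKMBDHV*", "")[[1]]
  ch <- strsplit(pat, "")[[1]]
  bad <- setdiff(ch, ok)
  if (length(bad)) {
    stop("illegal pattern character(s) in element ", id, ": ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  if (!length(ch)) stop("empty pattern in element ", id, call. = FALSE)
}

#' Read a descriptor from a file
#'
#' @param path Path to a descriptor file in the dialect of
#'   [parse_descriptor()].
#' @param name Descriptor name; defaults to the file base name.
#' @return A `rose_descriptor`.
#' @export
read_descriptor <- function(path, name = NULL) {
  if (!file.exists(path)) stop("descriptor file not found: ", path, call. = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  parse_descriptor(readLines(path, warn = FALSE), name = name)
}

#' Built-in ROSE-G search descriptors
#'
#' Returns the two descriptors used for ROSE-G motif discovery: a
#' `permissive` one (any base opposite the Shine-Dalgarno-side bulge) that
#' also captures ROSE-like variants, and a `restrictive` one requiring the
#' double bulged-G arrangement diagnostic of ROSE-G.
#'
#' @return Named list of two `rose_descriptor` objects.
#' @examples
#' roseg_descriptors()$restrictive$win_len  # 48
#' @export
roseg_descriptors <- function() {
  dir <- system.file("extdata", package = "roseg")
  list(
    permissive = read_descriptor(file.path(dir, "roseg_permissive.dsc")),
    restrictive = read_descriptor(file.path(dir, "roseg_restrictive.dsc"))
  )
}

#' @export
print.rose_descriptor <- function(x, ...) {
  cat("<rose_descriptor> ", x$name, ": ",
      paste(x$structure_map$ref, collapse = " "),
      " (window ", x$win_len, " nt)\n", sep = "")
  for (e in x$elements) {
    pat <- if (e$kind == "helix") paste0(e$pattern5, ":", e$pattern3) else e$pattern5
    cat(sprintf("  %-4s %-6s %d:%d  %s\n", e$id, e$kind,
                e$mismatch_allowance, e$insertion_allowance, pat))
  }
  invisible(x)
}

#' Serialize a descriptor back to its source dialect
#'
#' @param descriptor A `rose_descriptor`.
#' @return Character vector of lines round-tripping through
#'   [parse_descriptor()].
#' @export
format_descriptor <- function(descriptor) {
  sm <- paste(descriptor$structure_map$ref, collapse = " ")
  defs <- vapply(descriptor$elements, function(e) {
    if (e$kind == "helix") {
      paste(e$id, paste0(e$mismatch_allowance, ":", e$insertion_allowance),
            paste0(e$pattern5, ":", e$pattern3))
    } else {
      paste(e$id, e$mismatch_allowance, e$pattern5)
    }
  }, "")
  c(sm, unname(defs))
}
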