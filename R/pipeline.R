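# Candidate pipeline: classify matches and join them to downstream genes.

.expect_layout <- function(match, refs) {
  missing <- setdiff(refs, rownames(match$element_spans))
  if (length(missing)) {
    stop("match lacks expected element(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
}

# motif-orientation [start,end) (0-based) of an element within matched_rna
.motif_span <- function(match, ref) {
  i <- which(match$layout$ref == ref)
  c(match$layout$offset[i], match$layout$offset[i] + match$layout$length[i])
}

#' Classify a motif hit as ROSE-G or relaxed
#'
#' Reads the 5-nt core across the end of helix 1, the bulged single strand
#' s2 and the start of helix 2 (the CUGCU core in canonical ROSE-G), and the
#' opposing single-base bulge s4 on the Shine-Dalgarno side. A hit is called
#' `ROSE_G` when the core is exactly `CUGCU` *and* the opposing bulge is a
#' `G` (the diagnostic double bulged-G arrangement); anything else —
#' including the ROSE-like `U(U/C)GCU` consensus — is `RELAXED`.
#'
#' @param match A `motif_match` from a descriptor with the
#'   s1 h1 s2 h2 s3 h2' s4 h1' s5 layout.
#' @return List with `motif_class` (`"ROSE_G"` or `"RELAXED"`) and
#'   `motif_string` (the 5-nt core).
#' @export
classify_motif <- function(match) {
  stopifnot(inherits(match, "motif_match"))
  .expect_layout(match, c("h1", "s2", "h2", "s4"))
  h1 <- .motif_span(match, "h1")
  s2 <- .motif_span(match, "s2")
  h2 <- .motif_span(match, "h2")
  s4 <- .motif_span(match, "s4")
  rna <- match$matched_rna
  core <- paste0(substr(rna, h1[2] - 1L, h1[2]),
                 substr(rna, s2[1] + 1L, s2[2]),
                 substr(rna, h2[1] + 1L, h2[1] + 2L))
  s4_base <- substr(rna, s4[1] + 1L, s4[2])
  cls <- if (core == "CUGCU" && s4_base == "G") "ROSE_G" else "RELAXED"
  list(motif_class = cls, motif_string = core)
}

# forward-reference coordinate of the first base of the descriptor's
# terminal AUG (the last 3 nt of s5 in motif orientation)
#' @keywords internal
match_aug_start <- function(match) {
  s5 <- match$element_spans["s5", ]
  if (match$strand == "+") unname(s5["end"] - 3L) else unname(s5["start"] + 2L)
}

#' Join motif matches to downstream gene starts
#'
#' Each match carries its own start codon (the descriptor window ends in
#' `NNAUG`), so by default a candidate is kept only when an annotated CDS
#' start coincides with the descriptor's terminal AUG (`max_offset = 0`); a
#' wider window tolerates small disagreements between annotation and
#' descriptor placement. Matches on sequences without any same-strand gene
#' are retained unjoined and flagged (`gene_id = NA`). Duplicate hits
#' (identical seq_id, strand and span) are collapsed first.
#'
#' @param matches A `motif_match_list`.
#' @param genes Data frame with columns `gene_id`, `seq_id`, `strand`,
#'   `cds_start` (0-based forward coordinate of the start codon's first
#'   base) and optionally `product` (e.g. from [read_gff_genes()]).
#' @param max_offset Maximum tolerated |AUG start - annotated start| in nt.
#' @return A candidate table (data frame) with columns `seq_id`, `strand`,
#'   `start`, `end`, `gene_id`, `offset`, `motif_class`, `motif_string`,
#'   `matched_rna`, `product`.
#' @export
annotate_candidates <- function(matches, genes = NULL, max_offset = 0L) {
  stopifnot(inherits(matches, "motif_match_list"))
  if (is.null(genes)) {
    genes <- data.frame(gene_id = character(0), seq_id = character(0),
                        strand = character(0), cds_start = integer(0),
                        product = character(0), stringsAsFactors = FALSE)
  }
  if (!"product" %in% names(genes)) genes$product <- NA_character_
  # collapse duplicates across iterative searches
  if (length(matches)) {
    key <- vapply(matches, function(m) {
      paste(m$seq_id, m$strand, m$span[1], m$span[2])
    }, "")
    matches <- matches[!duplicated(key)]
  }
  rows <- lapply(matches, function(m) {
    cl <- classify_motif(m)
    aug <- match_aug_start(m)
    cand <- genes[genes$seq_id == m$seq_id & genes$strand == m$strand, ]
    if (!nrow(cand)) {
      gene_id <- NA_character_; offset <- NA_integer_; product <- NA_character_
    } else {
      offs <- aug - cand$cds_start
      i <- which.min(abs(offs))
      if (abs(offs[i]) > max_offset) return(NULL)  # joined but too far: drop
      gene_id <- cand$gene_id[i]; offset <- as.integer(offs[i])
      product <- cand$product[i]
    }
    data.frame(seq_id = m$seq_id, strand = m$strand,
               start = m$span[1], end = m$span[2],
               gene_id = gene_id, offset = offset,
               motif_class = cl$motif_class, motif_string = cl$motif_string,
               matched_rna = m$matched_rna, product = product,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(seq_id = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      gene_id = character(0), offset = integer(0),
                      motif_class = character(0), motif_string = character(0),
                      matched_rna = character(0), product = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$seq_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan, annotate and classify in one call
#'
#' Convenience wrapper running [scan_set()], [annotate_candidates()] and
#' per-hit classification over a sequence set.
#'
#' @inheritParams scan_set
#' @inheritParams annotate_candidates
#' @return List with `matches` (a `motif_match_list`) and `candidates` (the
#'   candidate table).
#' @export
rose_pipeline <- function(descriptor, seqs, genes = NULL,
                          rules = pairing_rules(),
                          strand = c("both", "+", "-"), max_offset = 0L) {
  matches <- scan_set(descriptor, seqs, rules, match.arg(strand))
  list(matches = matches,
       candidates = annotate_candidates(matches, genes, max_offset))
}
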