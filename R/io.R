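# Standard-format IO. FASTA via Biostrings; GFF3/BED via rtracklayer.
# Coordinates are 0-based half-open internally and in BED; GFF3 is 1-based
# fully closed and converted on the way in/out.

#' Read sequences from a FASTA file
#'
#' @param path FASTA file (DNA or RNA alphabet; `T`/`U` both accepted).
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read gene annotations (CDS starts) from GFF3
#'
#' Extracts CDS features and reduces each to the forward-reference, 0-based
#' coordinate of its start codon's first base: the feature `start - 1` on
#' the plus strand, `end - 1` on the minus strand.
#'
#' @param path GFF3 file.
#' @param feature Feature type to use (default `"CDS"`).
#' @return Data frame with `gene_id`, `seq_id`, `strand`, `cds_start`,
#'   `product`, suitable for [annotate_candidates()].
#' @export
read_gff_genes <- function(path, feature = "CDS") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path, call. = FALSE)
  g <- rtracklayer::import(path, format = "gff3")
  g <- g[as.character(g$type) == feature]
  if (!length(g)) {
    return(data.frame(gene_id = character(0), seq_id = character(0),
                      strand = character(0), cds_start = integer(0),
                      product = character(0), stringsAsFactors = FALSE))
  }
  md <- S4Vectors::mcols(g)
  pick <- function(cols) {
    for (c in cols) {
      if (c %in% names(md)) {
        v <- md[[c]]
        if (methods::is(v, "List") || is.list(v)) {
          v <- vapply(as.list(v), function(e) {
            if (length(e)) as.character(e[[1]]) else NA_character_
          }, "")
        } else {
          v <- as.character(v)
        }
        if (any(!is.na(v))) return(v)
      }
    }
    rep(NA_character_, length(g))
  }
  ids <- pick(c("ID", "locus_tag", "gene", "Name"))
  ids[is.na(ids)] <- paste0("cds_", which(is.na(ids)))
  strand <- as.character(BiocGenerics::strand(g))
  data.frame(
    gene_id = ids,
    seq_id = as.character(GenomicRanges::seqnames(g)),
    strand = strand,
    cds_start = ifelse(strand == "-",
                       BiocGenerics::end(g) - 1L,
                       BiocGenerics::start(g) - 1L),
    product = pick("product"),
    stringsAsFactors = FALSE
  )
}

#' Write gene annotations as GFF3
#'
#' @param genes Data frame with `gene_id`, `seq_id`, `strand`, `cds_start`,
#'   optionally `cds_end` (0-based half-open end; defaults to a 90-nt CDS)
#'   and `product`.
#' @param path Output path.
#' @export
write_gff_genes <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    st <- genes$strand[i]
    first <- genes$cds_start[i]
    len <- if ("cds_len" %in% names(genes)) genes$cds_len[i] else 90L
    if (st == "+") {
      g_start <- first + 1L           # 1-based inclusive
      g_end <- first + len
    } else {
      g_end <- first + 1L
      g_start <- max(1L, first - len + 2L)
    }
    attrs <- paste0("ID=", genes$gene_id[i])
    if ("product" %in% names(genes) && !is.na(genes$product[i])) {
      attrs <- paste0(attrs, ";product=", genes$product[i])
    }
    writeLines(paste(genes$seq_id[i], "roseg", "CDS", g_start, g_end, ".",
                     st, "0", attrs, sep = "\t"), con)
  }
  invisible(path)
}

#' Write a candidate table as TSV
#'
#' @param candidates Candidate table from [annotate_candidates()].
#' @param path Output path.
#' @param header Optional character vector of `#`-prefixed provenance lines.
#' @export
write_candidates_tsv <- function(candidates, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(candidates, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a candidate table written by [write_candidates_tsv()]
#' @param path TSV path.
#' @return Data frame.
#' @export
read_candidates_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write match spans as BED6
#'
#' BED is 0-based half-open, matching the internal coordinate convention.
#' The name field carries the motif class when available.
#'
#' @param candidates Candidate table (or data frame with `seq_id`, `start`,
#'   `end`, `strand`, optionally `motif_class`).
#' @param path Output path.
#' @export
write_bed <- function(candidates, path) {
  name <- if ("motif_class" %in% names(candidates)) {
    candidates$motif_class
  } else {
    rep(".", nrow(candidates))
  }
  df <- data.frame(candidates$seq_id, candidates$start, candidates$end,
                   name, 0L, candidates$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
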