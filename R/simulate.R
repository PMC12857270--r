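# Synthetic-data generators: genomes with planted motif instances and truth
# annotations, replicate reporter-assay tables with configured fold
# effects, and probing lane profiles with region-wise cleavage enhancement.
#
# Every generator seeds the RNG from its config, so identical configs give
# byte-identical output.

#' Simulation configuration
#'
#' Bundles the stated experimental world: genome background composition and
#' number of planted motif instances; replicate structure and fold effects
#' of the reporter assays (defaults: 3 biological replicates, 10 %
#' multiplicative noise, 4.1-fold induction at 42 degC as measured for the
#' validated wild-type thermometer, 2-fold at 37 degC); and probing
#' cleavage rates (unpaired positions cleave 3x faster than paired).
#'
#' @param seed Integer RNG seed.
#' @param genome_length Genome length in nt.
#' @param gc_fraction Background GC fraction (0..1, exclusive).
#' @param n_planted Number of planted motif instances.
#' @param plant_strands `"+"`, `"-"` or `"both"` (alternating).
#' @param plant_mutations Mutation strings applied to every planted
#'   instance (1-based positions on the 48-nt instance), or a list with one
#'   character vector per plant.
#' @param assay List: `base_activity` (Miller units at 25 degC),
#'   `base_a420` (in vitro readout at 25 degC), `fold_37`, `fold_42`, `cv`
#'   (coefficient of variation of the multiplicative noise), `n_reps`.
#' @param probing List: `paired_rate`, `unpaired_rate`, `noise_cv`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, genome_length = 100000L, gc_fraction = 0.5,
                       n_planted = 5L, plant_strands = "both",
                       plant_mutations = NULL,
                       assay = list(), probing = list()) {
  stopifnot(gc_fraction > 0, gc_fraction < 1, n_planted >= 0)
  a <- utils::modifyList(list(base_activity = 100, base_a420 = 0.1,
                              fold_37 = 2, fold_42 = 4.1, cv = 0.1,
                              n_reps = 3L), assay)
  p <- utils::modifyList(list(paired_rate = 1, unpaired_rate = 3,
                              noise_cv = 0.1), probing)
  stopifnot(a$cv >= 0, a$n_reps >= 1, p$paired_rate > 0, p$unpaired_rate > 0,
            p$noise_cv >= 0)
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 gc_fraction = gc_fraction, n_planted = as.integer(n_planted),
                 plant_strands = match.arg(plant_strands, c("both", "+", "-")),
                 plant_mutations = plant_mutations,
                 assay = a, probing = p),
            class = "sim_config")
}

# mean-one multiplicative lognormal noise with coefficient of variation cv
.mult_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Sample one motif instance conforming to a descriptor
#'
#' Draws each unpaired position uniformly from its allowed base set and
#' each helix position pair jointly and uniformly from the ordered pairs
#' that satisfy both strand patterns *and* the pairing rules, so the result
#' matches the descriptor in a single window covering it (verified by
#' construction; property-tested against the scanner). Uses the current
#' RNG state; seed with `set.seed()` for reproducibility.
#'
#' @param descriptor A fixed-length `rose_descriptor`.
#' @param rules A [pairing_rules()] object.
#' @return An RNA string of length `descriptor$win_len`.
#' @export
sample_motif_instance <- function(descriptor, rules = pairing_rules()) {
  sm <- descriptor$structure_map
  out <- integer(descriptor$win_len)
  for (id in names(descriptor$elements)) {
    e <- descriptor$elements[[id]]
    if (e$kind == "strand") {
      m <- iupac_matrix(e$pattern5)[1:4, , drop = FALSE]
      off <- sm$offset[sm$ref == id]
      for (i in seq_len(ncol(m))) {
        ok <- which(m[, i])
        out[off + i] <- if (length(ok) == 1L) ok else sample(ok, 1L)
      }
    } else {
      m5 <- iupac_matrix(e$pattern5)[1:4, , drop = FALSE]
      m3 <- iupac_matrix(e$pattern3)[1:4, , drop = FALSE]
      off5 <- sm$offset[sm$element == id & !sm$primed]
      off3 <- sm$offset[sm$element == id & sm$primed]
      L <- ncol(m5)
      for (i in seq_len(L)) {
        cand <- which(outer(m5[, i], m3[, L - i + 1L]) &
                        rules$matrix[1:4, 1:4], arr.ind = TRUE)
        if (!nrow(cand)) {
          stop("unsatisfiable pattern/pairing combination in helix ", id,
               " position ", i, call. = FALSE)
        }
        k <- if (nrow(cand) == 1L) 1L else sample(nrow(cand), 1L)
        out[off5 + i] <- cand[k, 1]
        out[off3 + L - i + 1L] <- cand[k, 2]
      }
    }
  }
  int_to_rna(out)
}

#' Generate a genome with planted motif instances and truth annotations
#'
#' Draws an i.i.d. background with the configured GC fraction, plants
#' `n_planted` descriptor-conforming instances at non-overlapping positions
#' (minus-strand plants are inserted as reverse complements), annotates a
#' fake CDS starting at each instance's terminal AUG, and records the truth
#' set. Optional per-plant mutations are applied to the instance before
#' insertion; the recorded class is re-derived from the actually planted
#' sequence (`NONE` if it no longer matches the descriptor).
#'
#' @param config A [sim_config()].
#' @param descriptor A `rose_descriptor` (default: the restrictive ROSE-G
#'   search descriptor).
#' @param rules A [pairing_rules()] object.
#' @param seq_id Name of the emitted record.
#' @return List with `seqs` (named character vector, DNA), `genes` (data
#'   frame for [annotate_candidates()]), `truth` (data frame: plant, span,
#'   strand, class, motif_string, mutations, gene_id) and `config`.
#' @export
generate_genome <- function(config, descriptor = roseg_descriptors()$restrictive,
                            rules = pairing_rules(), seq_id = "syn1") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$genome_length
  win <- descriptor$win_len
  if (config$n_planted > 0 && L <= win * config$n_planted) {
    stop("genome_length must exceed win_len * n_planted", call. = FALSE)
  }
  gc <- config$gc_fraction
  bg <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))

  n <- config$n_planted
  starts <- integer(0)   # 0-based
  if (n > 0) {
    tries <- 0L
    while (length(starts) < n) {
      tries <- tries + 1L
      if (tries > 1000L * n) {
        stop("cannot place ", n, " non-overlapping instances in ", L, " nt",
             call. = FALSE)
      }
      cand <- sample.int(L - win + 1L, 1L) - 1L
      if (!any(abs(cand - starts) < win)) starts <- c(starts, cand)
    }
    starts <- sort(starts)
  }

  strands <- switch(config$plant_strands,
                    "+" = rep("+", n), "-" = rep("-", n),
                    both = rep(c("+", "-"), length.out = n))
  muts <- config$plant_mutations
  if (!is.null(muts) && !is.list(muts)) muts <- rep(list(muts), n)

  truth <- NULL
  genes <- NULL
  for (i in seq_len(n)) {
    inst <- sample_motif_instance(descriptor, rules)
    mi <- if (is.null(muts)) character(0) else muts[[((i - 1L) %% length(muts)) + 1L]]
    if (length(mi)) inst <- apply_mutations(inst, mi)
    ilen <- nchar(inst)
    # truth class from the actually planted sequence
    hits <- scan_sequence(descriptor, inst, rules, strand = "+")
    if (length(hits) && hits[[1]]$span[1] == 0L && hits[[1]]$span[2] == ilen) {
      cl <- classify_motif(hits[[1]])
    } else {
      cl <- list(motif_class = "NONE", motif_string = NA_character_)
    }
    dna <- chartr("U", "T", inst)
    st <- strands[i]
    if (st == "-") dna <- chartr("ACGT", "TGCA",
                                 paste(rev(strsplit(dna, "")[[1]]), collapse = ""))
    p <- starts[i]
    bg[(p + 1L):(p + ilen)] <- strsplit(dna, "")[[1]]
    aug <- if (st == "+") p + ilen - 3L else p + 2L
    gene_id <- sprintf("gene_%03d", i)
    genes <- rbind(genes, data.frame(
      gene_id = gene_id, seq_id = seq_id, strand = st,
      cds_start = aug, cds_len = 90L,
      product = "ABC transporter, synthetic planted gene",
      stringsAsFactors = FALSE))
    truth <- rbind(truth, data.frame(
      plant = i, seq_id = seq_id, strand = st, start = p, end = p + ilen,
      motif_class = cl$motif_class, motif_string = cl$motif_string,
      mutations = paste(mi, collapse = ","), gene_id = gene_id,
      stringsAsFactors = FALSE))
  }

  seqs <- stats::setNames(paste(bg, collapse = ""), seq_id)
  if (is.null(truth)) {
    truth <- data.frame(plant = integer(0), seq_id = character(0),
                        strand = character(0), start = integer(0),
                        end = integer(0), motif_class = character(0),
                        motif_string = character(0), mutations = character(0),
                        gene_id = character(0), stringsAsFactors = FALSE)
    genes <- data.frame(gene_id = character(0), seq_id = character(0),
                        strand = character(0), cds_start = integer(0),
                        cds_len = integer(0), product = character(0),
                        stringsAsFactors = FALSE)
  }
  list(seqs = seqs, genes = genes, truth = truth, config = config)
}

#' Write a simulated genome to FASTA + GFF3 + truth files
#'
#' @param sim Result of [generate_genome()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`fasta`, `gff3`, `truth_tsv`,
#'   `truth_json`).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(fasta = file.path(dir, "genome.fasta"),
                gff3 = file.path(dir, "genes.gff3"),
                truth_tsv = file.path(dir, "truth.tsv"),
                truth_json = file.path(dir, "truth.json"))
  write_fasta(sim$seqs, paths$fasta)
  write_gff_genes(sim$genes, paths$gff3)
  utils::write.table(sim$truth, paths$truth_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(config = sim$config[c("seed", "genome_length",
                                                  "gc_fraction", "n_planted",
                                                  "plant_strands")],
                            truth = sim$truth),
                       paths$truth_json, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Generate a replicate reporter-assay measurement table
#'
#' Per construct and temperature, draws `n_reps` activities as
#' `base * fold(T) * lognormal(cv)` (mean-one noise). For `in_vivo` rows
#' the activity is converted back to an A420 reading with plausible
#' OD600/volume/time so that [miller_units()] reproduces the intended
#' activity; `in_vitro` rows carry the activity directly as A420.
#'
#' @param config A [sim_config()] (assay block used).
#' @param constructs Data frame with columns `construct`, `assay`,
#'   `fold_37`, `fold_42`; default: a wild-type with the configured folds
#'   and a null (gyrA-like) construct with folds 1.
#' @return List with `table` (measurement data frame for
#'   [heat_induction()]) and `truth` (the constructs table).
#' @export
generate_assay_table <- function(config, constructs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  a <- config$assay
  if (is.null(constructs)) {
    constructs <- data.frame(
      construct = c("wt", "null"), assay = "in_vivo",
      fold_37 = c(a$fold_37, 1), fold_42 = c(a$fold_42, 1),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("construct", "assay", "fold_37", "fold_42") %in%
                  names(constructs)),
            all(constructs$fold_37 > 0), all(constructs$fold_42 > 0))
  set.seed(config$seed)
  rows <- list()
  for (i in seq_len(nrow(constructs))) {
    cn <- constructs$construct[i]
    assay <- constructs$assay[i]
    folds <- c(`25` = 1, `37` = constructs$fold_37[i],
               `42` = constructs$fold_42[i])
    for (tmp in c(25, 37, 42)) {
      act <- (if (assay == "in_vivo") a$base_activity else a$base_a420) *
        folds[[as.character(tmp)]] * .mult_noise(a$n_reps, a$cv)
      if (assay == "in_vivo") {
        od <- round(stats::runif(a$n_reps, 0.3, 0.5), 3)
        vol <- 0.02
        time <- 90
        a420 <- act * time * vol * od / 1000
        rows[[length(rows) + 1L]] <- data.frame(
          construct = cn, assay = assay, temperature = tmp,
          replicate = seq_len(a$n_reps), a420 = a420, od600 = od,
          volume_ml = vol, time_min = time, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          construct = cn, assay = assay, temperature = tmp,
          replicate = seq_len(a$n_reps), a420 = act, od600 = NA_real_,
          volume_ml = NA_real_, time_min = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  list(table = do.call(rbind, rows), truth = constructs)
}

#' Generate wild-type and stabilized-mutant probing lane profiles
#'
#' Emulates the two-lane 42 degC in-line probing design. The supplied
#' structure is read as the wild-type state in which the core motif and
#' Shine-Dalgarno regions are melted: those positions cleave at
#' `unpaired_rate` in the wild-type lane, while the stabilized mutant lane
#' (bulges closed) emits `paired_rate` there. All other positions follow
#' the structure's pairing in both lanes, and both lanes share the
#' invariant control regions (the apical-loop positions and two unpaired
#' reference positions near the 3' end) used for normalization.
#'
#' @param config A [sim_config()] (probing block used).
#' @param structure A `secondary_structure` from [to_dot_bracket()].
#' @return List with `wt` and `mut` [lane_profile()]s, `regions` (a
#'   [region_map()]) and `truth` (the configured rates and their ratio).
#' @export
generate_probing_profiles <- function(config, structure) {
  stopifnot(inherits(config, "sim_config"),
            inherits(structure, "secondary_structure"))
  pr <- config$probing
  set.seed(config$seed)
  n <- structure$length
  paired_pos <- c(structure$pairs[, 1], structure$pairs[, 2])
  base_rate <- rep(pr$unpaired_rate, n)
  base_rate[paired_pos + 1L] <- pr$paired_rate

  roi <- sort(unique(c(structure$regions$ROSEG_core,
                       structure$regions$SD_side)))
  wt_rate <- base_rate
  wt_rate[roi + 1L] <- pr$unpaired_rate    # melted at 42 degC
  mut_rate <- base_rate
  mut_rate[roi + 1L] <- pr$paired_rate     # stabilized mutant stays paired

  # controls: the apical loop plus the two unpaired positions preceding the
  # start codon; invariant between the two lanes by construction
  loop <- structure$regions$L2
  ref2 <- (n - 5L):(n - 4L)
  regions <- region_map(ROSEG = structure$regions$ROSEG_core,
                        SD = setdiff(structure$regions$SD_side,
                                     structure$regions$ROSEG_core),
                        LOOP1 = loop, REF_A48_49 = ref2)

  wt <- lane_profile(wt_rate * .mult_noise(n, pr$noise_cv),
                     construct = "wt", temperature = 42)
  mut <- lane_profile(mut_rate * .mult_noise(n, pr$noise_cv),
                      construct = "stabilized_mutant", temperature = 42)
  list(wt = wt, mut = mut, regions = regions,
       truth = list(paired_rate = pr$paired_rate,
                    unpaired_rate = pr$unpaired_rate,
                    roi_ratio = pr$paired_rate / pr$unpaired_rate))
}
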