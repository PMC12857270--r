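# generators: motif instances, genomes with truth, assay tables, lanes

test_that("sampled motif instances always scan to a single covering match", {
  d <- roseg_descriptors()$restrictive
  rules <- pairing_rules()
  set.seed(101)
  for (i in 1:25) {
    inst <- sample_motif_instance(d, rules)
    expect_equal(nchar(inst), 48L)
    m <- scan_sequence(d, inst, rules, strand = "+")
    expect_length(m, 1L)
    expect_equal(m[[1]]$span, c(0L, 48L))
    expect_equal(substr(inst, 46, 48), "AUG")
    # every helix position pairs under the rules (oracle check)
    expect_equal(nrow(oracle_scan(d, inst)) >= 1, TRUE)
  }
  # strict-WC sampling satisfies strict-WC scanning
  set.seed(102)
  wc <- pairing_rules(wobble = FALSE)
  inst <- sample_motif_instance(d, wc)
  expect_length(scan_sequence(d, inst, wc, strand = "+"), 1L)
  # unsatisfiable: helix strands that cannot pair
  bad <- parse_descriptor(c("s1 h1 h1' s2", "s1 0 A", "h1 0:0 G:G", "s2 0 A"))
  set.seed(103)
  expect_error(sample_motif_instance(bad), "unsatisfiable")
})

test_that("instance sampling is deterministic under a fixed seed", {
  d <- roseg_descriptors()$restrictive
  set.seed(55); a <- replicate(5, sample_motif_instance(d))
  set.seed(55); b <- replicate(5, sample_motif_instance(d))
  expect_identical(a, b)
})

test_that("generated genomes have the configured length, GC and plants", {
  cfg <- sim_config(seed = 61, genome_length = 100000L, gc_fraction = 0.6,
                    n_planted = 5L)
  sim <- generate_genome(cfg)
  s <- sim$seqs[[1]]
  expect_equal(nchar(s), 100000L)
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
  expect_lt(abs(gc - 0.6), 0.01)
  expect_equal(nrow(sim$truth), 5L)
  expect_setequal(unique(sim$truth$strand), c("+", "-"))
  # planted spans do not overlap
  tr <- sim$truth[order(sim$truth$start), ]
  expect_true(all(diff(tr$start) >= 48L))
  # determinism
  sim2 <- generate_genome(cfg)
  expect_identical(sim$seqs, sim2$seqs)
  expect_identical(sim$truth, sim2$truth)
})

test_that("truth files round-trip through FASTA/GFF3", {
  cfg <- sim_config(seed = 62, genome_length = 20000L, n_planted = 4L)
  sim <- generate_genome(cfg)
  dir <- tempfile()
  paths <- write_simulation(sim, dir)
  seqs <- read_fasta(paths$fasta)
  expect_identical(unname(seqs), unname(sim$seqs))
  genes <- read_gff_genes(paths$gff3)
  genes <- genes[order(genes$gene_id), ]
  expect_equal(genes$cds_start, sim$genes$cds_start)
  expect_equal(genes$strand, sim$genes$strand)
  # re-deriving planted spans from the emitted FASTA reproduces the truth
  truth <- read.table(paths$truth_tsv, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  d <- roseg_descriptors()$restrictive
  for (i in seq_len(nrow(truth))) {
    frag <- substr(seqs[[1]], truth$start[i] + 1L, truth$end[i])
    if (truth$strand[i] == "-") {
      frag <- paste(oracle_revcomp(oracle_chars(frag)), collapse = "")
    }
    m <- scan_sequence(d, frag, strand = "+")
    expect_length(m, 1L)
    expect_equal(classify_motif(m[[1]])$motif_class, truth$motif_class[i])
  }
})

test_that("scan -> annotate -> classify recovers every unmutated plant", {
  cfg <- sim_config(seed = 63, genome_length = 50000L, n_planted = 6L)
  sim <- generate_genome(cfg)
  res <- rose_pipeline(roseg_descriptors()$restrictive, sim$seqs, sim$genes)
  joined <- merge(sim$truth, res$candidates,
                  by.x = c("seq_id", "strand", "start"),
                  by.y = c("seq_id", "strand", "start"))
  expect_equal(nrow(joined), 6L)                       # sensitivity 1.0
  expect_equal(joined$motif_class.x, joined$motif_class.y)  # class truth
  expect_true(all(joined$offset == 0L))
})

test_that("assay generator reproduces intended activities through Miller units", {
  cfg <- sim_config(seed = 64, assay = list(cv = 0, n_reps = 3, fold_42 = 4,
                                            fold_37 = 2))
  sim <- generate_assay_table(cfg)
  r <- heat_induction(sim$table, "wt")
  expect_equal(r$factor_42, 4.0)                      # noiseless limit exact
  expect_equal(r$factor_37, 2.0)
  expect_equal(heat_induction(sim$table, "null")$factor_42, 1.0)
  # the a420/od600/volume/time columns reproduce the intended activity
  vivo <- sim$table[sim$table$construct == "wt" & sim$table$temperature == 25, ]
  act <- miller_units(vivo$a420, vivo$time_min, vivo$volume_ml, vivo$od600)
  expect_equal(act, rep(100, 3))
  # determinism
  sim2 <- generate_assay_table(cfg)
  expect_identical(sim$table, sim2$table)
})

test_that("null constructs bracket factor 1 and noisy folds center on truth", {
  folds <- vapply(1:60, function(i) {
    cfg <- sim_config(seed = 1000L + i,
                      assay = list(cv = 0.1, n_reps = 3, fold_42 = 1))
    sim <- generate_assay_table(cfg, data.frame(
      construct = "null", assay = "in_vitro", fold_37 = 1, fold_42 = 1,
      stringsAsFactors = FALSE))
    heat_induction(sim$table, "null", elevated = 42)$factor_42
  }, 0)
  expect_gt(mean(folds > 1), 0.2)
  expect_gt(mean(folds < 1), 0.2)
  expect_lt(abs(median(folds) - 1), 0.1)
})

test_that("probing generator hits the configured rates in the noiseless limit", {
  d <- roseg_descriptors()$restrictive
  m <- scan_sequence(d, roseg_example_hit())[[1]]
  st <- to_dot_bracket(m)
  cfg <- sim_config(seed = 65, probing = list(paired_rate = 1,
                                              unpaired_rate = 3, noise_cv = 0))
  pro <- generate_probing_profiles(cfg, st)
  ct <- condition_contrast(pro$wt, pro$mut, pro$regions)
  expect_equal(ct$ratio[ct$region == "ROSEG"], 1 / 3)
  expect_equal(ct$ratio[ct$region == "SD"], 1 / 3)
  expect_equal(ct$ratio[ct$region == "LOOP1"], 1)
  # equal rates -> all contrasts 1
  cfg2 <- sim_config(seed = 65, probing = list(paired_rate = 2,
                                               unpaired_rate = 2, noise_cv = 0))
  ct2 <- condition_contrast2 <- local({
    p <- generate_probing_profiles(cfg2, st)
    condition_contrast(p$wt, p$mut, p$regions)
  })
  expect_true(all(abs(ct2$ratio - 1) < 1e-12))
  # unpaired control regions cleave faster than helix interiors
  cfg3 <- sim_config(seed = 66, probing = list(noise_cv = 0.1))
  pro3 <- generate_probing_profiles(cfg3, st)
  n3 <- normalize_regions(pro3$mut, pro3$regions)
  expect_gt(n3[["LOOP1"]], n3[["ROSEG"]])
})
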