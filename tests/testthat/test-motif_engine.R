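# descriptor parsing, scanning, and match probability

restrictive_text <- c(
  "s1 h1 s2 h2 s3 h2' s4 h1' s5",
  "s1 0 ***",
  "h1 0:0 ****CT:RG****",
  "s2 0 G",
  "h2 0:0 NU****:****RG",
  "s3 0 NNN****",
  "s4 0 G",
  "s5 0 *******NNAUG")

test_that("the restrictive search descriptor parses to the expected layout", {
  d <- parse_descriptor(restrictive_text)
  expect_s3_class(d, "rose_descriptor")
  expect_equal(d$structure_map$ref,
               c("s1", "h1", "s2", "h2", "s3", "h2'", "s4", "h1'", "s5"))
  expect_equal(d$win_len, 48L)  # 3+6+1+6+7+6+1+6+12
  expect_equal(d$elements$s4$pattern5, "G")
  expect_equal(d$elements$h1$pattern5, "****CU")  # T normalized to U
  expect_true(all(vapply(d$elements, `[[`, 1L, "mismatch_allowance") == 0L))
  expect_true(all(vapply(d$elements, `[[`, 1L, "insertion_allowance") == 0L))
  # built-in copy is the same descriptor
  expect_equal(roseg_descriptors()$restrictive$structure_map,
               d$structure_map)
})

test_that("typographic characters from the printed dialect are accepted", {
  fancy <- c("s1 h1 s2 h1′ s3",
             "s1 0 ∗∗",
             "h1 0:0 GC:GC",
             "s2 0 NN",
             "s3 0 AUG")
  d <- parse_descriptor(fancy)
  expect_equal(d$structure_map$ref, c("s1", "h1", "s2", "h1'", "s3"))
  expect_equal(d$elements$s1$pattern5, "**")
  # round-trip through the serializer
  expect_equal(parse_descriptor(format_descriptor(d))$structure_map,
               d$structure_map)
})

test_that("malformed descriptors are rejected with specific errors", {
  expect_error(parse_descriptor(c("s1 h3 s2", "s1 0 A", "s2 0 A")),
               "undefined element")
  expect_error(parse_descriptor(c("s1 h1 s2 h1' s3", "s1 0 A", "s2 0 A",
                                  "s3 0 A", "h1 0:0 GG:C")),
               "unequal length")
  expect_error(parse_descriptor(c("s1 h1 s2 h1' s3", "s1 0 A", "s2 0 A",
                                  "s3 0 A", "h1 0:2 GC:GC")),
               "insertion")
  expect_error(parse_descriptor(c("s1", "s1 0 AXG")), "illegal pattern")
  expect_error(parse_descriptor(c("s1 h1 s2 h2' s3", "s1 0 A", "s2 0 A",
                                  "s3 0 A", "h1 0:0 G:C", "h2 0:0 G:C")),
               "absent from structure map|once unprimed")
})

test_that("the worked 48-mer yields exactly one match with the known spans", {
  d <- roseg_descriptors()$restrictive
  m <- scan_sequence(d, roseg_example_hit(), strand = "+")
  expect_length(m, 1L)
  expect_equal(m[[1]]$span, c(0L, 48L))
  expect_equal(unname(m[[1]]$element_spans["s2", ]), c(9L, 10L))
  expect_equal(unname(m[[1]]$element_spans["s4", ]), c(29L, 30L))
  expect_equal(m[[1]]$matched_rna, roseg_example_hit())

  # breaking the bulged-G constraint (s2, 0-based position 9) kills the hit
  broken <- roseg_example_hit()
  substr(broken, 10, 10) <- "A"
  expect_length(scan_sequence(d, broken, strand = "+"), 0L)

  # empty-ish input: shorter than the window
  expect_length(scan_sequence(d, "ACGU"), 0L)
  # invalid characters are an error, not a silent skip
  expect_error(scan_sequence(d, "ACGX"), "invalid sequence character")
})

test_that("T input is normalized and DNA/RNA give identical matches", {
  d <- roseg_descriptors()$restrictive
  dna <- chartr("U", "T", roseg_example_hit())
  m <- scan_sequence(d, dna)
  expect_length(m, 1L)
  expect_equal(m[[1]]$matched_rna, roseg_example_hit())
})

test_that("minus-strand hits are reported in forward coordinates", {
  d <- roseg_descriptors()$restrictive
  set.seed(42)
  bg <- random_seq(300)
  fwd <- plant_in(bg, roseg_example_hit(), 100)
  rc <- paste(oracle_revcomp(oracle_chars(fwd)), collapse = "")
  m_fwd <- scan_sequence(d, fwd)
  m_rc <- scan_sequence(d, rc)
  expect_true(length(m_fwd) >= 1L)
  expect_equal(length(m_fwd), length(m_rc))
  # strand symmetry: a + hit at [s,e) on S is a - hit at [L-e, L-s) on rc(S)
  L <- nchar(fwd)
  df_fwd <- as.data.frame(m_fwd)
  df_rc <- as.data.frame(m_rc)
  flipped <- data.frame(
    seq_id = df_fwd$seq_id,
    strand = ifelse(df_fwd$strand == "+", "-", "+"),
    start = L - df_fwd$end, end = L - df_fwd$start,
    matched_rna = df_fwd$matched_rna, stringsAsFactors = FALSE)
  flipped <- flipped[order(flipped$start, flipped$strand), ]
  rownames(flipped) <- NULL
  expect_equal(df_rc, flipped)
})

test_that("mismatch allowances relax sequence constraints but never pairing", {
  # helix with fixed GC:GC plus a strict strand; one strand mismatch allowed
  d0 <- parse_descriptor(c("s1 h1 s2 h1' s3",
                           "s1 0 A", "h1 0:0 GC:GC", "s2 1 AAA", "s3 0 A"))
  hit <- "AGCAAAGCA"        # exact
  near <- "AGCAAUGCA"       # one violation in s2
  far <- "AGCUUUGCA"        # two violations in s2
  nopair <- "AGCAAAGGA"     # s3/h1' region breaks pairing
  expect_length(scan_sequence(d0, hit, strand = "+"), 1L)
  expect_length(scan_sequence(d0, near, strand = "+"), 1L)
  expect_length(scan_sequence(d0, far, strand = "+"), 0L)
  # pairing violations are never excused by the allowance
  d1 <- parse_descriptor(c("s1 h1 s2 h1' s3",
                           "s1 0 A", "h1 2:0 GC:GC", "s2 0 AAA", "s3 0 A"))
  expect_length(scan_sequence(d1, "AGCAAAUUA", strand = "+"), 0L)
})

test_that("enlarging the pairing alphabet never removes a match", {
  d <- roseg_descriptors()$permissive
  set.seed(7)
  for (i in 1:20) {
    s <- plant_in(random_seq(200), sample_motif_instance(d), 50)
    wc <- as.data.frame(scan_sequence(d, s, pairing_rules(wobble = FALSE)))
    wob <- as.data.frame(scan_sequence(d, s, pairing_rules(wobble = TRUE)))
    key <- function(df) paste(df$strand, df$start, df$end)
    expect_true(all(key(wc) %in% key(wob)))
  }
})

test_that("scanning is deterministic and ordered", {
  d <- roseg_descriptors()$permissive
  set.seed(11)
  s <- plant_in(plant_in(random_seq(400), sample_motif_instance(d), 30),
                sample_motif_instance(d), 200)
  a <- as.data.frame(scan_sequence(d, s))
  b <- as.data.frame(scan_sequence(d, s))
  expect_identical(a, b)
  expect_true(all(diff(a$start) >= 0))
})

test_that("match_probability matches enumeration on tiny descriptors", {
  # unconstrained single strand
  d_any <- parse_descriptor(c("s1", "s1 0 ****"))
  expect_equal(match_probability(d_any), 1.0)

  # 1-bp helix with G:C patterns: P = 1/16 under WC+wobble
  d_gc <- parse_descriptor(c("s1 h1 s2 h1' s3",
                             "s1 0 *", "h1 0:0 G:C", "s2 0 *", "s3 0 *"))
  expect_equal(match_probability(d_gc), 1 / 16)
  expect_equal(oracle_enumeration_probability(d_gc), 1 / 16)

  # wobble-sensitive case: U:* helix position
  d_u <- parse_descriptor(c("s1 h1 s2 h1' s3",
                            "s1 0 *", "h1 0:0 U:*", "s2 0 *", "s3 0 *"))
  expect_equal(match_probability(d_u),
               oracle_enumeration_probability(d_u))
  expect_equal(match_probability(d_u, pairing_rules(wobble = FALSE)),
               oracle_enumeration_probability(d_u, wobble = FALSE))

  # degenerate codes on both helix strands
  d_ry <- parse_descriptor(c("s1 h1 h1' s2",
                             "s1 0 N", "h1 0:0 RN:YG", "s2 0 A"))
  expect_equal(match_probability(d_ry),
               oracle_enumeration_probability(d_ry))

  expect_error(match_probability(parse_descriptor(c("s1", "s1 1 AA"))),
               "zero mismatch")
})

test_that("simulated hit counts agree with the analytic expectation", {
  # a deliberately loose descriptor so random hits actually occur
  d <- parse_descriptor(c("s1 h1 s2 h1' s3",
                          "s1 0 R", "h1 0:0 NN:NN", "s2 0 **", "s3 0 Y"))
  p <- match_probability(d)
  set.seed(123)
  n_rep <- 40
  len <- 4000
  counts <- vapply(seq_len(n_rep), function(i) {
    nrow(as.data.frame(scan_sequence(d, random_seq(len), strand = "+")))
  }, 1)
  lambda <- (len - d$win_len + 1) * p
  z <- (mean(counts) - lambda) / sqrt(lambda / n_rep)
  expect_lt(abs(z), 3)
})
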