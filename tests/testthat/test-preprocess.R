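mkreads <- function(bases, quals) {
  tibble::tibble(read_id = sprintf("R%03d", seq_along(bases)),
                 bases = bases, qual_string = quals)
}
q_of <- function(score, n) strrep(intToUtf8(score + 33), n)

test_that("mean-quality filter keeps >= q_mean with inclusive boundary", {
  reads <- mkreads(rep(strrep("A", 10), 3),
                   c(q_of(37, 10), q_of(10, 10),
                     paste0(q_of(10, 5), q_of(30, 5))))  # means 37, 10, 20
  kept <- filter_by_quality(reads, 20)
  expect_identical(kept$read_id, c("R001", "R003"))
  expect_error(filter_by_quality(mkreads("A", ""), 20), "empty quality")
})

test_that("primer/UMI extraction standardises 12-mers to 8 and drops bad reads", {
  pr <- builtin_primer_set()
  p12 <- pr$sequence[pr$name == "P5-UMI12"]
  umi12 <- "ACGTACGTACGT"
  body <- strrep("G", 30)
  reads <- mkreads(paste0(p12, umi12, body), q_of(37, 62))
  res <- extract_primer_and_umi(reads, pr, end = "5")
  expect_identical(res$reads$primer_name, "P5-UMI12")
  expect_identical(res$reads$umi, umi12)
  expect_identical(res$reads$umi8, substr(umi12, 1, 8))
  expect_identical(res$reads$bases, body)
  # two mismatches tolerated, three are not
  mod <- function(s, k) { substr(s, 1, k) <- strrep("N", k); s }
  r2 <- mkreads(paste0(mod(p12, 2), umi12, body), q_of(37, 62))
  expect_identical(nrow(extract_primer_and_umi(r2, pr, end = "5")$reads), 1L)
  r3 <- mkreads(paste0(mod(p12, 3), umi12, body), q_of(37, 62))
  res3 <- extract_primer_and_umi(r3, pr, end = "5")
  expect_identical(nrow(res3$reads), 0L)
  expect_identical(unname(res3$log[["n_unmatched"]]), 1L)
})

test_that("tied primers drop the read and are logged", {
  pr <- tibble::tibble(name = c("PA", "PB"), end = "5",
                       sequence = c("AAAACCCC", "AAAACCCG"),
                       umi_length = c(8L, 8L))
  # one mismatch to each primer: a tie
  reads <- mkreads(paste0("AAAACCCT", strrep("A", 40)), q_of(37, 48))
  res <- extract_primer_and_umi(reads, pr, end = "5")
  expect_identical(nrow(res$reads), 0L)
  expect_identical(unname(res$log[["n_tied"]]), 1L)
})

test_that("consensus follows quality-weighted majority with N on ties", {
  # identical reads: consensus is the read itself
  c1 <- build_consensus(rep("ACGTACGTAC", 3), rep(q_of(37, 10), 3))
  expect_length(c1, 1)
  expect_identical(c1[[1]]$seq, "ACGTACGTAC")
  expect_identical(c1[[1]]$read_count, 3L)
  # {A,A,C} at equal quality -> A; {A,C} -> N
  c2 <- build_consensus(c("AAAAAAAAAA", "AAAAAAAAAA", "CAAAAAAAAA"),
                        rep(q_of(30, 10), 3))
  expect_identical(substr(c2[[1]]$seq, 1, 1), "A")
  c3 <- build_consensus(c("AAAAAAAAAA", "CAAAAAAAAA"), rep(q_of(30, 10), 2))
  expect_identical(substr(c3[[1]]$seq, 1, 1), "N")
  # higher-quality base wins over count parity
  c4 <- build_consensus(c("AAAAAAAAAA", "CAAAAAAAAA"),
                        c(paste0(q_of(20, 1), q_of(30, 9)),
                          paste0(q_of(37, 1), q_of(30, 9))))
  expect_identical(substr(c4[[1]]$seq, 1, 1), "C")
})

test_that("consensus equals the brute-force tally on small random groups", {
  set.seed(201)
  for (rep_i in 1:25) {
    k <- sample(2:5, 1)
    template <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                      collapse = "")
    bases <- vapply(seq_len(k), function(i) perturb(template, 1, 20, 1), "")
    quals <- vapply(seq_len(k), function(i)
      paste(sample(c("5", "F"), 20, replace = TRUE), collapse = ""), "")
    got <- build_consensus(bases, quals)
    expect_length(got, 1)
    expect_identical(got[[1]]$seq, consensus_oracle(bases, quals))
  }
})

test_that("far-divergent members of one UMI signature are split (collision)", {
  set.seed(7)
  a <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
  b <- perturb(a, 1, 40, 16)  # 40% divergent: a UMI collision
  got <- build_consensus(c(a, a, b), rep(q_of(37, 40), 3))
  expect_length(got, 2)
  counts <- sort(vapply(got, function(g) g$read_count, 0L))
  expect_identical(counts, c(1L, 2L))
})

test_that("length outliers in a UMI group are discarded and counted", {
  a <- strrep("ACGT", 10)
  short <- substr(a, 1, 12)   # 28 nt shorter than the mode
  got <- build_consensus(c(a, a, short), rep(q_of(37, 40), 2) |> c(q_of(37, 12)))
  expect_length(got, 1)
  expect_identical(got[[1]]$seq, a)
  expect_identical(got[[1]]$n_discarded, 1L)
})

test_that("paired-end assembly obeys the overlap arithmetic", {
  set.seed(11)
  full <- paste(sample(c("A", "C", "G", "T"), 350, replace = TRUE), collapse = "")
  fwd <- substr(full, 1, 200)
  rev_bio <- substr(full, 171, 350)          # 30-nt exact overlap
  rev_read <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev_bio)))
  a <- assemble_pairs(fwd, rev_read)
  expect_identical(nchar(a$seq), 350L)       # L1 + L2 - overlap
  expect_identical(a$seq, full)
  expect_identical(a$overlap, 30L)
  # no qualifying overlap -> NULL (reverse-complement of G-run is a C-run)
  other <- paste(rep("G", 100), collapse = "")
  expect_null(assemble_pairs(strrep("A", 100), other,
                             min_overlap = 30, max_mismatch_rate = 0))
})

test_that("overlap disagreements resolve toward the higher-quality side", {
  set.seed(12)
  full <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  fwd <- substr(full, 1, 60)
  rev_bio <- substr(full, 31, 100)
  # corrupt one base inside the forward copy of the overlap
  fwd_bad <- fwd
  substr(fwd_bad, 45, 45) <- if (substr(fwd, 45, 45) == "A") "C" else "A"
  rev_read <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev_bio)))
  a <- assemble_pairs(fwd_bad, rev_read,
                      fwd_w = rep(1, 60), rev_w = rep(5, 70))
  expect_identical(a$mismatches, 1L)
  expect_identical(a$seq, full)              # reverse (higher weight) wins
  b <- assemble_pairs(fwd_bad, rev_read,
                      fwd_w = rep(5, 60), rev_w = rep(1, 70))
  expect_identical(b$seq, fwd_bad |> paste0(substr(full, 61, 100)))
})

test_that("isotype annotation matches stubs at the 3' end", {
  stubs <- ref_fixture$constant_stubs
  g1 <- stubs$sequence[stubs$isotype == "IGHG1"]
  seqs <- paste0(strrep("A", 60), c(g1, perturb(g1, 1, 40, 2), strrep("T", 40)))
  # exact, two mismatches, and hopeless
  set.seed(5)
  iso <- annotate_isotype(seqs, stubs)
  expect_identical(iso$c_call[1], "IGHG1")
  expect_identical(iso$isotype[1], "IgG")
  expect_identical(iso$subtype[1], "IGHG1")
  expect_identical(iso$c_call[2], "IGHG1")
  expect_true(is.na(iso$c_call[3]))
  # tie between subtypes of one isotype -> ambiguous subtype, isotype kept
  stubs2 <- tibble::tibble(isotype = c("IGHG1", "IGHG2"),
                           sequence = c(paste0("AA", substr(g1, 3, 40)),
                                        paste0("CC", substr(g1, 3, 40))))
  probe <- paste0(strrep("A", 60), paste0("AC", substr(g1, 3, 40)))
  iso2 <- annotate_isotype(probe, stubs2)
  expect_identical(iso2$subtype, "ambiguous")
  expect_identical(iso2$isotype, "IgG")
})

test_that("collapse merges identical sequence+isotype and applies the UMI filter", {
  seqs <- tibble::tibble(
    sequence = c("AAAA", "AAAA", "AAAA", "CCCC", "GGGG", "GGGG"),
    isotype = c("IgG", "IgG", "IgG", "IgG", "IgM", "IgG"),
    subtype = c("IGHG1", "IGHG1", "IGHG1", "IGHG1", "IGHM", "IGHG1"),
    c_call = subtype,
    signature = c("S1", "S2", "S3", "S4", "S5", "S6"),
    read_count = c(1L, 2L, 5L, 1L, 3L, 3L))
  out2 <- collapse_and_filter(seqs, min_reads_per_umi = 2)
  aaaa <- out2[out2$sequence == "AAAA", ]
  expect_identical(aaaa$umi_count, 3L)
  expect_identical(aaaa$max_reads_per_umi, 5L)
  expect_false("CCCC" %in% out2$sequence)        # only 1 read per UMI
  out1 <- collapse_and_filter(seqs, min_reads_per_umi = 1)
  expect_true("CCCC" %in% out1$sequence)
  # same nucleotides, different isotype: two records
  expect_identical(sum(out1$sequence == "GGGG"), 2L)
  expect_identical(nrow(collapse_and_filter(seqs[0, ])), 0L)
})

test_that("preprocessing conserves reads at every stage and round-trips truth", {
  cfg <- sim_config(n_cells = 60, per_base_error = 0, seed = 13)
  cells <- simulate_repertoire(cfg, ref_fixture)
  gen <- generate_reads(cells, cfg, sample_id = "RT")
  pre <- preprocess_sample(gen$reads_fwd, gen$reads_rev, sample_id = "RT",
                           min_reads_per_umi = 1)
  expect_true(all(pre$report$n_in == pre$report$n_kept + pre$report$n_dropped))
  expect_setequal(pre$sequences$sequence, gen$truth$sequence)
  # isotype agreement with truth at zero error
  m <- match(pre$sequences$sequence, gen$truth$sequence)
  expect_identical(pre$sequences$c_call, gen$truth$c_call_true[m])
  # the 2-reads-per-UMI view keeps exactly the well-covered transcripts
  pre2 <- preprocess_sample(gen$reads_fwd, gen$reads_rev, sample_id = "RT",
                            min_reads_per_umi = 2)
  covered <- unique(gen$truth$sequence[gen$truth$n_reads >= 2])
  expect_setequal(pre2$sequences$sequence, covered)
})
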