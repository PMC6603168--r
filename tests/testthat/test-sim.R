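test_that("zero SHM yields exact germline recombinants and degenerate profiles hold", {
  cfg <- sim_config(n_cells = 40, shm_rate = c(naive = 0, memory = 0),
                    compartment_weights = c(naive = 1, memory = 0),
                    isotype_profile = list(
                      naive = c(IgM = 1, IgG1 = 0, IgG2 = 0, IgG3 = 0,
                                IgG4 = 0, IgA1 = 0, IgA2 = 0),
                      memory = c(IgM = 1, IgG1 = 0, IgG2 = 0, IgG3 = 0,
                                 IgG4 = 0, IgA1 = 0, IgA2 = 0)),
                    seed = 3)
  cells <- simulate_repertoire(cfg, ref_fixture)
  expect_true(all(cells$n_mut == 0))
  expect_true(all(lengths(cells$mut_positions) == 0))
  expect_true(all(cells$isotype_true == "IgM"))
  expect_true(all(cells$shm_true == 0))
  # reconstruct each sequence from its true gene calls: with zero SHM the
  # V prefix must match the germline V exactly
  for (i in sample(nrow(cells), 5)) {
    v <- ref_fixture$v_genes$sequence[ref_fixture$v_genes$name == cells$v_call_true[i]]
    vlen_min <- nchar(v) - 5
    expect_identical(substr(cells$sequence[i], 19, 18 + vlen_min),
                     substr(v, 1, vlen_min))
  }
})

test_that("mutated-position counts match the binomial expectation", {
  cfg <- sim_config(n_cells = 1000, shm_rate = c(naive = 0.05, memory = 0.05),
                    compartment_weights = c(naive = 1, memory = 0), seed = 17)
  cells <- simulate_repertoire(cfg, ref_fixture)
  vdj_len <- cells$vdj_end - cells$vdj_start
  # direct binomial oracle: mean count = mean(len) * rate, se from var
  expected <- mean(vdj_len) * 0.05
  se <- sqrt((mean(vdj_len * 0.05 * 0.95) + 0.05^2 * var(vdj_len)) / nrow(cells))
  expect_lt(abs(mean(cells$n_mut) - expected), 3 * se)
})

test_that("read emission respects UMI lengths, uniqueness and error rate", {
  cfg <- sim_config(n_cells = 120, per_base_error = 0.01, seed = 23)
  cells <- simulate_repertoire(cfg, ref_fixture)
  gen <- generate_reads(cells, cfg, sample_id = "ERR")
  expect_true(all(nchar(gen$truth$umi5) %in% c(8, 12)))
  expect_true(all(nchar(gen$truth$umi3) %in% c(8, 12)))
  expect_false(anyDuplicated(gen$truth$signature) > 0)
  # mismatch-rate oracle: reconstruct each read's error-free version from the
  # truth amplicon and count mismatches directly
  p5 <- builtin_primer_set(); p5 <- p5[p5$end == "5", ]
  p5seq <- setNames(p5$sequence, p5$umi_length)
  tx_of_read <- match(sub("\\|\\d+$", "", gen$reads_fwd$read_id), gen$truth$transcript_id)
  amp <- paste0(p5seq[as.character(nchar(gen$truth$umi5[tx_of_read]))],
                gen$truth$umi5[tx_of_read], gen$truth$sequence[tx_of_read])
  clean <- substr(amp, 1, nchar(gen$reads_fwd$bases))
  n_mm <- mapply(function(a, b) sum(utf8ToInt(a) != utf8ToInt(b)),
                 clean, gen$reads_fwd$bases, USE.NAMES = FALSE)
  n_bases <- sum(nchar(clean))
  rate <- sum(n_mm) / n_bases
  se <- sqrt(0.01 * 0.99 / n_bases)
  expect_lt(abs(rate - 0.01), 3 * se)
  # error positions are flagged Q20, clean positions Q37
  expect_true(all(grepl("^[F5]+$", gen$reads_fwd$qual_string)))
})

test_that("no-noise reads are identical across a transcript", {
  cfg <- sim_config(n_cells = 5, per_base_error = 0,
                    reads_per_transcript = c(naive = 3, memory = 3), seed = 4)
  cells <- simulate_repertoire(cfg, ref_fixture)
  gen <- generate_reads(cells, cfg, sample_id = "NN")
  tx <- sub("\\|\\d+$", "", gen$reads_fwd$read_id)
  for (t in unique(tx)) {
    expect_length(unique(gen$reads_fwd$bases[tx == t]), 1)
  }
})

test_that("simulation and read emission are deterministic given the seed", {
  cfg <- sim_config(n_cells = 30, seed = 77)
  c1 <- simulate_repertoire(cfg, ref_fixture)
  c2 <- simulate_repertoire(cfg, ref_fixture)
  expect_identical(c1, c2)
  d1 <- tempfile(); d2 <- tempfile()
  g1 <- generate_reads(c1, cfg, out_dir = d1, sample_id = "DT")
  g2 <- generate_reads(c2, cfg, out_dir = d2, sample_id = "DT")
  expect_identical(g1$reads_fwd, g2$reads_fwd)
  expect_identical(readLines(g1$truth_path), readLines(g2$truth_path))
  # FASTQ content identical after decompression
  expect_identical(read_fastq(g1$fastq[["fwd"]]), read_fastq(g2$fastq[["fwd"]]))
})

test_that("compartment marginals and clone sizes obey the configuration", {
  cfg <- sim_config(n_cells = 5000, condition = "stimulated", seed = 31)
  cells <- simulate_repertoire(cfg, ref_fixture)
  expect_identical(nrow(cells), 5000L)   # clone-size conservation
  frac <- table(cells$isotype_true) / nrow(cells)
  w <- cfg$compartment_weights
  prof <- cfg$isotype_profile
  expected_igm <- w[["naive"]] * prof$naive[["IgM"]] + w[["memory"]] * prof$memory[["IgM"]]
  expected_igg <- w[["naive"]] * sum(prof$naive[grep("IgG", names(prof$naive))]) +
    w[["memory"]] * sum(prof$memory[grep("IgG", names(prof$memory))])
  expect_lt(abs(frac[["IgM"]] - expected_igm), 0.02)
  expect_lt(abs(frac[["IgG"]] - expected_igg), 0.02)
})

test_that("timepoint plans share planted cells and never reuse UMIs", {
  cfg <- sim_config(n_cells = 60, seed = 5)
  plan <- plan_timepoints(cfg, ref_fixture, c("T1", "T2"), n_persistent = 10)
  expect_length(plan$samples, 2)
  expect_identical(nrow(plan$persistent_truth), 10L)
  planted1 <- plan$samples$T1[startsWith(plan$samples$T1$cell_id, "T1-P"), ]
  planted2 <- plan$samples$T2[startsWith(plan$samples$T2$cell_id, "T2-P"), ]
  expect_identical(planted1$sequence, planted2$sequence)
  used <- character(0); sigs <- list()
  for (s in names(plan$samples)) {
    gen <- generate_reads(plan$samples[[s]], cfg, sample_id = s,
                          used_signatures = used)
    used <- c(used, gen$signatures)
    sigs[[s]] <- gen$signatures
  }
  expect_length(intersect(sigs$T1, sigs$T2), 0)
  expect_error(plan_timepoints(cfg, ref_fixture, c("A", "B"),
                               persistent_fraction = 1.5),
               "persistence fraction")
  expect_error(plan_timepoints(cfg, ref_fixture, "only-one"), "two named samples")
})

test_that("zero persistence fraction plants nothing shared", {
  cfg <- sim_config(n_cells = 40, seed = 6)
  plan <- plan_timepoints(cfg, ref_fixture, c("T1", "T2"), n_persistent = 0)
  expect_identical(nrow(plan$persistent_truth), 0L)
  core1 <- substr(plan$samples$T1$sequence, plan$samples$T1$core_start + 1,
                  plan$samples$T1$core_end)
  core2 <- substr(plan$samples$T2$sequence, plan$samples$T2$core_start + 1,
                  plan$samples$T2$core_end)
  expect_length(intersect(core1, core2), 0)
})

test_that("configuration validation rejects bad parameters", {
  expect_error(sim_config(compartment_weights = c(naive = 0.5, memory = 0.2)),
               "sum to 1")
  expect_error(sim_config(per_base_error = 1.5), "per_base_error")
  expect_error(sim_config(umi_lengths = c(8, 10)), "8 or 12")
  cfg <- sim_config(n_cells = 5, read_length = c(fwd = 20L, rev = 20L))
  cells <- simulate_repertoire(cfg, ref_fixture)
  expect_error(generate_reads(cells, cfg), "primer\\+UMI")
})
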