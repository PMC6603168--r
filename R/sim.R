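#' Simulation configuration
#'
#' Builds the parameter set for the ground-truth repertoire simulator. The
#' defaults emulate the two experimental compartments the pipeline is built
#' to contrast: a naive-dominated PBMC compartment (>90% IgM, ~0.8% SHM,
#' mostly singleton clones, low transcript counts) and a stimulated/memory
#' compartment (IgG1-dominant, ~5.5% SHM, skewed clone sizes, at least
#' three-fold more reads per transcript, reflecting proliferation and mRNA
#' upregulation of activated B cells).
#'
#' @param n_cells number of B cells to simulate.
#' @param condition `"PBMC"` or `"stimulated"`; sets `compartment_weights`
#'   unless given explicitly.
#' @param compartment_weights named numeric `c(naive=, memory=)`, summing to 1.
#' @param isotype_profile list with elements `naive` and `memory`: named
#'   probability vectors over subtypes
#'   (IgM, IgG1, IgG2, IgG3, IgG4, IgA1, IgA2), each summing to 1.
#' @param shm_rate named numeric `c(naive=, memory=)`: per-site substitution
#'   probability applied uniformly over the V(D)J region.
#' @param clone_size list with `naive`/`memory` elements, each
#'   `list(exponent=, max=)` for a discrete power-law clone-size
#'   distribution P(s) proportional to s^-exponent on 1..max.
#' @param n_clones optional integer: draw exactly this many clones (cell
#'   count then follows from the drawn sizes) instead of filling `n_cells`.
#' @param transcripts_per_cell named numeric means (zero-truncated Poisson,
#'   parameterised as 1 + Poisson(mean - 1) so every cell yields a transcript).
#' @param reads_per_transcript named numeric means (same zero-truncated form).
#' @param per_base_error per-base sequencing substitution probability.
#' @param umi_lengths subset of `c(8, 12)`: UMI lengths available at each end.
#' @param read_length named integer `c(fwd=, rev=)` read lengths.
#' @param seed integer RNG seed; all outputs are deterministic given the seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cells = 2000,
                       condition = c("PBMC", "stimulated"),
                       compartment_weights = NULL,
                       isotype_profile = NULL,
                       shm_rate = c(naive = 0.008, memory = 0.055),
                       clone_size = list(naive = list(exponent = 3.5, max = 3),
                                         memory = list(exponent = 2.0, max = 50)),
                       n_clones = NULL,
                       transcripts_per_cell = c(naive = 1.5, memory = 4),
                       reads_per_transcript = c(naive = 2, memory = 6),
                       per_base_error = 0.002,
                       umi_lengths = c(8L, 12L),
                       read_length = c(fwd = 300L, rev = 250L),
                       seed = 1L) {
  condition <- match.arg(condition)
  if (is.null(compartment_weights)) {
    compartment_weights <- if (condition == "PBMC") {
      c(naive = 0.95, memory = 0.05)
    } else {
      c(naive = 0.25, memory = 0.75)
    }
  }
  if (is.null(isotype_profile)) {
    isotype_profile <- list(
      naive = c(IgM = 0.92, IgG1 = 0.03, IgG2 = 0.01, IgG3 = 0.005,
                IgG4 = 0.005, IgA1 = 0.02, IgA2 = 0.01),
      memory = c(IgM = 0.10, IgG1 = 0.65, IgG2 = 0.10, IgG3 = 0.04,
                 IgG4 = 0.01, IgA1 = 0.07, IgA2 = 0.03)
    )
  }
  cfg <- list(n_cells = as.integer(n_cells), condition = condition,
              compartment_weights = compartment_weights,
              isotype_profile = isotype_profile, shm_rate = shm_rate,
              clone_size = clone_size, n_clones = n_clones,
              transcripts_per_cell = transcripts_per_cell,
              reads_per_transcript = reads_per_transcript,
              per_base_error = per_base_error,
              umi_lengths = as.integer(umi_lengths),
              read_length = read_length, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  assert_that(cfg$n_cells > 0 || !is.null(cfg$n_clones), "n_cells must be positive")
  assert_that(abs(sum(cfg$compartment_weights) - 1) < 1e-9,
              "compartment weights must sum to 1")
  for (comp in c("naive", "memory")) {
    p <- cfg$isotype_profile[[comp]]
    assert_that(abs(sum(p) - 1) < 1e-9, "isotype profile (%s) must sum to 1", comp)
    assert_that(all(p >= 0 & p <= 1), "isotype probabilities must be in [0,1]")
    assert_that(cfg$shm_rate[[comp]] >= 0 && cfg$shm_rate[[comp]] <= 1,
                "shm_rate must be in [0,1]")
  }
  assert_that(cfg$per_base_error >= 0 && cfg$per_base_error <= 1,
              "per_base_error must be in [0,1]")
  assert_that(all(cfg$umi_lengths %in% c(8L, 12L)), "umi_lengths must be 8 or 12")
  invisible(cfg)
}

# map profile subtype names to constant-stub gene names
subtype_to_stub <- c(IgM = "IGHM", IgG1 = "IGHG1", IgG2 = "IGHG2",
                     IgG3 = "IGHG3", IgG4 = "IGHG4", IgA1 = "IGHA1", IgA2 = "IGHA2")

# internal: draw clone sizes from a truncated discrete power law
draw_clone_sizes <- function(n_target_cells, exponent, max_size, n_clones = NULL) {
  sizes_support <- seq_len(max_size)
  p <- sizes_support^(-exponent)
  p <- p / sum(p)
  if (!is.null(n_clones)) {
    return(sample(sizes_support, n_clones, replace = TRUE, prob = p))
  }
  if (n_target_cells == 0) return(integer(0))
  sizes <- integer(0)
  while (sum(sizes) < n_target_cells) {
    k <- max(16L, ceiling((n_target_cells - sum(sizes)) / sum(p * sizes_support)))
    sizes <- c(sizes, sample(sizes_support, k, replace = TRUE, prob = p))
  }
  cum <- cumsum(sizes)
  keep <- which(cum <= n_target_cells)
  sizes <- sizes[keep]
  if (sum(sizes) < n_target_cells) sizes <- c(sizes, n_target_cells - sum(sizes))
  sizes
}

# internal: one V(D)J recombination event (the clone founder).
# Uniform junctional trimming 0-5 nt per join end and uniform N-insertion
# 0-10 nt; returns the recombined sequence plus true coordinate anchors.
recombine <- function(ref, min_n = 0L, max_n = 10L) {
  leader <- if (is.na(ref$leader)) "" else ref$leader
  llen <- nchar(leader)
  v <- ref$v_genes[sample.int(nrow(ref$v_genes), 1), ]
  j <- ref$j_genes[sample.int(nrow(ref$j_genes), 1), ]
  has_d <- nrow(ref$d_genes) > 0
  d <- if (has_d) ref$d_genes[sample.int(nrow(ref$d_genes), 1), ] else NULL
  tv <- sample(0:5, 1)
  tj <- sample(0:5, 1)
  n1 <- sample(min_n:max_n, 1)
  n2 <- if (has_d) sample(min_n:max_n, 1) else 0L
  dseq <- ""
  if (has_d) {
    td5 <- sample(0:5, 1); td3 <- sample(0:5, 1)
    dlen_full <- nchar(d$sequence)
    if (td5 + td3 >= dlen_full) { td5 <- 0L; td3 <- 0L }
    dseq <- str_sub(d$sequence, td5 + 1, dlen_full - td3)
  }
  vseq <- str_sub(v$sequence, 1, nchar(v$sequence) - tv)
  jseq <- str_sub(j$sequence, tj + 1)
  nins1 <- if (n1 > 0) random_dna(n1) else ""
  nins2 <- if (n2 > 0) random_dna(n2) else ""
  vdj <- paste0(vseq, nins1, dseq, nins2, jseq)
  cys <- gene_region(ref, v$name, "CYS")
  jwf <- gene_region(ref, j$name, "JWF")
  k12 <- gene_region(ref, v$name, "KABAT12")
  k136 <- gene_region(ref, j$name, "KABAT136")
  jpos <- nchar(vseq) + nchar(nins1) + nchar(dseq) + nchar(nins2)  # J start in VDJ
  list(v_call = v$name, d_call = if (has_d && nchar(dseq) >= 5) d$name else NA_character_,
       j_call = j$name, vdj = vdj, leader_len = llen,
       sequence_prefix = paste0(leader, vdj),
       junction_start = llen + cys[1],
       junction_end = llen + jpos + (jwf[2] - tj),
       core_start = if (is.null(k12)) NA_integer_ else llen + k12[1],
       core_end = if (is.null(k136)) NA_integer_ else llen + jpos + (k136[2] - tj),
       vdj_start = llen, vdj_end = llen + nchar(vdj))
}

# internal: apply n substitution mutations at distinct positions (0-based,
# half-open window) of a sequence; returns list(sequence, positions)
mutate_seq <- function(seq, window_start, window_end, n_mut) {
  if (n_mut == 0) return(list(sequence = seq, positions = integer(0)))
  pos <- sort(sample(window_start:(window_end - 1), n_mut))
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    chars[p + 1] <- sample(setdiff(c("A", "C", "G", "T"), chars[p + 1]), 1)
  }
  list(sequence = paste(chars, collapse = ""), positions = pos)
}

#' Simulate a B-cell repertoire with known ground truth
#'
#' Draws clonal families per compartment from the configured clone-size
#' distribution, performs one V(D)J recombination per clone (uniform
#' junctional trimming 0-5 nt and N-insertion 0-10 nt at each join), applies
#' per-member somatic hypermutation at the compartment rate (substitutions
#' only, uniform over the V(D)J region), and draws a per-member isotype from
#' the compartment profile. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @param ref a `germline_reference`.
#' @return tibble of cells with true gene calls, full-length sequence
#'   (leader + V(D)J + constant stub), junction/core coordinates, mutated
#'   positions and true SHM percent.
#' @export
simulate_repertoire <- function(config, ref) {
  validate_sim_config(config)
  assert_that(nrow(ref$v_genes) > 0 && nrow(ref$j_genes) > 0,
              "reference must contain V and J genes")
  set.seed(config$seed)
  stubs <- stats::setNames(ref$constant_stubs$sequence, ref$constant_stubs$isotype)
  out <- list()
  clone_counter <- 0L
  cell_counter <- 0L
  for (comp in c("naive", "memory")) {
    w <- config$compartment_weights[[comp]]
    if (is.null(config$n_clones)) {
      n_comp <- round(w * config$n_cells)
      if (comp == "memory") n_comp <- config$n_cells - round(config$compartment_weights[["naive"]] * config$n_cells)
      sizes <- draw_clone_sizes(n_comp, config$clone_size[[comp]]$exponent,
                                config$clone_size[[comp]]$max)
    } else {
      n_cl <- round(w * config$n_clones)
      if (comp == "memory") n_cl <- config$n_clones - round(config$compartment_weights[["naive"]] * config$n_clones)
      sizes <- draw_clone_sizes(0L, config$clone_size[[comp]]$exponent,
                                config$clone_size[[comp]]$max, n_clones = n_cl)
    }
    profile <- config$isotype_profile[[comp]]
    rate <- config$shm_rate[[comp]]
    for (s in sizes) {
      clone_counter <- clone_counter + 1L
      rec <- recombine(ref)
      vdj_len <- rec$vdj_end - rec$vdj_start
      subtypes <- sample(names(profile), s, replace = TRUE, prob = profile)
      n_muts <- stats::rbinom(s, vdj_len, rate)
      for (m in seq_len(s)) {
        cell_counter <- cell_counter + 1L
        mut <- mutate_seq(rec$sequence_prefix, rec$vdj_start, rec$vdj_end, n_muts[m])
        stub <- stubs[[subtype_to_stub[[subtypes[m]]]]]
        seq_full <- paste0(mut$sequence, stub)
        cys_len <- rec$junction_start - rec$vdj_start
        shm_true <- 100 * sum(mut$positions >= rec$vdj_start &
                                mut$positions < rec$junction_start) / cys_len
        out[[cell_counter]] <- tibble(
          cell_id = sprintf("C%06d", cell_counter),
          clone_id_true = sprintf("SIMCLONE%05d", clone_counter),
          compartment = comp,
          v_call_true = rec$v_call, d_call_true = rec$d_call,
          j_call_true = rec$j_call,
          c_call_true = subtype_to_stub[[subtypes[m]]],
          isotype_true = isotype_class(subtypes[m]),
          sequence = seq_full,
          junction_true = str_sub(seq_full, rec$junction_start + 1, rec$junction_end),
          junction_start = rec$junction_start, junction_end = rec$junction_end,
          core_start = rec$core_start, core_end = rec$core_end,
          vdj_start = rec$vdj_start, vdj_end = rec$vdj_end,
          mut_positions = list(mut$positions),
          n_mut = n_muts[m],
          shm_true = shm_true
        )
      }
    }
  }
  bind_rows(out)
}

#' Emit UMI-tagged paired reads for simulated cells
#'
#' Every transcript receives a unique 5' and 3' UMI whose length is drawn
#' from `config$umi_lengths` (the matching primer variant is used); the 16-nt
#' signature (first 8 nt of each UMI) is guaranteed unique within the sample
#' and against `used_signatures`. Reads per transcript follow
#' 1 + Poisson(mean - 1); sequencing errors are i.i.d. per-base
#' substitutions. Qualities are Q37, with error positions flagged Q20.
#'
#' @param cells tibble from [simulate_repertoire()].
#' @param config a [sim_config()].
#' @param primers primer set tibble (default the bundled set).
#' @param out_dir if non-NULL, gzip FASTQ pair and truth TSV are written here.
#' @param sample_id sample name used in read ids and file names.
#' @param used_signatures character vector of 16-nt signatures already used
#'   by other samples (never reused).
#' @return list with `reads_fwd`, `reads_rev` (tibbles of read_id/bases/
#'   qual_string), `truth` (per-transcript tibble), `signatures`, and file
#'   paths when `out_dir` is given.
#' @export
generate_reads <- function(cells, config, primers = builtin_primer_set(),
                           out_dir = NULL, sample_id = "S1",
                           used_signatures = character(0)) {
  assert_that(nrow(cells) > 0, "cells must be nonempty")
  p5 <- primers[primers$end == "5", ]
  p3 <- primers[primers$end == "3", ]
  assert_that(all(config$umi_lengths %in% p5$umi_length) &&
                all(config$umi_lengths %in% p3$umi_length),
              "primer set lacks a variant for a configured UMI length")
  min_len <- max(nchar(p5$sequence) + p5$umi_length)
  assert_that(min(config$read_length) > min_len,
              "read length shorter than primer+UMI")
  set.seed(derive_seed(config$seed, paste0("reads-", sample_id)))

  comp <- cells$compartment
  tpc <- config$transcripts_per_cell[comp]
  n_tx_per_cell <- 1L + stats::rpois(nrow(cells), pmax(tpc - 1, 0))
  tx_cell <- rep(seq_len(nrow(cells)), n_tx_per_cell)
  n_tx <- length(tx_cell)

  umi5_len <- sample(config$umi_lengths, n_tx, replace = TRUE)
  umi3_len <- sample(config$umi_lengths, n_tx, replace = TRUE)
  umi5 <- random_dna(umi5_len)
  umi3 <- random_dna(umi3_len)
  sig <- paste0(str_sub(umi5, 1, 8), str_sub(umi3, 1, 8))
  # enforce signature uniqueness within sample and against other samples
  repeat {
    clash <- duplicated(sig) | sig %in% used_signatures
    if (!any(clash)) break
    umi5[clash] <- random_dna(umi5_len[clash])
    umi3[clash] <- random_dna(umi3_len[clash])
    sig[clash] <- paste0(str_sub(umi5[clash], 1, 8), str_sub(umi3[clash], 1, 8))
  }

  p5_seq <- stats::setNames(p5$sequence, p5$umi_length)[as.character(umi5_len)]
  p3_seq <- stats::setNames(p3$sequence, p3$umi_length)[as.character(umi3_len)]
  bio <- cells$sequence[tx_cell]
  amplicon <- paste0(p5_seq, umi5, bio, revcomp(umi3), revcomp(p3_seq))

  rpt <- config$reads_per_transcript[comp[tx_cell]]
  n_reads_tx <- 1L + stats::rpois(n_tx, pmax(rpt - 1, 0))
  read_tx <- rep(seq_len(n_tx), n_reads_tx)
  read_idx <- sequence(n_reads_tx)
  amp <- amplicon[read_tx]
  amp_len <- nchar(amp)
  lf <- pmin(config$read_length[["fwd"]], amp_len)
  lr <- pmin(config$read_length[["rev"]], amp_len)
  fwd <- str_sub(amp, 1, lf)
  rev_ <- revcomp(str_sub(amp, amp_len - lr + 1, amp_len))

  inject <- function(seqs, e) {
    n <- length(seqs)
    lens <- nchar(seqs)
    qual <- vapply(lens, function(L) strrep("F", L), "")   # Q37
    if (e > 0) {
      n_err <- stats::rbinom(n, lens, e)
      for (i in which(n_err > 0)) {
        pos <- sample.int(lens[i], n_err[i])
        ch <- strsplit(seqs[i], "")[[1]]
        for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
        seqs[i] <- paste(ch, collapse = "")
        q <- strsplit(qual[i], "")[[1]]
        q[pos] <- "5"                                      # Q20 at error sites
        qual[i] <- paste(q, collapse = "")
      }
    }
    list(seqs = seqs, qual = qual)
  }
  f <- inject(fwd, config$per_base_error)
  r <- inject(rev_, config$per_base_error)

  read_id <- sprintf("%s|T%06d|%03d", sample_id, read_tx, read_idx)
  reads_fwd <- tibble(read_id = read_id, bases = f$seqs, qual_string = f$qual)
  reads_rev <- tibble(read_id = read_id, bases = r$seqs, qual_string = r$qual)

  truth <- cells[tx_cell, ]
  truth$transcript_id <- sprintf("%s|T%06d", sample_id, seq_len(n_tx))
  truth$umi5 <- umi5
  truth$umi3 <- umi3
  truth$signature <- sig
  truth$n_reads <- n_reads_tx
  truth$sample_id <- sample_id

  res <- list(reads_fwd = reads_fwd, reads_rev = reads_rev, truth = truth,
              signatures = sig)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fq1 <- file.path(out_dir, paste0(sample_id, "_R1.fastq.gz"))
    fq2 <- file.path(out_dir, paste0(sample_id, "_R2.fastq.gz"))
    write_fastq(reads_fwd, fq1)
    write_fastq(reads_rev, fq2)
    truth_path <- file.path(out_dir, paste0(sample_id, "_truth.tsv"))
    tt <- truth
    tt$mut_positions <- vapply(tt$mut_positions, paste, "", collapse = ";")
    utils::write.table(tt, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
    res$fastq <- c(fwd = fq1, rev = fq2)
    res$truth_path <- truth_path
  }
  res
}

#' Plan multi-timepoint samples with planted persistent clones
#'
#' Simulates one independent repertoire per named sample and plants
#' `n_persistent` dedicated memory cells whose exact sequence recurs in
#' every sample (sequence-identical members; UMIs are drawn freshly per
#' sample at read generation and never reused across samples). Half of the
#' planted cells (by `mutated_fraction`) carry ~3% SHM in the V core, the
#' rest are unmutated, so the strict >1% mutated classification is exercised
#' on both sides.
#'
#' @param config base [sim_config()]; each sample uses a seed derived from it.
#' @param ref germline reference.
#' @param sample_ids at least two sample names (timepoints).
#' @param n_persistent number of planted persistent cells; may instead be
#'   given as `persistent_fraction` of `n_cells` (must be <= 1).
#' @param persistent_fraction optional fraction alternative to `n_persistent`.
#' @param mutated_fraction fraction of planted cells carrying >1% SHM.
#' @return list with `samples` (named list of cell tibbles) and
#'   `persistent_truth` (planted core sequences with mutated flag).
#' @export
plan_timepoints <- function(config, ref, sample_ids,
                            n_persistent = 50L, persistent_fraction = NULL,
                            mutated_fraction = 0.5) {
  assert_that(length(sample_ids) >= 2, "need at least two named samples")
  if (!is.null(persistent_fraction)) {
    assert_that(persistent_fraction >= 0 && persistent_fraction <= 1,
                "persistence fraction must be in [0,1]")
    n_persistent <- round(persistent_fraction * config$n_cells)
  }
  samples <- list()
  for (s in sample_ids) {
    cfg_s <- config
    cfg_s$seed <- derive_seed(config$seed, paste0("tp-", s))
    samples[[s]] <- simulate_repertoire(cfg_s, ref)
  }
  persistent_truth <- tibble()
  if (n_persistent > 0) {
    set.seed(derive_seed(config$seed, "persistent"))
    n_mutated <- round(mutated_fraction * n_persistent)
    cores <- character(0)
    planted <- list()
    i <- 0L
    while (length(planted) < n_persistent) {
      i <- i + 1L
      rec <- recombine(ref)
      mutated <- length(planted) < n_mutated
      if (mutated) {
        # ~3% SHM in the V core (denominator = bases before the junction)
        cys_len <- rec$junction_start - rec$vdj_start
        n_mut <- max(2L, round(0.032 * cys_len))
        mut <- mutate_seq(rec$sequence_prefix, rec$vdj_start, rec$junction_start, n_mut)
      } else {
        mut <- list(sequence = rec$sequence_prefix, positions = integer(0))
      }
      subtype <- if (mutated) "IgG1" else "IgM"
      stub <- ref$constant_stubs$sequence[ref$constant_stubs$isotype ==
                                            subtype_to_stub[[subtype]]]
      seq_full <- paste0(mut$sequence, stub)
      core <- str_sub(seq_full, rec$core_start + 1, rec$core_end)
      if (core %in% cores) next
      cores <- c(cores, core)
      cys_len <- rec$junction_start - rec$vdj_start
      planted[[length(planted) + 1]] <- tibble(
        cell_id = sprintf("P%04d", length(planted) + 1L),
        clone_id_true = sprintf("PERSIST%04d", length(planted) + 1L),
        compartment = "memory",
        v_call_true = rec$v_call, d_call_true = rec$d_call,
        j_call_true = rec$j_call,
        c_call_true = subtype_to_stub[[subtype]],
        isotype_true = isotype_class(subtype),
        sequence = seq_full,
        junction_true = str_sub(seq_full, rec$junction_start + 1, rec$junction_end),
        junction_start = rec$junction_start, junction_end = rec$junction_end,
        core_start = rec$core_start, core_end = rec$core_end,
        vdj_start = rec$vdj_start, vdj_end = rec$vdj_end,
        mut_positions = list(mut$positions),
        n_mut = length(mut$positions),
        shm_true = 100 * length(mut$positions) / cys_len,
        core_true = core, mutated_true = mutated
      )
    }
    planted <- bind_rows(planted)
    persistent_truth <- planted[, c("cell_id", "core_true", "mutated_true",
                                    "isotype_true", "shm_true")]
    for (s in sample_ids) {
      add <- planted
      add$cell_id <- paste0(s, "-", add$cell_id)
      add$core_true <- NULL; add$mutated_true <- NULL
      samples[[s]] <- bind_rows(samples[[s]], add)
    }
  }
  list(samples = samples, persistent_truth = persistent_truth)
}

#' Spike monoclonal-antibody lineages into a simulated repertoire
#'
#' Generates `n_mabs` memory-type heavy-chain sequences standing in for
#' recombinantly expressed mAbs. The first `n_matched` receive
#' `relatives_per_mab` planted clonal relatives in the repertoire (same
#' V/J/junction length, 1-2 CDRH3 substitutions — well under a 12%
#' threshold — plus a few V-region mutations); the remaining mAbs receive
#' relatives whose CDRH3 distance is ~20%, beyond the threshold, so a
#' constant-threshold search must reject them.
#'
#' @param cells repertoire cell tibble to augment.
#' @param config a [sim_config()] (only the seed is used).
#' @param ref germline reference.
#' @param n_mabs number of mAbs.
#' @param n_matched how many get in-threshold relatives.
#' @param relatives_per_mab planted relatives per mAb.
#' @return list `mabs` (tibble name/sequence plus truth), `cells`
#'   (augmented repertoire), `truth` (per-mAb expected match flag).
#' @export
spike_mab_lineages <- function(cells, config, ref, n_mabs = 8L, n_matched = 7L,
                               relatives_per_mab = 3L) {
  set.seed(derive_seed(config$seed, "mabs"))
  mabs <- list(); extra <- list(); truth <- list()
  for (i in seq_len(n_mabs)) {
    # long N-insertions guarantee CDRH3 long enough to place mutations
    rec <- recombine(ref, min_n = 8L, max_n = 10L)
    mut <- mutate_seq(rec$sequence_prefix, rec$vdj_start, rec$vdj_end,
                      stats::rbinom(1, rec$vdj_end - rec$vdj_start, 0.03))
    stub <- ref$constant_stubs$sequence[ref$constant_stubs$isotype == "IGHG1"]
    mab_seq <- paste0(mut$sequence, stub)
    mab_name <- sprintf("MAB%02d", i)
    cdrh3_start <- rec$junction_start + 3L
    cdrh3_end <- rec$junction_end - 3L
    cdrh3_len <- cdrh3_end - cdrh3_start
    in_threshold <- i <= n_matched
    n_cdrh3_mut <- if (in_threshold) {
      min(2L, floor(0.12 * cdrh3_len))
    } else {
      ceiling(0.2 * cdrh3_len)
    }
    for (r in seq_len(relatives_per_mab)) {
      relmut <- mutate_seq(mut$sequence, cdrh3_start, cdrh3_end, n_cdrh3_mut)
      relmut2 <- mutate_seq(relmut$sequence, rec$vdj_start, rec$junction_start,
                            sample(1:3, 1))
      rel_seq <- paste0(relmut2$sequence, stub)
      all_pos <- sort(unique(c(mut$positions, relmut$positions, relmut2$positions)))
      cys_len <- rec$junction_start - rec$vdj_start
      extra[[length(extra) + 1]] <- tibble(
        cell_id = sprintf("%s-REL%d", mab_name, r),
        clone_id_true = paste0("CLONE-", mab_name),
        compartment = "memory",
        v_call_true = rec$v_call, d_call_true = rec$d_call,
        j_call_true = rec$j_call, c_call_true = "IGHG1", isotype_true = "IgG",
        sequence = rel_seq,
        junction_true = str_sub(rel_seq, rec$junction_start + 1, rec$junction_end),
        junction_start = rec$junction_start, junction_end = rec$junction_end,
        core_start = rec$core_start, core_end = rec$core_end,
        vdj_start = rec$vdj_start, vdj_end = rec$vdj_end,
        mut_positions = list(all_pos), n_mut = length(all_pos),
        shm_true = 100 * sum(all_pos < rec$junction_start) / cys_len
      )
    }
    mabs[[i]] <- tibble(name = mab_name, sequence = mab_seq,
                        v_call_true = rec$v_call, j_call_true = rec$j_call,
                        junction_true = str_sub(mab_seq, rec$junction_start + 1,
                                                rec$junction_end))
    truth[[i]] <- tibble(name = mab_name, expect_match = in_threshold)
  }
  list(mabs = bind_rows(mabs), cells = bind_rows(cells, bind_rows(extra)),
       truth = bind_rows(truth))
}

#' Spike a single large clone into a repertoire
#'
#' Adds one clonal family of `size` members sharing a founder recombination,
#' each member mutated at `shm_rate` over the V(D)J region. Used to plant
#' dominant clones for immunodominance analyses.
#'
#' @inheritParams spike_mab_lineages
#' @param size clone size (members).
#' @param shm_rate per-site mutation rate for members.
#' @param subtype isotype subtype for all members.
#' @param tag clone id tag used in truth.
#' @return augmented cell tibble.
#' @export
spike_clone <- function(cells, config, ref, size = 166L, shm_rate = 0.03,
                        subtype = "IgG1", tag = "DOMINANT") {
  set.seed(derive_seed(config$seed, paste0("spike-", tag)))
  rec <- recombine(ref)
  stub <- ref$constant_stubs$sequence[ref$constant_stubs$isotype ==
                                        subtype_to_stub[[subtype]]]
  vdj_len <- rec$vdj_end - rec$vdj_start
  cys_len <- rec$junction_start - rec$vdj_start
  out <- lapply(seq_len(size), function(m) {
    mut <- mutate_seq(rec$sequence_prefix, rec$vdj_start, rec$vdj_end,
                      stats::rbinom(1, vdj_len, shm_rate))
    seq_full <- paste0(mut$sequence, stub)
    tibble(
      cell_id = sprintf("%s-%04d", tag, m), clone_id_true = paste0("CLONE-", tag),
      compartment = "memory",
      v_call_true = rec$v_call, d_call_true = rec$d_call, j_call_true = rec$j_call,
      c_call_true = subtype_to_stub[[subtype]], isotype_true = isotype_class(subtype),
      sequence = seq_full,
      junction_true = str_sub(seq_full, rec$junction_start + 1, rec$junction_end),
      junction_start = rec$junction_start, junction_end = rec$junction_end,
      core_start = rec$core_start, core_end = rec$core_end,
      vdj_start = rec$vdj_start, vdj_end = rec$vdj_end,
      mut_positions = list(mut$positions), n_mut = length(mut$positions),
      shm_true = 100 * sum(mut$positions < rec$junction_start) / cys_len
    )
  })
  bind_rows(cells, bind_rows(out))
}
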