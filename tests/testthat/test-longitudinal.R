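test_that("core trimming spans Kabat 12-136 and depends only on the span", {
  ref <- ref_fixture
  v <- ref$v_genes$sequence[1]; vn <- ref$v_genes$name[1]
  j <- ref$j_genes$sequence[1]; jn <- ref$j_genes$name[1]
  q <- paste0(v, j)
  ann <- annotate_rearrangements(tibble::tibble(sequence_id = "g", sequence = q),
                                 ref)$rearrangements
  core <- trim_core_region(ann)
  k12 <- ref$regions[ref$regions$gene == vn & ref$regions$region == "KABAT12", ]
  k136 <- ref$regions[ref$regions$gene == jn & ref$regions$region == "KABAT136", ]
  expected <- paste0(substring(v, k12$start + 1), substr(j, 1, k136$end))
  expect_identical(core, expected)
  # changing bases outside the span leaves the core untouched
  q2 <- paste0("TTTTTT", q, "GGGG")
  ann2 <- annotate_rearrangements(tibble::tibble(sequence_id = "g2", sequence = q2),
                                  ref)$rearrangements
  expect_identical(trim_core_region(ann2), core)
})

test_that("persistence requires presence in every sample and is monotone", {
  mk <- function(cores, sample) tibble::tibble(
    sequence_id = paste0(sample, seq_along(cores)),
    sequence = cores, core_start = 0L, core_end = nchar(cores),
    isotype = "IgG", shm_percent = 0.5,
    umi_signatures = lapply(seq_along(cores), function(i) paste0(sample, "-", i)))
  s1 <- mk(c("AAAA", "CCCC", "GGGG"), "X")
  s2 <- mk(c("AAAA", "CCCC"), "Y")
  s3 <- mk(c("AAAA", "TTTT"), "Z")
  two <- find_persistent_sequences(list(s1, s2))
  expect_setequal(two$core_sequence, c("AAAA", "CCCC"))
  three <- find_persistent_sequences(list(s1, s2, s3))
  expect_identical(three$core_sequence, "AAAA")   # monotone shrinkage
  # a sample against itself returns all its unique cores
  self <- find_persistent_sequences(list(s1, s1))
  expect_setequal(self$core_sequence, s1$sequence)
  # shared UMI signatures across samples flag contamination
  s2b <- s2; s2b$umi_signatures[[1]] <- "X-1"
  flagged <- find_persistent_sequences(list(s1, s2b))
  expect_true(flagged$contamination_suspect[flagged$core_sequence == "AAAA"])
})

test_that("mutated classification is strictly greater than 1% SHM", {
  mk <- function(shm, sample) tibble::tibble(
    sequence_id = paste0(sample, "1"), sequence = "AAAA",
    core_start = 0L, core_end = 4L, isotype = "IgG", shm_percent = shm,
    umi_signatures = list(paste0(sample, "-sig")))
  at_cutoff <- find_persistent_sequences(list(mk(1.0, "A"), mk(1.0, "B")))
  expect_false(at_cutoff$mutated)
  below <- find_persistent_sequences(list(mk(0.5, "A"), mk(0.5, "B")))
  expect_false(below$mutated)
  above <- find_persistent_sequences(list(mk(1.2, "A"), mk(1.2, "B")))
  expect_true(above$mutated)
})

test_that("planted persistent sequences are recovered exactly through the pipeline", {
  cfg <- sim_config(n_cells = 80, per_base_error = 0, seed = 71)
  plan <- plan_timepoints(cfg, ref_fixture, c("T1", "T2", "T3"), n_persistent = 12)
  used <- character(0); samples <- list()
  for (s in names(plan$samples)) {
    gen <- generate_reads(plan$samples[[s]], cfg, sample_id = s,
                          used_signatures = used)
    used <- c(used, gen$signatures)
    pre <- preprocess_sample(gen$reads_fwd, gen$reads_rev, sample_id = s,
                             min_reads_per_umi = 1)
    samples[[s]] <- annotate_rearrangements(pre$sequences, ref_fixture)$rearrangements
  }
  pers <- find_persistent_sequences(samples)
  expect_identical(nrow(pers), 12L)
  expect_true(all(pers$umi_disjoint))
  m <- match(pers$core_sequence, plan$persistent_truth$core_true)
  expect_false(anyNA(m))
  expect_identical(pers$mutated, plan$persistent_truth$mutated_true[m])
})

test_that("an identical mAb matches; a 13.3% CDRH3 neighbour does not", {
  cfg <- sim_config(n_cells = 50, per_base_error = 0, seed = 72)
  cells <- simulate_repertoire(cfg, ref_fixture)
  r <- annotate_cells(cells)
  # identical mAb: pick a repertoire member as the mAb itself
  mab_same <- tibble::tibble(name = "SELF", sequence = cells$sequence[1])
  rep1 <- match_mabs_to_clones(r, mab_same, ref_fixture, threshold = 0.12)
  expect_identical(rep1$status, "matched")
  expect_gte(rep1$n_matching_sequences, 1L)
  # hand-built neighbour at CDRH3 distance 4/30 = 13.3%: shares V/J/length
  donor <- cells[which(nchar(cells$junction_true) == 36)[1], ]
  if (!is.na(donor$cell_id[1])) {
    cdrh3_start <- donor$junction_start + 3
    far <- perturb_at(donor$sequence, cdrh3_start + c(1, 8, 15, 22))
    mab_far <- tibble::tibble(name = "FAR", sequence = far)
    rep2 <- match_mabs_to_clones(r[r$sequence_id == donor$cell_id, ],
                                 mab_far, ref_fixture, threshold = 0.12)
    expect_identical(rep2$status, "unmatched")
    # the same neighbour is accepted once the threshold admits 13.3%
    rep3 <- match_mabs_to_clones(r[r$sequence_id == donor$cell_id, ],
                                 mab_far, ref_fixture, threshold = 0.14)
    expect_identical(rep3$status, "matched")
  }
  # unannotatable mAb is reported as such
  repx <- match_mabs_to_clones(r, tibble::tibble(name = "JUNK",
                                                 sequence = strrep("ACGT", 50)),
                               ref_fixture)
  expect_identical(repx$status, "unmatched_unannotatable")
})

test_that("spiked mAb lineages drive the expected 7-of-8 match structure", {
  cfg <- sim_config(n_cells = 120, condition = "stimulated",
                    per_base_error = 0, seed = 73)
  cells <- simulate_repertoire(cfg, ref_fixture)
  sp <- spike_mab_lineages(cells, cfg, ref_fixture, n_mabs = 8, n_matched = 7)
  r <- annotate_cells(sp$cells)
  rep_ <- match_mabs_to_clones(r, sp$mabs, ref_fixture, threshold = 0.12)
  m <- match(rep_$name, sp$truth$name)
  expect_identical(rep_$status == "matched", sp$truth$expect_match[m])
})

test_that("stepwise lineage reproduces germline -> A -> B with unit edges", {
  cfg <- sim_config(n_cells = 1, shm_rate = c(naive = 0, memory = 0),
                    compartment_weights = c(naive = 1, memory = 0), seed = 2)
  cells <- simulate_repertoire(cfg, ref_fixture)
  s0 <- cells$sequence[1]
  sA <- perturb_at(s0, 60)
  sB <- perturb_at(sA, 90)
  r <- annotate_rearrangements(
    tibble::tibble(sequence_id = c("A", "B"), sequence = c(sA, sB),
                   isotype = "IgM", umi_count = c(3L, 1L)), ref_fixture)$rearrangements
  g <- germline_rearrangement(r, ref_fixture)
  tree <- build_lineage(r, g)
  expect_identical(nrow(tree$nodes), 3L)
  expect_identical(tree$nodes$kind, c("germline", "observed", "observed"))
  expect_identical(tree$edges$nt_mutations, c(1, 1))
  expect_identical(tree$edges$parent[1], "GERMLINE")
  expect_identical(tree$edges$parent[2], tree$edges$child[1])
  # singleton clone: one germline -> member edge
  r1 <- r[1, ]
  t1 <- build_lineage(r1, germline_rearrangement(r1, ref_fixture))
  expect_identical(nrow(t1$edges), 1L)
  # newick export is well-formed and readable by ape
  nwk <- lineage_to_newick(tree)
  phylo <- ape::read.tree(text = nwk)
  expect_identical(sort(c(phylo$tip.label, phylo$node.label)),
                   sort(tree$nodes$id))
})

test_that("lineage total length matches the Kruskal oracle and the star bound", {
  cfg <- sim_config(n_clones = 40, n_cells = 0, condition = "stimulated",
                    compartment_weights = c(naive = 0, memory = 1),
                    clone_size = list(naive = list(exponent = 3.5, max = 3),
                                      memory = list(exponent = 1.2, max = 8)),
                    per_base_error = 0, seed = 74)
  cells <- simulate_repertoire(cfg, ref_fixture)
  r <- annotate_cells(cells)
  r <- cluster_clones(r, 0.12)
  checked <- 0L
  for (cid in unique(r$clone_id)) {
    members <- r[r$clone_id == cid, ]
    if (nrow(members) < 2 || nrow(members) > 8) next
    if (dplyr::n_distinct(members$v_call) > 1) next
    g <- germline_rearrangement(members, ref_fixture)
    tree <- build_lineage(members, g)
    aligned <- igflow:::aligned_vdj(members)
    seqs <- c(g, setdiff(sort(unique(aligned)), g))
    d <- igflow:::pairwise_hamming(seqs)
    expect_equal(lineage_total_length(tree), kruskal_mst_weight(d))
    star <- sum(d[1, -1])
    expect_lte(lineage_total_length(tree), star)
    checked <- checked + 1L
  }
  expect_gt(checked, 3)
})

test_that("immunodominance grid conserves clone counts and places overlays", {
  clones <- tibble::tibble(
    clone_id = sprintf("CL%02d", 1:20),
    abundance_reads = c(rep(1, 15), 5, 20, 80, 166, 300),
    mean_shm = c(rep(0, 15), 1.2, 2.5, 4.0, 3.0, 6.5))
  g <- immunodominance_grid(clones)
  expect_identical(sum(g$grid$count), 20L)
  # all-singleton unmutated repertoire: all mass in the first cell
  g0 <- immunodominance_grid(tibble::tibble(clone_id = "a",
                                            abundance_reads = 1, mean_shm = 0))
  expect_identical(max(g0$grid$count), 1L)
  nonzero <- g0$grid[g0$grid$count > 0, ]
  expect_identical(nonzero$abundance_bin, "(0,1]")
  # a planted dominant clone lands in a high-abundance bin with its mAb label
  mabs <- tibble::tibble(name = "INF-like", status = "matched",
                         n_matching_sequences = 166L, clone_id = "CL19")
  g2 <- immunodominance_grid(clones, mabs)
  expect_identical(g2$overlay$name, "INF-like")
  expect_equal(g2$overlay$abundance_reads, 166)
  expect_equal(g2$overlay$mean_shm, 3.0)
})
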