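#' Trim rearrangements to the Kabat 12-136 core
#'
#' Returns the nucleotide substring spanning the codons mapped to Kabat
#' positions 12 (on the V segment) through 136 (on FWR4), as projected onto
#' the query during annotation. Rows with unresolved boundaries get `NA`
#' and are excluded from persistence analyses.
#'
#' @param rearrs annotated rearrangement tibble (with `core_start`,
#'   `core_end`).
#' @return character vector of core sequences (NA where unresolved).
#' @export
trim_core_region <- function(rearrs) {
  ok <- !is.na(rearrs$core_start) & !is.na(rearrs$core_end) &
    rearrs$core_end > rearrs$core_start
  out <- rep(NA_character_, nrow(rearrs))
  out[ok] <- substring(rearrs$sequence[ok], rearrs$core_start[ok] + 1L,
                       rearrs$core_end[ok])
  out
}

#' Find sequences persisting across all samples
#'
#' Exact-string intersection of Kabat-trimmed core sequences across every
#' supplied sample. Matching is nucleotide-only (isotype-agnostic) but each
#' persistent set records the isotypes and SHM observed per sample, a
#' consensus isotype, and a mutated flag (strictly >`mutated_cutoff`% SHM).
#' UMI disjointness between samples is verified: a persistent core whose UMI
#' signatures recur across samples is flagged contamination-suspect and
#' excluded from headline counts.
#'
#' @param samples named list (>= 2) of annotated rearrangement tibbles.
#' @param mutated_cutoff SHM percent above which a set is called mutated
#'   (strict inequality; default 1).
#' @return tibble: `core_sequence`, `isotype_consensus`, `mean_shm`,
#'   `mutated`, `umi_disjoint`, `contamination_suspect`, plus per-sample
#'   list-columns `isotypes`, `shm`, `umi_signatures`.
#' @export
find_persistent_sequences <- function(samples, mutated_cutoff = 1) {
  assert_that(length(samples) >= 2, "need at least two samples")
  cores <- lapply(samples, function(s) {
    s$core <- trim_core_region(s)
    s[!is.na(s$core), ]
  })
  shared <- Reduce(intersect, lapply(cores, function(s) s$core))
  if (length(shared) == 0) {
    return(tibble(core_sequence = character(), isotype_consensus = character(),
                  mean_shm = numeric(), mutated = logical(),
                  umi_disjoint = logical(), contamination_suspect = logical()))
  }
  out <- lapply(sort(shared), function(core) {
    hits <- lapply(cores, function(s) s[s$core == core, ])
    isotypes <- lapply(hits, function(h) unique(h$isotype[!is.na(h$isotype)]))
    shm <- lapply(hits, function(h) h$shm_percent)
    sigs <- lapply(hits, function(h) unique(unlist(h$umi_signatures)))
    all_iso <- unlist(isotypes)
    iso_cons <- if (length(all_iso)) names(sort(table(all_iso), decreasing = TRUE))[1] else NA_character_
    pairs <- utils::combn(length(sigs), 2)
    disjoint <- all(vapply(seq_len(ncol(pairs)), function(k) {
      length(intersect(sigs[[pairs[1, k]]], sigs[[pairs[2, k]]])) == 0
    }, TRUE))
    mshm <- mean(unlist(shm), na.rm = TRUE)
    tibble(core_sequence = core, isotype_consensus = iso_cons,
           mean_shm = mshm, mutated = mshm > mutated_cutoff,
           umi_disjoint = disjoint, contamination_suspect = !disjoint,
           isotypes = list(isotypes), shm = list(shm),
           umi_signatures = list(sigs))
  })
  bind_rows(out)
}

#' Match monoclonal antibodies to repertoire clonal families
#'
#' Each mAb heavy chain is annotated through the same germline pipeline and
#' then joins constant-threshold clonal clustering as an ordinary sequence:
#' same V gene, same J gene, same CDRH3 length, and up to `threshold`
#' normalized CDRH3 mismatch (default 12%), single linkage. A mAb is
#' "matched" when it co-clusters with at least one repertoire sequence.
#' This search is intended for the all-unique-reads repertoire view
#' (`min_reads_per_umi = 1`).
#'
#' @param rearrs annotated repertoire rearrangement tibble.
#' @param mabs tibble with `name` and `sequence` columns.
#' @param ref `germline_reference`.
#' @param threshold normalized CDRH3 distance threshold (default 0.12).
#' @return tibble per mAb: `name`, `status` (`matched`, `unmatched`,
#'   `unmatched_unannotatable`), `n_matching_sequences`, `clone_id`.
#' @export
match_mabs_to_clones <- function(rearrs, mabs, ref, threshold = 0.12) {
  ann <- annotate_rearrangements(
    tibble(sequence_id = paste0("MAB|", mabs$name), sequence = mabs$sequence),
    ref)
  mab_rearrs <- ann$rearrangements
  annotated <- mabs$name %in% sub("^MAB\\|", "", mab_rearrs$sequence_id)
  shared <- c("sequence_id", "sequence", "v_call", "j_call", "junction",
              "junction_length", "cdr3")
  pool <- bind_rows(
    rearrs[, intersect(names(rearrs), c(shared, "isotype", "umi_count"))],
    mab_rearrs[, intersect(names(mab_rearrs), shared)]
  )
  pool <- cluster_clones(pool, threshold, region = "cdr3")
  is_mab <- grepl("^MAB\\|", pool$sequence_id)
  out <- lapply(mabs$name, function(nm) {
    if (!nm %in% sub("^MAB\\|", "", pool$sequence_id[is_mab])) {
      return(tibble(name = nm, status = "unmatched_unannotatable",
                    n_matching_sequences = 0L, clone_id = NA_character_))
    }
    cid <- pool$clone_id[pool$sequence_id == paste0("MAB|", nm)][1]
    members <- pool[pool$clone_id == cid & !is_mab, ]
    tibble(name = nm,
           status = if (nrow(members) > 0) "matched" else "unmatched",
           n_matching_sequences = nrow(members),
           clone_id = if (nrow(members) > 0) cid else NA_character_)
  })
  bind_rows(out)
}

#' Reconstruct the clone's germline rearrangement
#'
#' Builds the inferred naive ancestor for a clone over the aligned V(D)J
#' span (FWR1 start through FWR4 end): germline V bases outside the
#' junction, the per-position majority of member junctions inside it (the
#' untemplated region has no germline), and germline J bases after the
#' junction.
#'
#' @param members clone rearrangement tibble (shared V/J/junction length).
#' @param ref `germline_reference`.
#' @return a single germline sequence string over the aligned span.
#' @export
germline_rearrangement <- function(members, ref) {
  v_seq <- gene_sequence(ref, members$v_call[1])
  j_seq <- gene_sequence(ref, members$j_call[1])
  cys <- gene_region(ref, members$v_call[1], "CYS")
  jwf <- gene_region(ref, members$j_call[1], "JWF")
  junctions <- members$junction
  jl <- nchar(junctions[1])
  assert_that(all(nchar(junctions) == jl), "members must share junction length")
  jm <- seq_matrix(junctions)
  maj <- apply(jm, 2, function(col) {
    tb <- sort(table(col), decreasing = TRUE)
    as.integer(names(tb)[1])
  })
  paste0(substr(v_seq, 1, cys[1]), intToUtf8(maj), substring(j_seq, jwf[2] + 1))
}

#' Build a parsimony lineage for one clonal family
#'
#' Minimum-spanning-tree over the germline ancestor and the clone's distinct
#' aligned V(D)J sequences under Hamming distance, rooted at the germline.
#' Edges spanning two or more mutations keep their full mutational-step
#' count as the edge label (intermediate haplotypes are only materialised
#' when they equal another observed member, in which case they are already
#' nodes). Ties during tree growth break deterministically by sequence
#' lexicographic order. Nodes carry the isotype set and summed UMI read
#' counts of the sequences they represent.
#'
#' @param members clone rearrangement tibble; all members must share V gene,
#'   J gene and junction length.
#' @param germline germline sequence over the aligned span (e.g. from
#'   [germline_rearrangement()]); must match the members' aligned length.
#' @return `lineage_tree`: list with `nodes` (id, sequence, kind, isotypes,
#'   umi_reads) and `edges` (parent, child, nt_mutations).
#' @export
build_lineage <- function(members, germline) {
  aligned <- aligned_vdj(members)
  assert_that(length(unique(nchar(c(aligned, germline)))) == 1,
              "members (and germline) must have equal aligned length")
  umi <- members$umi_count %||% rep(1L, nrow(members))
  iso <- members$isotype %||% rep(NA_character_, nrow(members))
  uniq <- sort(unique(aligned))
  node_iso <- lapply(uniq, function(s) sort(unique(stats::na.omit(iso[aligned == s]))))
  node_umi <- vapply(uniq, function(s) sum(umi[aligned == s]), 0)
  seqs <- c(germline, setdiff(uniq, germline))
  kinds <- c("germline", rep("observed", length(seqs) - 1L))
  # if the germline itself was observed, it stays the root but keeps counts
  obs_at <- match(seqs, uniq)
  n <- length(seqs)
  d <- pairwise_hamming(seqs)
  # Prim's algorithm from the germline root with lexicographic tie-breaking
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  edges <- list()
  while (!all(in_tree)) {
    cand <- expand.grid(p = which(in_tree), c = which(!in_tree))
    w <- d[cbind(cand$p, cand$c)]
    best_w <- min(w)
    sel <- cand[w == best_w, , drop = FALSE]
    ord <- order(seqs[sel$c], seqs[sel$p])
    pick <- sel[ord[1], ]
    edges[[length(edges) + 1]] <- tibble(parent = pick$p, child = pick$c,
                                         nt_mutations = best_w)
    in_tree[pick$c] <- TRUE
  }
  edges <- bind_rows(edges)
  ids <- c("GERMLINE", sprintf("N%03d", seq_len(n - 1L)))
  nodes <- tibble(
    id = ids, sequence = seqs, kind = kinds,
    isotypes = lapply(obs_at, function(k) if (is.na(k)) character(0) else node_iso[[k]]),
    umi_reads = vapply(obs_at, function(k) if (is.na(k)) 0 else node_umi[k], 0))
  edges$parent <- ids[edges$parent]
  edges$child <- ids[edges$child]
  structure(list(nodes = nodes, edges = edges), class = "lineage_tree")
}

# internal: member sequences over the aligned V(D)J span (FWR1..FWR4)
aligned_vdj <- function(members) {
  assert_that(all(!is.na(members$fwr1_start)) && all(!is.na(members$fwr4_end)),
              "members must carry region coordinates")
  substring(members$sequence, members$fwr1_start + 1L, members$fwr4_end)
}

#' Total mutational length of a lineage tree
#' @param tree a `lineage_tree`.
#' @return sum of edge mutation counts.
#' @export
lineage_total_length <- function(tree) sum(tree$edges$nt_mutations)

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf("lineage_tree: %d nodes (%d observed), total length %d\n",
              nrow(x$nodes), sum(x$nodes$kind == "observed"),
              lineage_total_length(x)))
  invisible(x)
}

#' Export a lineage tree as Newick
#'
#' Edge lengths are nucleotide mutation counts; node ids are used as labels.
#'
#' @param tree a `lineage_tree`.
#' @param path optional file to write to.
#' @return the Newick string, invisibly if written to file.
#' @export
lineage_to_newick <- function(tree, path = NULL) {
  kids <- split(seq_len(nrow(tree$edges)), tree$edges$parent)
  fmt <- function(id, blen) {
    ch <- kids[[id]]
    lab <- if (is.null(ch)) id else {
      inner <- paste(vapply(ch, function(e)
        fmt(tree$edges$child[e], tree$edges$nt_mutations[e]), ""), collapse = ",")
      sprintf("(%s)%s", inner, id)
    }
    if (is.na(blen)) lab else sprintf("%s:%d", lab, blen)
  }
  nwk <- paste0(fmt("GERMLINE", NA), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Immunodominance grid of clonal families
#'
#' Two-dimensional histogram of clones over read abundance (log2-scaled
#' bins) and mean SHM (linear bins), with named mAb clones overlaid as
#' points at their clone's (read abundance, mean SHM). Cell counts sum to
#' the clone count.
#'
#' @param clones clone summary tibble from [clone_table()].
#' @param mab_matches optional match report from [match_mabs_to_clones()];
#'   matched mAbs are placed on the grid.
#' @param shm_bin_width SHM bin width in percent (default 1).
#' @return list with `grid` (tibble: abundance_bin, shm_bin, count, bin
#'   boundaries) and `overlay` (tibble of mAb points).
#' @export
immunodominance_grid <- function(clones, mab_matches = NULL, shm_bin_width = 1) {
  max_ab <- max(clones$abundance_reads)
  ab_breaks <- 2^(0:ceiling(log2(max(2, max_ab + 1))))
  ab_breaks <- c(0, ab_breaks)
  shm_max <- max(c(clones$mean_shm, shm_bin_width), na.rm = TRUE)
  shm_breaks <- seq(0, ceiling(shm_max / shm_bin_width) * shm_bin_width + shm_bin_width,
                    by = shm_bin_width)
  ab_bin <- cut(clones$abundance_reads, ab_breaks, include.lowest = FALSE)
  shm_bin <- cut(clones$mean_shm, shm_breaks, include.lowest = TRUE, right = FALSE)
  tab <- as.data.frame(table(abundance_bin = ab_bin, shm_bin = shm_bin),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "count"
  overlay <- tibble(name = character(), clone_id = character(),
                    abundance_reads = numeric(), mean_shm = numeric())
  if (!is.null(mab_matches)) {
    hit <- mab_matches[mab_matches$status == "matched", ]
    idx <- match(hit$clone_id, clones$clone_id)
    found <- !is.na(idx)
    overlay <- tibble(name = hit$name[found], clone_id = hit$clone_id[found],
                      abundance_reads = clones$abundance_reads[idx[found]],
                      mean_shm = clones$mean_shm[idx[found]])
  }
  list(grid = as_tibble(tab), overlay = overlay,
       ab_breaks = ab_breaks, shm_breaks = shm_breaks)
}
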