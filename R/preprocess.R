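#' Filter reads by mean Phred quality
#'
#' Keeps reads whose arithmetic mean Phred score is at least `q_mean`
#' (boundary inclusive); order is preserved. This is the keep-if-mean-Q>=20
#' reading of the usual amplicon QC step.
#'
#' @param reads tibble with `bases` and `qual_string` columns.
#' @param q_mean minimum mean Phred score (default 20).
#' @return the retained rows of `reads`.
#' @export
filter_by_quality <- function(reads, q_mean = 20) {
  assert_that(all(nchar(reads$qual_string) > 0), "empty quality string")
  means <- vapply(reads$qual_string,
                  function(q) mean(utf8ToInt(q) - 33L), 0, USE.NAMES = FALSE)
  reads[means >= q_mean, , drop = FALSE]
}

# internal: mismatch count of `pattern` against substrings of `x` at offset
mismatches_at <- function(pattern, x, offset = 1L) {
  plen <- nchar(pattern)
  sub <- str_sub(x, offset, offset + plen - 1L)
  ok <- nchar(sub) == plen
  out <- rep(NA_integer_, length(x))
  if (any(ok)) {
    m <- matrix(utf8ToInt(paste(sub[ok], collapse = "")), ncol = plen, byrow = TRUE)
    out[ok] <- as.integer(colSums(t(m) != utf8ToInt(pattern)))
  }
  out
}

#' Annotate reads with primer and UMI
#'
#' Identifies the best-matching primer anchor within the first
#' `search_window` start offsets of each read (at most `max_mismatch`
#' mismatches), excises the adjacent UMI of the primer's declared length, and
#' standardises it to `umi8`, the first 8 nt. Reads matching no primer, or
#' tied between two primers at equal mismatch count, are dropped and counted.
#'
#' @param reads read tibble (`read_id`, `bases`, `qual_string`).
#' @param primer_set primer tibble (see [read_primer_set()]).
#' @param end which primer end to use: `"5"` for forward reads, `"3"` for
#'   reverse reads.
#' @param max_mismatch maximum primer mismatches (default 2).
#' @param search_window number of candidate start offsets scanned (default 3).
#' @return list with `reads` (annotated, primer+UMI trimmed off; columns
#'   `primer_name`, `umi`, `umi8` added) and `log` (named drop counts).
#' @export
extract_primer_and_umi <- function(reads, primer_set, end = c("5", "3"),
                                   max_mismatch = 2L, search_window = 3L) {
  end <- match.arg(end)
  pr <- primer_set[primer_set$end == end, ]
  assert_that(nrow(pr) > 0, "no primers declared for the %s' end", end)
  n <- nrow(reads)
  best_mm <- rep(Inf, n); best_primer <- rep(NA_integer_, n)
  best_off <- rep(NA_integer_, n); tied <- rep(FALSE, n)
  for (p in seq_len(nrow(pr))) {
    mm_p <- rep(Inf, n); off_p <- rep(NA_integer_, n)
    for (o in seq_len(search_window)) {
      mm <- mismatches_at(pr$sequence[p], reads$bases, o)
      better <- !is.na(mm) & mm < mm_p
      mm_p[better] <- mm[better]; off_p[better] <- o
    }
    strictly <- mm_p < best_mm
    equal <- is.finite(mm_p) & mm_p == best_mm
    tied[equal] <- TRUE
    tied[strictly] <- FALSE
    best_primer[strictly] <- p; best_off[strictly] <- off_p[strictly]
    best_mm[strictly] <- mm_p[strictly]
  }
  matched <- is.finite(best_mm) & best_mm <= max_mismatch & !tied
  dropped_tie <- sum(tied & is.finite(best_mm) & best_mm <= max_mismatch)
  out <- reads[matched, , drop = FALSE]
  p_idx <- best_primer[matched]
  off <- best_off[matched]
  plen <- nchar(pr$sequence)[p_idx]
  ulen <- pr$umi_length[p_idx]
  umi_start <- off + plen
  umi <- str_sub(out$bases, umi_start, umi_start + ulen - 1L)
  keep_len_ok <- nchar(umi) == ulen
  out <- out[keep_len_ok, , drop = FALSE]
  umi <- umi[keep_len_ok]
  umi_start <- umi_start[keep_len_ok]; ulen <- ulen[keep_len_ok]
  p_idx <- p_idx[keep_len_ok]
  bio_start <- umi_start + ulen
  out$primer_name <- pr$name[p_idx]
  out$umi <- umi
  out$umi8 <- str_sub(umi, 1, 8)
  out$qual_string <- str_sub(out$qual_string, bio_start, nchar(out$bases))
  out$bases <- str_sub(out$bases, bio_start, nchar(out$bases))
  list(reads = out,
       log = c(n_in = n, n_matched = nrow(out),
               n_unmatched = n - nrow(out) - dropped_tie,
               n_tied = dropped_tie))
}

# internal: quality-weighted per-position majority consensus of equal-anchor
# reads (strings may differ slightly in length; right-padded internally).
# Returns list(seq, weights): weights are per-position winning quality sums.
consensus_core <- function(bases, qual_strings) {
  k <- length(bases)
  if (k == 1 || length(unique(bases)) == 1) {
    q <- utf8ToInt(qual_strings[1]) - 33L
    if (k > 1) q <- q * k
    return(list(seq = bases[1], weights = q))
  }
  lens <- nchar(bases)
  L <- max(lens)
  pad <- strrep("-", L - lens)
  m <- matrix(utf8ToInt(paste(paste0(bases, pad), collapse = "")),
              nrow = k, ncol = L, byrow = TRUE)
  qm <- matrix(utf8ToInt(paste(paste0(qual_strings, pad), collapse = "")) - 33L,
               nrow = k, ncol = L, byrow = TRUE)
  qm[m == utf8ToInt("-")] <- 0L
  codes <- utf8ToInt(paste(c("A", "C", "G", "T", "N"), collapse = ""))
  w <- vapply(codes, function(cc) colSums(qm * (m == cc)), numeric(L))
  if (L == 1) w <- matrix(w, nrow = 1)
  winner <- max.col(w, ties.method = "first")
  top <- w[cbind(seq_len(L), winner)]
  n_top <- rowSums(w == top & top > 0)
  cons <- c("A", "C", "G", "T", "N")[winner]
  cons[n_top > 1] <- "N"                     # tie rule
  # trim positions with >50% absent coverage from the ends
  covered <- colSums(m != utf8ToInt("-")) > k / 2
  keep <- which(covered)
  if (length(keep) == 0) return(list(seq = "", weights = numeric(0)))
  lo <- min(keep); hi <- max(keep)
  list(seq = paste(cons[lo:hi], collapse = ""), weights = top[lo:hi])
}

#' Build a consensus sequence for one UMI group
#'
#' Per-position majority base weighted by quality sums; ties become `N`;
#' terminal positions with more than 50% absent coverage are trimmed.
#' Members whose length differs from the length mode by more than
#' `length_tolerance` are discarded (and counted). After consensus, members
#' disagreeing with each other at more than 10% of positions are taken as a
#' UMI collision and the group is split by complete-linkage clustering at
#' 10% distance; each split is returned as its own consensus.
#'
#' @param bases character vector of member read sequences (one orientation).
#' @param qual_strings matching Phred+33 quality strings.
#' @param length_tolerance maximum deviation from the modal length (nt).
#' @param collision_cutoff pairwise disagreement fraction triggering a split.
#' @return list of consensus records: each has `seq`, `weights`,
#'   `read_count`, `n_discarded`.
#' @export
build_consensus <- function(bases, qual_strings, length_tolerance = 10L,
                            collision_cutoff = 0.10) {
  stopifnot(length(bases) == length(qual_strings), length(bases) >= 1)
  lens <- nchar(bases)
  mode_len <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
  ok <- abs(lens - mode_len) <= length_tolerance
  n_discarded <- sum(!ok)
  bases <- bases[ok]; qual_strings <- qual_strings[ok]
  groups <- list(seq_along(bases))
  if (length(bases) > 1) {
    trunc_len <- min(nchar(bases))
    d <- pairwise_hamming(str_sub(bases, 1, trunc_len)) / trunc_len
    if (max(d) > collision_cutoff) {
      hc <- stats::hclust(stats::as.dist(d), method = "complete")
      cl <- stats::cutree(hc, h = collision_cutoff)
      groups <- split(seq_along(bases), cl)
    }
  }
  out <- lapply(groups, function(idx) {
    cc <- consensus_core(bases[idx], qual_strings[idx])
    cc$read_count <- length(idx)
    cc$n_discarded <- 0L
    cc
  })
  out[[1]]$n_discarded <- n_discarded
  unname(out)
}

#' Assemble a forward/reverse consensus pair
#'
#' The reverse consensus is reverse-complemented, then the maximal-scoring
#' ungapped overlap of at least `min_overlap` nt with mismatch rate at most
#' `max_mismatch_rate` is sought (score = matches - mismatches). Overlap
#' disagreements are resolved toward the base with the higher quality-weight;
#' pairs with no qualifying overlap return `NULL`.
#'
#' @param fwd,rev consensus sequences (rev in read orientation).
#' @param fwd_w,rev_w per-position quality weights (defaults: unit weights).
#' @param min_overlap minimum overlap length (default 10).
#' @param max_mismatch_rate maximum overlap mismatch fraction (default 0.2).
#' @param rev_is_revcomp set TRUE when `rev` (and `rev_w`) are already in
#'   forward orientation (batch callers precompute the reverse complement).
#' @return list(`seq`, `overlap`, `mismatches`) or `NULL` on failure.
#' @export
assemble_pairs <- function(fwd, rev, fwd_w = NULL, rev_w = NULL,
                           min_overlap = 10L, max_mismatch_rate = 0.2,
                           rev_is_revcomp = FALSE) {
  if (is.null(fwd_w)) fwd_w <- rep(1, nchar(fwd))
  if (is.null(rev_w)) rev_w <- rep(1, nchar(rev))
  rc <- if (rev_is_revcomp) rev else revcomp(rev)
  rc_w <- if (rev_is_revcomp) rev_w else rev(rev_w)
  L1 <- nchar(fwd); L2 <- nchar(rc)
  # fast path: an exact suffix-prefix overlap (the common, error-free case)
  seedlen <- min(15L, L1, L2)
  seed <- substr(fwd, L1 - seedlen + 1L, L1)
  hit <- regexpr(seed, rc, fixed = TRUE)[1]
  if (hit > 0) {
    o <- hit + seedlen - 1L
    if (o >= min_overlap && o <= min(L1, L2) &&
        substr(fwd, L1 - o + 1L, L1) == substr(rc, 1, o)) {
      return(list(seq = paste0(substr(fwd, 1, L1 - o), rc),
                  overlap = o, mismatches = 0L))
    }
  }
  f <- utf8ToInt(fwd); r <- utf8ToInt(rc)
  best <- NULL; best_score <- -Inf
  for (o in seq(min(L1, L2), min_overlap)) {
    ftail <- f[(L1 - o + 1):L1]
    rhead <- r[1:o]
    mism <- sum(ftail != rhead)
    if (mism / o > max_mismatch_rate) next
    score <- (o - mism) - mism
    if (score > best_score) {
      best_score <- score
      best <- list(o = o, mism = mism)
    }
  }
  if (is.null(best)) return(NULL)
  o <- best$o
  ftail <- f[(L1 - o + 1):L1]; rhead <- r[1:o]
  fw <- fwd_w[(L1 - o + 1):L1]; rw <- rc_w[1:o]
  merged <- ifelse(fw >= rw, ftail, rhead)
  assembled <- intToUtf8(c(f[seq_len(L1 - o)], merged, r[seq(o + 1, length.out = L2 - o)]))
  list(seq = assembled, overlap = o, mismatches = best$mism)
}

#' Annotate isotype and subtype from the constant-region stub
#'
#' Matches the 3' end of each assembled sequence against the constant-region
#' stubs by ungapped comparison (at most `max_mismatch` mismatches). A tie
#' between subtypes of the same isotype keeps the isotype and reports the
#' subtype as `"ambiguous"`; a cross-isotype tie (or no qualifying stub)
#' leaves the sequence unassigned.
#'
#' @param sequences character vector of assembled sequences.
#' @param constant_stubs tibble with `isotype` (stub gene name, e.g. IGHG1)
#'   and `sequence` columns.
#' @param max_mismatch maximum stub mismatches (default 2).
#' @return tibble with `c_call` (stub name or NA), `isotype`, `subtype`.
#' @export
annotate_isotype <- function(sequences, constant_stubs, max_mismatch = 2L) {
  assert_that(nrow(constant_stubs) > 0, "constant_stubs must be nonempty")
  n <- length(sequences)
  mm <- matrix(Inf, n, nrow(constant_stubs))
  for (s in seq_len(nrow(constant_stubs))) {
    stub <- constant_stubs$sequence[s]
    slen <- nchar(stub)
    tail_s <- str_sub(sequences, nchar(sequences) - slen + 1L, nchar(sequences))
    ok <- nchar(tail_s) == slen
    if (any(ok)) {
      m <- matrix(utf8ToInt(paste(tail_s[ok], collapse = "")), ncol = slen, byrow = TRUE)
      mm[ok, s] <- colSums(t(m) != utf8ToInt(stub))
    }
  }
  best <- apply(mm, 1, min)
  c_call <- rep(NA_character_, n)
  subtype <- rep(NA_character_, n)
  stub_names <- constant_stubs$isotype
  stub_iso <- isotype_class(stub_names)
  for (i in which(is.finite(best) & best <= max_mismatch)) {
    winners <- which(mm[i, ] == best[i])
    if (length(winners) == 1) {
      c_call[i] <- stub_names[winners]
      subtype[i] <- stub_names[winners]
    } else if (length(unique(stub_iso[winners])) == 1) {
      c_call[i] <- paste(stub_names[winners], collapse = ",")
      subtype[i] <- "ambiguous"
    } # cross-isotype tie: unassigned
  }
  iso <- isotype_class(c_call)
  iso[subtype %in% "ambiguous"] <- stub_iso[match(
    vapply(strsplit(c_call[subtype %in% "ambiguous"], ","), `[`, "", 1), stub_names)]
  tibble(c_call = c_call, isotype = iso, subtype = subtype)
}

#' Collapse identical sequences of the same isotype and apply the UMI filter
#'
#' Exact-nucleotide duplicates with identical isotype are merged: their
#' distinct UMI signatures are pooled into `umi_count` and the largest
#' per-UMI read count is kept as `max_reads_per_umi`. A sequence is retained
#' when `max_reads_per_umi >= min_reads_per_umi`; with `min_reads_per_umi = 1`
#' this is the "all unique reads" view used for constant-threshold
#' comparisons.
#'
#' @param seqs tibble with columns `sequence`, `isotype`, `subtype`, `c_call`,
#'   `signature`, `read_count`.
#' @param min_reads_per_umi retention threshold on the best-covered UMI
#'   (default 2).
#' @param sample_id sample name stamped into sequence ids.
#' @return ProcessedSequence tibble: `sequence_id`, `sequence`, `isotype`,
#'   `subtype`, `c_call`, `umi_count`, `max_reads_per_umi`, `umi_signatures`
#'   (list column).
#' @export
collapse_and_filter <- function(seqs, min_reads_per_umi = 2L, sample_id = "S1") {
  if (nrow(seqs) == 0) {
    return(tibble(sequence_id = character(), sequence = character(),
                  isotype = character(), subtype = character(),
                  c_call = character(), umi_count = integer(),
                  max_reads_per_umi = integer(), umi_signatures = list()))
  }
  collapsed <- seqs |>
    group_by(.data$sequence, .data$isotype) |>
    summarise(subtype = .data$subtype[1], c_call = .data$c_call[1],
              umi_count = n_distinct(.data$signature),
              max_reads_per_umi = max(.data$read_count),
              umi_signatures = list(unique(.data$signature)),
              .groups = "drop") |>
    arrange(.data$sequence, .data$isotype)
  collapsed$sequence_id <- sprintf("%s|SEQ%06d", sample_id, seq_len(nrow(collapsed)))
  collapsed <- collapsed[collapsed$max_reads_per_umi >= min_reads_per_umi, ]
  collapsed[, c("sequence_id", "sequence", "isotype", "subtype", "c_call",
                "umi_count", "max_reads_per_umi", "umi_signatures")]
}

#' Preprocess one sample: raw paired reads to unique consensus sequences
#'
#' Runs the full read-level stage: mean-quality filtering of both mates,
#' 5'/3' primer and UMI annotation, grouping of read pairs by the 16-nt UMI
#' signature, per-group quality-weighted consensus, paired-end assembly,
#' isotype annotation, and isotype-scoped duplicate collapsing with the
#' reads-per-UMI filter. Per-stage input/kept/dropped counts are returned and
#' satisfy `n_in = n_kept + n_dropped` at every stage.
#'
#' @param reads_fwd,reads_rev read tibbles (or FASTQ paths) for the two mates.
#' @param primers primer set tibble.
#' @param constant_stubs constant-region stub table used for isotype calls.
#' @param q_mean mean-quality threshold (default 20).
#' @param min_reads_per_umi reads-per-UMI retention threshold (default 2).
#' @param sample_id sample name.
#' @param metadata optional named list (donor, timepoint, condition,
#'   replicate) copied onto the output.
#' @return list with `sequences` (ProcessedSequence tibble), `groups`
#'   (per-signature consensus/assembly table), and `report` (per-stage
#'   counts).
#' @export
preprocess_sample <- function(reads_fwd, reads_rev, primers = builtin_primer_set(),
                              constant_stubs = builtin_germline_reference()$constant_stubs,
                              q_mean = 20, min_reads_per_umi = 2L,
                              sample_id = "S1", metadata = list()) {
  if (is.character(reads_fwd)) reads_fwd <- read_fastq(reads_fwd)
  if (is.character(reads_rev)) reads_rev <- read_fastq(reads_rev)
  report <- list()
  note <- function(stage, unit, n_in, n_kept) {
    report[[length(report) + 1]] <<- tibble(stage = stage, unit = unit,
                                            n_in = n_in, n_kept = n_kept,
                                            n_dropped = n_in - n_kept)
  }

  n0 <- nrow(reads_fwd)
  f_q <- filter_by_quality(reads_fwd, q_mean)
  r_q <- filter_by_quality(reads_rev, q_mean)
  keep_ids <- intersect(f_q$read_id, r_q$read_id)
  f_q <- f_q[f_q$read_id %in% keep_ids, ]
  r_q <- r_q[r_q$read_id %in% keep_ids, ]
  note("quality_filter", "read_pairs", n0, length(keep_ids))

  f_p <- extract_primer_and_umi(f_q, primers, end = "5")
  r_p <- extract_primer_and_umi(r_q, primers, end = "3")
  pair_ids <- intersect(f_p$reads$read_id, r_p$reads$read_id)
  fwd <- f_p$reads[match(pair_ids, f_p$reads$read_id), ]
  rev_ <- r_p$reads[match(pair_ids, r_p$reads$read_id), ]
  note("primer_umi", "read_pairs", length(keep_ids), length(pair_ids))

  signature <- paste0(fwd$umi8, rev_$umi8)
  idx_by_sig <- split(seq_along(signature), signature)
  n_pairs <- length(pair_ids)
  cons <- vector("list", 0)
  n_discarded_reads <- 0L
  for (sig in names(idx_by_sig)) {
    idx <- idx_by_sig[[sig]]
    cf <- build_consensus(fwd$bases[idx], fwd$qual_string[idx])
    cr <- build_consensus(rev_$bases[idx], rev_$qual_string[idx])
    n_discarded_reads <- n_discarded_reads + cf[[1]]$n_discarded
    # pair up splits in order; counts follow the forward split
    for (part in seq_len(min(length(cf), length(cr)))) {
      cons[[length(cons) + 1]] <- list(
        signature = if (part == 1) sig else paste0(sig, ".", part),
        fwd = cf[[part]], rev = cr[[min(part, length(cr))]],
        read_count = cf[[part]]$read_count)
    }
  }
  note("umi_consensus", "read_pairs", n_pairs, n_pairs - n_discarded_reads)

  rev_rc_all <- revcomp(vapply(cons, function(g) g$rev$seq, ""))
  assembled <- lapply(seq_along(cons), function(k) {
    g <- cons[[k]]
    assemble_pairs(g$fwd$seq, rev_rc_all[k], g$fwd$weights,
                   rev(g$rev$weights), rev_is_revcomp = TRUE)
  })
  ok <- !vapply(assembled, is.null, TRUE)
  groups <- tibble(
    signature = vapply(cons[ok], function(g) g$signature, ""),
    sequence = vapply(assembled[ok], function(a) a$seq, ""),
    read_count = vapply(cons[ok], function(g) g$read_count, 0L),
    overlap = vapply(assembled[ok], function(a) as.integer(a$overlap), 0L))
  note("assembly", "umi_groups", length(cons), sum(ok))

  iso <- annotate_isotype(groups$sequence, constant_stubs)
  groups <- bind_cols(groups, iso)
  assigned <- !is.na(groups$isotype)
  note("isotype", "umi_groups", nrow(groups), sum(assigned))
  groups_assigned <- groups[assigned, ]

  sequences <- collapse_and_filter(groups_assigned, min_reads_per_umi, sample_id)
  note("collapse_filter", "unique_sequences",
       length(unique(paste(groups_assigned$sequence, groups_assigned$isotype))),
       nrow(sequences))

  for (nm in c("donor", "timepoint", "condition", "replicate")) {
    sequences[[nm]] <- metadata[[nm]] %||% NA_character_
  }
  sequences$sample_id <- sample_id
  list(sequences = sequences, groups = groups, report = bind_rows(report))
}
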