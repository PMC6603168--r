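# Alignment scoring used throughout: match +1, mismatch -1, gap -4 per
# gapped position (linear). Germline genes are aligned globally, the query
# locally ("local-global" in Biostrings terms), so every germline base must
# be placed.
align_params <- function() {
  list(mat = Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                      baseOnly = FALSE),
       gap_open = 0, gap_ext = 4)
}

# internal: align a set of queries against one germline gene
align_to_gene <- function(queries, gene_seq, score_only = FALSE) {
  p <- align_params()
  Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(queries), Biostrings::DNAString(gene_seq),
    substitutionMatrix = p$mat, gapOpening = p$gap_open, gapExtension = p$gap_ext,
    type = "local-global", scoreOnly = score_only)
}

# internal: projections for a whole alignment set against one gene.
# Ungapped alignments (the overwhelming majority) are pure offsets; gapped
# ones are reconstructed from the indel ranges, which Biostrings reports in
# alignment-column coordinates (insertions = subject gaps, deletions =
# pattern gaps).
projections_for_set <- function(aln, gene_len) {
  qstart0 <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  ni <- Biostrings::nindel(aln)
  ins_w <- Biostrings::insertion(ni)[, "WidthSum"]
  del_w <- Biostrings::deletion(ni)[, "WidthSum"]
  gapped <- which(ins_w + del_w > 0)
  base <- 0:gene_len
  out <- lapply(qstart0, function(q0) q0 + base)
  if (length(gapped)) {
    idl <- Biostrings::indel(aln)
    ins_l <- Biostrings::insertion(idl)
    del_l <- Biostrings::deletion(idl)
    for (k in gapped) {
      L <- gene_len + ins_w[k]
      is_ins <- is_del <- rep(FALSE, L)
      ir <- ins_l[[k]]; dr <- del_l[[k]]
      for (r in seq_along(ir)) {
        is_ins[IRanges::start(ir)[r]:IRanges::end(ir)[r]] <- TRUE
      }
      for (r in seq_along(dr)) {
        is_del[IRanges::start(dr)[r]:IRanges::end(dr)[r]] <- TRUE
      }
      has_q <- !is_del
      qprior <- qstart0[k] + cumsum(has_q) - as.integer(has_q)
      proj <- integer(gene_len + 1)
      proj[seq_len(gene_len)] <- qprior[!is_ins]
      proj[gene_len + 1L] <- qstart0[k] + sum(has_q)
      out[[k]] <- proj
    }
  }
  out
}

# internal: longest common substring length (and the D gene interval) between
# a short query segment and a D gene; exact, ungapped
longest_d_match <- function(segment, d_seq, min_len = 5L) {
  ls <- nchar(segment); ld <- nchar(d_seq)
  if (ls < min_len) return(0L)
  for (L in seq(min(ls, ld), min_len)) {
    subs <- unique(substring(d_seq, 1:(ld - L + 1), L:ld))
    hit <- vapply(subs, function(s) grepl(s, segment, fixed = TRUE), TRUE)
    if (any(hit)) return(L)
  }
  0L
}

#' Assign germline V, D and J genes
#'
#' Best V by global(-in-germline) banded alignment score (match +1,
#' mismatch -1, gap -4); best J likewise, restricted to the query downstream
#' of the V; best D by ungapped exact-substring scan of the intervening
#' segment (minimum 5 nt, otherwise no D call). Score ties break to the
#' lexicographically smallest gene name. Sequences with no V alignment at
#' `min_v_identity` (or shorter than 100 nt, or with no J placement) are
#' flagged unannotatable.
#'
#' With `prescreen = TRUE` (default) a 24-nt 5'-tag match (at most 4
#' mismatches) shortlists candidate V genes before full alignment; queries
#' matching no tag fall back to the full gene panel.
#'
#' @param sequences character vector of query sequences.
#' @param ref `germline_reference`.
#' @param min_v_identity minimum V identity (matches / aligned columns).
#' @param prescreen logical; use the k-mer V shortlist.
#' @return tibble with `v_call`, `d_call`, `j_call`, `v_identity`,
#'   `v_score`, `j_score`, projection list-columns `v_proj`, `j_proj`
#'   (0-based germline-to-query coordinate maps) and `annotatable`.
#' @export
assign_vdj <- function(sequences, ref, min_v_identity = 0.6, prescreen = TRUE) {
  n <- length(sequences)
  v_tbl <- ref$v_genes[order(ref$v_genes$name), ]
  j_tbl <- ref$j_genes[order(ref$j_genes$name), ]
  nv <- nrow(v_tbl)
  long_enough <- nchar(sequences) >= 100

  candidates <- matrix(TRUE, n, nv)
  if (prescreen && n > 0) {
    qset <- Biostrings::DNAStringSet(sequences)
    for (v in seq_len(nv)) {
      tag <- substr(v_tbl$sequence[v], 1, min(24, nchar(v_tbl$sequence[v])))
      candidates[, v] <- Biostrings::vcountPattern(tag, qset, max.mismatch = 4) > 0
    }
    none <- rowSums(candidates) == 0
    candidates[none, ] <- TRUE
  }
  candidates[!long_enough, ] <- FALSE

  scores <- matrix(-Inf, n, nv)
  for (v in seq_len(nv)) {
    idx <- which(candidates[, v])
    if (!length(idx)) next
    scores[idx, v] <- align_to_gene(sequences[idx], v_tbl$sequence[v],
                                    score_only = TRUE)
  }
  best_v <- apply(scores, 1, function(s) if (all(!is.finite(s))) NA_integer_ else which.max(s))

  v_call <- rep(NA_character_, n); d_call <- rep(NA_character_, n)
  j_call <- rep(NA_character_, n)
  v_identity <- rep(NA_real_, n); v_score <- rep(NA_real_, n)
  j_score <- rep(NA_real_, n)
  v_proj <- vector("list", n); j_proj <- vector("list", n)

  for (v in sort(unique(best_v[!is.na(best_v)]))) {
    idx <- which(!is.na(best_v) & best_v == v)
    vseq <- v_tbl$sequence[v]
    aln <- align_to_gene(sequences[idx], vseq)
    nm <- Biostrings::nmatch(aln); nmm <- Biostrings::nmismatch(aln)
    ident <- nm / (nm + nmm)
    ok <- is.finite(ident) & ident >= min_v_identity
    proj <- projections_for_set(aln, nchar(vseq))
    sc <- Biostrings::score(aln)
    v_call[idx[ok]] <- v_tbl$name[v]
    v_identity[idx[ok]] <- ident[ok]
    v_score[idx[ok]] <- sc[ok]
    v_proj[idx[ok]] <- proj[ok]
  }

  # J assignment downstream of the V alignment end
  has_v <- which(!is.na(v_call))
  v_end_q <- rep(NA_integer_, n)
  for (i in has_v) v_end_q[i] <- v_proj[[i]][length(v_proj[[i]])]
  suffix <- rep("", n)
  jfit <- has_v[v_end_q[has_v] + min(nchar(j_tbl$sequence)) <= nchar(sequences[has_v])]
  suffix[jfit] <- substring(sequences[jfit], v_end_q[jfit] + 1L)
  if (length(jfit)) {
    nj <- nrow(j_tbl)
    jscores <- matrix(-Inf, length(jfit), nj)
    for (j in seq_len(nj)) {
      jscores[, j] <- align_to_gene(suffix[jfit], j_tbl$sequence[j], score_only = TRUE)
    }
    best_j <- apply(jscores, 1, which.max)
    for (j in sort(unique(best_j))) {
      idx <- jfit[best_j == j]
      jseq <- j_tbl$sequence[j]
      aln <- align_to_gene(suffix[idx], jseq)
      nm <- Biostrings::nmatch(aln); nmm <- Biostrings::nmismatch(aln)
      ident <- nm / (nm + nmm)
      ok <- is.finite(ident) & ident >= min_v_identity
      proj <- projections_for_set(aln, nchar(jseq))
      sc <- Biostrings::score(aln)
      j_call[idx[ok]] <- j_tbl$name[j]
      j_score[idx[ok]] <- sc[ok]
      for (k in which(ok)) j_proj[[idx[k]]] <- v_end_q[idx[k]] + proj[[k]]
    }
  }
  annotatable <- !is.na(v_call) & !is.na(j_call)

  # best-effort D call on the V-J intervening segment (never used for cloning)
  if (nrow(ref$d_genes)) {
    d_tbl <- ref$d_genes[order(ref$d_genes$name), ]
    for (i in which(annotatable)) {
      j_start_q <- j_proj[[i]][1]
      if (j_start_q - v_end_q[i] < 5) next
      seg <- substring(sequences[i], v_end_q[i] + 1L, j_start_q)
      lens <- vapply(d_tbl$sequence, function(d) longest_d_match(seg, d), 0L)
      if (max(lens) >= 5) d_call[i] <- d_tbl$name[which.max(lens)]
    }
  }
  tibble(v_call = v_call, d_call = d_call, j_call = j_call,
         v_identity = v_identity, v_score = v_score, j_score = j_score,
         v_proj = v_proj, j_proj = j_proj, annotatable = annotatable)
}

#' Project germline region boundaries onto the query
#'
#' Germline framework/CDR bounds, the junction (conserved V-end cysteine
#' codon through the J tryptophan/phenylalanine codon, boundary codons
#' included), the CDRH3 (junction minus boundary codons), and the Kabat
#' 12-136 core span are projected through the V and J alignments onto query
#' coordinates (0-based half-open). Boundaries destroyed by alignment gaps
#' collapse to zero-width intervals and the row is flagged unresolved.
#'
#' @param vdj tibble from [assign_vdj()] (must include `v_proj`/`j_proj`).
#' @param sequences the query sequences aligned in `vdj`.
#' @param ref `germline_reference`.
#' @return `vdj` with region coordinate columns, `junction`,
#'   `junction_length`, `cdr3`, `core_start`, `core_end`, `regions_resolved`.
#' @export
partition_regions <- function(vdj, sequences, ref) {
  n <- nrow(vdj)
  v_regions <- c("FWR1", "CDR1", "FWR2", "CDR2", "FWR3")
  # cache region bounds per gene (list: gene -> list(region -> c(start,end)))
  bounds <- split(ref$regions[, c("region", "start", "end")], ref$regions$gene)
  bget <- function(gene, region) {
    b <- bounds[[gene]]
    r <- which(b$region == region)
    if (!length(r)) NULL else c(b$start[r[1]], b$end[r[1]])
  }
  store <- list()
  for (r in c(tolower(v_regions), "fwr4")) {
    store[[paste0(r, "_start")]] <- rep(NA_integer_, n)
    store[[paste0(r, "_end")]] <- rep(NA_integer_, n)
  }
  junction <- rep(NA_character_, n); junction_length <- rep(NA_integer_, n)
  cdr3 <- rep(NA_character_, n)
  core_start <- rep(NA_integer_, n); core_end <- rep(NA_integer_, n)
  resolved <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (!vdj$annotatable[i]) next
    vp <- vdj$v_proj[[i]]; jp <- vdj$j_proj[[i]]
    vg <- vdj$v_call[i]; jg <- vdj$j_call[i]
    ok <- TRUE
    for (r in v_regions) {
      b <- bget(vg, r)
      if (is.null(b)) next
      s <- vp[b[1] + 1L]; e <- vp[b[2] + 1L]
      store[[paste0(tolower(r), "_start")]][i] <- s
      store[[paste0(tolower(r), "_end")]][i] <- e
      if (e <= s) ok <- FALSE
    }
    f4 <- bget(jg, "FWR4")
    if (!is.null(f4)) {
      store$fwr4_start[i] <- jp[f4[1] + 1L]; store$fwr4_end[i] <- jp[f4[2] + 1L]
      if (store$fwr4_end[i] <= store$fwr4_start[i]) ok <- FALSE
    }
    cys <- bget(vg, "CYS"); jwf <- bget(jg, "JWF")
    if (!is.null(cys) && !is.null(jwf)) {
      js <- vp[cys[1] + 1L]; je <- jp[jwf[2] + 1L]
      if (je > js) {
        junction[i] <- substring(sequences[i], js + 1L, je)
        junction_length[i] <- je - js
        if (je - js > 6) cdr3[i] <- substring(sequences[i], js + 4L, je - 3L)
      } else ok <- FALSE
    } else ok <- FALSE
    k12 <- bget(vg, "KABAT12"); k136 <- bget(jg, "KABAT136")
    if (!is.null(k12) && !is.null(k136)) {
      core_start[i] <- vp[k12[1] + 1L]
      core_end[i] <- jp[k136[2] + 1L]
    }
    resolved[i] <- ok
  }
  for (nm in names(store)) vdj[[nm]] <- store[[nm]]
  vdj$junction <- junction; vdj$junction_length <- junction_length
  vdj$cdr3 <- cdr3
  vdj$core_start <- core_start; vdj$core_end <- core_end
  vdj$regions_resolved <- resolved
  vdj
}

#' Compute somatic hypermutation percent against the germline V
#'
#' `shm_percent` = 100 x mismatched aligned columns / aligned columns over
#' the V-segment alignment, excluding columns projected into the junction;
#' indel columns count in neither numerator nor denominator. Rows with zero
#' qualifying columns get `NA` and are flagged.
#'
#' @param vdj tibble from [partition_regions()].
#' @param sequences the query sequences.
#' @param ref `germline_reference`.
#' @return `vdj` with an `shm_percent` column.
#' @export
compute_shm <- function(vdj, sequences, ref) {
  vdj$shm_percent <- NA_real_
  v_chars <- lapply(stats::setNames(ref$v_genes$sequence, ref$v_genes$name), utf8ToInt)
  cys_pos <- vapply(ref$v_genes$name,
                    function(g) { b <- gene_region(ref, g, "CYS"); if (is.null(b)) NA_integer_ else b[1] },
                    0L)
  for (i in seq_len(nrow(vdj))) {
    if (!vdj$annotatable[i]) next
    g_chars <- v_chars[[vdj$v_call[i]]]
    vp <- vdj$v_proj[[i]]
    glen <- length(g_chars)
    cp <- cys_pos[[vdj$v_call[i]]]
    junction_start <- if (!is.na(cp)) vp[cp + 1L] else vp[glen + 1L]
    q_chars <- utf8ToInt(sequences[i])
    qpos <- vp[seq_len(glen)]                 # query pos of each germline base
    aligned <- diff(vp) >= 1L                 # deletion columns have diff 0
    usable <- aligned & qpos < junction_start & qpos >= 0 & qpos < length(q_chars)
    if (!any(usable)) next
    mism <- q_chars[qpos[usable] + 1L] != g_chars[usable]
    # insertions in the query (columns absent from germline) are excluded by
    # construction: we walk germline columns only
    vdj$shm_percent[i] <- 100 * sum(mism) / sum(usable)
  }
  vdj
}

#' Annotate processed sequences into rearrangement records
#'
#' Runs [assign_vdj()], [partition_regions()] and [compute_shm()] over a
#' ProcessedSequence table and returns AIRR-style rearrangement records.
#' Unannotatable sequences are excluded and counted in the report.
#'
#' @param processed ProcessedSequence tibble (from [preprocess_sample()]) or
#'   any tibble with `sequence_id` and `sequence` columns.
#' @param ref `germline_reference`.
#' @param min_v_identity minimum V identity for annotation.
#' @return list with `rearrangements` (annotated tibble, alignment
#'   list-columns dropped) and `report`.
#' @export
annotate_rearrangements <- function(processed, ref, min_v_identity = 0.6) {
  vdj <- assign_vdj(processed$sequence, ref, min_v_identity)
  vdj <- partition_regions(vdj, processed$sequence, ref)
  vdj <- compute_shm(vdj, processed$sequence, ref)
  keep <- vdj$annotatable
  res <- bind_cols(processed[keep, , drop = FALSE],
                   vdj[keep, setdiff(names(vdj), c("v_proj", "j_proj", "annotatable"))])
  res$clone_id <- NA_character_
  list(rearrangements = as_tibble(res),
       report = tibble(stage = "annotate", unit = "unique_sequences",
                       n_in = nrow(processed), n_kept = sum(keep),
                       n_dropped = sum(!keep)))
}
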