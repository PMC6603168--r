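# Shared fixtures and independent oracles used across the suite.

ref_fixture <- builtin_germline_reference()

# annotate a cell table straight from the simulator (skipping read emission)
annotate_cells <- function(cells, ref = ref_fixture) {
  ann <- annotate_rearrangements(
    tibble::tibble(sequence_id = cells$cell_id, sequence = cells$sequence,
                   isotype = cells$isotype_true, umi_count = 1L), ref)
  ann$rearrangements
}

# independent dynamic-programming oracle for the aligner: subject globally
# aligned, query locally (free query start/end); linear gap cost
dp_align_score <- function(query, subject, match = 1, mismatch = -1, gap = 4) {
  q <- strsplit(query, "")[[1]]; s <- strsplit(subject, "")[[1]]
  n <- length(q); m <- length(s)
  H <- matrix(-Inf, n + 1, m + 1)
  H[, 1] <- 0
  H[1, ] <- -gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- H[i, j] + if (q[i] == s[j]) match else mismatch
      H[i + 1, j + 1] <- max(sub, H[i, j + 1] - gap, H[i + 1, j] - gap)
    }
  }
  max(H[, m + 1])
}

# brute-force per-position consensus tally (quality-weighted majority, tie N)
consensus_oracle <- function(bases, qual_strings) {
  k <- length(bases); L <- nchar(bases[1])
  out <- character(L)
  for (p in seq_len(L)) {
    ch <- substr(bases, p, p)
    qv <- vapply(substr(qual_strings, p, p), utf8ToInt, 0L, USE.NAMES = FALSE) - 33L
    w <- tapply(qv, ch, sum)
    top <- max(w)
    winners <- names(w)[w == top]
    out[p] <- if (length(winners) == 1) winners else "N"
  }
  paste(out, collapse = "")
}

# union-find single-linkage oracle over one partition of junctions
union_find_clusters <- function(junctions, threshold) {
  n <- length(junctions)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  L <- nchar(junctions[1])
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d <- sum(utf8ToInt(junctions[i]) != utf8ToInt(junctions[j])) / L
    if (d <= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, 0L)
}

# Kruskal MST oracle: total weight of a minimum spanning tree
kruskal_mst_weight <- function(d) {
  n <- nrow(d)
  if (n == 1) return(0)
  edges <- which(upper.tri(d), arr.ind = TRUE)
  edges <- edges[order(d[edges]), , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  total <- 0; used <- 0L
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a != b) {
      parent[a] <- b
      total <- total + d[edges[e, 1], edges[e, 2]]
      used <- used + 1L
      if (used == n - 1L) break
    }
  }
  total
}

# substitute specific positions deterministically (A<->C, G<->T)
perturb_at <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  swap <- c(A = "C", C = "A", G = "T", T = "G")
  ch[positions] <- swap[ch[positions]]
  paste(ch, collapse = "")
}

# substitute `n_mut` random positions of a window with a different base
perturb <- function(seq, window_start, window_end, n_mut) {
  pos <- sample(window_start:window_end, n_mut)
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# small two-gene reference (short genes) written to temp files, for oracle
# tests of the alignment primitive
tiny_reference <- function(v_len = 40, seed = 99) {
  set.seed(seed)
  rdna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")
  v1 <- rdna(v_len); v2 <- rdna(v_len)
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  writeLines(c(">TV1*01", v1, ">TV2*01", v2, ">TJ1*01", rdna(20),
               ">TC1", rdna(20)), fa)
  df <- data.frame(
    gene = c("TV1*01", "TV2*01", "TJ1*01", "TC1"),
    segment = c("V", "V", "J", "C"),
    region = "GENE", start = 0L, end = c(v_len, v_len, 20L, 20L))
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  read_germline_reference(fa, tsv)
}
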