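# internal: collapse allele-level calls (IGHV1-2*01) to gene level (IGHV1-2)
gene_level <- function(call) sub("\\*.*$", "", call)

# internal: partition key used for all clonal operations
partition_key <- function(rearrs, region = c("junction", "cdr3")) {
  region <- match.arg(region)
  len <- nchar(rearrs[[region]])
  paste(gene_level(rearrs$v_call), gene_level(rearrs$j_call), len, sep = "|")
}

#' Distance to nearest neighbour within V/J/length partitions
#'
#' Within each (V gene, J gene, junction length) partition, computes each
#' sequence's minimum Hamming distance on the junction, divided by the
#' junction length. Partition singletons yield no value. Gene calls are
#' collapsed to gene level (alleles merged) before partitioning.
#'
#' @param rearrs rearrangement tibble with `v_call`, `j_call`, `junction`.
#' @param region distance region: `"junction"` (threshold estimation
#'   convention) or `"cdr3"` (constant-threshold matching convention).
#' @return tibble `sequence_id`, `dist_nearest` (NA for singletons).
#' @export
distance_to_nearest <- function(rearrs, region = "junction") {
  key <- partition_key(rearrs, region)
  out <- tibble(sequence_id = rearrs$sequence_id, dist_nearest = NA_real_)
  ok <- !is.na(rearrs[[region]])
  for (idx in split(which(ok), key[ok])) {
    if (length(idx) < 2) next
    s <- rearrs[[region]][idx]
    d <- pairwise_hamming(s) / nchar(s[1])
    diag(d) <- Inf
    out$dist_nearest[idx] <- apply(d, 1, min)
  }
  out
}

#' Estimate the clonal distance threshold from a distance-to-nearest profile
#'
#' Fits a Gaussian kernel density (Silverman's rule bandwidth) to the
#' distance-to-nearest values on \code{[0, 1]}. In the expected bimodal case
#' (clone-mates near zero, unrelated background around 0.3) the threshold is
#' the density minimum between the two highest well-separated local maxima.
#' A pair of maxima only counts as bimodality when both modes reach at least
#' `min_mode_height` of the tallest peak, the modes are at least
#' `min_separation` apart, and the valley between them dips below
#' `valley_depth` of the lower mode, so kernel wiggle inside or beside a
#' single mode is not mistaken for clonal structure. Effectively unimodal
#' profiles, or fewer than `min_distances` finite values, fall back to the
#' constant 0.12.
#'
#' @param distances numeric vector of normalized distances (NAs dropped).
#' @param sample_id label carried into the result.
#' @param min_distances minimum number of finite distances (default 50).
#' @param fallback fallback threshold (default 0.12).
#' @param min_separation minimum distance between modes (default 0.05).
#' @param valley_depth maximum valley height as a fraction of the lower of
#'   the two modes (default 0.75).
#' @param min_mode_height minimum mode height as a fraction of the tallest
#'   peak (default 0.05).
#' @return list of class `threshold_estimate`: `sample_id`, `n_distances`,
#'   `threshold`, `method` (`"valley"` or `"fallback"`).
#' @export
find_threshold <- function(distances, sample_id = "S1", min_distances = 50L,
                           fallback = 0.12, min_separation = 0.05,
                           valley_depth = 0.75, min_mode_height = 0.05) {
  d <- distances[is.finite(distances)]
  res <- function(threshold, method) {
    structure(list(sample_id = sample_id, n_distances = length(d),
                   threshold = threshold, method = method),
              class = "threshold_estimate")
  }
  if (length(d) < min_distances) {
    warning(sprintf("only %d finite distances; using fallback threshold %.2f",
                    length(d), fallback))
    return(res(fallback, "fallback"))
  }
  dens <- stats::density(d, bw = "nrd0", from = 0, to = 1, n = 512)
  y <- dens$y; x <- dens$x
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (y[1] > y[2]) is_max <- c(1L, is_max)
  is_max <- is_max[y[is_max] >= min_mode_height * max(y)]
  if (length(is_max) >= 2) {
    ord <- is_max[order(y[is_max], decreasing = TRUE)]
    # scan mode pairs from strongest down for a genuine bimodal pair
    for (a in seq_len(length(ord) - 1)) {
      for (b in seq(a + 1, length(ord))) {
        lo <- min(ord[a], ord[b]); hi <- max(ord[a], ord[b])
        if (x[hi] - x[lo] < min_separation) next
        valley <- lo + which.min(y[lo:hi]) - 1L
        if (y[valley] > valley_depth * min(y[lo], y[hi])) next
        thr <- x[valley]
        if (thr > 0 && thr < 1) return(res(thr, "valley"))
      }
    }
  }
  res(fallback, "fallback")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("threshold_estimate [%s]: %.4f (%s, n=%d)\n",
              x$sample_id, x$threshold, x$method, x$n_distances))
  invisible(x)
}

#' Cluster rearrangements into clonal families
#'
#' Single-linkage agglomeration within each (V gene, J gene, junction
#' length) partition: two sequences are linked when their normalized
#' junction Hamming distance is at most `threshold`; connected components
#' are clones. Clone ids are deterministic (partitions and members sorted).
#'
#' @param rearrs rearrangement tibble.
#' @param threshold normalized distance threshold in (0, 1].
#' @param region `"junction"` or `"cdr3"` (constant-threshold mAb mode).
#' @return `rearrs` with a `clone_id` column.
#' @export
cluster_clones <- function(rearrs, threshold, region = "junction") {
  assert_that(threshold > 0 && threshold <= 1, "threshold must be in (0,1]")
  key <- partition_key(rearrs, region)
  rearrs$clone_id <- NA_character_
  usable <- !is.na(rearrs[[region]])
  # sequences without the distance region become singleton clones
  rearrs$clone_id[!usable] <- sprintf("NOREGION|%s#1", rearrs$sequence_id[!usable])
  for (pk in sort(unique(key[usable]))) {
    idx <- which(usable & key == pk)
    s <- rearrs[[region]][idx]
    if (length(idx) == 1) {
      comp <- 1L
    } else {
      d <- pairwise_hamming(s) / nchar(s[1])
      adj <- d <= threshold
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                               diag = FALSE)
      comp <- igraph::components(g)$membership
    }
    # renumber components deterministically by smallest member sequence_id
    first_id <- tapply(rearrs$sequence_id[idx], comp, min)
    ord <- rank(first_id, ties.method = "first")
    for (cc in unique(comp)) {
      rearrs$clone_id[idx[comp == cc]] <- sprintf("%s#%d", pk, ord[as.character(cc)])
    }
  }
  # compact, deterministic clone ids
  ids <- sort(unique(rearrs$clone_id))
  rearrs$clone_id <- sprintf("CL%06d", match(rearrs$clone_id, ids))
  rearrs
}

#' Summarise clonal families
#'
#' @param rearrs clustered rearrangement tibble (with `clone_id`).
#' @return tibble per clone: partition key fields, `abundance_sequences`
#'   (unique members), `abundance_reads` (summed UMI counts), `mean_shm`,
#'   and per-isotype member counts.
#' @export
clone_table <- function(rearrs) {
  assert_that(!is.null(rearrs$clone_id), "run cluster_clones() first")
  umi <- rearrs$umi_count %||% rep(1L, nrow(rearrs))
  rearrs$.umi <- umi
  rearrs |>
    group_by(.data$clone_id) |>
    summarise(v_gene = gene_level(.data$v_call[1]),
              j_gene = gene_level(.data$j_call[1]),
              junction_length = .data$junction_length[1],
              abundance_sequences = n(),
              abundance_reads = sum(.data$.umi),
              mean_shm = mean(.data$shm_percent, na.rm = TRUE),
              isotype_counts = list(table(.data$isotype)),
              .groups = "drop")
}

#' Derive the constant cross-sample threshold
#'
#' The median of per-sample optimized thresholds (expressed in percent),
#' rounded half-up to the nearest integer percent. With an even number of
#' samples the median is the mean of the two middle values.
#'
#' @param per_sample_thresholds numeric vector of thresholds in percent.
#' @return integer percent.
#' @export
derive_constant_threshold <- function(per_sample_thresholds) {
  assert_that(length(per_sample_thresholds) > 0, "no thresholds supplied")
  as.integer(round_half_up(stats::median(per_sample_thresholds)))
}
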