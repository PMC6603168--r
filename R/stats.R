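#' Summarise a repertoire sample
#'
#' Counts heavy-chain sequences and clonal families overall and per isotype,
#' with mean SHM at the sequence level (unweighted mean over unique
#' sequences) and at the clone level (mean over clones of the clone's mean
#' member SHM). Means are only reported for nonempty groups.
#'
#' @param rearrs clustered rearrangement tibble.
#' @param threshold the clonal threshold used (recorded in the summary).
#' @return list with `totals` (tibble) and `by_isotype` (tibble).
#' @export
summarize_repertoire <- function(rearrs, threshold = NA_real_) {
  totals <- tibble(
    n_sequences = nrow(rearrs),
    n_clones = n_distinct(rearrs$clone_id),
    threshold = threshold
  )
  by_iso <- rearrs |>
    filter(!is.na(.data$isotype)) |>
    group_by(.data$isotype) |>
    summarise(
      n_sequences = n(),
      n_clones = n_distinct(.data$clone_id),
      mean_shm_sequences = mean(.data$shm_percent, na.rm = TRUE),
      .groups = "drop"
    )
  clone_shm <- rearrs |>
    filter(!is.na(.data$isotype)) |>
    group_by(.data$isotype, .data$clone_id) |>
    summarise(clone_mean = mean(.data$shm_percent, na.rm = TRUE), .groups = "drop") |>
    group_by(.data$isotype) |>
    summarise(mean_shm_clones = mean(.data$clone_mean), .groups = "drop")
  list(totals = totals,
       by_isotype = left_join(by_iso, clone_shm, by = "isotype"))
}

#' Aggregate per-sample means into a condition-level mean
#'
#' Unweighted mean of per-sample percent values, rounded to one decimal --
#' the convention used for condition-level SHM summaries.
#'
#' @param per_sample_means numeric vector of per-sample percents.
#' @return the rounded mean.
#' @export
aggregate_condition_means <- function(per_sample_means) {
  assert_that(length(per_sample_means) > 0, "no per-sample means supplied")
  round_half_up(mean(per_sample_means), 1)
}

#' Isotype or subtype proportions
#'
#' Fractions over assigned sequences; sums to 1. At subtype level only
#' subtypes present in the input appear.
#'
#' @param rearrs rearrangement tibble with `isotype`/`subtype`.
#' @param level `"isotype"` or `"subtype"`.
#' @return tibble `group`, `n`, `fraction`.
#' @export
isotype_proportions <- function(rearrs, level = c("isotype", "subtype")) {
  level <- match.arg(level)
  g <- rearrs[[level]]
  g <- g[!is.na(g)]
  assert_that(length(g) > 0, "no sequences with an assigned %s", level)
  tab <- sort(table(g), decreasing = TRUE)
  tibble(group = names(tab), n = as.integer(tab),
         fraction = as.numeric(tab) / sum(tab))
}

#' Germline V-gene usage
#'
#' Per-gene sequence fractions (allele calls collapsed to gene level),
#' optionally stratified by isotype; rows ordered by gene name.
#'
#' @param rearrs rearrangement tibble.
#' @param by_isotype stratify by isotype.
#' @return tibble `v_gene` (, `isotype`), `n`, `fraction`.
#' @export
vgene_usage <- function(rearrs, by_isotype = FALSE) {
  rearrs$v_gene <- gene_level(rearrs$v_call)
  if (by_isotype) {
    out <- rearrs |>
      filter(!is.na(.data$isotype)) |>
      count(.data$isotype, .data$v_gene, name = "n") |>
      group_by(.data$isotype) |>
      mutate(fraction = .data$n / sum(.data$n)) |>
      ungroup() |>
      arrange(.data$isotype, .data$v_gene)
  } else {
    out <- rearrs |>
      count(.data$v_gene, name = "n") |>
      mutate(fraction = .data$n / sum(.data$n)) |>
      arrange(.data$v_gene)
  }
  out
}

#' Repertoire Dissimilarity Index
#'
#' Subsampling-based distance between two repertoires on V-gene usage: each
#' iteration subsamples both repertoires to `depth` sequences without
#' replacement, forms per-gene count vectors over the union gene set,
#' applies a log2(1 + x) transform, and takes the Euclidean distance. The
#' score is the mean over iterations; deterministic given `seed`.
#'
#' @param usage_a,usage_b character vectors of per-sequence V-gene calls
#'   (allele suffixes are collapsed).
#' @param depth subsample size; must not exceed either repertoire.
#' @param iterations number of subsample iterations (default 100).
#' @param seed RNG seed.
#' @return mean RDI score (non-negative).
#' @export
rdi <- function(usage_a, usage_b, depth, iterations = 100L, seed = 1L) {
  a <- gene_level(usage_a); b <- gene_level(usage_b)
  assert_that(depth <= length(a) && depth <= length(b),
              "depth exceeds a sample's size")
  genes <- sort(unique(c(a, b)))
  # each repertoire gets its own seed stream derived from its content, so the
  # score is symmetric in its arguments and identical inputs draw identically
  content_tag <- function(x) paste0(length(x), ":", sum(utf8ToInt(paste(sort(x), collapse = ""))))
  ta <- content_tag(a); tb <- content_tag(b)
  draw <- function(x, tag, i) {
    set.seed(derive_seed(as.numeric(seed) + 7L * i, tag))
    table(factor(sample(x, depth), levels = genes))
  }
  scores <- vapply(seq_len(iterations), function(i) {
    ca <- draw(a, ta, i)
    cb <- draw(b, tb, i)
    sqrt(sum((log2(1 + as.numeric(ca)) - log2(1 + as.numeric(cb)))^2))
  }, 0)
  mean(scores)
}

#' Two-sample t comparison of SHM distributions
#'
#' Convenience wrapper over Student's two-sample t statistic for comparing
#' SHM distributions between repertoires (e.g. IgM vs IgG, or PBMC vs
#' stimulated), with Holm-Sidak adjustment across multiple comparisons.
#'
#' @param shm_list named list of numeric SHM vectors; all pairs are compared.
#' @return tibble `group_a`, `group_b`, `t`, `df`, `p`, `p_adj`.
#' @export
shm_t_tests <- function(shm_list) {
  nms <- names(shm_list)
  pairs <- utils::combn(nms, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- shm_list[[pairs[1, k]]]; b <- shm_list[[pairs[2, k]]]
    tt <- stats::t.test(a, b)
    tibble(group_a = pairs[1, k], group_b = pairs[2, k],
           t = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value)
  })
  out <- bind_rows(out)
  m <- nrow(out)
  ord <- order(out$p)
  adj <- 1 - (1 - out$p[ord])^(m - seq_len(m) + 1)   # Holm-Sidak step-down
  adj <- cummax(pmin(adj, 1))
  out$p_adj <- NA_real_
  out$p_adj[ord] <- adj
  out
}
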