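#' Load and validate a run configuration
#'
#' The run configuration is a single YAML document describing the sample
#' manifest, reference and primer paths, all stage parameters and the seed.
#' Referenced files must exist at validation time; parameters are checked
#' against their documented ranges before any stage runs.
#'
#' Schema (top level): `samples` (list of `{id, donor, timepoint, condition,
#' replicate, fastq_fwd, fastq_rev}`), optional `simulate` (list of
#' [sim_config()] arguments per sample id instead of FASTQ paths),
#' `reference` (`builtin` or `{fasta, regions}`), `primers` (`builtin` or a
#' path), `params` (`q_mean`, `min_reads_per_umi`, `constant_threshold`,
#' `mutated_cutoff`), `seed`, `output_dir`, optional `mabs` (FASTA path) and
#' `persistence: true`.
#'
#' @param x path to a YAML file or an already-parsed list.
#' @return validated config list of class `igflow_config`.
#' @export
run_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  assert_that(!is.null(cfg$samples) || !is.null(cfg$simulate),
              "config needs a sample manifest or a simulate block")
  defaults <- list(q_mean = 20, min_reads_per_umi = 2L,
                   constant_threshold = 0.12, mutated_cutoff = 1)
  cfg$params <- utils::modifyList(defaults, cfg$params %||% list())
  p <- cfg$params
  assert_that(p$q_mean >= 0 && p$q_mean <= 60, "q_mean out of range")
  assert_that(p$min_reads_per_umi >= 1, "min_reads_per_umi must be >= 1")
  assert_that(p$constant_threshold > 0 && p$constant_threshold < 1,
              "constant_threshold must be in (0,1)")
  cfg$seed <- cfg$seed %||% 1L
  cfg$output_dir <- cfg$output_dir %||% tempfile("igflow_run_")
  if (!is.null(cfg$samples)) {
    for (s in cfg$samples) {
      assert_that(!is.null(s$id), "every sample needs an id")
      if (is.null(cfg$simulate)) {
        for (f in c(s$fastq_fwd, s$fastq_rev)) {
          assert_that(file.exists(f), "missing FASTQ: %s", f)
        }
      }
    }
  }
  if (!is.null(cfg$mabs)) assert_that(file.exists(cfg$mabs), "missing mAb FASTA: %s", cfg$mabs)
  structure(cfg, class = "igflow_config")
}

# internal: resolve the germline reference declared in a config
config_reference <- function(cfg) {
  if (is.null(cfg$reference) || identical(cfg$reference, "builtin")) {
    builtin_germline_reference()
  } else {
    read_germline_reference(cfg$reference$fasta, cfg$reference$regions)
  }
}

#' Run the full pipeline
#'
#' Executes, per sample: (optional) simulation, preprocessing, annotation,
#' per-sample threshold estimation and clonal clustering, and summary
#' statistics; then cross-sample persistence detection and mAb matching when
#' configured. All artifacts (AIRR TSVs, threshold report, summaries, run
#' report) are written under `output_dir`. Fully deterministic given the
#' config seed. A stage failure aborts with a stage-tagged error; artifacts
#' already written are retained.
#'
#' @param cfg an `igflow_config` (or path / list accepted by [run_config()]).
#' @return list with per-sample results (`rearrangements`, `clones`,
#'   `threshold`, `summary`, `report`), optional `persistence` and
#'   `mab_matches`, and the `run_report`.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "igflow_config")) cfg <- run_config(cfg)
  ref <- config_reference(cfg)
  primers <- if (is.null(cfg$primers) || identical(cfg$primers, "builtin")) {
    builtin_primer_set()
  } else read_primer_set(cfg$primers)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- cfg$params
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  results <- list(); thresholds <- numeric(0)
  used_sigs <- character(0)
  run_report <- list(seed = cfg$seed, params = p, samples = list())

  for (s in cfg$samples) {
    sid <- s$id
    meta <- s[intersect(names(s), c("donor", "timepoint", "condition", "replicate"))]
    if (!is.null(cfg$simulate)) {
      sim_args <- utils::modifyList(cfg$simulate, s$simulate %||% list())
      sim_args$seed <- derive_seed(cfg$seed, sid)
      sim_args <- sim_args[intersect(names(sim_args), names(formals(sim_config)))]
      scfg <- do.call(sim_config, sim_args)
      cells <- stage("simulate", simulate_repertoire(scfg, ref))
      gen <- stage("simulate", generate_reads(cells, scfg, primers,
                                              out_dir = cfg$output_dir,
                                              sample_id = sid,
                                              used_signatures = used_sigs))
      used_sigs <- c(used_sigs, gen$signatures)
      reads_fwd <- gen$reads_fwd; reads_rev <- gen$reads_rev
    } else {
      reads_fwd <- s$fastq_fwd; reads_rev <- s$fastq_rev
    }
    pre <- stage("preprocess", preprocess_sample(
      reads_fwd, reads_rev, primers, ref$constant_stubs,
      q_mean = p$q_mean, min_reads_per_umi = p$min_reads_per_umi,
      sample_id = sid, metadata = meta))
    ann <- stage("annotate", annotate_rearrangements(pre$sequences, ref))
    rearrs <- ann$rearrangements
    dtn <- stage("cluster", distance_to_nearest(rearrs))
    thr <- stage("cluster", find_threshold(dtn$dist_nearest, sample_id = sid))
    rearrs <- stage("cluster", cluster_clones(rearrs, thr$threshold))
    clones <- clone_table(rearrs)
    summ <- stage("stats", summarize_repertoire(rearrs, thr$threshold))
    thresholds[sid] <- thr$threshold

    write_airr(rearrs[, setdiff(names(rearrs), "umi_signatures")],
               file.path(cfg$output_dir, paste0(sid, "_airr.tsv")),
               params = list(seed = cfg$seed, threshold = signif(thr$threshold, 4)))
    results[[sid]] <- list(rearrangements = rearrs, clones = clones,
                           threshold = thr, summary = summ,
                           report = bind_rows(pre$report, ann$report))
    run_report$samples[[sid]] <- list(
      threshold = thr$threshold, threshold_method = thr$method,
      stages = as.data.frame(results[[sid]]$report))
  }

  thr_tbl <- tibble(sample_id = names(results),
                    n_distances = vapply(results, function(r) r$threshold$n_distances, 0L),
                    threshold = vapply(results, function(r) r$threshold$threshold, 0),
                    method = vapply(results, function(r) r$threshold$method, ""))
  utils::write.table(thr_tbl, file.path(cfg$output_dir, "thresholds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  out <- list(samples = results, thresholds = thr_tbl, run_report = run_report,
              output_dir = cfg$output_dir)

  if (isTRUE(cfg$persistence) && length(results) >= 2) {
    pers <- stage("persist", find_persistent_sequences(
      lapply(results, function(r) r$rearrangements),
      mutated_cutoff = p$mutated_cutoff))
    out$persistence <- pers
    utils::write.table(
      pers[, c("core_sequence", "isotype_consensus", "mean_shm", "mutated",
               "umi_disjoint", "contamination_suspect")],
      file.path(cfg$output_dir, "persistence.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(cfg$mabs)) {
    mabs <- read_fasta(cfg$mabs)
    names(mabs) <- c("name", "sequence")
    all_rearrs <- bind_rows(lapply(results, function(r) r$rearrangements))
    out$mab_matches <- stage("map-mabs", match_mabs_to_clones(
      all_rearrs, mabs, ref, threshold = p$constant_threshold))
    utils::write.table(out$mab_matches,
                       file.path(cfg$output_dir, "mab_matches.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_run_report(run_report, file.path(cfg$output_dir, "run_report.json"))
  out
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `igflow` Rscript (see
#' `inst/scripts/igflow.R`). Subcommands: `all --config run.yaml`,
#' `map-mabs --airr sample.tsv --mabs mabs.fasta [--threshold 0.12]`,
#' `persist --airr a.tsv --airr b.tsv [...]`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status: 0 success, 2 validation error, 3 stage failure.
#' @export
igflow_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    message("usage: igflow <all|map-mabs|persist> [options]")
    return(2L)
  }
  cmd <- args[1]
  opts <- list()
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    opts[[key]] <- c(opts[[key]], args[i + 1])
    i <- i + 2
  }
  run <- function(expr) {
    tryCatch({ expr; 0L },
             error = function(e) {
               message("error: ", conditionMessage(e))
               if (grepl("^\\[stage ", conditionMessage(e))) 3L else 2L
             })
  }
  switch(cmd,
    all = run({
      res <- run_pipeline(run_config(opts$config))
      message("pipeline complete: ", res$output_dir)
    }),
    `map-mabs` = run({
      rearrs <- read_airr(opts$airr)
      rearrs$umi_signatures <- NULL
      mabs <- read_fasta(opts$mabs)
      names(mabs) <- c("name", "sequence")
      thr <- as.numeric(opts$threshold %||% 0.12)
      rep_ <- match_mabs_to_clones(rearrs, mabs, builtin_germline_reference(), thr)
      utils::write.table(rep_, opts$out %||% stdout(), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }),
    persist = run({
      tabs <- lapply(opts$airr, read_airr)
      names(tabs) <- paste0("S", seq_along(tabs))
      for (k in seq_along(tabs)) {
        tabs[[k]]$umi_signatures <- strsplit(tabs[[k]]$umi_signatures %||%
                                               character(nrow(tabs[[k]])), ";")
      }
      pers <- find_persistent_sequences(tabs)
      utils::write.table(
        pers[, c("core_sequence", "isotype_consensus", "mean_shm", "mutated")],
        opts$out %||% stdout(), sep = "\t", quote = FALSE, row.names = FALSE)
    }),
    { message("unknown subcommand: ", cmd); 2L }
  )
}
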