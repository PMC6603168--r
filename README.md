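# igflow

UMI-based analysis of heavy-chain B-cell receptor (BCR) repertoires from
paired-end immunoglobulin amplicon sequencing, built for the contrast between
ordinary PBMC repertoires (naive-dominated: >90% IgM, ~1% somatic
hypermutation, singleton clones) and polyclonally stimulated PBMC
repertoires enriched for memory B cells (IgG-switched, elevated SHM, large
clonal expansions). It is aimed at immunologists who want to mine deep
memory repertoires for antigen-specific clonal families — e.g. to ask
whether known monoclonal antibodies (mAbs) have clonal relatives in a
donor's repertoire, whether specific sequences persist across blood draws,
and which clonal families dominate by abundance and maturation.

## What it computes

For each sample, raw paired FASTQ reads are taken through:

1. **UMI preprocessing** — mean-quality filtering (keep mean Q ≥ 20),
   primer/UMI annotation with standardisation of 8/12-nt UMIs to 8 nt,
   grouping of read pairs by the 16-nt UMI signature, quality-weighted
   per-position consensus, paired-end assembly, isotype/subtype annotation
   from constant-region stubs, and collapsing of identical sequences of the
   same isotype with a reads-per-UMI ≥ 2 retention filter.
2. **Germline annotation** — V/D/J gene assignment by gene-global alignment
   (match +1, mismatch −1, gap −4), framework/CDR partitioning, junction
   extraction, and SHM as percent mismatch to the germline V segment
   (junction and indel columns excluded):
   `shm = 100 · mismatched columns / aligned columns`.
3. **Clonal inference** — per-sequence distance-to-nearest on the junction
   within (V gene, J gene, junction length) partitions; per-sample threshold
   at the valley of the bimodal density (fallback 12%); single-linkage
   clustering into clonal families. The constant cross-sample threshold is
   the rounded median of per-sample optimized thresholds
   (`derive_constant_threshold()`), which evaluates to 12% on published
   per-replicate threshold values from deep PBMC and stimulated-PBMC
   repertoires.
4. **Statistics** — isotype/subtype proportions, V-gene usage, sequence- and
   clone-level SHM summaries, condition-level aggregates, and the
   subsampling-based Repertoire Dissimilarity Index on V-gene usage.
5. **Longitudinal analyses** — persistent sequences (nucleotide-identical
   Kabat-12–136 cores present in every timepoint, with UMI-disjointness
   checks and a strict >1% SHM "mutated" classification), mAb-to-repertoire
   clonal matching at a constant 12% CDRH3 threshold on the all-unique-reads
   view, germline-rooted minimum-spanning-tree lineages with
   mutational-step edge labels, and an immunodominance grid of clones over
   (read abundance × mean SHM).

A ground-truth simulator (`sim_config()`, `simulate_repertoire()`,
`generate_reads()`, `plan_timepoints()`, `spike_mab_lineages()`) emulates
both compartments with known gene calls, mutations, isotypes, UMIs and
planted persistent/mAb structure, so every stage is validated against truth.

## Worked example

```r
library(igflow)

ref <- builtin_germline_reference()
cfg <- sim_config(n_cells = 500, condition = "stimulated", seed = 7)
cells <- simulate_repertoire(cfg, ref)
gen <- generate_reads(cells, cfg, sample_id = "demo", out_dir = tempdir())

pre <- preprocess_sample(gen$fastq[["fwd"]], gen$fastq[["rev"]], sample_id = "demo")
pre$report
#> # A tibble: 6 × 5
#>   stage           unit              n_in n_kept n_dropped
#>   <chr>           <chr>            <int>  <int>     <int>
#> 1 quality_filter  read_pairs        9086   9086         0
#> 2 primer_umi      read_pairs        9086   9086         0
#> 3 umi_consensus   read_pairs        9086   9086         0
#> 4 assembly        umi_groups        1929   1929         0
#> 5 isotype         umi_groups        1929   1929         0
#> 6 collapse_filter unique_sequences   673    465       208
```

Every stage conserves its inputs (`n_in = n_kept + n_dropped`); here the
only losses are the 208 unique sequences whose best UMI saw a single read —
exactly the sequences that could be PCR/sequencing artefacts.

```r
rearrs <- annotate_rearrangements(pre$sequences, ref)$rearrangements
thr <- find_threshold(distance_to_nearest(rearrs)$dist_nearest, sample_id = "demo")
thr
#> threshold_estimate [demo]: 0.2798 (valley, n=349)
rearrs <- cluster_clones(rearrs, thr$threshold)
summarize_repertoire(rearrs, thr$threshold)$by_isotype
#> # A tibble: 3 × 5
#>   isotype n_sequences n_clones mean_shm_sequences mean_shm_clones
#>   <chr>         <int>    <int>              <dbl>           <dbl>
#> 1 IgA              38       29               5.77            5.60
#> 2 IgG             303      120               5.28            5.17
#> 3 IgM             124       98               2.28            1.96
```

The stimulated sample shows the memory signature the pipeline is built to
detect: IgG dominates (303/465 = 65% of sequences) and carries ~5.3% SHM,
against ~2.3% in the residual IgM fraction. The distance-to-nearest profile
is bimodal, and its valley (0.28 here, at desk scale) separates clone mates
from the unrelated background.

An end-to-end run over a sample manifest, with per-sample AIRR TSVs,
threshold and persistence reports, is a single call:

```r
res <- run_pipeline(run_config("run.yaml"))
```

or from a shell: `Rscript inst/scripts/igflow.R all --config run.yaml`.

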