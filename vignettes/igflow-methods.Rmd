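---
title: "igflow: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{igflow: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

igflow analyses heavy-chain B-cell receptor (BCR) repertoires from paired-end
immunoglobulin amplicon sequencing with unique molecular identifiers (UMIs) at
both ends of each transcript. Its scientific target is the contrast between a
naive-dominated PBMC compartment and an *in vitro* stimulated compartment
enriched for antigen-experienced memory B cells: class-switched isotypes,
elevated somatic hypermutation (SHM), skewed clone sizes, and clonal families
that persist across blood draws and contain known monoclonal antibodies
(mAbs). This vignette documents the models, the parameters that matter, and
the design decisions behind each stage.

## The processing model

**UMI preprocessing.** Reads are kept when their arithmetic mean Phred score
is at least `q_mean` (default 20, boundary inclusive — the permissive reading
of the usual "average Q 20" rule; the literal "removes reads with average Q
scores >20" would discard exactly the good reads). Primer anchors are matched
at the read start within a short offset window at up to 2 mismatches; a tie
between two primers is treated as unresolvable and the read is dropped with a
logged count. The UMI of the primer's declared length (8 or 12 nt) follows the
primer and is standardised to its first 8 nt, so mixed-length designs collapse
to a uniform 8+8 signature; the 5' and 3' halves are concatenated into the
16-nt signature that identifies one cDNA molecule. Read pairs sharing a
signature are combined by per-position majority vote weighted by quality sums,
with ties emitting `N` and terminal positions covered by fewer than half the
members trimmed. Because two molecules can collide on a signature, a group
whose members disagree at more than 10% of positions is split by
complete-linkage clustering at 10% distance — a conservative guard that never
merges distinct biology at the cost of occasionally splitting a noisy group.
Consensus pairs are assembled by the maximal-scoring ungapped overlap of at
least 10 nt with at most 20% mismatches, with disagreements resolved toward
the higher quality weight. Isotype and subtype come from matching the 3' end
against constant-region stubs at up to 2 mismatches; a tie between subtypes of
one isotype keeps the isotype and reports the subtype as ambiguous. Finally,
identical nucleotide sequences of the same isotype are collapsed, pooling
their UMI signatures, and a sequence is retained when its best-covered UMI saw
at least `min_reads_per_umi` reads (default 2; the `1` setting is the
"all unique reads" view used for constant-threshold comparisons and
persistence searches). Every stage reports `n_in = n_kept + n_dropped`, and
the suite asserts this conservation on every run.

**Annotation.** Germline V genes are aligned globally-in-the-gene /
locally-in-the-query (match +1, mismatch −1, linear gap −4) via
`Biostrings::pairwiseAlignment`; a 24-nt 5'-tag prescreen (≤4 mismatches)
shortlists V candidates so that full dynamic programming usually runs once
per query. J genes are aligned the same way, restricted to the query
downstream of the V; D genes are a best-effort longest-exact-substring call
(≥5 nt) on the intervening segment and are never used by clonal partitioning.
Score ties break to the lexicographically smallest gene name, making calls
deterministic. Region boundaries (FWR1–FWR4, CDR1–3), the junction (conserved
V-end cysteine codon through the J tryptophan/phenylalanine codon), and the
Kabat 12–136 core span are projected through the alignment onto query
coordinates; all internal coordinates are 0-based half-open. SHM is the
percentage of mismatched aligned columns over the V-segment alignment,
excluding columns that project into the junction and excluding indel columns
from both numerator and denominator. The J segment is deliberately excluded
from the SHM denominator: this makes SHM exactly recoverable from simulation
truth and keeps the definition identical for real and simulated data. Novel
germline allele inference is out of scope; SHM is always relative to the
shipped reference.

**Clonal inference.** Sequences are partitioned by (V gene, J gene, junction
length), with allele-level calls collapsed to gene level because allele
fragmentation splits genuine clones under SHM. Within a partition, the
distance between two sequences is the Hamming distance on the junction
divided by junction length; requiring equal junction length is what makes
the Hamming distance well-defined, and no indel-tolerant variant is
attempted. The per-sample threshold comes from a Gaussian kernel density
(Silverman's rule) of distance-to-nearest values: in a deep repertoire the
profile is bimodal — clone mates near zero, unrelated background around
0.3 — and the threshold is the density minimum between the two dominant
modes. A mode pair is only believed when the modes are ≥0.05 apart, both
reach ≥5% of the tallest peak, and the valley dips below 75% of the lower
mode; otherwise the profile is treated as unimodal and the constant 12%
fallback is used. These gates exist because kernel densities of small
samples wiggle, and a literal "minimum between the two highest maxima" rule
happily finds a valley inside a single mode. The 12% constant is itself the
rounded median of per-sample optimized thresholds across published
replicate repertoires, and `derive_constant_threshold()` reproduces that
arithmetic (half-up rounding of the sort-and-average median). Clustering is
single linkage at the threshold; connected components are clones. The mAb
matching mode uses the same machinery with the distance region switched to
the CDRH3 (junction minus its boundary codons) at the constant 12%, on the
all-unique-reads view.

**Longitudinal analyses.** Persistence is an exact-string intersection of
Kabat-12–136-trimmed cores across all samples: matching is nucleotide-only
and isotype-agnostic, but isotypes and SHM are recorded per sample and each
persistent set is classified mutated when mean SHM strictly exceeds 1%. UMI
disjointness across samples is verified for every persistent set; shared
signatures flag contamination suspects rather than silently counting them.
Lineages are minimum spanning trees over the germline ancestor plus the
clone's distinct aligned V(D)J sequences under Hamming distance, rooted at
the germline, grown by Prim's algorithm with lexicographic tie-breaking.
Multi-mutation edges keep their full step count as the label; intermediate
haplotypes are only nodes when observed, since a full Sankoff/dnapars
parsimony is deliberately traded for a deterministic, oracle-checkable
construction that still reproduces germline rooting, branching structure and
mutational-step labels. The germline ancestor takes germline bases outside
the junction and the member majority inside it (the untemplated N region has
no germline). The immunodominance grid bins clones by log2-scaled read
abundance and linear SHM (1% bins), with matched mAb clones overlaid at
their clone's coordinates.

## The simulator and what passing tests mean

The generator draws clonal families per compartment from a truncated
discrete power law, performs one V(D)J recombination per clone (uniform 0–5
nt trimming per join end, uniform 0–10 nt N-insertions — a deliberately
simple junctional model whose only job is to produce junction-length and
junction-sequence diversity), applies substitution-only SHM uniformly over
the V(D)J region at the compartment rate, draws a per-member isotype from
the compartment profile, and emits UMI-tagged paired reads with i.i.d.
per-base substitution errors. Quality strings are two-valued (Q37, with
error positions flagged Q20) so the mean-quality filter has predictable
behaviour. Reads and transcripts per cell follow 1 + Poisson(mean − 1), so
every cell is observable and the configured means are exact.

Defaults are the emulated study conditions: PBMC = 95% naive cells (92% IgM, 0.8%
SHM, clone sizes exponent 3.5 capped at 3 — mostly singletons) and 5%
memory; stimulated = 75% memory (IgG1 65%, IgG total 80%, 5.5% SHM, sizes
exponent 2.0 capped at 50) with memory cells carrying 4 transcripts per cell
at 6 reads per transcript against the naive 1.5 and 2 — the ≥3× factor
reflecting transcriptional upregulation of activated B cells. Per-base error
is 0.002 on 300/250 nt reads.

What the simulator does **not** model: lineage-internal SHM trees (clones
are star-shaped around a founder; lineage tests use a separately scripted
stepwise fixture), light-chain pairing, indels under SHM, quality-dependent
error profiles, primer-site mutations, or chimeric reads. Passing tests
therefore demonstrate that the pipeline recovers planted structure exactly
under its own generative assumptions — they do not certify performance on
real MiSeq data, where indels, hotspot-biased SHM and library artefacts
add failure modes this package does not attempt to emulate.

## Numerical choices and degenerate inputs

- Half-up rounding is used wherever printed-table conventions apply
  (threshold percents, condition-level SHM to one decimal).
- Ties: consensus ties → `N`; primer ties → read dropped; subtype ties →
  ambiguous; alignment score ties → lexicographic gene name; lineage-growth
  ties → lexicographic sequence order. Every tie rule is deterministic.
- Empty inputs return empty outputs (collapse) or explicit errors (threshold
  derivation, condition means, isotype proportions on unassigned-only input).
- Sequences shorter than 100 nt, with no qualifying V (identity < 0.6), or
  with no J placement are excluded as unannotatable, with logged counts.
- RDI subsampling seeds each repertoire's stream from a content hash plus
  the user seed, making the score symmetric in its arguments and exactly
  zero for identical inputs.
- The duplication-invariance of the threshold estimator is approximate, not
  exact: Silverman's bandwidth depends on n, so duplicating every distance
  moves the discretized valley by at most a grid step or two.

## Validation problem sizes

The acceptance layer exercises the full pipeline at desk scale, chosen so
sampling error sits well inside the stated tolerances: a 2,000-cell
noise-free round trip (set equality of recovered and true transcripts, 100%
V/J and isotype calls); 500 clones of sizes 1–50 at 3% SHM clustered to an
adjusted Rand index ≥0.95 with the clustering checked against a union-find
oracle partition by partition; three 300-cell timepoints with 50 planted
persistent sequences recovered exactly and UMI-disjoint; 8 spiked mAbs of
which exactly the 7 with in-threshold relatives match; lineage total lengths
equal to a Kruskal oracle on all ≤8-member clones; and a 2,000-cell
stimulated vs PBMC contrast whose IgG fraction and SHM means land within 2
percentage points of the configured effect. The enrichment contrast runs on
the ≥2-reads-per-UMI view and its expectations are propagated through that
filter analytically (zero-truncated Poisson retention per compartment),
because the all-unique view also counts error-generated phantom-UMI
singletons, which weight toward the high-read memory compartment. Exact-count
recoveries (the 50 persistent, the 7-of-8 mAbs) run at zero sequencing error,
as exact set recovery through single-read transcripts is information-
theoretically impossible once body errors can masquerade as novel sequences;
the error model is exercised separately by the error-rate and filtering
tests.

## Known limitations

- The aligner is a simplified V(D)J annotator, not IgBLAST: no species
  frames, no productive/unproductive logic, no allele inference.
- Clone inference requires equal junction lengths; indel-bearing clone
  members are split by construction.
- The lineage method is an MST approximation of parsimony; internal nodes
  are never inferred beyond observed haplotypes.
- The RDI parameterisation (depth, iterations) is caller-chosen; published
  scores depend on unstated parameters and are not reproduced as anchors.
- Condition-level aggregates are unweighted across samples by design
  (matching the printed-table convention); sequence-count weighting is a
  caller-side choice.
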