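# repab

Integrated analysis of the human immunoglobulin repertoire across its
genomic and proteomic readouts: bulk B-cell receptor sequencing
(bulkBCR-seq — deep, unpaired, UMI-counted), single-cell BCR sequencing
(scBCR-seq — shallow, natively paired heavy/light chains, barcode-counted),
and bottom-up mass spectrometry of serum antibodies (Ab-seq — peptides,
no nucleotides). `repab` is for immunologists and computational biologists
who want to compare these readouts within and across donors and to use
personalized BCR references to recover clonotypes — including paired-chain
V(D)J sequences — from serum antibody peptides.

## What it computes

Starting from AIRR Rearrangement clonotype tables (the post-aligner
representation; read-level processing is out of scope):

* **V-gene usage**, unweighted by clonotype size, compared across samples
  by Pearson correlation over the union of observed genes;
* **CDR3 overlap** as the Jaccard index
  `J(A,B) = |A ∩ B| / |A ∪ B|` on unique CDR3 amino-acid sets;
* **Clonal evenness** from Hill diversity
  `D(α) = (Σᵢ fᵢ^α)^(1/(1−α))` on the clonal frequency distribution `f`,
  normalized as `E(α) = D(α)/n` over α ∈ [0, 10] (Shannon limit at α = 1);
* **Light-chain coherence (LCC)**: the probability that two cells with the
  same heavy V gene and identical CDRH3 amino-acid sequence, yet different
  clonotypes, share a light-chain V gene — within and across donors;
* **Replicate merging**: cumulative pooling of scBCR-seq technical
  replicates and the resulting depth-versus-overlap curve against bulk;
* **Ab-seq integration**: exact matching of serum-digest peptides to
  reference variable regions; the four-stage filter ladder
  (all → antibody-specific → CDR3-overlapping at ≥ 3 contiguous residues →
  uniquely vs multi-mapped); source attribution (bulk / sc / both); clonal
  rank; class-switch tables; V(D)J reconstruction; and paired-chain
  recovery through single-cell barcodes;
* **Group statistics**: Kruskal–Wallis plus pairwise Wilcoxon rank-sum
  tests with Bonferroni correction, as used for pairwise repertoire
  feature comparisons;
* **A seeded synthetic generator** (germline scaffolds, donor-specific
  gene usage, Zipf clonal expansion, coherence-pair construction, serum
  sampling, four in-silico protease digests, contaminants, decoys) so the
  entire pipeline runs and is tested without external data.

## Worked example

A donor with a deep bulk repertoire and a 1000-cell paired single-cell
sample drawn partly from the same clonal pool; serum peptides from four
protease digests mapped back against both references:

```r
library(repab)

gh <- germline_model(chain = "heavy", seed = 1)
gl <- germline_model(n_v = 20, n_j = 4, chain = "kappa", seed = 2)

cfg  <- simulation_config(n_clonotypes = 5000, seed = 7)
bulk <- simulate_repertoire(cfg, gh, donor = "D1", seed = 7)
sc   <- simulate_paired_repertoire(
  simulation_config(n_clonotypes = 1000, seed = 7), gh, gl,
  donor = "D1", seed = 8, n_coherence_pairs = 100,
  pool = bulk, pool_fraction = 0.6)

light_chain_coherence_within(sc)
#> <lcc_result> within_donor: 85 coherent / 100 eligible pairs (85.00%), 200 cells

usage_correlation(list(gene_usage(bulk), gene_usage(sc)))$matrix[1, 2]
#> [1] 0.9199162
jaccard_overlap(cdr3_set(bulk), cdr3_set(sc))
#> [1] 0.04031811

ptab <- simulate_abseq_run(list(bulk, sc), cfg, n_serum = 50, seed = 9)
idx  <- build_reference_index(bulk_reps = bulk, sc_reps = sc)
clf  <- classify_matches(match_peptides(ptab, idx))
clf$ladder
#> <filter_ladder> all 2911 >= antibody-specific 2911 >= CDR3-overlapping 948
#>   = unique 924 + multi 24

ident <- reconstruct_vdj(clf, idx)
pc <- recover_paired_chain(
  ident[ident$source_attribution %in% c("sc", "both"), ], sc)
nrow(pc); mean(pc$pair_ambiguity)
#> [1] 371
#> [1] 0
```

Reading the output: the two sequencing methods agree on the donor's V-gene
usage (r = 0.92) while sharing only 4% of CDR3 sequences — the depth gap.
Of 2911 serum peptides, 948 overlap a reference CDR3 by at least three
residues and 924 of those map to a single clonotype identity; all 50
simulated serum clonotypes are recovered, and every single-cell-supported
identification yields an unambiguous paired light chain. The class-switch
table (`class_switch_table(ident, ptab)`) shows reference IgA/IgD/IgM
clonotypes predominantly detected in the IgG serum fraction, as configured
by the default transition matrix.

An end-to-end configuration-driven run (with outputs and a JSON manifest)
is available as:

```r
res <- run_pipeline(list(seed = 5), out_dir = "run1")
```

## Acceptance script

`scripts/acceptance.R` re-runs the full integrated pipeline from scratch
against the installed package — simulation, repertoire features, replicate
merging and depth curve, decoy/contaminant-aware peptide mapping,
identification and paired-chain recovery — and writes the results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The seed controls every source of randomness; a rerun with the same seed
reproduces the same numbers.

## Package layout

* `R/repertoire.R` — domain containers, AIRR TSV and reference FASTA I/O,
  productivity and one-heavy-one-light filters, clonotype assembly;
* `R/simulate.R` — the synthetic world (germlines, repertoires, paired
  cells, replicates, digestion, serum runs, decoys);
* `R/features.R` — gene usage, Jaccard, evenness, light-chain coherence;
* `R/merge.R` — replicate merging and depth-overlap curves;
* `R/abseq.R` — reference index, peptide matching, filter ladder,
  identification, paired-chain recovery, class switching, CDR3 distances;
* `R/stats.R` — group statistics and the pipeline orchestrator;
* `vignettes/integrated-repertoire-proteomics.Rmd` — the methods notes:
  model assumptions, parameter choices, numerical decisions, limitations.
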