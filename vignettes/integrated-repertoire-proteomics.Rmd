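---
title: "Methods: integrated BCR repertoire and serum antibody analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated BCR repertoire and serum antibody analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repab)
```

# The problem

An individual's immunoglobulin repertoire can be read out three ways:
bulk B-cell receptor sequencing (deep, unpaired, UMI-counted), single-cell
BCR sequencing (shallow, natively paired heavy/light chains,
barcode-counted), and bottom-up mass spectrometry of serum antibodies
("Ab-seq": peptides, no nucleotides, no pairing). `repab` implements the
analyses needed to compare these readouts and to integrate them: repertoire
feature quantification that is robust to the depth gap between methods,
replicate-merging depth analysis, and mapping of serum-digest peptides onto
a personalized BCR reference to recover clonotypes and full V(D)J
sequences — plus a seeded synthetic generator so that every stage is
testable without any sequencing or proteomics data.

# Containers and the clonotype key

A clonotype is one recombined receptor chain: V/J gene calls (collapsed to
gene level — allele suffixes are stripped on ingestion, since short-read
single-cell libraries cannot support allele calls), the CDR3 in nucleotide
and amino-acid space, the full variable-region amino-acid sequence with the
CDR3 location as a 0-based half-open interval, an isotype, and an
abundance. The clonotype key concatenates CDR3 (nucleotide when available,
else amino acid — the fallback is recorded on the repertoire), V gene,
J gene, and isotype. Abundance is the number of distinct UMIs (bulk) or
distinct cell barcodes (single cell); single-cell droplets are retained
only when they contain exactly one heavy and one light chain. Coordinates
are 0-based half-open throughout (peptide match spans, CDR3 spans), which
makes interval intersection — the CDR3-overlap computation — single-line
arithmetic. The AIRR `junction_aa` field is taken as the CDR3 verbatim
(with its conserved C/W anchors), matching the common aligner export
convention; no anchor trimming is applied.

# Repertoire features

**V-gene usage** is unweighted: every clonotype counts once regardless of
size. This is deliberate — UMI counts and barcode counts measure different
things (molecules vs. cells), so any size weighting would confound the
method comparison. Profiles are compared by Pearson correlation over the
*union* of genes observed in either sample with absent genes at frequency
0; intersection support is available as an option but would inflate
correlations for shallow samples. A pair whose aligned vectors have zero
variance yields `NA` with a warning, never a silent 0.

**CDR3 overlap** is the Jaccard index `J = |A∩B| / |A∪B|` on unique CDR3
amino-acid string sets, with no V/J conditioning.

**Evenness** uses Hill diversities
`D(α) = (Σ f_i^α)^(1/(1−α))` on the clonal frequency distribution,
evaluated on an α grid from 0 to 10 (step 0.1 — the range is standard, the
step is our choice). The α = 1 singularity is evaluated as the Shannon
limit `exp(−Σ f_i log f_i)`; zero frequencies are dropped so that `D(0)`
is observed richness. Evenness `E = D/n` is 1 for a perfectly uniform
repertoire and decreases with clonal expansion.

**Light-chain coherence (LCC)** asks: given two cells with the same heavy
V gene and *identical* CDRH3 amino-acid sequence (100% identity only) that
are nonetheless different clonotypes (different nucleotide CDR3s), how
often do they use the same light-chain V gene? Within a donor, clonally
identical cells are excluded; across donors every cross pair with matching
heavy V + CDRH3 is eligible. When no pair qualifies the percentage is `NA`
— reported as such, not as 0. The implementation counts pairs by
contingency within (heavy V, CDRH3) groups and is verified against a
brute-force all-pairs enumeration.

# Replicate merging and the depth analysis

Single-cell technical replicates are merged cumulatively: cells pooled
with per-member barcode prefixes, clonotypes rebuilt, sizes recomputed from
the pooled distinct barcodes. Merging operates on clonotype/cell tables,
not raw reads, so consensus effects of read-level merging are explicitly
out of scope. The depth analysis draws one random replicate ordering per
seed and traces Jaccard overlap with the bulk CDR3 set as k = 1…K
replicates accumulate; the merged CDR3 set is exactly the union of member
sets (a tested invariant), so the curve is computed from cumulative set
unions.

# Peptide mapping and the filter ladder

The reference index holds bulk and single-cell clonotypes (deduplicated at
the sequence × key level within each source; identical variable regions in
both sources stay once per source and are linked through their shared
amino-acid identity), decoy sequences, and contaminant proteins. A peptide
hit is an exact contiguous substring occurrence in a reference variable
region; all occurrences are recorded. Matching uses a 7-mer seed table
with substring verification (brute-force scan as the test oracle). I/L
equivalence is off by default — search engines report a concrete residue —
but is available as a flag since the two residues are isobaric.

The four-stage ladder follows the processing of serum peptide data:

1. **all** — peptides not matching any contaminant protein;
2. **antibody-specific** — of those, peptides hitting at least one BCR
   reference and no decoy;
3. **CDR3-overlapping** — of those, peptides whose best hit overlaps the
   CDR3 by ≥ 3 contiguous residues (boundary inclusive);
4. **uniquely mapped** vs **multi-mapped** — whether all reference hits
   share one clonotype identity.

Identity for uniqueness is `(chain, V gene, J gene, CDR3 aa)` by default:
peptide evidence cannot distinguish synonymous nucleotide variants, so
counting them as distinct would manufacture spurious multi-mapping.
Nucleotide-level uniqueness is available via `unique_scope =
"clonotype_key"`. Cross-source hits on the same identity do not make a
peptide multi-mapped; they set the source attribution to "both".
Uniqueness is evaluated over all reference hits of a peptide regardless of
chain; since heavy and light references virtually never share substrings
of peptide length, this is equivalent to per-chain evaluation, and a
collision would surface as multi-mapping rather than a wrong
identification.

Identified clonotypes are reported with the full variable-region sequence,
the supporting peptide's match span (for display), the clonal rank
(competition ranking by descending size: ties share the smallest rank of
the group), and — for single-cell-supported identifications — the paired
chain recovered through the cell barcodes of the identified clonotype.
When barcodes disagree on the partner, the majority partner is reported
with an ambiguity fraction (ties flagged), rather than discarded; the
repertoire's LCC value is the natural companion statistic for judging
that residual ambiguity. Class switching is summarized by cross-tabulating
the reference isotype of each uniquely mapped identification against the
serum fraction of its supporting peptide. CDR3 diversity of the
identified set uses unit-cost Levenshtein distances per chain
(`utils::adist`).

# The synthetic world

The generator exists so that every downstream computation has ground
truth. Its defaults state the modeled conditions once:

* **Germline**: scaffold models (V framework of ~80 aa ending where the
  CDR3 begins, J suffix of ~12 aa) stand in for a germline reference;
  variable regions are `V-scaffold + CDR3 + J-scaffold`. Random scaffolds
  contain cleavage residues at natural frequencies, so digests produce
  realistic peptide length mixtures.
* **Donor identity**: per-donor V/J usage is Dirichlet-drawn from an RNG
  stream seeded by a hash of the donor label, so the same donor has the
  same usage in every sample and method — the property behind same-donor
  correlation structure — without any shared state between calls.
* **CDR3s**: lengths 8–25 with mode 15, anchored `C…W`, interiors uniform
  over the 20 amino acids; inter-donor sharing is therefore negligible by
  construction (tested: J < 1e-3 at n = 10⁴) unless a shared pool is
  supplied.
* **Clonal expansion**: Zipf-like sizes `size(rank) ∝ rank^(−s)` with
  s = 1.1 and a scale factor putting the largest clone at ~20n molecules;
  exponents may be given per isotype.
* **Nucleotides**: CDR3s are back-translated with a fixed codon table
  (lexicographically first codon per residue); synonymous "variants"
  select alternative codons through a mixed-radix index, which is how
  light-chain-coherence groups (same CDRH3 aa, different clonotype keys)
  are built.
* **Coherence pairs**: groups are pairs of cells; the first carries the
  group's canonical light V (a deterministic hash of the CDRH3, so it
  agrees across donors sharing a pool), the second reuses it with
  probability ρ (default 0.9, inside the observed 88–93% range) or
  resamples from the full light-gene distribution, leaving chance-level
  collisions possible. With pair-sized groups the expected measured LCC
  equals ρ + (1−ρ)·Σq² — recoverable to a few percentage points, which is
  what the parameter-recovery tests assert.
* **Clonal cells**: cells drawn from a bulk pool share both chains of
  their clone (a B-cell clone has one light partner), so paired-chain
  ground truth is well defined for expanded clones.
* **Serum**: clonotypes sampled with weight `size^β`; β defaults to 0
  (size-independent) because the quantitative serum-vs-BCR abundance
  relation is unknown — the paper-level observation is merely a *low*
  correlation, so the exponent stays an explicit free parameter.
  Class switching uses a configurable row-stochastic matrix, default
  biased toward IgG; light chains fall into the kappa serum fraction.
* **Digestion**: trypsin (after K/R, not before P), high-specificity
  chymotrypsin (after F/W/Y, not before P — the enzyme's low-specificity
  L/M sites are excluded, matching common search-engine defaults),
  AspN (before D), and chymotrypsin-then-trypsin as the union of both
  site sets (sequential digestion of fully cleaved products yields the
  same sites, and the union form is directly verifiable). Missed
  cleavages 0–2 by fragment-window concatenation, length window 7–40 aa.
  No semi-specific peptides.
* **Decoys and contaminants**: decoys are scaffold-built sequences with
  shuffled CDR3 interiors, enforced disjoint (as full strings) from the
  true reference; contaminants are three fixed synthetic proteins
  (labelled synthetic — they are not real protein sequences).

What the generator does **not** emulate: somatic hypermutation lineages,
isotype-specific constant regions, spectrum-level effects (m/z, intensity,
retention time), sequencing error, or UMI collision noise. A green test
therefore establishes the correctness of the analysis layer on clonotype
tables, not the robustness of upstream read processing.

# Numerical and design choices

* α = 1 Hill singularity via the Shannon limit; continuity is tested to
  1e-4 across α = 1 ± 1e-6.
* Zero-variance correlation pairs are `NA` + warning; empty-set Jaccard
  and zero-pair LCC are `NA`, matching the "no pairs met the criteria"
  reporting convention.
* Deterministic output orders everywhere (descending size, then key), so
  merging is order-insensitive and reruns are byte-identical.
* Competition ranking for clonal rank: with heavy singleton tails, large
  tie groups collapse to their smallest rank. Consequently "rank greater
  than half the repertoire" is not a stable property of size-independent
  sampling even when sampling is exactly uniform; the trend tests instead
  assert that identifications avoid the expanded head of the repertoire
  (median rank above 0.25·n; under 20% of identifications in the top
  decile).
* Wilcoxon rank-sum tests use the standard exact/approximate switching of
  `stats::wilcox.test` (exact for small tie-free groups), verified against
  full permutation enumeration; Bonferroni adjustment is `min(1, m·p)`.
  Pairwise correlation/overlap values are treated as independent
  observations in these tests — a known pseudo-replication inherited from
  the field's convention, documented rather than "fixed".
* Configuration files for `run_pipeline()` are JSON (an R list works
  too); a stage failure aborts with the stage name while earlier outputs
  remain on disk.

# A small worked run

```{r pipeline, eval = FALSE}
res <- run_pipeline(list(seed = 5, n_bulk = 2000, n_sc_cells = 600,
                         n_replicates = 4, replicate_depth = 150,
                         n_serum = 30))
res$abseq$classified$ladder
res$features$lcc
```

On this configuration the run prints a filter ladder of
`all 2066 >= antibody-specific 880 >= CDR3-overlapping 580 = unique 567 +
multi 13` and a within-donor LCC of `93.33%` (28/30 pairs) — numbers
produced by the code above, regenerated identically for a fixed seed.

# Known limitations

The pipeline begins at clonotype tables: read-level error correction,
contig assembly and UMI consensus building are upstream concerns. Decoy
databases share germline scaffolds with the true reference, so framework
peptides often hit decoys and are conservatively excluded from the
antibody-specific stage; CDR3-overlapping counts are essentially
unaffected. The synthetic class-switch model draws one serum isotype per
clonotype — real serum can contain several isotypes of one clone. FDR
estimation from target-decoy score distributions, spectral search, and
peptide quantification are out of scope.
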