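---
title: "Methods: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tirscape)
```

This vignette records the model behind each module, why the defaults
are what they are, and the numerical decisions that a reader auditing
the results would want stated explicitly.

## Coordinates and sequence conventions

All coordinates are 0-based half-open internally; BED output keeps that
convention, and BLAST outfmt-6 input (1-based inclusive, `sstart >
send` meaning minus strand) is converted on read by
`read_blast_hits()`. Minus-strand loci are reverse-complemented into
transposase sense at `extract_flanks()`, so every downstream stage —
TIR detection, ORF finding, consensus building — works in one
orientation, and boundary calls are mapped back to genomic space at the
end. Sequences are uppercased; any character outside `ACGT` is treated
as ambiguous (`N`-like) and never matches.

## Boundary calling

### TIR model

`detect_tir()` searches for a substitution-only inverted repeat: the
first `L` bases of the element against the reverse complement of the
last `L`. Defaults:

* `min_len = 10`, `max_len = 40` — brackets the ~28 bp TIR of the
  modelled family with room for diverged relatives, while keeping
  chance hits rare (the Monte-Carlo unit test bounds the false-positive
  rate on random 300-mers at ≤2%).
* `max_terminal_offset = 5` — the TIR must start within 5 bp of each
  candidate terminus; real termini coincide with the TIR, so a large
  offset only admits noise.
* `max_mismatch_frac = 0.2` — at 28 bp this allows the ~5 substitutions
  expected of a moderately diverged copy.
* score = `length − 3 × mismatches` (equivalently matches − 2 ×
  mismatches), so a longer TIR wins only if the extra length is not
  bought with mismatches.

Indels inside the TIR are deliberately out of scope: the repeat is
short, and allowing gaps would require an alignment per candidate pair
for marginal sensitivity gain.

### Joint TIR/TSD scoring

`call_boundaries()` slides candidate termini within `boundary_slop =
30` bp of the merged-hit core and scores each candidate pair:

```
boundary_score = tir_score + 10 * is_ta_tsd + tsd_len
```

The element termini are defined as the TIR termini, with the TSD
immediately outside — that is the cut-and-paste geometry: the
duplicated TA abuts, but is not part of, the element. The TA bonus of
10 is large relative to one TIR match (1) but small relative to the TIR
itself, so a genuine TA TSD breaks ties without overriding a clearly
better repeat.

### The palindromic-TA ambiguity and the family polish

A TA TSD is its own reverse complement. When a chance second TA sits
immediately outside a genuine TSD, the candidate that absorbs the TSD
into the TIR (gaining 2 matched bases) can outscore the true terminus.
This is unresolvable copy-by-copy — both readings are locally
consistent. `call_boundaries(family_polish = TRUE)` therefore runs a
second pass (`polish_family_boundaries()`): it takes the consensus TIR
over high-confidence calls (≥3 calls, modal TIR length), then
re-anchors every copy to the offset that minimises mismatch against
that consensus. The family-level signal disambiguates what a single
copy cannot. With the polish on, boundary recovery on planted families
is exact for ≥90% of copies and within ±2 bp for all of them; unit
tests that target single-copy behaviour construct flanks without chance
TAs so that they test the scorer, not the ambiguity.

## Classification

A copy is `intact` only if *all* of the following hold; `coding_only`
if the coding tests pass but the terminal ones fail; otherwise
`fragment`:

* a detected TIR and TSD (terminal integrity);
* an ORF of ≥`min_aa = 300` aa (`find_longest_orf()` scans all three
  sense frames; the ancestral transposase is 425 aa, so 300 tolerates
  internal deletion but rejects fragments);
* a DD35D catalytic triad (`find_triad()`): aspartates D1, D2, D3 with
  `d1_d2_range = c(50, 250)` and exactly `spacer23 = 35` residues
  between D2 and D3. The fixed 35-aa spacer is the family signature;
  the wide D1–D2 window reflects real variation in that region. The
  third residue may optionally be glutamate (`allow_e = TRUE`) for
  DDE-like relatives, off by default.
* both DNA-binding motifs (`scan_motif()` against
  `toy_dbd_profiles()`: a Brinker-like and an HTH-like profile, match
  threshold 75% of the maximum score). These are deliberately toy
  position profiles — stand-ins with the right shape, not curated HMMs;
  users with real profiles supply their own via `motif_profile()`.

`count_copies()` counts family members from coverage/identity against
the consensus with strict inequalities (`> 0.40` coverage, `> 0.80`
identity), so a copy exactly at a threshold is excluded —
reproducibility beats generosity at the margin.

## Consensus and divergence

`build_consensus()` uses center-star alignment to the longest copy as
reference, majority vote per reference column (ties broken
alphabetically A<C<G<T for determinism), and drops gap-majority
columns. With ≤5 copies a majority vote is statistically meaningless,
so the function returns the longest copy as a `representative` instead
and labels the mode; downstream code can branch on it.

`k2p()` implements Kimura's two-parameter distance with pairwise
deletion: columns containing a gap or ambiguity in either sequence are
excluded; P = transition fraction, Q = transversion fraction over the
remaining columns;

```
K = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)
```

and the pair is reported `saturated` (K = NA) when either logarithm's
argument is ≤0. The estimator is exercised against an independently
coded closed form in the test suite; agreement is at machine precision.

`landscape()` bins copies at `floor(100 K / bin_width)` with
`bin_width = 1` (percent) and weights each copy by its aligned length,
so the landscape is coverage in bp, not copy count — a long old copy
contributes what it actually occupies in the genome. `flag_young()`
uses a strict `K < 0.02` cut-off and declares the family
`recently_active` when ≥5 copies or ≥10% of copies are young. The
strict inequality matters: copies simulated *to* K = 0.02 straddle the
boundary, and the convention must be stated, not implied.

Global alignment (`align_global()`) uses Biostrings'
`pairwiseAlignment` with match +1, mismatch −1, linear gap −2
(`gapOpening = 0`, `gapExtension = 2`) and refuses sequences over
20 kb — pairwise DP on full elements is fine; chromosomes are not the
intended input.

## Integration preference

### Feature assignment

`assign_feature()` resolves each TA site to one of six ordered
categories — promoter > exon > intron > `genic_unresolved` (gene body
with no exon model) > downstream > intergenic — with `promoter_bp =
downstream_bp = 1000`. Precedence, not proximity, decides the category;
within a category the gene with the nearest TSS wins. Strict precedence
makes the assignment a function, so two runs can never disagree on
overlapping annotations.

### The odds-ratio fold estimator

The generative model plants genic sites at `genic_fold` f times the
per-TA rate of intergenic sites. The naive frequency-ratio estimate
(site fraction in genes ÷ background fraction in genes) is *attenuated*
to

```
f / (f g + (1 - g))
```

when genes cover a fraction `g` of TA positions — with g ≈ 0.25 and
f = 3 it reports ≈1.95, not 3. The odds ratio

```
(sites in / sites out) / (background in / background out)
```

cancels the coverage term and recovers f for any g. All fold columns in
`feature_distribution()` and friends, and the acceptance experiments,
use the odds ratio for this reason; the significance test is the
package's `fisher_exact()` on the same 2×2 table.

### Fisher's exact test

`fisher_exact()` is a vectorised two-sided test on 2×2 tables: the
hypergeometric point probabilities of all tables with the observed
margins are summed for those no more probable than the observed table,
with a relative tolerance of 1 + 1e-7 for ties (the same convention as
`stats::fisher.test`) and the result clamped to 1. It exists because
the pipeline tests thousands of tables and `stats::fisher.test` is
scalar; equality with the reference implementation is enforced in the
test suite over every table with total ≤ 40 (135,751 tables) at
< 1e-10 absolute difference. `stars()` maps p to the usual bands
(`****` ≤ 1e-4, `***` ≤ 1e-3, `**` ≤ 0.01, `*` ≤ 0.05, else `ns`).

### Other preference summaries

`tss_profile()` bins signed distances to the nearest TSS (default
±3000 bp in 100-bp bins, negative = upstream). `gene_body_decile()`
places intragenic sites into ten strand-oriented length-normalised
bins. `expression_binned_frequency()` groups genes into expression
octiles and reports sites per Mb of gene body per octile.
`chromatin_state_enrichment()` compares state occupancy of sites
against random loci and aborts on sites that overlap conflicting state
annotations rather than resolving them silently.
`target_site_matrix()` tallies base composition at offsets −10..+11
around the TA (minus-strand sites reverse-complemented first; IUPAC
codes resolved by count ties), reports the consensus, the central
8-mer (offsets −3..+4) and its palindromicity (fraction of the 8-mer
that matches its own reverse complement).

## The generator: scope and limits

The synthetic module exists so every estimator can be validated against
a known truth; it is *not* a genome evolution simulator.

* `simulate_genome()` draws i.i.d. bases at `gc = 0.41` — no isochores,
  repeats or composition autocorrelation.
* `make_ancestral_element()` constructs a 2.4-kb element that satisfies
  every classifier rule by construction: 28-bp TIR, 425-aa ORF with the
  DD35D triad and both toy motifs. The construction enforces a
  *maximality contract*: the first base inside each TIR is set so that
  it cannot pair with its partner (without creating a spurious ATG), so
  `detect_tir()` finds exactly the planted 28 bp and boundary tests are
  unambiguous.
* `mutate_to_k()` applies independent per-site substitutions at
  transition/transversion rates solved by `uniroot` (tolerance 1e-14)
  so that the *expected* K2P distance equals the target exactly, with
  ts/tv = 2. No indels, no rate heterogeneity, no selection — by
  design, so that measured K is attributable to the planted K.
* `plant_family()` inserts at TA positions, duplicates the TA, chooses
  strands at random, enforces `min_spacing = 5000` between copies, and
  damages a configurable fraction of copies (left/right truncation of
  20–50%, or an in-frame stop replacing codon 201). Truth coordinates
  are tracked through the genome's growth.
* `simulate_sites()` samples TA positions with weights that multiply a
  genic fold, a Gaussian TSS attraction, an expression-rank power and
  an 8-mer context weight — each axis independently switchable so each
  estimator can be tested in isolation.

Problem sizes in the defaults (150 kb + 50 kb fixture genome, tens of
copies, thousands of sites) are package choices made for second-scale
runtimes; every generator takes explicit sizes for larger experiments.

## Determinism

Every stochastic function takes a `seed` and restores the caller's RNG
state afterwards (`with_seed()`); `run_pipeline()` derives stage seeds
as fixed offsets of the config seed. The serialised `config.yaml`
deliberately omits `out_dir` so that two runs into different
directories are byte-identical — determinism is asserted file-by-file
in the acceptance tests.
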