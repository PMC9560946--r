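---
title: "Methods: single-nucleus SNP filtering and karyon inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-nucleus SNP filtering and karyon inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyosnp)
```

## The problem

Arbuscular mycorrhizal (AM) fungi carry hundreds of haploid nuclei in a
single asexual spore. Individual nuclei can be flow-sorted from one spore,
whole-genome amplified by multiple displacement amplification (MDA), and
sequenced, giving one haploid sample per nucleus — typically on the order
of 19–24 usable nuclei per spore. Two biological architectures are of
interest:

* **homokaryon** — all nuclei belong to one genotype class; residual
  variation is a thin scatter of private mutations carried by single
  nuclei;
* **heterokaryon** — two genotype classes coexist, separated by fixed
  differences at some density per kilobase (in *Rhizophagus irregularis*
  this architecture is linked to the mating-type locus).

`karyosnp` implements the downstream half of such a study as a reusable,
tested pipeline: given per-nucleus variant observations (VCF with
per-sample GT/DP/AD and site quality annotations), it applies the
filtering chain used for single-nucleus haploid data, computes the
repeat-aware SNP density that summarizes intra-spore diversity, and asks
which karyon architecture the data are consistent with. Upstream steps —
read alignment and the variant caller itself — are out of scope; their
output contract (observations plus site annotations) is the input here.

## The filter chain

The chain runs in a fixed order; each stage has a dedicated function and
`run_filter_chain()` composes them.

1. **Site hard filters** (`apply_site_hard_filters`). A site fails when
   any quality statistic crosses the standard recommended threshold
   *strictly*: QD < 2, FS > 60, MQ < 40, MQRankSum < −12.5,
   ReadPosRankSum < −8, QUAL < 30, SOR > 3.0. Boundary values pass.
   Rank-sum statistics are undefined at sites without mixed evidence; a
   missing rank-sum never fails its test, matching how threshold filters
   treat absent annotations. The chain never recomputes these statistics
   from reads — they are inputs.
2. **Haploid genotype calls** (`call_haploid_genotype`). Majority vote on
   gate-surviving read counts: zero depth → MISSING; more ref than alt →
   REF; more alt → ALT; an exact tie with positive depth → MISSING. The
   tie rule is a design choice: a haploid call at a 50/50 split is
   indefensible, and MISSING feeds conservatively into the missingness
   filter.
3. **Cell masking** (`mask_unreliable_cells`). A (site, nucleus) cell is
   set to MISSING when it has fewer than 5 reads **and** an allele
   fraction strictly between 0.1 and 0.9. The conjunction is the literal
   grammatical reading of the rule; because the intent could also be read
   as a disjunction, `combine = "OR"` is available and results should
   state the mode used. With zero informative reads the allele fraction
   is undefined; the ambiguity condition is then false, so depth alone
   governs (this avoids 0/0). AF exactly 0.1 or 0.9 never counts as
   ambiguous (open interval).
4. **Missingness filter** (`filter_by_missingness`). A site is removed
   when MISSING calls exceed one third of all sequenced nuclei,
   *strictly*. The printed "33%" is interpreted as exactly 1/3, so 3
   missing of 9 nuclei is retained; the fraction is configurable. The
   denominator is the full nucleus count, not the non-missing count.
5. **SNP extraction** (`extract_snp_sites`). A retained site is a SNP iff
   at least one non-missing call is ALT. Sites where *every* non-missing
   call is ALT are counted as SNPs — they may be assembly-consensus
   artifacts rather than polymorphism — and are flagged separately in the
   report so they can be audited.

Tightening any knob (higher `min_depth`, wider AF band, lower missingness
tolerance) can only shrink the SNP set; this monotonicity is tested as a
property.

## SNP density

Density is the number of SNPs outside the repeat mask divided by the
non-repeat assembly size, reported per kilobase. Repeat intervals are
merged before any arithmetic so overlapping annotations are not
double-subtracted, and the denominator comes from exact interval
arithmetic, never from rounded megabase values: published tables rounded
to 0.1 Mb cannot reproduce their own printed densities in every case (one
field spore reproduces exactly; the other gives 0.23 vs a printed 0.24),
which is why full precision is kept internally and half-up rounding to
two decimals is applied only at the reporting layer.

## Karyon inference

The classifier combines three pieces of evidence:

* **Density bands.** Published estimates place MAT-locus homokaryons
  around 0.2 SNPs/kb and heterokaryons at 0.45–0.8 SNPs/kb. These numbers
  come from cultured *R. irregularis*; their transferability to other
  genera is unknown, so they are explicit, documented defaults
  (`karyon_thresholds()`), not constants.
* **Nucleus bipartition** (`partition_nuclei`). Average-linkage
  agglomerative clustering into two groups on pairwise normalized Hamming
  distance over shared non-missing sites, chosen over likelihood mixture
  models for determinism and auditability. Pairs sharing fewer than 10
  informative sites get the mean trusted distance (0.5 when nothing is
  trusted). The partition score is 1 − mean(within)/mean(between),
  clamped to [0, 1].
* **Permutation null** (`permutation_null`). Calls are shuffled within
  each site, preserving per-site ALT counts and the missingness pattern —
  exactly the null of "no nucleus-level structure, same site-frequency
  spectrum". The p-value uses the add-one estimator, so it can never be
  smaller than 1/(B+1).

`classify_karyon()` is deliberately conservative: *heterokaryon-consistent*
requires density at or above the heterokaryon band AND a strong
(score ≥ 0.8), significant (p ≤ 0.05) bipartition;
*homokaryon-consistent* requires density at or below the homokaryon band
AND the absence of such a bipartition; everything else — including the
intermediate densities observed in field spores — is *undetermined*. The
"-consistent" phrasing is intentional: without a mating-type marker this
is evidence about architecture, not proof.

## The synthetic spore world

The simulator exists so every stage can be validated by parameter
recovery without raw reads. Its defaults are the stated study conditions
where those exist, and a single realistic choice elsewhere:

* **Nuclei per spore**: fixtures default to 22 and 19, the numbers of
  successfully sequenced nuclei for the two field spores (without
  asserting which spore had which; the study selected 22–24 per spore).
* **Coverage**: per-(site, nucleus) depth is lognormal with mean 30 and
  sigma 1.0, plus an independent dropout probability of 0.1. MDA
  amplification is highly uneven with locus dropout; the lognormal +
  dropout pair is the simplest widely used surrogate, and no read-level
  model is specified by the study. Sigma 1.0 gives the heavy right tail
  and occasional near-zero coverage characteristic of MDA libraries.
* **Quality gates**: the caller's minimum mapping quality 30 and base
  quality 20 act before counting, so they are modeled as per-read discard
  probabilities (defaults 0.05 and 0.02) rather than by simulating
  alignments — only the surviving counts matter downstream. Discarded
  reads still count toward DP, so `ref + alt <= depth` as in real AD/DP
  fields.
* **Sequencing error**: each surviving read reports the wrong allele with
  probability 0.005 (Illumina-scale post-filter error).
* **Variant structure**: heterokaryon fixed differences are Poisson at
  `divergence_per_kb` over the assembly, each site's alternate allele
  carried by exactly one class (chosen at random per site — the reference
  assembly is a consensus of both classes); class sizes are binomial with
  both classes forced non-empty. Private mutations are Poisson at
  `private_mut_per_kb` **at the spore level**, each carried by one
  uniformly chosen nucleus. The spore-level reading matters: published
  density bands describe the aggregated SNP set of a spore, and a
  per-nucleus reading of the same numeric rate would inflate the
  aggregate density by the nucleus count, making the homokaryon band
  unreachable by construction.
* **Annotations**: drawn from independent fixed distributions with a
  configurable fraction (default 5%) of sites pushed past exactly one
  hard-filter threshold, and 10% of sites lacking rank-sum annotations.
  Hard filters are marginal threshold tests, so joint annotation
  structure is irrelevant to their correctness.
* **Decoy sites**: invariant sites default to 10× the variant count so
  missingness and hard filters are exercised on non-SNPs. In noise-floor
  experiments with zero true variants this default would emit nothing, so
  such tests request a fixed decoy count explicitly.

What the simulator does **not** emulate: real MDA chimeras, mapping bias,
linked error along reads, repeat-induced mismapping (repeat intervals
affect only the density denominator, not the error model), or the
correlation structure of real quality annotations. A green
parameter-recovery test therefore establishes that the *filtering
arithmetic* is correct under the stated noise model, not that the model
captures every artifact of real single-nucleus data.

## Numerical and degenerate-input choices

* Strict inequalities everywhere the rules are stated as strict: hard
  filters (boundary passes), AF band (0.1/0.9 excluded), missingness
  (exactly 1/3 retained).
* Tie genotype calls become MISSING; distance pairs with no shared sites
  get 0.5; a between-group mean distance of 0 yields partition score 0.
* Multi-allelic records are rejected with an explicit error
  (`max_alternate_alleles = 1` per the caller parameter set), not
  silently split.
* Display rounding is half-up at 2 decimals (matching how the published
  table rounds); all internal arithmetic keeps full precision.
* All randomness flows through explicit seeds; identical seeds yield
  byte-identical fixtures and manifests.

## Known limitations

* The karyon density bands are borrowed priors from a different genus;
  verdicts near the band edges should be treated as undetermined in
  practice even when the classifier commits.
* The permutation null conditions on the observed site-frequency
  spectrum; it does not model linkage between sites, so on strongly
  linked private-mutation clusters the test can be slightly liberal.
* The two-group clustering cannot represent three or more nucleus
  classes; such a spore would surface as a strong but unstable
  bipartition.
* With only two nuclei the partition score is degenerate (any split is
  "perfect"); the permutation p-value then carries all the weight and the
  verdict is usually undetermined.
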