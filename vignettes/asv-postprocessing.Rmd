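---
title: "Post-denoising processing of amplicon feature tables: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-denoising processing of amplicon feature tables: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asvpost)
```

After denoising, an amplicon-sequencing experiment is summarized by a
feature table (read counts per amplicon sequence variant per sample), the
representative sequences, and optionally taxonomy and sample metadata.
`asvpost` covers the computational steps between that point and downstream
numerical ecology: removing between-sample crosstalk, resolving
variable-length amplicons that were concatenated instead of merged,
octave-plot quality summaries, and writing exact input bundles for Rhea,
MicrobiomeAnalyst and phyloseq. This vignette explains the models behind
those steps, the tunable parameters, what the synthetic generators emulate,
and the design decisions taken where more than one reasonable convention
exists.

## The crosstalk model

Highly multiplexed runs assign a small fraction of reads to the wrong
sample ("index hopping"). The damage is not to abundance estimates — the
leaked fraction is around a percent — but to *presence*: a feature abundant
in one sample acquires spurious low counts in many others, inflating
richness and prevalence statistics.

The filter models leakage as uniform: if feature $i$ has total count $C_i$
over $N$ samples and a fraction $\gamma$ of its reads leak, the expected
leaked count per sample is

$$e_i = \frac{\gamma\, C_i}{N}.$$

Each positive entry $x_{ij}$ is scored by

$$s_{ij} = \frac{e_i}{e_i + x_{ij}} \in (0, 1],$$

which is large when the observed count is small relative to the expected
leak. Entries with $s_{ij} \ge \tau$ are treated as crosstalk and set to
zero; all other entries are left untouched. With the default $\tau = 1/3$
the rule flags exactly the entries with $x_{ij} \le 2 e_i$ — counts within
twofold of what pure leakage would produce. Ties at the threshold are
flagged: at the boundary, removal of a suspicious minimum is the
conservative choice for diversity estimation.

Counts are zeroed, never decremented. Partial subtraction would produce
corrected abundances that depend on an uncertain $\gamma$, while zeroing
targets the actual failure mode (spurious presence) and keeps every
surviving count identical to the observed one.

Two guards bound the filter's aggressiveness, both applied per feature:

* `min_total` (default 1): features with fewer total reads than this are
  skipped outright; there is no signal to distinguish leak from presence.
* `max_row_loss` (default 0.1): if the flagged entries of a feature sum to
  more than this fraction of its reads, the feature is skipped and
  reported. A feature losing 10% or more of its reads to the rule does not
  look like a high-abundance feature with faint echoes — it looks like a
  genuinely rare, evenly spread feature, which uniform-leak logic would
  otherwise erase wholesale.

Skipped features pass through unchanged and are listed in the report;
all-zero rows pass through without being counted as skipped, since there is
nothing to filter. The default $\gamma = 0.01$ is the order of magnitude
reported for index hopping on patterned flow cells; it should be raised
only with evidence (e.g. positive controls appearing across samples).

Because $e_i$ is proportional to $C_i$, the flag pattern of a row is
invariant under integer scaling of that row — the filter responds to the
*shape* of a feature's distribution across samples, not its depth. This
scale covariance, the within-row monotonicity of zeroing (if a count is
removed, every smaller positive count in the row is too), identity at
$\gamma = 0$, and agreement with an entry-by-entry brute-force evaluation
are all enforced by the test suite over seeded random tables.

## Resolving variable-length amplicons

For markers with little length variation, paired-end reads overlap and are
merged before denoising. For highly length-variable markers such as the
fungal ITS region, some amplicons are longer than the two reads combined;
forcing a merge discards them. The alternative is to denoise the two reads
separately and concatenate each denoised pair with a run of `N`s, which
keeps long amplicons at the cost of leaving the genuinely overlapping ones
unmerged. `merge_features()` finishes the job after the fact:

1. **Split.** A sequence is split when it contains exactly one maximal run
   of at least `spacer_min_run` `N`s (default 5), strictly internal, with
   `N`-free flanks. Ten `N`s is the conventional spacer; accepting runs of
   five or more tolerates upstream trimming, while short runs are single
   ambiguity calls and never split. Two qualifying runs are ambiguous — the
   record is left alone with a warning. A flank containing its own `N`
   would make the fragment ill-defined for exact overlap comparison, so
   such records are also left alone (warned); this is this package's
   resolution of a case the splitting rule alone does not define.
2. **Merge.** Candidate overlap lengths $L$ run from
   $\min(|l|, |r|)$ down to `min_overlap` (default 12); the first $L$ whose
   suffix/prefix mismatch count is at most
   $\lfloor f \cdot L \rfloor$ wins, giving the *longest* acceptable
   overlap and minimizing spurious short-homology joins. The merged
   sequence is $l$ followed by the unmatched tail of $r$, so any
   mismatching overlap positions keep the left (forward-read-derived)
   base — forward reads are conventionally the higher-quality mate and no
   per-base qualities survive denoising. The default mismatch fraction
   $f = 0$ reflects that denoised sequences are consensus sequences: true
   overlaps should be exact. No reverse-complementation is attempted;
   orientation is the upstream concatenation's contract.
3. **Collapse.** Features whose final sequences coincide are summed
   per sample, so column totals are conserved exactly. The surviving id is
   the member with the largest total count (ties: first in input order),
   and that member's taxonomy is retained — the most abundant member is the
   best-supported representative.

Merging is idempotent: a merged sequence contains no qualifying spacer, so
a second pass is a no-op. This is tested, as is exact template recovery on
simulated pairs.

## Octave plots

An octave plot is a per-sample histogram of feature abundances with
logarithmic (base-2) bins: bin $k$ counts the features whose count $c$
satisfies $2^k \le c < 2^{k+1}$. Zero counts are excluded, so bin totals
equal the number of features detected in the sample. Healthy samples show
a broad, roughly bell-shaped profile; a spike at the low bins signals
residual noise, contamination or crosstalk, and a sample worth inspecting
before analysis. The package computes the bins on raw counts — the
histogram is a property of the observed reads, and normalization would
blur the singleton/doubleton structure the plot exists to show.

Bins are computed by exact integer comparison against powers of two
(`findInterval` over $2^0 \dots 2^{31}$), never via floating-point
logarithms, so boundary counts cannot be misbinned; exactness is verified
by brute force against a bit-length oracle for every count up to $2^{16}$.
The tidy output (`sample_id`, `bin`, `low_edge`, `high_edge`,
`n_features`) is the primary artifact; `autoplot()` renders it.

## Export formats

The MicrobiomeAnalyst bundle is comma-separated with sentinel first header
cells `#NAME` (abundance, metadata) and `#TAXONOMY` (taxonomy); the Rhea
input is a single tab-separated table headed `#OTUId` with an optional
trailing `taxonomy` column joining the lineage with `";"`, empty ranks
preserved. These dialects are pinned byte-exactly in golden tests: if
either downstream tool changes its format, the break surfaces as a test
failure rather than silent corruption. Identifiers containing the
delimiter are quoted for MicrobiomeAnalyst and rejected for Rhea, which
has no quoting convention. File names (`abundance.csv`, `taxonomy.csv`,
`metadata.csv`, `otutable_rhea.tab`) are this package's convention.

The phyloseq hand-off (`build_phyloseq()`, `inst/scripts/asvpost-handoff.R`)
assembles the same components into a `phyloseq` object, reading a newick
tree verbatim via `ape` when given; one example macro (per-sample alpha
diversity) demonstrates scripted analysis over the object.

## What the synthetic generators emulate

The generators exist so every stage can be tested against known ground
truth with no external data.

* `simulate_community()` draws per-feature totals from a log-normal
  distribution (`meanlog = 6`, `sdlog = 1.5`; median ≈ 400 reads spanning
  roughly 10–10⁵), the standard first-order model for community abundance
  profiles, and assigns each feature a small "home" sample set (default:
  one sample, i.e. a sample-exclusive community — the cleanest backdrop
  for leak detection).
* `inject_crosstalk()` emulates demultiplexing misassignment: a
  binomial($C_i$, $\gamma$) number of reads per feature is drawn without
  replacement from its home samples and redistributed uniformly at random,
  conserving the feature's total exactly (misassignment moves reads, it
  does not create them). The mask of entries that went from zero to
  positive is the ground truth a filter should remove.
* `simulate_concatenated_pairs()` builds random templates and cuts each
  into two `read_len` fragments whose true overlap is drawn from
  `overlap_range` (negative = true gap), joined with an `N` spacer. A
  record is exactly mergeable back to its template iff its true overlap
  meets the merge policy. The per-record template length is determined by
  `2 * read_len - overlap`, so it is not an independent parameter.

All generators run inside an isolated RNG scope keyed by an explicit seed:
identical arguments give bit-identical output and the caller's random
state is untouched.

What the generators do **not** emulate: sequencing error and chimeras
(inputs here are post-denoising), index- or lane-structured leakage (the
filter's uniform-leak model is also the generator's, so these tests cannot
detect model misspecification against structured hopping), compositional
correlations between taxa, and read-level quality. Passing tests therefore
demonstrate internal correctness of the implemented models, not that the
uniform-leak model captures every real instrument's behaviour.

## Numerical and interface choices

* Tables are features × rows, samples × columns on disk; a
  `samples_as_rows` flag transposes on load. The first header cell is
  ignored on read (`""`, `"#OTU ID"`, `"#NAME"` all seen in the wild).
* Cells must parse as non-negative integers; anything else is an error
  naming the feature and sample — silent coercion of a malformed table is
  worse than a refusal.
* Sequences are uppercased on load and IUPAC ambiguity codes outside
  `{A,C,G,T,N}` are mapped to `N` with a warning: the merge logic only
  distinguishes `N`, and keeping rare ambiguity codes would complicate
  exact overlap comparison for no benefit. Duplicate FASTA ids are a hard
  error.
* Score/threshold comparisons use `>=` so behaviour at ties is defined;
  both the implementation and the brute-force test oracle evaluate the
  same expression, so floating-point rounding cannot make them disagree.
* All text output is UTF-8 with Unix line endings, making byte-level
  reproducibility assertions meaningful across platforms.

The test suite and the acceptance checks run at deliberately desk-sized
problem scales — up to 10×10 tables for oracle comparisons (200 of them),
100 random tables for law checks, 500 simulated pairs per merge scenario,
a 50-feature × 12-sample community for the end-to-end crosstalk recovery,
and the full 1…65536 range for octave binning. These sizes give the
property checks combinatorial variety while keeping a full run to well
under a minute per module; the algorithms themselves are linear in table
size and have been run on tables orders of magnitude larger.

## Known limitations

* $\gamma$ is a single global constant; per-sample or per-index leak
  structure is neither modeled nor estimable here (estimating $\gamma$
  from spike-ins or mock communities is out of scope).
* The crosstalk score has no notion of uncertainty: an entry exactly at
  the threshold is removed, with no multiple-testing or FDR framing.
* Overlap merging is exact-match oriented; it does not use alignment with
  gaps, so indel-bearing overlaps (rare in denoised consensus sequences)
  will not merge and remain concatenated — a conservative failure.
* Octave plots are descriptive; the package deliberately draws no
  automatic sample-exclusion decisions from them.
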