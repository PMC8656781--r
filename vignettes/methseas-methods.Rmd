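---
title: "Models and methods behind methseas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methseas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methseas)
```

# Scope and model

`methseas` analyses paired tumor/normal methylation-array data at the
level of individual CpG probes. The measured quantity is the beta value,
the methylated signal over the total locus intensity with a stabilizing
offset:

$$\beta = \frac{M}{M + U + \mathrm{offset}}.$$

The offset defaults to 100, the conventional damping constant for
fluorescence intensities on the scale of hundreds to thousands; with
offset 0 the literal ratio is recovered, and `generate_intensities()`
inverts the map exactly (round-trip error below $10^{-9}$), which is how
the beta computation is validated.

The statistical model is deliberately nonparametric. Within each probe,
the tumor–normal differences of the 24 (by default) matched pairs are
exchangeable under the null; the paired Wilcoxon signed-rank test is used
per site, and multiplicity is handled by the Westfall–Young step-down
maxT permutation procedure under the paired sign-flip null, which
preserves the correlation between probes and therefore gives strong
family-wise error control without independence assumptions.

# Probe filtering

Three exclusion rules are applied in a fixed order, each probe attributed
to the first rule it trips: sex-chromosome probes (X/Y confound
methylation with sex), probes with a common SNP within 5 bp of the
targeted CpG (genotype masquerades as methylation), and probes without a
unique mapping to the reference (cross-reactive signal). SNP proximity
and mapping uniqueness are consumed as manifest flags: recomputing them
would require a SNP catalogue and a genome aligner and is deliberately
out of scope; the flags are upstream metadata of the array manifest.

# CpG island detection and neighborhoods

Islands are detected from sequence with a 200-bp window sliding at 1-bp
steps. A window qualifies when its GC fraction is **strictly** greater
than 0.5 and its observed/expected CpG ratio — the Gardiner–Garden form
$n_{CpG} \cdot L / (n_C \cdot n_G)$ — is at least 0.6 (**inclusive**).
The asymmetric strictness mirrors the phrasing of the standard
definition ("higher than 50 %", "greater or equal to 0.6") and is pinned
by unit tests at both boundaries. Qualifying windows that overlap or
book-end are union-merged into maximal islands, whose GC fraction and
obs/exp ratio are recomputed over the merged interval; windows containing
`N` never qualify. The step size, the merge rule and the obs/exp formula
are not forced by the definition itself; the 1-bp step with union-merge
is the deterministic, assumption-free reading, and it is verified against
a brute-force enumeration of all qualifying windows on random sequences.

Every position is then assigned exactly one neighborhood class. With $d$
the number of bases strictly between the position and the nearest island:
shores for $d \le 2000$, shelves for $2000 < d \le 4000$, open sea for
$d > 4000$ (or no island on the chromosome). Both interior bounds are
inclusive. `N_` (north) marks the side where the nearest island lies at
a higher coordinate than the position, `S_` (south) the lower side; the
orientation convention is not fixed by common usage, so this choice is
documented here and exercised by a reflection-symmetry property test
(mirroring the coordinate axis must swap N and S exactly). A tie between
two equidistant islands breaks toward the island with the lower start.

# Functional gene regions

Gene models carry an explicit `tss` column (0-based coordinate of the
first transcribed base: `start` on `+`, `end - 1` on `-`). The
strand-aware upstream distance $u \ge 1$ yields TSS200 ($u \le 200$) or
TSS1500 ($200 < u \le 1500$); positions inside the gene are classed 5′
UTR, first exon, 3′ UTR or body. Per gene, exactly one class is emitted
with precedence `TSS200 > TSS1500 > UTR5 > FirstExon > UTR3 > Body`,
matching the array-annotation convention; a probe hit by several genes
keeps all per-gene assignments, and tabulations count each probe at most
once per class. Gene context is `coding` if any assigned gene is
protein-coding, else `noncoding` (including miR genes), else
`intergenic`. The coding-over-noncoding precedence for probes hitting
both is a genuine free choice; it is fixed here so that counts are
deterministic, and flagged as such.

# Per-site testing and maxT adjustment

Zero within-pair differences are dropped before ranking (the classic
signed-rank treatment rather than Pratt's); absolute differences get
midranks, and $W$ is the rank sum of positive differences. The p-value is
exact — full enumeration of the $2^{n'}$ sign assignments — whenever the
reduced sample has $n' \le 25$ tie-free values, the customary crossover
beyond which enumeration buys nothing; ties or larger $n'$ switch to the
normal approximation with tie-corrected variance and a 0.5 continuity
correction. An all-zero difference vector is flagged degenerate with
$p = 1$.

The maxT statistic per probe is the absolute standardized signed-rank
statistic $|W - \mu| / \sigma$ with $\mu = S/2$ and
$\sigma^2 = \sum r_i^2 / 4$ (tie-corrected through the midranks). This
keeps the adjusted test aligned with the raw test rather than switching
to a $t$-statistic. Each permutation flips the sign of a pair's
difference vector across *all* probes simultaneously. Adjusted p-values
use successive maxima over the probes ordered by decreasing observed
statistic, with the $+1$ correction in numerator and denominator in the
sampled regime, and are monotonized along the ordering. When
$2^{n_{\text{pairs}}} \le n_{\text{perm}}$ the full flip set is
enumerated, making the result seed-independent; otherwise a seed is
mandatory — irreproducible permutation p-values are treated as an error,
not a warning.

Direction calls gate on the **raw** p-value at $\alpha = 0.05$ by
default, with the adjusted p-value reported alongside (`gate_maxt`
switches the gate). Genome-wide tables at the scale of tens of thousands
of discovered sites are raw-p tabulations; whether a family-wise-adjusted
column should gate instead is left to the analyst, and both columns are
always present when maxT is computed.

# Fold change and candidate selection

Beta values are bounded fractions, so a plain ratio of medians explodes
as the normal median approaches 0. The signed fold change is
$r = (m_T + 0.01)/(m_N + 0.01)$, reported as $r$ when $r \ge 1$ and
$-1/r$ otherwise, so magnitudes are always $\ge 1$ and the sign encodes
the direction (ratio exactly 1 is reported $+1$ by convention). The
pseudo-count of 0.01 — one percentage point of methylation — is exposed
as a parameter. Worked anchor cases: medians 0.79 vs 0.04 give
$0.80/0.05 = +16$; medians 0.19 vs 0.57 give $-0.58/0.20 = -2.9$.
Candidate selection keeps significant sites with $|FC| \ge 2$ in either
direction.

# Tabulation conventions

Chromosome × neighborhood × direction tables collapse N/S shores and
shelves into `Shore`/`Shelf` groups (four columns), counting each
significant site exactly once by its single neighborhood class; the full
six-class breakdown remains available from the annotations. "Unique
sites" means unique probe positions: a probe assigned to several
overlapping genes counts once per table cell, and the per-gene listing
appears only in the heat-map matrix export, where overlapping genes are
all named. Reported percentages are rounded to one decimal, half-up
(`floor(10x + 0.5)/10`), matching the usual presentation of such tables;
R's default banker's rounding would differ at exact .05 boundaries.

# Over-representation analysis

The enrichment stage is a generic hypergeometric over-representation
test: for a miR's target set of size $n$ within a universe of size $N$,
the overlap $k$ with a pathway of size $K$ is scored with the exact upper
tail $P[X \ge k]$, computed with `phyper`. This replaces the EASE-style
conservative Fisher variant used by interactive web tools, whose exact
internals are not reproducible; the substitution is deliberate and
documented. BH adjustment is applied across pathways within each miR
only, since compilation of significant pathways is per miR. The default
universe is the union of all pathway genes and can be overridden — there
is no canonical background for target-prediction gene lists, so the
choice is exposed rather than hidden. Manual curation of cancer-relevant
pathways is represented by an optional include list, not an algorithm.

# The synthetic-data generator

The generator emulates the design the pipeline targets: 24 tumor/normal
pairs, probes split between CpG-island/promoter context and open sea.

* **Noise model.** Beta values are Beta-distributed with mean $\mu$ and
  concentration $\kappa$ (`shape1` $= \mu\kappa$, `shape2`
  $= (1-\mu)\kappa$). No published noise model exists for this design;
  Beta noise is the standard behavior of bounded methylation fractions.
  $\kappa = 50$ gives a standard deviation of about 0.05 at
  $\mu = 0.15$ — typical array-replicate noise.
* **Baselines.** Island/promoter probes have normal-tissue mean 0.15,
  open-sea probes 0.75 (both configurable). This mirrors the
  island-hyper / open-sea-hypo asymmetry of tumor methylomes and makes
  the tabulation stages exercise both directions.
* **Planted effects.** Tumor means are shifted by $\pm\delta$
  ($\delta = 0.3$ by default), hyper effects planted preferentially on
  island probes and hypo effects on open-sea probes; shifted means are
  clipped to $(0.001, 0.999)$ with a reported clip count.
* **Islands by construction.** Island sequence is sampled CG-rich and
  re-sampled until *every* 200-bp window passes the island criterion, so
  planted truth labels cannot be wrong; the background is AT-rich with
  all CpG dinucleotides removed, so no background window can qualify.
  Islands are separated by more than 8 kb so open-sea positions exist.
* **Determinism.** Each artifact (genome, manifest, betas) draws from its
  own RNG stream derived from the single configuration seed; identical
  configurations give byte-identical outputs, and generation never
  disturbs the caller's RNG state.

What the generator does **not** emulate: Illumina type I/II probe
chemistry, dye bias, batch effects, copy-number confounding, tumor
purity, spatial correlation of methylation along the genome, and
clinical substructure among the pairs. Passing tests on synthetic data
therefore validate the algorithms and their operating characteristics
(error control, power, annotation correctness), not robustness to those
real-data artefacts.

# Validation design and problem sizes

The test suite checks every operation against an independent oracle:
full sign-pattern enumeration for the exact Wilcoxon p (1000 random
vectors, $n \le 10$), brute-force window enumeration for island
detection (50 random 2-kb sequences), naive nearest-island scans for
neighborhood classes (1000 random positions), and combinatorial
summation for the hypergeometric tail (100 random configurations).
Operating characteristics are measured by simulation: the family-wise
error of maxT over 1000 complete-null datasets of 50 probes × 24 pairs
(400 sign-flip permutations each) is required to lie in $[0.03, 0.07]$,
and recall of planted $\delta = 0.3$ effects at $\kappa = 50$ with 24
pairs (200 signal + 800 null probes) must reach 0.9 with no sign flips
among selected ≥ 2-fold candidates. These sizes were chosen so the whole
suite runs in a couple of minutes while keeping Monte-Carlo error well
inside the asserted bands. A packaged fixture transcribing the published
chromosome × region count tables is re-aggregated through the cross-tab
operations and must reproduce every marginal exactly; two mislabelled
rows in the printed miR table are transcribed as printed, and only the
margins that reconcile (170 sites; 115 hypo, 55 hyper) are asserted.

# Known limitations

* Probe filtering trusts manifest flags; no SNP catalogue or remapping.
* The island detector implements the stated window definition only; no
  extra length or merging heuristics beyond window union.
* Raw-p gating at $\alpha = 0.05$ across hundreds of thousands of probes
  is a discovery screen, not an error-controlled inference; the maxT
  column is provided for the latter.
* Fold changes of medians are unstable when both medians are near 0;
  the pseudo-count bounds but does not remove this.
* The ORA stage tests marginal overlap only — no pathway topology, no
  inter-miR dependence.
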