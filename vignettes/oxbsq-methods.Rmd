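---
title: "Separating 5mC and 5hmC from paired BS/oxBS libraries: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating 5mC and 5hmC from paired BS/oxBS libraries: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Standard bisulfite sequencing cannot tell 5-methylcytosine (5mC) from
5-hydroxymethylcytosine (5hmC): both marks protect a cytosine from
conversion, so the "methylation" level of a BS library is really the sum
mC + hmC. Oxidative bisulfite (oxBS) sequencing resolves the two marks by
running a second library in which 5hmC is first oxidized (KRuO4) to
5-formylcytosine, which then converts like an unmodified base. The oxBS
library therefore reads out 5mC alone, and the 5hmC level is obtained by
differencing the two readouts:

$$\widehat{mC} = L_{oxBS}, \qquad \widehat{hmC} = L_{BS} - L_{oxBS},$$

where each \(L\) is an aggregate (count-pooled) unconverted-call fraction.
This package implements that estimator together with everything an analysis
of a paired BS/oxBS study needs around it — read filtering, spike-in
conversion QC, genomic-element summaries, group statistics — and a
synthetic methylome generator that provides ground truth for validating
every step.

## The chemistry forward model

The generator simulates each sequenced molecule through an explicit
conversion model. For a site with true fractions \(m\) (5mC) and \(h\)
(5hmC), the probability that a read reports an unconverted C is

$$P_C^{BS} = m(1-\epsilon_m) + h(1-\epsilon_h) + (1-m-h)(1-\beta)$$
$$P_C^{oxBS} = m(1-\epsilon_m) + h\left[(1-\omega)(1-\epsilon_h) +
  \omega(1-\beta)\right] + (1-m-h)(1-\beta)$$

with \(\beta\) the bisulfite conversion probability of unmodified C
(default 0.995), \(\omega\) the oxidation probability of 5hmC (default
0.975), and \(\epsilon_m, \epsilon_h\) inappropriate-conversion
probabilities (default 0). The defaults sit deliberately just above the
>99% / >97% acceptance bounds commonly applied to the assay, so simulated
spike-in QC passes by a realistic, not comfortable, margin. Per site,
depth is Poisson around the target coverage independently in each library
and modified-call counts are Binomial(depth, \(P_C\)).

Two consequences worth noting:

* The naive difference estimator is slightly attenuated: at \(m = 0.5, h
  = 0.15\) and default chemistry the expected readouts are \(L_{BS} =
  0.652\) and \(L_{oxBS} = 0.506\), so the recovered hmC is ~14.6% rather
  than 15% and the recovered mC ~50.6% rather than 50%. Both remain
  within one percentage point of the truth, which is why no correction is
  applied by default — mirroring common practice.
* The model is analytically invertible. `corrected_levels()` solves the
  two-equation system for \((m, h)\) given \((\beta, \omega)\) — e.g. from
  spike-ins — and is exact on noiseless input (tested as a round-trip
  identity). Estimates are clipped to the simplex \(\{m \ge 0, h \ge 0, m
  + h \le 1\}\) and flagged when clipping occurred.

Apparent CH-context methylation is dominated by conversion failure: with
true mCH = 0.5% and \(1-\beta = 0.5\%\), the expected CH readout is just
under 1%. This reproduces the known inflation of CH estimates by failed
conversion, and is the reason the package estimates conversion from
spike-ins rather than from CH sites.

## Spike-in conversion QC

Three synthetic control sequences carry cytosines of known class:
unmodified C, 5mC, and 5hmC. The bisulfite rate is the converted fraction
at unmodified-C sites. The oxidation efficiency cannot be read directly
from hmC sites (a molecule reads T only if it was oxidized *and*
converted), so `estimate_oxidation_rate()` normalizes the hmC T-fraction
by the bisulfite rate estimated in the same library:
\(\hat\omega = \hat{T}_{hmC,oxBS} / \hat\beta_{oxBS}\), with a
delta-method standard error. mC spike-in sites report protection failure
(\(\epsilon_m\)) descriptively; no correction is applied by default.
Gating treats the >99%/>97% bounds as per-sample minima; failures warn by
default and error in strict mode.

## The synthetic methylome

The generator emulates an adult (hippocampus-like) mammalian methylome on
a compact mock genome: three 300-kb autosomes, a 200-kb chrX and a 100-kb
chrY (~1.2 Mb, about 1.2 x 10^5 strand-specific CG sites), with 60 CpG
islands (500–1500 bp, CG-dinucleotide probability 0.4 per dinucleotide,
giving >=3x background CG density by construction), 60 stranded promoters
(TSS +/- 2 kb) and a 5% repeat fraction (1.5-kb elements of background
composition). This size keeps binomial sampling error on pooled CG levels
well below one percentage point at 10x coverage while a full 12-sample
simulation plus quantification runs in roughly half a minute on one core —
the problem size used throughout the tests and the acceptance script.

Truth targets by compartment and context:

| quantity | default | where |
|---|---|---|
| genomic mCG | 0.50 | genome-wide pooled expectation |
| genomic hmCG | 0.15 | genome-wide pooled expectation |
| mCH / hmCH | 0.005 / 0.0005 | uniform |
| CGI-interior mCG / hmCG | 0.05 / 0.02 | island bodies |
| repeat mCG / hmCG | 0.95 / 0.02 | repeat elements |
| chrX female mCG excess | +0.02 | whole chrX, CG |
| chrX male hmCG excess | +0.02 | whole chrX, CG |
| aging hmCG (old - young) | +0.03 | CGI shores + shelves |
| aging mCG (old - young, males) | -0.015 | promoter TSS +/- 1 kb |

The genomic mCG/hmCG targets are interpreted as *genome-wide pooled*
expectations — that is what whole-methylome studies report — so the
background-compartment mean is calibrated at truth-assignment time:
given the realized numbers of background, island-interior and repeat CG
sites, the background mean solves the mixture equation so that the
site-weighted average equals the genomic target. Without this, the
hypomethylated islands and hypermethylated repeats would mechanically pull
the pooled level away from the intended total.

Per-site, per-sample truth is Beta-distributed around the compartment mean
with concentration 20 (an open choice: the replicate-to-replicate
variance of biological samples is not something the assay literature pins
down; concentration 20 gives a per-site SD of ~0.11 at a 0.5 mean, which
propagates realistic between-replicate noise without destabilizing pooled
levels). The infinite-concentration limit is a point mass and is retained
for exact tests. \(m\) and \(h\) are drawn independently and renormalized
onto the simplex when their sum exceeds 1; this affects mostly repeat
sites (mean 0.95 + 0.02) and biases pooled levels negligibly. Additive
effect injections that push a site mean outside \([0,1]\) are clipped with
a warning counting the affected sites — at the defaults this happens only
where the chrX sex excess, the aging shore/shelf excess and a repeat
overlap (a few hundred sites).

All randomness flows from one top-level seed through named substreams
(reference, truth-by-sample, counts-by-sample, reads, spike-ins, assays),
so each module is independently reproducible and emitted files are
byte-identical across runs at a fixed (config, seed).

What the generator does *not* emulate: sequencing errors beyond
quality/ambiguity annotation, PCR duplicates, mapping bias or mappability
structure, fragment-length or GC bias, chromosome-scale genomes, and
5fC/5caC. Passing tests therefore demonstrate correctness of the
estimators and bookkeeping under the stated chemistry model, not
robustness to alignment artifacts in real libraries.

## Read handling

Synthetic paired-end reads carry coordinate tags (chromosome, fragment
start and length, strand, library, per-mate trim offsets) in their names,
so placement is exact and no aligner is needed; mate 1 is the fragment
5' end in molecule orientation and mate 2 the reverse complement of its
3' end. Filtering keeps a pair iff both mates pass: mean base quality
>= 25 (interpreted as the mate mean, since per-base vs mean is
ambiguous in common usage; a per-base mode is available) and at most one
ambiguous base per mate. Rejection is pair-level because downstream
libraries are paired. Filtering precedes the 3-bp both-end trim — the
order is not dictated by the protocol, and filtering first means the
quality statistics describe the read as sequenced. Adapter removal is
assumed done upstream (the generator emits adapter-free reads); only the
additional 3-bp end trim is implemented, and trimming updates the
coordinate tags so counting stays exact.

## Aggregation and genomic elements

Pooling is count-weighted throughout: the pooled level of a site group is
\(\sum \text{modified} / \sum \text{total}\), identical to the
coverage-weighted mean of site levels (an exact identity the tests assert
against a brute-force oracle). hmC is always computed on the pooled BS and
oxBS readouts — per-site clamping at zero is applied only to per-site
diagnostics, never before pooling, so the aggregate difference is
unbiased. CG sites on the two strands are kept as separate records
(collapsing to symmetric CpG units would discard CH asymmetry). Per-site
output requires at least one read in each library; pooled quantities have
no minimum because pooling is count-based.

Chromosome summaries pool all autosomes together (the pooled value, not a
mean over chromosomes — the alternative is a one-line change in the
grouping), report chrX and chrY separately, and treat chrY records in a
female-labelled sample as a hard error, since that indicates a
design/label mismatch rather than noise.

Shores span 0–2 kb and shelves 2–4 kb from each island edge — the
standard shore/shelf convention; a "±4 kb" flank is ambiguous between
total and per-annulus widths, and this reading lets both shores and
shelves exist inside the flank. Flanks of neighboring islands are split
at the midpoint between the islands; flanks running off a chromosome end
are truncated and flagged. Promoter windows are tiled into forty 100-bp
bins (-20..-1, +1..+20) in the gene's orientation, with minus-strand
promoters mirrored; CGI profiles use 200-bp edge-anchored bins on each
flank with the variable-length island body as a single bin 0, avoiding
length-rescaling artifacts. Meta-profiles pool counts within an
element's bin but average *elements* unweighted, so a deeply covered
element cannot dominate the profile; bins with no covered sites are
missing, not zero. Overlapping promoters/CGIs are all retained — a site
may contribute to several elements. Region aggregates (five CGI classes;
four orientation-aware 1-kb promoter super-bins) pool member sites
directly; super-bins pool rather than average their 100-bp bins (the
averaging alternative is available through the profile path).

The repeat surrogate deliberately reports the *BS* level (mC + hmC
combined, no oxBS subtraction) over repeat elements next to the
genome-wide BS level: it reproduces the bias of repeat-element
pyrosequencing as a proxy for global methylation — near-saturated repeats
versus a ~65% genome-wide BS readout at the defaults.

## Group statistics

Each endpoint (e.g. pooled autosomal mCG, chrX hmCG, upstream-shore hmCG)
gets a fixed-effects two-way sex x age ANOVA with interaction. Balanced
designs — the default — use the orthogonal decomposition, for which the
sums of squares satisfy the exact identity SS_total = SS_sex + SS_age +
SS_interaction + SS_error (asserted to 1e-9 relative in the tests);
unbalanced input falls back to Type II sums of squares with a warning
(the original analysis tool's SS type is not documented, and Type II is
the conventional choice for unbalanced factorial designs without
interaction-driven hypotheses). Benjamini–Hochberg correction is applied
within declared endpoint families (one family per figure-panel-like
group, e.g. the five CGI classes), not across everything. SNK post hoc
tests run only for terms whose BH-adjusted p passes the 0.05 gate —
gating on the adjusted value is the conservative reading of "post hoc
after correction" — using the step-down studentized-range procedure:
sorted means, range-r critical values from `qtukey`, and no subdivision
of non-significant spans. Unequal group sizes use the harmonic mean n and
are flagged. Three-level age designs are supported; defaults are
two-level.

One caveat found while testing: the familiar claim that BH is idempotent
is false as a general statement — re-adjusting an adjusted vector
re-scales by n/rank and can change it. The step-up rule's true fixed
points (tied/fully-adjusted vectors) are what the tests assert, along
with monotonicity and the never-decrease property.

## Assay quantitation

* **qPCR efficiency.** Least-squares slope of Ct on log10(quantity) over
  a dilution series; \(E = 10^{-1/\text{slope}} - 1\) (100% at slope
  -3.3219). The widely circulated variant "E = -1 + 10^(slope/-1)" is a
  garbling of this formula — it returns absurd values for any realistic
  slope — and the implementation uses the correct form, which reproduces
  the 75% benchmark on a noiseless series generated at per-cycle factor
  1.75. Fold changes use \((1+E)^{-\Delta\Delta C_t}\) with
  \(\Delta\Delta C_t = \Delta C_t^{sample} - \overline{\Delta
  C_t}^{calibrator}\); E = 1 reproduces the classic \(2^{-\Delta\Delta
  C_t}\) rule, and analyzing an inefficient assay as if E = 1
  monotonically overestimates ratios above 1 (asserted on synthetic
  series).
* **Digital PCR.** Poisson partition counting: \(\lambda = -\ln(1 -
  \text{positives}/\text{total})\), copies/uL = \(\lambda\) / partition
  volume (default 8.09e-4 uL, the QuantStudio-3D class; the value is
  configurable because chip geometry is not universal), then
  dilution/volume/mass bookkeeping to copies per ug input under 1:1
  RNA-to-cDNA carryover. Saturated chips are an error rather than a
  truncated estimate.
* **ELISA.** Absorbance is modeled as affine in the per-base
  modified-cytosine density of the well. Standards built at a different
  CG density than the sample genome bias the interpolated level by
  exactly the density ratio k; `elisa_quantify()` exposes both the raw
  and the k-corrected level, and the simulator/estimator pair inverts
  exactly in the noiseless case (a 50%-methylated genome read against
  five-fold-density standards returns 10% raw). The default curve is
  linear, matching two-point mixture standards; interpolation outside the
  standard range is flagged.

## Numerical and degenerate-input conventions

Internal coordinates are 0-based half-open; cytosine-report I/O converts
to and from the 1-based Bismark dialect. Context is assigned from the
strand's own 5'-to-3' neighborhood (minus-strand context from the reverse
complement); sites within 2 bp of a chromosome end get N-padded
trinucleotides and an undefined CH subclass is flagged rather than
guessed. Zero-depth sites are emitted by the simulator but excluded (with
counted reasons) from per-site estimates. Conversion probabilities are
clamped to \([0,1]\) against floating-point epsilon at simplex-boundary
sites. Degenerate ANOVA layouts (zero residual variance) are flagged and
report undefined p rather than Inf statistics.

## Known limitations

Single-site differential calling is out of scope (aggregation first, then
group statistics). No fC/caC chemistry. The read simulator's noise model
is limited to quality and ambiguity annotation, so filter behavior on
real base-caller error profiles is untested. The chrY truth uses the same
compartment targets as autosomes. ELISA saturation (4-parameter logistic
plates) is not simulated by default, though the quantifier flags
out-of-range absorbances.
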