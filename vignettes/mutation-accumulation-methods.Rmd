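---
title: "Estimating mutation rates and spectra from mutation-accumulation experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mutation rates and spectra from mutation-accumulation experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutacc)
library(dplyr)
```

## The experimental design this package analyses

A mutation-accumulation (MA) experiment propagates many replicate lines of
a (here, haploid) microbe through repeated single-cell bottlenecks. At an
effective population size near one, selection is essentially powerless, so
spontaneous mutations fix at the rate at which they arise. Whole-genome
sequencing of the terminal lines against the ancestral reference then
yields a nearly unbiased census of spontaneous mutation: for each line a
set of base substitutions and small (1–30 bp) insertions/deletions, a
callable-site mask describing where a mutation could have been detected,
and a generation count.

`mutacc` implements the downstream analysis of such an experiment for
AT-rich, microsatellite-dense genomes such as that of the social amoeba
*Dictyostelium discoideum* (~77% AT, ~14% of the genome in simple sequence
repeats), together with a forward simulator of the whole experiment so
that every estimator can be validated by parameter recovery.

## The estimators

**Per-line and experiment-wide rates.** The per-line base-substitution
rate is $\mu_{bs} = m/(nT)$, with $m$ the number of substitutions called
in the line, $n$ its callable sites and $T$ its generations. The
experiment-wide rate is the *unweighted mean* of per-line rates, with
$SE = sd/\sqrt{n_{lines}}$; this matches the per-line-then-average design
of MA studies, in which each line is one independent realisation of the
mutational process. The exposure-weighted pooled estimator
$\sum m_i / \sum n_i T_i$ is reported alongside; the two differ only when
$nT$ varies across lines and the choice is a design decision, not a fact
of the data.

**BCa bootstrap intervals.** Confidence intervals resample MA *lines*
with replacement (the line is the independent unit; resampling lines
resamples their $(m, n, T)$ triples jointly, so variation in callable
sites and generations is propagated). The bias-corrected and accelerated
interval uses $z_0 = \Phi^{-1}(\#\{\hat\theta^*_b < \hat\theta\}/B)$ and
the jackknife acceleration
$a = \sum d_i^3 / (6 (\sum d_i^2)^{3/2})$, $d_i = \bar\theta_{(\cdot)} -
\hat\theta_{(i)}$, with $B = 1000$ replicates by default. A degenerate
bootstrap distribution (all replicates identical, e.g. all lines equal)
falls back to the percentile interval with a warning. The implementation
is the package's own; in the test suite it is cross-checked against the
independent `boot` implementation on skewed data.

**Spectrum, conditional rates, equilibrium GC.** Substitutions are
tallied into the six strand-symmetric classes (A:T→G:C and G:C→A:T
transitions; A:T→C:G, A:T→T:A, G:C→T:A, G:C→C:G transversions); no
pyrimidine normalisation is needed because classes pair complementary
changes. Conditional rates divide the GC-changing classes by the summed
site-generations of the matching base pair:
$\mu_{A/T\to G/C} = (m_{AT\to GC\,ts} + m_{AT\to CG\,tv}) / \sum_i
n_{AT,i} T_i$, and symmetrically for $\mu_{G/C\to A/T}$. The
GC-conservative classes contribute to neither. Site-generations are
pooled across lines by default; a per-line-mean alternative is available
(`per_line = TRUE`) because the two conventions differ when coverage
varies, and published reports rarely say which was used. The GC content
at mutation equilibrium is
$\mu_{A/T \to G/C} / (\mu_{G/C\to A/T} + \mu_{A/T\to G/C})$ — the fixed
point a neutrally evolving sequence approaches under these two rates
alone — and the GC-direction bias is their ratio.

**Multinucleotide mutations (MNMs).** Mutations within 50 nt of each
other in a single line are unlikely to be independent events: under
uniform placement the chance that any pair among $m$ mutations falls
within $w$ bp of each other in $n$ callable sites is the birthday-type
approximation
$P = 1 - \prod_{k=1}^{m-1}(1 - 2wk/n)$,
which the package validates against a Monte-Carlo placement oracle (5%
relative agreement on grids with $P \gtrsim 10^{-2}$, where the MC error
itself is below 2% with the trial counts used; the formula is smooth in
its arguments so the desk-scale values at much smaller $P$ follow from
the same algebra). Clusters are found by single-linkage chaining of
sorted positions with gap ≤ 50 bp — so a chain's total span may exceed
the window; a `strict` mode caps the span instead. Indels participate
via their anchored position. Collapsing each cluster to one event reduces
per-line counts by exactly $\sum(\text{size}-1)$, and the package reports
the per-line event counts before and after collapse.

**Poisson goodness of fit.** If mutations arise independently, per-line
counts are Poisson. The test estimates $\hat\lambda$ as the mean count,
bins at $k = 0, 1, 2, \dots$, pools the right tail until every expected
bin holds at least one line, and uses $\chi^2 = \sum (O-E)^2/E$ with
$df = \text{bins} - 2$ (normalisation plus the estimated mean). The
binning convention is the package's own — published $\chi^2$ values for
this test depend on unstated binning, so exact reproduction is not a
goal; the type-I error of the binned test is verified by simulation to
sit near the nominal 5% (the acceptance suite requires 2–9% over 1000
Poisson experiments of 37 lines).

**SSR detection and slippage context.** The scanner reports every
maximal perfect tandem tract with unit length 1–10, at least 3 complete
copies and at least 8 bp of tract (all configurable; perfect repeats
only). Each tract is attributed to its smallest repeating period, the
motif is canonicalised to its lexicographically smallest rotation
(reverse complements are *not* folded — repeat context is strand-local
on the reference), and overlapping candidates are resolved greedily
left-to-right with ties broken toward longer tracts, then smaller units.
The scanner is required, by test, to agree exactly with a brute-force
enumeration oracle on hundreds of random sequences. A substitution is in
an SSR iff its position lies in a tract; an indel iff its anchored base
plus inserted/deleted span overlaps one. Homopolymer (unit length 1)
tracts carry a dedicated flag because A:T runs dominate slippage
mutation in AT-rich genomes. Enrichment of mutations in SSRs is tested
with a one-sided exact binomial against the callable SSR fraction; the
exact test is the package's default because published enrichment
p-values of this kind rarely name the test used.

**Functional effects.** Substitutions in CDS are classified by mutating
the codon in place (on the coding strand) and translating; indels in CDS
are flagged frameshift when their length is not a multiple of 3.
Deletions spanning a CDS boundary are classified by their anchored base
and flagged ambiguous. The neutral nonsynonymous/synonymous expectation
weights all nine single-base changes of every sense codon by codon usage
and by $\kappa = 2\,\mathrm{Ts/Tv}$ for transitions versus 1 per
transversion direction, so the implied pooled Ts/Tv equals the observed
input; changes creating stop codons count as nonsynonymous and stop
codons are excluded from usage. A full six-class spectrum weighting is
available as an option. The observed $(N, S)$ counts are compared to the
expected proportions $(R/(1+R), 1/(1+R))$ with a 1-df $\chi^2$. Note
that the standard 1-df computation applied to counts of (21, 4) against
$R = 3.32$ gives $\chi^2 \approx 1.64$, not the 0.88 sometimes printed
for that configuration; the package reports its own exact computation.

**Effective population size.** For haploids the expected nucleotide
diversity is $\theta = 2 N_e \mu$, so $\hat N_e = \theta / (2 \hat\mu)$,
with $\theta$ supplied (a published standing-heterozygosity estimate is
an input, not something re-estimated here). The CI for $N_e$ is the
monotone transform of $\mu$'s bootstrap CI (bounds swap); the report
records this provenance because error-propagation alternatives give
slightly different intervals.

## What the simulator emulates — and what it does not

`simulation_config()` defaults describe the study conditions the package
targets: a 1 Mb, 2-chromosome genome at 22.5% GC; 14.3% of sites in
planted SSR tracts with unit lengths drawn 1–10 biased toward 1, 3 and 6
bp and geometric copy numbers (mean 6, minimum 3); 62% of the genome in
non-overlapping protein-coding genes (ATG start, no internal stops,
length a multiple of 3, random strand); 37 lines at 81.3% callable
fraction; a transversion-biased, strongly G/C→A/T-biased six-class
spectrum; deletion-biased indels (81.8% deletions, matching a 4.5:1
deletion:insertion regime) with slippage indels inside SSRs at 3× the
background indel rate (the multiplier that turns a 14.3% SSR genome
fraction into roughly a third of indels falling in SSRs); and 12% of
substitution events arriving as MNM pairs within ±50 bp (reflecting 8 of
37 substitutions clustering into 4 events). Two of the six class weights
(A:T→T:A and G:C→C:G) are only jointly constrained by published totals;
the default 13/3 split allocates them roughly in proportion to A:T
versus G:C site availability in a 77% AT genome. Rates default to a
scaled-up regime (`mu_bs = 2.5e-6`, `mu_indel = 5e-6`, T = 20) so that a
1 Mb genome accumulates per-line counts of the same order as a real
34 Mb experiment over ~1500 generations; the estimators are
scale-consistent, so recovery at this scale exercises exactly the same
code paths.

Each substitution event first draws its six-class identity from the
spectrum weights and then lands on a uniformly chosen callable site of
the matching base pair, so realised class frequencies follow the weights
and per-site rates differ between A:T and G:C sites exactly as the
spectrum implies (a G/C→A/T-biased spectrum makes individual G/C sites
hotter in an AT-rich genome — the regime the defaults emulate, with an
implied equilibrium GC near 8%). MNM partner sites are constrained to
the ±50 bp window and draw their class conditionally on the local
reference base. Beyond this base-pair-level difference and the SSR
slippage multiplier there is no local rate heterogeneity, no sequencing
error, no coverage model, no read-level data and no selection during
propagation.
Slippage indels change copy number by exactly ±1 unit. Substitution
event intensity is thinned by $(1 + f_{MNM})$ so that the expected
substitution *count* per line equals $\mu_{bs}\,nT$: the configured rate
is the rate of called substitutions, which is what the raw-count
estimator measures. Collisions (a later event landing on an
already-mutated site) are resolved deterministically in favour of the
later event, with a warning; at realistic rates they are negligible.
Passing tests on these data therefore demonstrate estimator correctness
under the model's own assumptions — uniform placement, perfect calls,
known masks — and not robustness to alignment artefacts, false calls or
mutation-rate heterogeneity in real genomes.

## Numerical conventions and edge cases

- Coordinates: intervals are 0-based half-open (BED) internally; point
  positions are 1-based (VCF); GFF3 is 1-based inclusive. Indels are VCF
  left-anchored with one base of context.
- Multi-allelic VCF records are an error by default (haploid
  single-colony isolates should not produce them); splitting is opt-in.
- Complex records (REF and ALT both > 1 base, different lengths) are
  classified by net length change and flagged; same-length multi-base
  records are rejected.
- Indels over 30 bp and variants outside the callable mask are dropped
  with a logged count, mirroring the size window of the target study
  design.
- `ts_tv_ratio` with zero transversions returns `Inf` with a warning;
  `equilibrium_gc(0, 0)` is an error; `poisson_gof` needs ≥ 5 lines and
  returns `NA` statistics for all-zero counts.
- All simulation and bootstrap functions are pure functions of their
  seed: identical config + seed gives byte-identical FASTA/VCF/BED/GFF3
  output and identical intervals. JSON reports use sorted keys and are
  byte-stable across reruns.
- Problem sizes used by the test suite (chosen to keep the full run in
  minutes while leaving each check statistically sharp): 20 replicate
  recovery experiments at the default study scale against one fixed
  reference genome; 200 random 5 kb sequences for the SSR oracle; 1000
  replicates for the GOF type-I check; 200 experiments for BCa coverage;
  2–3×10^5 Monte-Carlo trials per MNM grid point.

## Known limitations

- The SSR scanner models perfect repeats only; imperfect or compound
  microsatellites are fragmented into their perfect cores.
- The MNM chance probability is an approximation that treats placements
  as independent and windows as non-wrapping; it is validated against
  Monte Carlo, not exact combinatorics.
- Poisson GOF binning (right-tail pooling at expected ≥ 1) is one of
  several defensible conventions; $\chi^2$ values are comparable only
  within a convention.
- The neutral NS/S expectation depends on the codon usage table
  supplied; with uniform usage it reduces to classical opportunity
  counting, and no organism-specific table ships with the package.
- Centromere/telomere exclusion and any other repeat masking are
  delegated entirely to the callable masks provided by the caller.
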