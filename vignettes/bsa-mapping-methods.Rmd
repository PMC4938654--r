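---
title: "Methods: BSA-seq mapping of a recessive locus with bsamap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BSA-seq mapping of a recessive locus with bsamap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The mapping design

bsamap targets a classical monogenic recessive mapping design.  A
mutation arises in an elite background (call the carrier parent MH86);
heterozygous carriers are crossed to a genetically distant cultivar
(93-11), and F1 plants heterozygous at the locus are selfed.  The F2
then segregates 3 normal : 1 mutant.  Two DNA bulks are formed — the
M-pool from 50 mutant plants and the N-pool from 50 phenotypically
normal plants — and sequenced at low coverage (~12x per pool) together
with the parents (~50x / ~30x).

At a marker tightly linked to the causal locus, every plant in the
M-pool is homozygous for the carrier haplotype, so the MH86-allele
frequency in the M-pool approaches 1.  Normal plants are 1/3 homozygous
wild type and 2/3 heterozygous, so the N-pool frequency approaches 1/3.
Far from the locus both pools sit near 1/2.  The mapping signal is the
difference of these pool frequencies.

# The CAAFD statistic

For a window of $n$ oriented markers the cubic average allele frequency
difference is

$$\mathrm{CAAFD} = \left\{ \frac{1}{n} \sum_{i=1}^{n}
  \left( \frac{m_{1i}}{m_{1i}+m_{2i}} - \frac{n_{1i}}{n_{1i}+n_{2i}}
  \right) \right\}^{3}$$

with $m_{1i}, m_{2i}$ the MH86/93-11 allele counts at marker $i$ in the
M-pool and $n_{1i}, n_{2i}$ the same in the N-pool.  The cube is applied
to the **window mean**, not per marker; `caafd()` implements exactly
that form and the test suite pins the distinction (a window with
per-marker differences 1 and 0 scores $0.5^3 = 0.125$, not $0.5$).
Cubing is order-preserving and sign-preserving; it suppresses the
near-zero background relative to the peak.  At an ideal peak the
expectation is $(1 - 1/3)^3 = 8/27 \approx 0.296$.  Antisymmetry under
pool swap and the $[-1, 1]$ bounds are enforced as property tests.

## Window conventions

The scan (`scan_genome()`, defaults 2000-kb window, 10-kb step) places
window centers on the step grid starting at 0 and spans
$[c - w/2,\, c + w/2)$ in 0-based half-open coordinates, truncating at
position 0 and at the observed marker extent; windows without markers
are omitted and there is no minimum marker count beyond 1.  Edge
handling is a package choice — windows at chromosome ends are truncated
rather than dropped — since nothing in the underlying method constrains
it.  The rolling cumulative-sum implementation is required by test to
match a naive per-window recomputation to $10^{-12}$.

`call_peak_region()` takes the window with maximal $|\mathrm{CAAFD}|$
(ties broken by genomic order, for determinism) and grows the region
over consecutive same-sign windows with magnitude at least
$\alpha = 0.5$ of the peak.  The $\alpha$ threshold is a package
invention — published profiles are typically delimited by eye — and is
exposed as a parameter.

# Marker selection

Raw four-sample variant calls become markers when (i) each parent has
depth $\ge$ 10 with $\ge$ 90% of reads on one allele and the parents'
majority alleles differ ("explicit polymorphism"; the thresholds are
package defaults chosen to tolerate ~1% base error at 30–50x parental
coverage), (ii) both pools have depth $\ge$ 4, and (iii) the mean of the
two pools' MH86-allele frequencies lies in the **closed** interval
$[0.3, 0.7]$.  "Allele frequency" is read as the MH86-allele frequency
— the orientation the CAAFD formula uses; because the interval is
symmetric about 0.5 the selected set is invariant under re-orienting
every marker, which the suite checks.  Note the causal region itself
passes the filter: its expected mean frequency is
$(1 + 1/3)/2 = 2/3 \le 0.7$.  Multi-allelic sites are excluded at parse
time.

# Selected-recessive fine mapping

Each phenotypically mutant F2 plant carries two mutation-bearing
gametes, so a panel of $N$ mutants exposes $G = 2N$ informative gametes
per marker.  With genotype counts A/H/B (homozygous MH86 /
heterozygous / homozygous 93-11), $R = H + 2B$ gametes are recombinant
and $\hat r = R/G$ is the binomial maximum-likelihood estimate, capped
at 0.5 defensively for imported data.  The LOD score is the base-10
binomial likelihood ratio against free recombination,
$R\log_{10}(\hat r/0.5) + (G-R)\log_{10}((1-\hat r)/0.5)$, with the
$R = 0$ term zero by convention, and map distances use the Kosambi
function $d = 25\ln\{(1+2r)/(1-2r)\}$ cM with the closed-form inverse
$r = \tfrac12\tanh(d/50)$ (round-trip accurate to $10^{-12}$ by test).

`delimit_interval()` performs two-point analysis against the trait
locus only: marker order is taken from the physical map, the block of
markers with the fewest recombinants (ideally zero — complete
cosegregation) is located, and the innermost recombinant-bearing
markers bracketing it delimit the interval.  Multipoint likelihood
ordering is deliberately out of scope: in this design the marker order
is known, and the trait-bracketing logic is what narrows the interval.
A side with no recombinant marker is flagged open rather than clipped.

# Candidate screening

Within the mapped interval the causal variant must show a unique
presence pattern: mutant allele only in the M-pool, **both** alleles in
the N-pool (a mixture of +/+ and -/+ plants), and wild type only in
both parents — the mutation postdates both parental genomes.  An allele
is "present" when it has $\ge$ 2 supporting reads and $>$ 5% of the
group's reads; both thresholds are package parameters (the underlying
method states only the qualitative pattern).  Groups with no allele
passing are reported as `no_data` and such variants are routed to an
`undetermined` list instead of being rejected: at ~12x pool depth the
N-pool "both alleles" call fails stochastically (the minor allele has
expectation 4 reads, and $P[\mathrm{Binom}(12, 1/3) < 2] \approx 5\%$),
which is why the packaged screening fixtures model the interval screen
as consensus-level — 50x counts without read error, as if read from
assembled sequences — unlike the genome-wide scan, which keeps the raw
low-coverage error model.  With raw reads instead, a handful of error
reads in a deeply sequenced parent can exceed the 5% contamination
threshold and spuriously mask the causal pattern (probability a few
percent per site at 1% base error), which is a read-level artefact the
consensus comparison does not have.  `cosegregation_test()` then checks strict
genotype–phenotype concordance in an independent F2 sample.

# Segregation statistics

`segregation_chisq()` tests two observed phenotype counts against a
ratio (default 3:1) with one degree of freedom.  The Yates continuity
correction is on by default —
$\sum \max(|O - E| - 0.5,\, 0)^2 / E$, clamped at zero — and the
uncorrected Pearson statistic is always reported alongside, because for
classical F2 counts in the few-hundreds both appear in the literature
and the corrected form is the conservative convention for 1-df tests.
`cross_summary()` averages per-panicle seed-setting rates (sample SD,
$n-1$) rather than pooling spikelet counts, reporting the pooled rate
separately; a single panicle yields SD 0 with an explicit flag.

# The synthetic data generator

`simulate_f2_population()` builds each plant from two independent
gametes of a genome-wide heterozygous F1.  Crossovers follow a
no-interference model: along the evaluation grid the gamete is a
two-state Markov chain whose switch probability between adjacent
positions is the Haldane recombination fraction of their genetic
distance.  This is the exact finite-dimensional marginal of a
Poisson-count, uniform-position crossover process, and it vectorises
over all gametes at once.  A single genome-wide scale (default 1 cM =
250 kb, a rice-typical order of magnitude) converts physical to genetic
distance.  The evaluation grid is the regular marker grid plus the
causal position, so the causal genotype is exact; the mutation rides
the MH86 haplotype genome-wide, which fixes the CAAFD sign convention
(positive at the peak).

Sequencing is modelled as independent allele draws: per marker and
pool, depth is Poisson (default 12x; parents 50x/30x), each read
samples one of the bulk's $2 \times 50$ haplotypes uniformly and
reports it correctly with probability $1 -$ `base_error` (default
0.01).  There are no read pairs, no mapping bias, no InDel realignment
artefacts, no depth overdispersion beyond Poisson, and no
linkage-disequilibrium structure beyond the cross itself — allele
counts are the pipeline contract, and alignment/calling are upstream of
it.  Phenotyping error (default 0) flips labels before bulking.  The
N-pool is drawn uniformly from the normal class; how normal plants were
chosen for bulking in real experiments is generally unstated, so random
sampling is the default and the bulk is an explicit argument.  A truth
sidecar with exact bulk frequencies is always produced for
parameter-recovery tests.

Passing tests on these simulations therefore show that the statistics
recover what this idealised model plants; they do not certify
robustness to alignment artefacts, reference bias, segregation
distortion, or mis-scored phenotypes beyond the simple flip model.

# Problem sizes and test-design choices

The packaged checks use desk-scale versions of the design:

* **Peak recovery**: the default config — 5 chromosomes of 30 Mb,
  markers every 5 kb (~30,000 genome-wide), bulks 50/50 at 12x with 1%
  base error, causal locus at chr4:25 Mb — over 10 seeds, requiring the
  top window within 1 Mb of the truth in at least 9.
* **Ideal-case magnitude**: one 30-Mb chromosome at 200x pools with no
  base error, mean peak CAAFD over 20 seeds within $8/27 \pm 0.03$.
  This check uses a 400-kb window: a window's genetic half-width is
  then 0.8 cM, so the closed-form within-window attenuation of the mean
  difference ($\int e^{-2d}$ over the window, about 3%) is negligible,
  while the sharply peaked profile keeps the global maximum at the
  causal window.  With wide windows the statistic is attenuated by
  linkage itself (about 12% at 2 Mb under the default scale), and on a
  near-flat profile the maximum over thousands of windows rides noise
  excursions upward; the narrow-window fixture isolates the statistic
  from both effects.
* **Fine mapping**: 200 panels of 199 mutants, one marker 4 cM from the
  locus, mean $\hat r$ within 3 SE of the Haldane truth.
* **Candidate screen**: the causal variant implanted among 500
  background variants (parental polymorphisms, carrier-private
  variants, and noise sites), unique recovery required in 10/10 seeds
  at consensus-level 50x screening counts; a 280-plant error-free
  cosegregation panel must be concordant.

These sizes keep a full test run around a minute while leaving the
statistical bands (3 SD / 3 SE) untouched.

# Numerical and degenerate-input choices

Zero-depth markers are flagged unusable upstream and never reach the
scan.  Empty windows are omitted, an empty scan is an error for peak
calling, all-zero genotype counts are an error for $\hat r$, and
$r \ge 0.5$ is an error for `kosambi()` (infinite distance) while the
per-marker table reports `Inf`.  Ties at the peak break to the smallest
genomic coordinate.  Pipeline randomness derives from one global seed
split into per-stage seeds, so a rerun with the same config is
byte-identical; file coordinate conventions (1-based TSV/VCF, 0-based
half-open BED/bedGraph) are stated in each file's header line.

# Known limitations

* Two-point linkage only; no multipoint ordering or interference model
  (the Kosambi function is used purely as a distance transform).
* No smoothing of the window profile and no permutation-based
  significance envelope; the region call is threshold-based.
* The simulator's uniform cM/bp scale ignores recombination hot/cold
  spots, and its Poisson depth ignores overdispersion common in real
  libraries.
* The candidate screen operates per variant call; it cannot recover a
  causal variant that the upstream caller missed entirely.
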