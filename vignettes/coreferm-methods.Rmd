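---
title: "Modeling the porcine fecal core microbiota as a pH-limited Monod chemostat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the porcine fecal core microbiota as a pH-limited Monod chemostat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coreferm)
```

## The model

`coreferm` simulates a continuous anaerobic fermentation (a chemostat) of
the pig fecal core microbiota: 16 core genera plus an aggregate group
`others` representing the rest of the community, growing on four bulk
resource pools (resistant starch, non-starch polysaccharides, protein,
simple sugars) and producing thirteen metabolites, some of which — lactate,
succinate, hydrogen, carbon dioxide, acetate — are themselves consumed by
other groups (cross-feeding). The baseline state vector therefore has
34 components: 17 microbial biomasses, 4 resources and 13 metabolites, all
in g/L.

Each group carries one or more fermentation *pathways*. A pathway couples
resources to products through molar stoichiometry (molar mass $m_k$ and
molecule count $n_k$ per entry) and Monod kinetics. Pathway entries are
classified as essential (`Se`), substitutable (`S`), water (`Sw`), boosting
(`Sb`) or product (`P`). The pathway growth rate is

$$\mu_{ji} = \mu_{\max,ji}\,\lambda(\mathrm{pH})\; G_{ji}\; b_{ji},$$

where $\lambda$ is the trapezoidal pH limitation defined by four ascending
"pH corners" (zero growth at or beyond the outer pair, maximal growth
between the inner pair, linear shoulders), $G_{ji}$ combines the Monod
terms $S/(K+S)$ of the growth resources, and $b_{ji}$ is the boosting
multiplier. The combination rules are:

* essential resources combine by the minimum of their Monod terms
  (Liebig's law of the minimum);
* substitutable resources contribute Monod terms weighted by their share
  of the total substitutable substrate mass, so that a vanishing pool
  contributes nothing and all-zero pools give rate 0 rather than 0/0;
* when both classes are present the essential minimum multiplies the
  substitutable sum;
* each boosting resource multiplies the rate by $1 + S_b/(K_b+S_b)$, which
  is 1 in the absence of the booster and at most 2 at saturation. We
  rejected a $(1+S/(K+S))/2$ normalization because it would halve the rate
  when the booster is absent, contradicting the requirement that a missing
  booster leaves the pathway rate unchanged.

Uptake follows from growth through the yield $Y$ (g biomass per g
resource): every essential resource is consumed at $U = \mu_{ji}/Y$, and
substitutable resources split $\mu_{ji}/Y$ in proportion to their
contribution to the weighted Monod sum. Water uptake is stoichiometric:
$U_w = (m_w n_w / \sum_i m_i n_i)\sum_i U_i$ over the growth resources of
the pathway. Production then distributes the leftover mass flux over the
products by their $m_z n_z$ shares:

$$M_{jz} = \frac{m_z n_z}{\sum_k m_k n_k}
  \Big(\sum_i U_{ji} + U_{jw} - \mu_{ji}\Big),$$

so that $\sum_z M_{jz} + \mu_j = \sum_i U_{ji} + U_{jw}$ holds identically
— mass entering a cell either becomes biomass or leaves as product. The
property suite verifies this balance to a relative $10^{-9}$ over
thousands of randomized parameter sets, and a closed ($D = 0$) simulation
with a tracked water pool conserves total system mass to solver precision.

Because yields are at most 1 and water closes the balance, the residual in
the production rule is never negative. Water and boosting entries carry no
yield: water consumption is purely stoichiometric, and boosting resources
are catalytic (they raise the rate without being consumed). When the
species registry does not track a water pool, water is drawn from an
implicit, unlimited reservoir — the registry can include `water` when a
closed mass budget is wanted.

The chemostat couples the strains through

$$\dot B_j = B_j(\mu_j - D) + D\,B_{\mathrm{in},j}, \qquad
  \dot S = D(S_{\mathrm{in}} - S) - \sum_j U_j B_j + \sum_j M_j B_j,$$

with one balance per chemical species, so a metabolite consumed by a
cross-feeder needs no special casing. The dilution rate is the reciprocal
of the retention time; the experimental 9 h retention gives
$D = 0.111\ \mathrm{h^{-1}}$.

## Strains

Intra-group variability is modeled by drawing strains around each group:
`mu_max` and every half-saturation constant are scaled by independent
uniform factors in $[1-v, 1+v]$ and the inner pH corners are shifted by up
to $\pm v$ pH units, redrawing any proposal that violates the corner
ordering. The default variability is $v = 0.1$; the nearly-in-vivo preset
uses two strains per group (34 microbial states). Group-level outputs are
the sums of their strains, which the suite checks at every time point.
Strain draws are seeded, so identical (scenario, community, seed) triples
reproduce trajectories bit for bit.

## Scenario presets and parameters that matter

`build_scenario()` returns the study conditions: dilution rate
0.111 h⁻¹; medium with resistant starch 4.32, NSP 7, protein 15 and sugars
2 g/L; all metabolites starting at 0 g/L (no production without growth);
35 simulated days with hourly output. pH is fixed at 6.4, the midpoint of
the experimental 6.0–6.8 band; a time schedule can be supplied instead,
and we treat fixed pH as the default because the controller held the
vessel inside a narrow band. Initial community biomass defaults to
$10^{12.7}$ bacteria/L at $4.6\times10^{-12}$ g per cell — chosen so the
aggregate `others` group starts near its observed ~12.5 pseudo-log10
level — partitioned by the fecal-inoculum relative abundances. The
nearly-in-vivo preset adds a continuous microbial inflow at 10% of each
group's initial concentration; the study states that groups flow in
continuously but not at what level, so the 10% default is our choice and
is configurable. The 234 mL vessel volume does not enter the
concentration-based equations and is carried as metadata only.

`apply_synbiotic()` implements interventions: boosted resources scale
their inflow concentration (5× resistant starch: 4.32 → 21.6 g/L), boosted
microbes have initial concentration and continuous inflow set to
fold-change × baseline (20× Lactobacillus from 0.1365 g/L gives
2.73 g/L). A fold-change of exactly 1 is a no-op, so an all-ones boost map
is the identity.

Integration uses a stiff solver (`deSolve::lsoda`) at relative tolerance
$10^{-8}$ and absolute tolerance $10^{-10}$; cross-feeding pools such as
lactate sit many orders below the bulk resources, which makes the system
stiff. States are clipped of numerical dust below $10^{-15}$ g/L, and an
excursion below $-100\times$ the absolute tolerance aborts with a pointer
to tighter tolerances rather than silently flooring.

## The fixture community

The per-genus kinetic tables of the original study (culture-derived
$\mu_{\max}$, $K$, $Y$ and stoichiometries for representative species) are
not available, so the package ships a **synthetic** parameter library,
built to reproduce the community ecology the study reports rather than its
exact numbers. The design principles:

* saccharolytic yields anchor at 0.333 g/g; maximum growth rates lie in
  0.1–1.5 h⁻¹; half-saturation constants start from the 0.001 g/L default
  and stay within biologically compatible ranges;
* the five genera reported to maintain growth in the bioreactor —
  Prevotella, Megasphaera, Succinivibrio, Blautia, Ruminococcus — plus
  `others` each hold a distinct niche: NSP, lactate, sugars, H₂+CO₂,
  resistant starch and protein respectively. In a chemostat, coexistence
  requires such niche separation (the competitive-exclusion principle),
  and each persister is the strongest competitor (lowest subsistence
  concentration $K D/(\mu_{\max}\lambda - D)$) on its substrate;
* the remaining eleven genera are competitive losers or have
  $\mu_{\max}\lambda$ near or below $D$, so they wash out over days — the
  fate the study reports for its fastidious genera. Phascolarctobacterium,
  a succinate consumer, is tuned just below persistence so it declines
  slowly over the whole run, mirroring its reported trajectory;
* `others` carries ten pathways representing the metabolic functional
  groups of the non-core microbiota (proteolysis, polysaccharide
  degradation, lactate-producing fermentation, lactate-to-butyrate
  conversion, succinate-to-propionate conversion, methanogenesis,
  homoacetogenesis, butyrogenesis, ethanol fermentation). Its
  cross-feeding pathways use deliberately high half-saturation constants
  so that the subsidized generalist does not competitively exclude the
  specialist core genera from their niches;
* lactate is produced continuously (by `others`' lactate-producing
  pathway, and transiently by Streptococcus and Lactobacillus before they
  wash out) and scavenged by Megasphaera, whose small lactate K pins the
  pool orders of magnitude below the 0.1 mM detection limit — the
  undetected-lactate behavior observed both in vitro and in silico.

With these parameters the baseline 35-day run settles well before day 35
(all derivatives fall below $10^{-6}$ g/L/h by about day 27), with the
persister set above at 10–12 pseudo-log10 bacteria/L and an
acetate-dominated SCFA profile. Since the kinetic values are synthetic,
the study's printed steady-state concentrations are not reproduced
quantitatively, and nothing in the test suite asserts that they are; the
fixtures are validated against structural, qualitative and arithmetic
properties instead.

## Observation model and evaluation

Model output converts to observation units as the measurement pipeline
would produce them: metabolites to mM via $c \cdot 1000 / m$; biomass to
bacteria/L at $4.6\times10^{-12}$ g per cell and then to pseudo-log10,
with every value at or below 1 bacterium/L reported as 0. Comparisons
(`compare()`) interpolate the model linearly to the observation times —
the pairing rule is our choice, as the study does not state one — and
floor modeled metabolites below 0.1 mM and abundances below 1 bacterium/L
to 0, mimicking the GC-MS and qPCR detection limits; this is what makes
"undetected in both" score an RMSE of exactly 0 mM with an undefined
RMSE%. Per variable we report RMSE, RMSE% (100 × RMSE / observation mean,
missing when the mean is 0) and the two-sided t-test p-value of the slope
from regressing modeled on observed values, without multiple-testing
correction. Across-reactor spreads use the sample (n−1) standard
deviation.

The synthetic observation generator applies multiplicative lognormal noise
to bacteria/L (σ = 0.15, about 0.065 log10 units) and additive Gaussian
noise to metabolite mM (σ = 2 mM), then the same detection truncation.
These defaults emulate the visual scatter of the reported early
fluctuations and are documented as synthetic; sigma 0 reproduces the truth
exactly. The default sampling schedule is dense early and sparse late
(0 and 8 h, then days 1–35), approximating the reported sampling pattern.
What passing tests show about real data is therefore limited: the
generator reproduces the derived quantities and their error structure, not
sequencing reads, chromatograms, compositional biases or temporal
autocorrelation of a live reactor.

## Calibrating half-saturation constants

`calibrate_K()` formalizes the study's empirical tuning loop: all group K
values start at 0.001 g/L and a seeded search proposes per-group values
within (10⁻⁴, 10⁻²) g/L — the biologically compatible band around the
starting default — scoring each proposal by the unweighted sum of
per-variable RMSEs on the observation scales (the study tuned
"empirically" with no stated objective; the unweighted sum is our choice).
The search cycles three proposal kinds: full-range log-uniform draws for
one coordinate, refinement draws from a 0.3-decade window around the
incumbent, and joint refinement moves of all coordinates. The joint moves
matter because cross-feeding couples the K values — a pure coordinate
descent can stall at points where no single-coordinate move improves the
fit although a correlated move does. A proposal is accepted only when it
improves the score by more than a relative $10^{-3}$: below that threshold
score differences are interpolation and solver noise, and accepting them
lets the search drift along directions the data do not constrain.

Identifiability shaped the benchmark world (`benchmark_truth()`) used to
validate the loop. In a substrate-rich, fast-growing chemostat, jointly
rescaling all K values leaves every observable trajectory unchanged —
substrate saturates except during a minutes-long depletion window, and the
steady-state substrate concentrations that do scale with K sit far below
the detection limits — so absolute K recovery is impossible in principle.
The benchmark is therefore oligotrophic and slow-growing (inflow sugars
0.05 g/L and NSP 0.08 g/L; resource consumers with $\mu_{\max}$ not far
above $D$): the Monod deficit $K/(K+S)$ then stays at the percent level
throughout a long washin and compounds into a clearly visible, two-sided
imprint on the pseudo-log10 growth curves, while the lactate converter's K
is anchored by the lactate pool itself. On this world the acceptance suite
recovers each true K within a factor of two from noise-free observations
(budget 500) and with zero median log-K bias across 20 noisy repetitions.

## Numerical and design choices, in brief

* Time grid: hourly output by default; the closed-form chemostat oracle
  integrates 4000 h to reach steady state within $10^{-4}$ relative.
* Tie-breaks: all substitutable pools at zero give pathway rate 0; an
  empty booster gives multiplier 1; proposals in the strain perturbation
  that violate corner ordering are redrawn, never emitted.
* The parameter-frame CSV layout has one column per chemical species plus
  bookkeeping columns; resource molecule counts live in `numMolecules`,
  product counts in `stoichiomProduct`, and scalar rows (maximum growth
  rate, pH corners) repeat their value across the pathway's species
  columns. Writes are deterministic, so identical specifications yield
  byte-identical files.
* Problem sizes in the test suite — 1000 conservation triples, a 20-point
  closed-form sweep, calibration budgets of 500 (noise-free) and 120 × 20
  seeds (noisy), full 35-day runs of the 34- and 51-state presets — were
  chosen as the smallest sizes at which the properties are sharply
  resolved.

## Known limitations

* The kinetic fixture library is synthetic; per-genus quantitative
  agreement with the original bioreactor is out of reach without the
  culture-derived parameter tables, and the package does not claim it.
* No host physiology: no SCFA absorption, immune interaction, spatial
  structure or compartmentalized gut geometry; the inflow medium is a
  boundary condition, not a digesta model.
* Yields are inputs; there is no thermodynamic or ATP-based yield
  derivation.
* Half-saturation constants of resource consumers are identifiable from
  community time series only when substrate concentrations pass through
  the K scale slowly (see the calibration section); calibrating a
  substrate-rich world will recover K ratios at best.
* pH feedback from fermentation acids on the medium is not modeled; pH is
  an input (fixed or scheduled).
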