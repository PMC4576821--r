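---
title: "Models and methods behind nucleoperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nucleoperm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoperm)
```

# The scientific setting

Chymotrypsin-like proteases cleave their substrate by covalent nucleophilic
catalysis: a triad-activated serine or cysteine attacks the scissile
carbonyl, the C-terminal product leaves, and the resulting acyl--enzyme
intermediate is hydrolysed to regenerate free enzyme. Swapping the
nucleophile (Cys to Ser or back) typically costs about four orders of
magnitude in activity, yet both nucleophiles occur within one structural
superfamily — so nucleophile switches must be evolutionarily accessible.
Handicap-recover experiments probe this directly: cripple the enzyme by
mutating its nucleophile, then let directed evolution recover activity and
ask where the compensatory mutations land and what they cost the original
nucleophile.

`nucleoperm` packages the quantitative machinery such a campaign needs:

* a mechanistic and a phenomenological model of the progress curves,
  with multi-start fitting and formal mono-vs-biphasic model selection;
* distance-shell classification of mutations around the catalytic triad
  in a PDB structure, with a permutation test for shell enrichment;
* trajectory statistics — per-round fold changes, trade-off ratios,
  neutrality calls, percent identity bookkeeping;
* a fully seeded synthetic-data module that emulates the screening
  campaign so every stage is testable end-to-end without external data.

# Kinetic models

## The mechanistic scheme

`simulate_full_scheme()` integrates mass-action kinetics for

$$E + S \underset{k_{\mathrm{off}}}{\overset{k_{\mathrm{on}}}{\rightleftharpoons}}
ES \xrightarrow{k_{\mathrm{acyl}}} EA + P_C \xrightarrow{k_{\mathrm{deacyl}}} E + P_N$$

with `deSolve::lsoda` at tolerances of `1e-12`, which holds the enzyme and
substrate mass balances to better than `1e-9` relative at every reported
time. The reported signal is the cleaved-substrate concentration
$S_0 - [S] - [ES]$: the FRET pair is destroyed at the acylation step, when
the C-terminal product is ejected, so the acyl-enzyme already counts as
signal. Units are minutes and micromolar throughout; conversions happen
only at I/O boundaries.

In the pseudo-first-order limit ($S_0 \ll E_0$, binding pre-equilibrated,
i.e. $k_{\mathrm{on}}E_0 \ll k_{\mathrm{off}}$ and
$k_{\mathrm{acyl}} \ll k_{\mathrm{off}}$) the simulated curve collapses to
the single exponential $S_0(1 - e^{-kt})$ with
$k = k_{\mathrm{acyl}} k_{\mathrm{on}} E_0 / k_{\mathrm{off}}$; the test
suite checks agreement to better than $10^{-3}$ relative. The scheme is
used for simulation and limiting behaviour only — the package never
estimates individual binding constants from data.

## The phenomenological fits

Observed traces are fitted with the closed forms

* monophasic: $y(t) = c + A\,(1 - e^{-k_{\mathrm{obs}}t})$
* biphasic (burst): $y(t) = c + A_1(1 - e^{-k_{\mathrm{obs1}}t})
  + A_2(1 - e^{-k_{\mathrm{obs2}}t})$

A biphasic curve with a fast phase and large $A_1$ is the signature of
rate-limiting breakdown of an acyl-enzyme intermediate; $A_1$ is the burst
amplitude. Fitting is bounded Levenberg--Marquardt (`minpack.lm::nls.lm`)
with multi-start initial values: rates log-uniform over
$[10^{-4}, 10^{2}]\ \mathrm{min}^{-1}$, amplitudes and offset seeded from
the data, 20 starts by default, a mandatory seed, and best-of-starts
selection. After every biphasic fit the labels are canonicalised so
$k_{\mathrm{obs1}} \ge k_{\mathrm{obs2}}$. An amplitude below three times
the residual noise estimate flags its rate as unidentifiable instead of
reporting a meaningless number.

Model selection uses the extra-sum-of-squares F-test between the nested
fits at $\alpha = 0.05$ (biphasic accepted iff $p < \alpha$; equal or
worse biphasic residuals fall back to the monophasic model by parsimony),
with small-sample AICc reported alongside for transparency.

Observed rates become second-order constants by dividing by the **total**
enzyme concentration in molar (`to_second_order()`): under the equimolar
1 µM assay, $k_{\mathrm{obs}} = 0.007\ \mathrm{min}^{-1}$ maps to
$7\times10^{3}\ \mathrm{min^{-1}M^{-1}}$. Dividing by total rather than
free or active enzyme is a declared convention; burst amplitudes are
reported but not used for active-site titration.

## Observation design

Parameter-recovery simulations span slow-phase second-order constants
from $10^3$ to $10^6\ \mathrm{min^{-1}M^{-1}}$ — four decades, the scale
of a nucleophile handicap — at 2 % noise with 60 time points. The grid
samples each phase on its own timescale: 20 points over five fast-phase
lifetimes and 40 points over five slow-phase lifetimes. This is the
standard burst-resolving design; with a single uniform window the fast
phase falls between the first two samples and its rate is only marginally
identified. Under this design the 50-seed median of every parameter is
recovered to a few percent.

# The synthetic campaign

The generator emulates the screening campaign's statistical structure:

* **Libraries.** Mutations per gene are Poisson with mean 1.3 (the
  campaign's reported mean; its ±0.4 most plausibly describes
  round-to-round variation of the mean, not the within-library SD, which
  for a Poisson is ≈1.14). Positions are uniform over a 237-residue gene;
  substitutions are uniform over the 19 alternatives.
* **Revertant exclusion.** Mutations that would restore position 151 to
  the ancestral cysteine are resampled, forcing the forward pathway, as
  revertants were discarded during the real screen.
* **Selection.** Each of 10 rounds screens 350 variants by a noisy
  read-out of the serine-background activity (0.2 log10 units of noise by
  default; an endpoint-fluorescence read-out mode is also available since
  the real screen's ranking statistic is not recorded) and carries the
  single best variant forward.
* **Effects.** Each mutation shifts both latent log10 activities by a
  draw from a mixture — 70 % deleterious/neutral $N(-0.3, 0.3)$, 30 %
  beneficial Exponential(mean 0.3) — with the serine and cysteine
  backgrounds coupled through a Gaussian copula at $\rho = 0.9$. The
  marginal quantile function is inverted on a 4096-point grid.
* **Parents.** The default calibration places the handicapped parent at
  $\log_{10}k_2 = 0.4$ (serine background; $10^{0.4} \approx 2.3$,
  consistent with a $7\times10^3$ endpoint after a $3\times10^3$-fold
  recovery) and the ancestral cysteine enzyme at $4.0$ — the scale of a
  campaign that starts four decades down and recovers to wild-type-like
  activity.

What the generator does **not** emulate: nucleotide-level error-prone PCR
bias, codon structure, protein-stability biophysics, expression/solubility
as a separate fitness axis (it is folded into the read-out noise), and
diminishing-returns epistasis — effects are additive on the log scale, so
long simulated campaigns overshoot the ~3.5-decade recovery a real
campaign shows. Passing tests therefore demonstrate correctness of the
machinery under a plausible generative model, not biological realism of
any particular trajectory.

The toy-structure generator plants one C-alpha pseudo-atom per residue at
controlled minimal distances from a three-residue triad, along random
directions in the octant opposite the non-origin triad atoms, so the
planted distance is provably the minimal distance; shells then contain
exactly the requested residue counts. Planted distances keep a 0.2 Å
margin from shell boundaries so the 3-decimal PDB coordinate precision
cannot flip an assignment.

# Shell analysis

Distances are minimal heavy-atom distances between all atoms of the query
residue and all atoms of any triad residue — the most common convention;
Cα–Cα or side-chain-only alternatives would need only a different atom
filter. Shells are half-open bands $[0,4)$, $[4,8)$, $[8,12)$,
$[12,\infty)$ Å so each distance maps to exactly one shell (printed "4–8 Å"
ranges do not specify endpoint handling; the half-open choice is declared
here and in output metadata). The triad is always user-specified, or
extracted from PDB SITE records when present — never hard-coded, since
only the nucleophile position (151) is common knowledge for this system.

Enrichment is tested against uniform placement of the observed number of
distinct mutated positions over an eligible set (by default all residues
of the chain minus the triad): the p-value is the upper-tail fraction of
seeded Monte-Carlo draws with at least the observed in-shell count, with
the $(1+x)/(1+n)$ correction. On small instances this must and does agree
with the exact hypergeometric tail within Monte-Carlo error; truncation
mutations are excluded because they are not placeable residues (the
point/truncation distinction is kept by `count_mutations()`).

# Trajectory statistics

`fold_change()` is the orientation-normalised ratio
$\max(a,b)/\min(a,b)$, reported to two significant figures — the
convention under which the evolved serine and reverted cysteine twins
($7\times10^3$ vs $3\times10^3\ \mathrm{min^{-1}M^{-1}}$) differ by
2.3-fold. `tradeoff_report()` measures neutrality of the cysteine path as
the worst per-round fold deviation from the reference round (default
round 0) against a fourfold threshold, and reports the endpoint twin
ratio. When a variant is biphasic, the slow-phase constant is the default
cross-variant activity measure (the rate-limiting step), configurable.

Percent identity uses direct positional mapping with the C-terminal
overhang of the longer sequence counted as mismatch — exactly right for
point mutants and truncations of a known parent, where no gap placement
search is needed (18 substitutions on 237 residues give
$219/237 = 92.4\ \%$); a Needleman–Wunsch mode via `Biostrings` is
provided for unrelated pairs. `apply_mutations()` refuses to apply a
mutation whose recorded parental residue disagrees with the sequence,
which catches off-by-one numbering early.

# Pipeline and reproducibility

`run_pipeline()` chains simulate → fit → trajectory → shells from a single
config (R list or YAML), writes only plain-text outputs (CSV, JSON, PDB,
FASTA), and emits a manifest carrying the seed, all parameters, the
package version and md5 checksums of every output. Unknown config keys are
rejected. Every stochastic component in the package takes an explicit
seed and is a pure function of (parameters, seed); re-running an identical
config reproduces byte-identical outputs, with only the manifest
timestamp differing. A failing stage renames its partial outputs to
`*.partial` and aborts naming the stage.

## Problem sizes used in the shipped checks

The package's own test and acceptance runs use: 50 seeds per recovery
setting across four activity decades; 100 seeds per model-selection arm
(10 multi-starts there, 20 for recovery fits); $10^4$ variants for the
Poisson goodness-of-fit; one full default campaign (10 rounds × 350
variants); and $10^5$ permutations against the exact hypergeometric
oracle. These sizes give Monte-Carlo errors comfortably below the margins
they are checked against.

# Known limitations

* The biphasic fit is phenomenological; whether the slow phase under
  equimolar single-turnover-like conditions is strictly deacylation or a
  mixture of processes is not resolved, and no attempt is made to map
  observed rates back onto microscopic constants.
* Second-order constants from different fit types (slow-phase constants
  vs monophasic kcat/KM) are compared directly across variants and
  backgrounds; the commensurability is a modelling choice.
* No inner-filter, photobleaching, pH or temperature corrections; no
  global fitting across variants.
* The effect-distribution defaults are a qualitative emulation; campaign
  statistics derived from them (e.g. the probability of a neutral
  cysteine path) are calibration read-outs, not biological estimates.
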