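# nucleoperm

Quantitative analysis of **handicap-recover directed evolution** in
covalent proteases: what happens when you swap the catalytic nucleophile
of a chymotrypsin-like protease (Cys ↔ Ser), cripple the enzyme by ~10⁴,
and evolve the activity back?

The package is for protein engineers and enzymologists running (or
re-analysing) such campaigns. It provides:

* **Burst kinetics.** Simulation of the two-step covalent mechanism
  E + S ⇌ ES → EA + P_C → E + P_N (acylation destroys the FRET pair;
  deacylation regenerates enzyme), and multi-start bounded least-squares
  fitting of progress curves with the closed forms

  * monophasic: *y(t) = c + A(1 − e^(−k_obs t))*
  * biphasic (burst): *y(t) = c + A₁(1 − e^(−k_obs1 t)) + A₂(1 − e^(−k_obs2 t))*,
    with k_obs1 ≥ k_obs2 by convention,

  plus extra-sum-of-squares F-test model selection and conversion of
  observed rates to second-order constants k_obs/[E]₀ (min⁻¹ M⁻¹).
* **Shell enrichment.** Minimal heavy-atom distances from each mutated
  residue to the catalytic triad of a PDB structure, classification into
  half-open shells (<4, 4–8, 8–12, ≥12 Å), and a seeded permutation test
  for enrichment of mutations in a target shell against uniform random
  placement.
* **Trajectory statistics.** Per-round fold improvements, nucleophile
  trade-off ratios with a fourfold neutrality threshold, endpoint twin
  ratios, percent identity and mutation bookkeeping.
* **Synthetic data.** A seeded generator for everything above: noisy
  traces, error-prone PCR libraries (Poisson mutations, mean 1.3 per
  gene), 10-round best-of-350 selection with nucleophile-revertant
  exclusion at position 151, and toy structures with planted shell
  geometry.
* **Pipeline.** `run_pipeline()` chains simulate → fit → trajectory →
  shells from one YAML/list config with a checksummed manifest;
  `inst/scripts/nucleoperm-cli.R` is a thin command-line wrapper.

## Worked example

Fit a noisy burst trace recorded under the equimolar 1 µM assay and
convert to second-order constants:

```r
library(nucleoperm)

tr <- generate_trace(list(A1 = 0.4, kobs1 = 2, A2 = 0.6, kobs2 = 0.05),
                     cond = assay_conditions(E0 = 1, S0 = 1),
                     n_points = 60, t_max = 100, noise_sd = 0.02, seed = 1)
sel <- select_model(tr, alpha = 0.05, n_starts = 10, seed = 1)
sel$model
#> [1] "biphasic"        # F-test p = 1.26e-24 against the monophasic fit
sel$fit_bi
#> phase_fit (biphasic): A1 = 0.4211, kobs1 = 1.811 | A2 = 0.5936,
#>   kobs2 = 0.04959 min^-1, offset = -0.01248
#>   R^2 = 0.99148, SS = 0.01697, n = 60

variant_kinetics(sel, E0_uM = 1, variant_id = "evolved")
#> k2_obs1 = 1.81e+06, k2_obs2 = 4.96e+04 min^-1 M^-1
```

The fast phase (k_obs1, burst amplitude A₁) reports on acylation of the
enzyme present at mixing; the slow phase is the rate-limiting breakdown
of the acyl-enzyme. Dividing by [E]₀ = 1 µM puts both on the
min⁻¹ M⁻¹ scale used to compare variants — e.g. the evolved twin
enzymes' endpoint constants differ by

```r
fold_change(7e3, 3e3)
#> [1] 2.3
```

Shell enrichment on a structure with a planted second shell:

```r
ts <- toy_structure(16, c(second = 9, beyond = 4), seed = 2)
write_pdb(ts, "toy.pdb")
m   <- parse_structure("toy.pdb")
tri <- triad_definition(ts$triad, m)
muts <- data.frame(position = ts$residues$resno[ts$residues$shell == "second"][1:7],
                   kind = "point")
shell_enrichment(m, tri, muts, n_permutations = 1e5, seed = 3)
#> shell enrichment: 7/7 mutations in the second shell; p = 0.02109
#>   (100000 permutations, seed 3)
```

All 7 mutations landing 4–8 Å from the triad is unlikely under uniform
placement over the 13 non-triad residues (p ≈ 0.02): the second shell is
enriched.

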