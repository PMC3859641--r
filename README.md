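# ubistruct

Structural propensity analysis of protein ubiquitination sites.

## The problem

High-throughput proteomics has mapped tens of thousands of lysine
ubiquitination sites, but which lysines get selected remains poorly
explained by flanking sequence alone. When sites are mapped onto protein
structures, Ub sites turn out to be slightly but consistently more
solvent-exposed, more protruding, and — unexpectedly — more *central* in
the residue packing than unmodified lysines, and their local backbone
conformations are non-random. `ubistruct` is a reusable pipeline for
quantifying exactly these effects on any set of structures with labelled
lysines, and for measuring how much the structural signals add to the
sequence pattern.

For structural bioinformaticians it provides, as tidy tibble-in /
tibble-out functions:

* **Accessibility descriptors** — Shrake–Rupley SASA, relative solvent
  accessibility (RSA, capped at 100 %), protrusion index CX
  (empty/occupied volume in a 10 Å sphere) and depth index DPX (distance
  of a buried atom to the nearest exposed one).
* **Residue contact networks** — Cβ < 7.5 Å (or any-atom < 4.0 Å) graphs;
  degree, reachable-set closeness centrality
  `C(v) = (r_v / Σ d(v,u)) · (r_v / (n−1))`, and distance to the geometric
  centre with radius-of-gyration correction.
* **Local conformation** — κ/α virtual angles of the Cα trace
  (helix ≈ (89°, +50°)), a 22-letter structural alphabet assigned by
  nearest centroid, seven conformational groups, and DSSP file reading.
* **Context and microenvironment** — ±k symbol windows with Fisher-exact
  two-sample enrichment tables, and three-shell (0–7.5–11.5–15.5 Å)
  residue propensities.
* **Functional-site association** — interface ΔASA classes
  (rim < 25 Å² < intermediate < 85 Å² < core), ligand- and catalytic-site
  distances with the 11.5 Å "ubiquitin radius" cutoff, and
  ΔΔG > 2 kcal/mol folding-hotspot flags from alanine-scan tables.
* **Discrimination layer** — Wilcoxon tests with effect size r = Z/√N
  (negative when Ub sites are shifted higher), positional naive Bayes
  likelihood scores under stratified 5-fold CV, unit scaling, weighted
  combination with grid-searched weights, midrank ROC/AUC and DeLong's
  paired test.
* **A seeded synthetic benchmark** — toy helix-bundle / β-sandwich / coil
  structures whose planted Ub labels realise requested effect sizes, so
  every stage is testable end to end without downloads.

## Worked example

Generate the default synthetic benchmark (75 chains, ~2 000 labelled
lysines, planted effect sizes r = −0.10 on CX and closeness) and run the
full analysis:

```r
library(ubistruct)

spec  <- synthetic_spec(seed = 42)
bench <- generate_benchmark_set(spec)
an    <- analyze_sites(bench$models, bench$sites, panel = "core", seed = 42)
an
#> <ubi_analysis: 1943 sites (389 Ub / 1554 NonUb), 5 descriptors>
#> Descriptor comparisons (Wilcoxon p, effect r):
#>              descriptor  p_value effect_r n_ub n_nonub
#> 1                cx_max 1.72e-04  -0.0852  389    1554
#> 2                degree 2.01e-03   0.0701  389    1554
#> 3             closeness 5.67e-06  -0.1030  389    1554
#> 4           center_dist 1.50e-05   0.0982  389    1554
#> 5 center_dist_corrected 8.85e-02   0.0386  389    1554
#> Indicator AUCs:
#>   indicator   auc delong_p_vs_seq
#> 1        cx 0.561        2.76e-02
#> 2 closeness 0.574        6.18e-03
#> 3    seq_nb 0.511              NA
#> 4   conf_nb 0.517        7.89e-01
#> 5    shell1 0.502        7.01e-01
#> 6    shell2 0.508        9.06e-01
#> 7  combined 0.595        9.61e-05
```

Reading this: the planted upward shifts of the Ub sites in protrusion
(`cx_max`, r = −0.085) and closeness (r = −0.103) are recovered within
±0.03 at p ≪ 0.01; the sequence-context indicator is near chance (the
benchmark plants no sequence signal); and the weighted combination
(AUC 0.595) beats every single indicator, with DeLong's test confirming
the gain over the sequence indicator alone. `tidy(an)`, `glance(an)` and
`autoplot(an)` give the comparison table, a one-row AUC summary, and the
overlaid ROC curves.

The case study shipped with the package — five literature-reported
ubiquitination sites on human farnesyl pyrophosphate synthase (PDB 3N45)
— illustrates the functional-association layer:

```r
sites <- read_site_table(system.file("extdata", "3n45_case_study_sites.tsv",
                                     package = "ubistruct"))
sum(sites$label == "Ub")
#> [1] 5
# with a local copy of the 3N45 structure:
# m  <- parse_structure("3n45.pdb", chain = "A")
# ligand_association(m, dplyr::tibble(chain_id = "A", res_number = 332L))
# -> min_dist to bivalent metals ~ 5.5 A, direct association
```

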