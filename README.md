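# rotidiet

Diet-selectivity analysis for paired gut-content / ambient-water
metabarcoding surveys.

## The problem

Rotifers such as *Polyarthra* are among the most abundant metazoan grazers
in lakes, but what they actually eat in situ is hard to observe: gut-content
18S metabarcoding gives a read count table for the diet, and a paired
ambient-water library gives one for what was available. Turning those two
tables into ecological statements requires a chain of decisions — the
consumer's own reads must be subtracted, counts aggregated to a usable
taxonomic rank, selectivity quantified against availability, and the
community-level contrast and its environmental drivers tested. `rotidiet`
packages that chain as tested, reusable functions for anyone analysing
consumer-diet metabarcoding against an availability baseline.

## The statistics at its core

* **Ivlev electivity**: for taxon *i* with relative abundance *r_i* in the
  diet and *p_i* in the ambient water,
  *E = (r_i − p_i) / (r_i + p_i)* ∈ [−1, 1].
  *E* > +0.25 is classified as preference, *E* < −0.25 as discrimination,
  the band between as non-selective feeding (strict inequalities).
* **McNaughton dominance** *Y_i* = (read share of *i*) × (fraction of
  samples occupied), ranking the ambient community's dominants.
* **Wilcoxon rank-sum + Benjamini–Hochberg FDR** per taxon on per-sample
  relative abundances, gut vs water.
* **Bray–Curtis / ANOSIM**: rank-based permutation *R* with the
  conventional effect bands (*R* > 0.75 large, 0.5–0.75 medium, 0.25–0.5
  small, ≤ 0.25 negligible).
* **Exact hypergeometric rarefaction**:
  *E[S_n] = Σ_i [1 − C(N−N_i, n) / C(N, n)]* in log-gamma arithmetic.
* **Constrained ordination**: correspondence analysis, DCA axis-1 gradient
  length (in species-turnover SD units) to choose linear RDA (< 3 SD) vs
  unimodal CCA (> 4 SD), and Monte-Carlo permutation forward selection of
  environmental variables (pseudo-F on reduced-model residual
  permutations). All ordination engines are implemented in the package and
  are verified against dense eigen-decomposition oracles and `vegan` in
  the test suite.
* **Synthetic study generator**: paired gut/water tables under
  "ingestion ∝ availability × preference" (*q_k ∝ w_k p_k*) with a
  dominant consumer self-read fraction, season-structured Dirichlet
  baselines, multinomial read sampling and trophic-factor-driven
  environmental covariates — so every stage can be tested against known
  ground truth.

## Worked example

The `analysis/` directory is a numbered workflow over a simulated campaign
(3 sites × 4 seasons, one water library at 60,000 reads and one gut library
at 5,500 reads each, 90% consumer self-reads; Chrysophyceae- and
Synurophyceae-type taxa given a 4-fold ingestion preference, some
Cryptophyceae-type taxa a 0.3-fold avoidance):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_selectivity.R
Rscript analysis/04_community.R
Rscript analysis/05_ordination.R
```

which prints, among other things:

```
Removed 59,538 consumer reads from 12 gut libraries (90.2% of gut reads)
OTUs: 40 shared, 0 gut-only, 0 water-only
  preferred in >=1 season: Chrysophyceae, Synurophyceae
Wilcoxon rank-sum gut vs water: 5/15 classes at FDR <= 0.05: Cryptophyceae,
  Synurophyceae, Chrysophyceae, Chlorophyceae, Trebouxiophyceae
ANOSIM gut vs water (class level): R = 0.74, p = 0.001 -> medium difference
DCA axis-1 gradient length: water 3.0 SD -> CCA; gut 3.0 SD -> CCA
Forward selection (999 permutations): NH4N
```

The preference/avoidance structure planted in the generator is recovered:
the preferred classes come out with seasonal *E* above +0.25 and as
significantly gut-enriched, the avoided class as discriminated against,
and the gut community separates from the water community by ANOSIM. Each
script writes its tables (seasonal electivity table with dominance,
enrichment, distances, rarefaction curves, ordination scores and the
forward-selection trace) under `results/`.

The same chain is available in one call as `run_pipeline()`; see
`?run_pipeline`.

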