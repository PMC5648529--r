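# mnpaths

Do two motor-neuron differentiation protocols — a growth-factor-guided
standard protocol (SP) and transcription-factor direct programming (DP) —
pass through the same intermediate cell states, or do they bifurcate after
neural commitment and reconverge only at the terminal motor-neuron state?
`mnpaths` is an R package plus a small analysis workflow that answers this
from droplet single-cell RNA-seq UMI count matrices: quality clean-up,
principal-variable-gene selection, density clustering and marker-based
annotation, differential expression with the study's filter presets,
cross-trajectory comparison, and an analytic bound on how long a
hypothetical rare transitional state could exist. A seeded synthetic-data
generator emulates the two-protocol droplet experiment with known ground
truth, so the entire pipeline is testable offline.

It is aimed at computational biologists who want each analysis step as a
plain, tested function over ordinary matrices and data frames.

## The models at the core

**Multinomial cell-state model.** A state is a probability vector $p_k$
over genes; a cell's counts $x_c$ are a multinomial sample from its
state's distribution. A query cell is assigned to the reference state
maximizing the log-likelihood

$$\ell(c \mid k) = \sum_g x_{cg} \log p_{kg},$$

with $p_k$ estimated from each reference cluster's pooled count fractions
(undetected genes get a $10^{-7}$ pseudo-total). Ties are reported and
tallied fractionally.

**Principal variable genes.** The top 1000 highly variable genes (Fano
factor relative to a mean-matched baseline) are z-scored; principal
components are retained only while their eigenvalues exceed the maximum
same-rank eigenvalue over column-permuted copies of the matrix; PV genes
are those loading above the 90th percentile on a retained component. All
trajectory comparisons (centroid cosine similarity, likelihood
assignment, kNN label transfer, 50-NN neighbor fractions) run in this
space.

**Lifetime bound.** If a gene's bulk expression over a protocol of
duration $T$ is $R$-fold below a housekeeping gene while the hypothetical
transitional state would express it $F$-fold above housekeeping, the
state's lifetime is at most $T/(RF)$; allowing a single transcript per
cell against $C$ housekeeping copies relaxes this to $TC/R$.

## Worked example

Simulate the reference two-protocol design, clean it up, and compare the
trajectories:

```r
library(mnpaths)

design <- two_protocol_design()          # 2000 genes, 6 states, shared ESC/LMN
spec   <- function(states, prot, seed)
  synthetic_spec(trajectory_topology(design$programs[states],
                                     shared_states = design$shared),
                 cells_per_state = 200, protocol = prot, seed = seed)
ex <- generate_two_protocol_experiment(spec(design$dp_states, "DP", 1),
                                       spec(design$sp_states, "SP", 2),
                                       design$shared)

qc_dp <- qc_pipeline(ex$dp)              # >=1000 UMIs, stress removal, normalize
qc_sp <- qc_pipeline(ex$sp)
cmp <- compare_protocols(qc_dp, qc_sp,
                         qc_dp$counts$cell_meta$true_state,
                         qc_sp$counts$cell_meta$true_state, seed = 1)
round(cmp$similarity, 3)
```

```
       ESC   PVNP    MNP    LMN
ESC  0.942 -0.219 -0.219 -0.351
NP  -0.214 -0.129 -0.130 -0.215
EMN -0.217 -0.130 -0.129 -0.213
LMN -0.356 -0.216 -0.219  0.940
```

The shared start (ESC) and terminal (LMN) states are each other's clear
maxima across protocols, while every pair of distinct intermediates is
dissimilar — the bifurcate-and-reconverge signature. The same object
carries the multinomial assignment of DP cells onto SP states
(`cmp$assignment$tally`), where the shared-state cells map back to their
matching states.

The analytic bound on a hidden Olig2+ intermediate in DP:

```r
lifetime_bound(T_days = 11, R = 1e6, F_ref = 5, C = 1000)
```

```
lifetime_bound (T = 11 d, R = 1e+06, F = 5, C = 1000):
  at reference level: fraction <= 2e-07, lifetime <= 0.19 s
  at one molecule/cell: fraction <= 0.001, lifetime <= 15.8 min
```

A transitional state expressing the gene at the reference level could
persist for at most 0.19 s — orders of magnitude below an mRNA lifetime —
and even a single-molecule state is capped at 0.1% of cells.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on the synthetic
design and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R               # MatrixMarket trios + ground truth
Rscript analysis/02_qc_cluster_annotate.R    # QC, tSNE, DBSCAN, annotation, fractions
Rscript analysis/03_differential_expression.R
Rscript analysis/04_trajectory_comparison.R  # cosine matrix, ML tally, SPRING layout
Rscript analysis/05_scores_lifetime.R        # panel scores, lifetime bound
```

`run_pipeline()` offers the same sequence behind a single YAML-validated
configuration.

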