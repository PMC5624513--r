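# pidnet

Gene regulatory network inference from single-cell expression data using
multivariate information theory.

Single-cell experiments expose cell-to-cell variability that pairwise
statistics only partly exploit. `pidnet` examines every **triplet** of genes
and decomposes the information two genes carry about a third into
non-negative redundant, unique and synergistic parts (partial information
decomposition, computed via the specific information). For a pair of genes
$X, Y$ embedded in a panel $S$, the **proportional unique contribution**
(PUC) sums, over every third gene $Z$, the share of the pair's mutual
information that is unique rather than redundant, with each gene treated as
the target in turn:

$$u_{X,Y} \;=\; \sum_{Z \in S \setminus \{X,Y\}}
  \frac{\mathrm{Unique}_Z(X;Y)}{I(X;Y)}
  \;+\; \sum_{Z \in S \setminus \{X,Y\}}
  \frac{\mathrm{Unique}_Z(Y;X)}{I(X;Y)}.$$

Because raw scores are not comparable across genes, the **PIDC** confidence
of an edge adds per-gene network context through the empirical cumulative
distributions of each gene's PUC scores:

$$c \;=\; F_X(u_{X,Y}) + F_Y(u_{X,Y}) \;\in\; [0, 2].$$

Edges are ranked by $c$. Relevance networks (raw MI), CLR and ARACNE are
included as comparators; all methods start from the same MI matrix, computed
from per-gene discretized expression (Bayesian blocks by default, uniform
width optionally) with a choice of maximum likelihood, Miller–Madow,
Dirichlet or shrinkage estimators.

The package is aimed at anyone inferring candidate (co-)regulatory
relationships from single-cell qPCR or (gene-subsetted) scRNA-seq panels,
and at methodologists who want the full validation loop: exact stochastic
(Gillespie) simulators for small thermodynamic and mass-action gene
circuits, snapshot cell-sampling schemes, a dropout model, and AUPR/AUROC
evaluation against gold-standard networks.

## Worked example

Simulate a three-gene circuit with a single activating edge G1 → G2 and a
stimulating ligand on G1, then infer the network:

```r
library(pidnet)

topo <- circuit_topology(3, data.frame(regulator = 1, target = 2, sign = 1),
                         stimulus_target = 1L)
ens   <- simulate_thermo(topo, repeats = 25, seed = 1)   # 25 x 41 records
cells <- ensemble_expression(ens)                        # 3 genes x 1025 cells
fit   <- infer_network(cells, method = "pidc")
fit
#> Inferred gene network (pidc): 3 genes, 1025 cells, 3 ranked edges
#>   discretizer: bayesian_blocks; estimator: ml
#>   gene_a gene_b     score rank
#> 1     G1     G2 1.6709530    1
#> 2     G2     G3 1.0321449    2
#> 3     G1     G3 0.3902867    3
```

The true edge (G1, G2) tops the ranking: its confidence 1.67 means the
pair's PUC score sits high in both genes' own score distributions. Scoring
against the known circuit:

```r
pr_and_roc(fit$edges, as_gold_standard(topo))
#> AUPR: 1   AUROC: 1
```

The decomposition itself is available per triplet — here the information
G1 and G3 carry about the regulated gene G2 (bits):

```r
d <- discretize_matrix(cells)
pid(d$G2, d$G1, d$G3)
#> Partial information decomposition (target G2; sources G1, G3)
#> redundancy   unique_x   unique_y    synergy
#>    0.15781    0.99800    0.00000    0.11336
```

The regulator G1 contributes ~1 bit of *unique* information about its
target, dwarfing the redundancy — the triplet signature the edge score is
built on.

A thin command-line interface wraps the same functions
(`inst/cli/pidnet simulate | infer | pid | evaluate | preprocess`), reading
and writing tab-separated matrices, ranked edge lists with provenance
headers, and three-column gold-standard files.

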