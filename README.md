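# csrwalign

Global multiple alignment of protein–protein interaction (PPI)
networks in R, built around a **context-sensitive random walk (CSRW)**
with restart.

## Who this is for

Comparative network analysis asks which proteins in the PPI networks of
different species correspond to each other, using both *node
similarity* (e.g. BLAST bit scores) and *topological similarity*
(conserved interaction patterns). `csrwalign` is for computational
biologists who want a self-contained aligner plus the standard
evaluation metrics and a synthetic benchmark generator, with no
external database dependencies: networks are plain edge lists,
similarities are 3-column score tables, annotations are 3-column label
tables.

## The method in brief

For each network pair $(G_U, G_V)$, a walker moves on the product of
the two networks. Where the neighbourhood holds node pairs with
positive similarity (the match set $\mathcal{M}$), it makes a
*simultaneous* move into one of them with probability proportional to
similarity; elsewhere it walks on a single network, modelling inserted
or deleted proteins. Transitions are restricted to $\mathcal{M}$ and
renormalized, giving the reduced stochastic matrix $\tilde{\mathbf P}$.
Its stationary distribution $\tilde\pi$ is blended with the normalized
similarity vector $\mathbf s$:

$$\mathbf c \;=\; \lambda\,\mathbf s + (1-\lambda)\,\tilde\pi,$$

where the restart probability $\lambda$ is the node fraction of the
$\lfloor K/100\cdot C\rfloor$ smallest connected components of the
reduced product graph ($K = 99$): well-connected inputs trust the walk,
fragmented inputs fall back to similarity. Scores may then be refined
by a probabilistic consistency transformation across third networks
(intra-network smoothing with weight $\alpha = 0.9$, cross-network
composition with weight $\beta = 0.8$, skipped for pairs with
$\lambda > \lambda_t = 0.7$). Finally, a greedy maximum-expected-
accuracy scan over all candidate pairs builds many-to-many equivalence
classes of up to `n_max = 10` members.

Evaluation metrics: correct nodes (CN), specificity (SPE), mean
normalized entropy (MNE), conserved interactions and conserved
orthologous interactions (CI, COI), coverage profiles, and pair-level
accuracy against a reference alignment.

## Worked example

```r
library(csrwalign)

A   <- csrw_network("A", rbind(c("u1","u2"), c("u2","u3")))  # path u1-u2-u3
B   <- csrw_network("B", rbind(c("v1","v2")))                # edge  v1-v2
sim <- sim_table("A", "B", c("u1","u2","u3"), c("v1","v2","v1"), c(2, 1, 1))

res <- pair_correspondence(A, B, sim)
res$chain
#> <csrw_chain A-B: |M| = 3, lambda = 0, 0 dangling>
round(res$c, 4)
#> [1] 0.3333 0.5000 0.1667
```

The three match states `(u1,v1)`, `(u2,v2)`, `(u3,v1)` form one
connected product graph, so `lambda = 0` and the correspondence scores
are the walk's stationary distribution `(1/3, 1/2, 1/6)` — `u2~v2`
scores highest because both sit at the centres of their networks.

```r
cs <- correspondence_set(network_set(A, B), list(res))
aln <- build_alignment(rank_pairs(cs), cs$networks)
aln
#> <csrw_alignment: 2 classes, 5 aligned nodes>

ann <- annotation_map(c("A","A","A","B","B"),
                      c("u1","u2","u3","v1","v2"),
                      c("F1","F2","F1","F1","F2"))
metrics_report(aln, network_set(A, B), ann)
#> classes          2 (evaluated 2 after filtering)
#> CN               5
#> SPE              1.0000
#> MNE              0.0000
#> CI               3
#> COI              3
#> class_coverage   2:2
#> node_coverage    2:5
```

Greedy construction founds `{u2,v2}` and `{u1,v1}`, then attaches `u3`
to the latter (many-to-many class). Both classes are functionally pure
(SPE 1, MNE 0) and all three edges run between the two classes with
support from both networks (CI = COI = 3).

## Command line

The same pipeline is scriptable via `exec/csrwalign` (or `cli_main()`):

```sh
csrwalign simulate --model dmc --networks 3 --sizes 200,200,200 \
          --seed 7 --out bench/
csrwalign align --net A=bench/network_A.tsv --net B=bench/network_B.tsv \
          --net C=bench/network_C.tsv --sim A,B=bench/sim_A-B.tsv \
          --sim A,C=bench/sim_A-C.tsv --sim B,C=bench/sim_B-C.tsv \
          --out bench/aln.tsv
csrwalign eval --alignment bench/aln.tsv --annotations bench/annotations.tsv \
          --net A=bench/network_A.tsv --net B=bench/network_B.tsv \
          --net C=bench/network_C.tsv --truth bench/true_alignment.tsv
```

## Scope

No database downloads, no BLAST execution, no GO/KEGG retrieval
(annotations are inputs), no exact reproduction of any published
benchmark's parameterization, and no optimal (ILP) alignment mode. See
`vignettes/csrwalign-methods.Rmd` for the model details, parameter
rationale, and known limitations.
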