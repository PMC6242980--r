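# sfcnlp — link prediction with similarity-based future common neighbors

`sfcnlp` predicts missing or future links in undirected simple networks
(protein–protein interaction maps, collaboration networks, food webs,
social graphs). Its users are network scientists and computational
biologists who want to rank unobserved node pairs by how likely they are
to be real links — e.g. to prioritise interaction candidates before
committing laboratory effort.

## The model

Classical similarity indexes score a pair (x, y) from its *current*
common neighbors. The SFCN (similarity-based future common neighbors)
model also credits nodes positioned to *become* common neighbors:

```
s(x,y) = α · s_C1(x,y) + β · ( Γx·Sy' + Sx·Γy' + Sx·Sy' )
```

where `Γx` is the 0/1 adjacency row of x, `Sx` the row of scores of a
base index C2 (positions x, y zeroed), and the three dot products
accumulate the three classes of future common neighbors: nodes already
linked to x, nodes already linked to y, and nodes linked to neither but
similar to both. C1 and C2 are any of the eight classical indexes
implemented here — CN, Salton, RA, HPI, HDI, LHN, LNBRA, LP — and a
configuration is named `SFCN-<C1>-<C2>`. Defaults are α = 9, β = 1.

Evaluation follows the standard protocol: the observed edges are split
into a training set (default 90%) and a probe set, indexes are computed
on the training graph only, and accuracy is measured by exact AUC (probe
vs nonexistent links, ties 0.5) and precision of the top-L predictions
(default L = 100), averaged over seeded replicates.

## Worked example

The package ships the reference 10-node example for the SFCN vector
construction (target pair (1, 3), C2 = RA):

```r
library(sfcnlp)
fx <- example1_fixture()
identify_fcn(fx$vectors)
#> future common neighbors of (1, 3)
#>   type 1 (linked to x): {4}  contribution 0.166667
#>   type 2 (linked to y): {5}  contribution 0.2
#>   type 3 (linked to neither): {8, 10}  contribution 0.0666667
#>   total future contribution: 0.433333 (coefficient of beta)
```

Node 4 is already linked to node 1 and has RA score 1/6 to node 3; node 5
is linked to 3 with score 1/5 to 1; nodes 8 and 10 are linked to neither
but similar to both, jointly contributing 1/15. The future term adds
13/30 · β to the pair's score.

An end-to-end experiment on a synthetic benchmark with community
structure (150 nodes, 3 planted communities):

```r
g <- generate_graph("planted_partition", seed = 1, n = 150,
                    k_communities = 3, p_in = 0.15, p_out = 0.01)
run_experiment(g, index_spec("cn"), n_replicates = 20, base_seed = 1)
#> CN: mean AUC 0.6233, mean precision@100 0.0180 (20 replicates, ratio 0.9)
run_experiment(g, sfcn_config("cn", "ra"), n_replicates = 20, base_seed = 1)
#> SFCN-CN-RA: mean AUC 0.7191, mean precision@100 0.0235 (20 replicates, ratio 0.9)
```

Accounting for future common neighbors lifts the mean AUC by about 0.1
on this benchmark. `parameter_sweep()` calibrates (α, β) on sub-splits of
the training set; `ratio_sweep()` measures robustness as the observed
fraction shrinks; `network_stats()` and `read_edge_list()` handle
descriptive statistics and plain two-column edge-list files.

## Command line

A thin launcher is installed at `inst/cli/sfcnlp`:

```sh
Rscript inst/cli/sfcnlp stats --input net.txt
Rscript inst/cli/sfcnlp score --input net.txt --method sfcn-cn-ra --pair a,b
Rscript inst/cli/sfcnlp evaluate --input net.txt --methods cn,ra,sfcn-cn-ra \
    --replicates 100 --seed 1 --output results.csv
Rscript inst/cli/sfcnlp sweep --input net.txt --mode grid --c1 cn --c2 ra
```

Every output embeds its resolved configuration and seed as `#` header
lines, so runs are reproducible from their outputs.

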