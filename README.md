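# cernasim

Simulation of competing endogenous RNA (ceRNA) regulation on bipartite
miRNA:target networks, for systems biologists who want to ask: *if this gene
or miRNA changes, what else in the network moves?*

Transcripts that share miRNAs compete for them. `cernasim` models each
miRNA's expression as a budget of repressive activity distributed over its
targets in proportion to affinity-weighted target abundance:

    RC[i,j] = Exp(miRNA_j) * AF[i,j] * Exp(Target_i) / Σ_k AF[k,j] * Exp(Target_k)
    R[i]    = Σ_j RC[i,j] * RE'[i,j]

where the affinity factor `AF = E' × STE'` (normalized binding free energy ×
seed-type effect) scales how much miRNA an edge sequesters and the region
effect `RE'` scales the degradation it exerts. A perturbation (fold change on
any node) is propagated by iterating redistribution and the synchronous gene
update `expr_new = max(0, expr + (R_prev − R_new))` until a fixed point: the
"ripple" spreads through shared miRNAs and common targets. On top of single
simulations the package screens every node for its network-wide perturbation
efficiency, overlays per-sample expression profiles on one interaction
template for cohort analysis, and calibrates significance cutoffs
(minimum perturbed nodes, minimum samples) with a finite Gaussian mixture.

## Worked example

The bundled eight-node network has miRNA M1 (expression 1,000) targeting
genes G1–G4 (expressions 10,000 / 10,000 / 5,000 / 10,000) and M2 targeting
G4–G6, with G4 bridging the two neighbourhoods:

```r
library(cernasim)
net <- make_sample_network()
round(distribute_mirna(net)$edge_rc$rc[1:4])
#> [1] 286 286 143 286

traj <- run_simulation(net, c(G2 = 2))   # double G2's transcription
round(traj[[2]]$gene_expression)
#>    G1    G2    G3    G4    G5    G6
#> 10063 19841  5032 10063 10000 10000

perturbation_metrics(traj, limit = 0.1)
#> Perturbation of G2 (fold 2): 3 node(s) perturbed, efficiency 0.6167% over 7 cycle(s)
```

At steady state M1 splits 286/286/143/286 over its targets. Doubling G2
pulls M1 toward it (286 → 444), releasing repression on G1, G3 and G4 — their
availability rises to ~10,063 and ~5,032. One cycle later the raised bridge
G4 sequesters more M2, so G5 and G6 rise too, although they share no miRNA
with the trigger. With a 0.1% perturbation limit, three nodes count as
perturbed with a mean absolute change of 0.62%.

Screening and calibration follow the same pattern:

```r
tab <- screen_all_nodes(net, fold = 3)                       # every node as trigger
cohort <- make_cohort(net, n_samples = 20, seed = 1)         # synthetic per-sample overlays
screen <- screen_cohort(net, cohort, fold = 3)
thr <- fit_significance_threshold(screen)                    # mixture-calibrated cutoffs
select_significant_nodes(screen, thr)
```

A command-line front end over the same functions lives at
`inst/cli/cernasim.R` (subcommands `fixtures`, `simulate`, `screen`,
`threshold`, `select`, `export`); GraphML/SIF export opens in
Cytoscape-compatible viewers.

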