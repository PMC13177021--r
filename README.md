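# scwnet

Complex-network analysis of supercritical water microstructure.

Above the critical point (T_c = 647.096 K, P_c = 220.64 bar) water's
hydrogen-bond network breaks down into transient clusters. `scwnet` treats a
configuration of rigid four-site water (TIP4P/2005 family) as a graph —
molecules as nodes, energetically significant pair interactions as edges —
and quantifies how the graph's topology responds to the thermodynamic state.
It is aimed at molecular-simulation practitioners who have frames (GRO-style
coordinate/velocity files) and want network-level descriptors rather than
radial distribution functions alone.

## The model

A pair of molecules (i, j) is connected when

```
V_Coulomb(i,j) + V_LJ(i,j) + E_kin(i,j) + lambda * 4 * E_kin(H)  <  0
```

- `V_Coulomb`: Coulomb's law over the nine charged-site pairs (H, H, M of
  each molecule);
- `V_LJ`: the single O–O Lennard-Jones term, `4*eps*[(sig/r)^12 - (sig/r)^6]`;
- `E_kin(i,j) = (1/2) * (m_w/2) * |dv_com|^2`: kinetic energy of relative
  center-of-mass motion (reduced mass of two equal molecules);
- `E_kin(H) = R*T`: the kinetic energy of a hydrogen-mass particle at the
  Maxwell–Boltzmann most probable speed (5.60 kJ/mol at T = 1.04 T_c);
- `lambda`: a calibrated weight on the thermal penalty (default 0.655).

Two geometric filters precede the criterion: only molecules inside a
concentric cube of 85% of the box edge are nodes (pair distances are
computed without minimum image), and a candidate pair is discarded when a
third body's center of mass lies inside a finite cylinder of radius
r_c = 0.3159 nm (the oxygen diameter) along the pair's COM–COM axis.

Downstream, the package computes network density `rho = 2E/(N(N-1))`,
average degree `<k> = 2E/N`, PageRank, connected components, and fits the
component-size distribution to the power law `n_c(s) = A * s^b`. It also
calibrates `lambda` against a reference cluster-size distribution (MAE
argmin over a grid), selects representative frames/components by PCA, and
classifies QTAIM bond-critical-point tables into noncovalent / partially
covalent / covalent interactions from the sign of the Laplacian and the
total energy density H = G + V.

## Worked example

Plant clusters of known sizes, rebuild them from the energetics alone, and
model the size distribution:

```r
library(scwnet)

hydrogenKineticEnergy(1.04 * 647.096)
#> [1] 5.595466   # kJ/mol; 5.60 at 2 decimals

params <- criterionParameters(lambda = 0.655, temperature = 673)
pl  <- plantedClusterFrame(c(`1` = 12, `2` = 6, `3` = 3, `4` = 2), seed = 42)
net <- buildNetwork(pl$frame, params)
net
#> InteractionNetwork: 41 nodes, 18 edges (29 interacting)
#>   lambda = 0.655, EkinH = 5.5956 kJ/mol, rc = 0.3159 nm

componentSizeDistribution(net)
#> ComponentSizeDistribution: 23 components over 41 nodes
#>  size count fraction
#>     1    12   0.5217
#>     2     6   0.2609
#>     3     3   0.1304
#>     4     2   0.0870

fitPowerLaw(componentSizeDistribution(net))
#> PowerLawFit: n_c(s) = 12.83 * s^(-1.3020)   [log-log R^2 = 0.9849]

networkDensity(net, "all")       #> 0.02195122
averageDegree(net)               #> 0.8780488
pageRankMean(net)$interacting    #> 0.03246753
```

The planted spec `{1: 12, 2: 6, 3: 3, 4: 2}` is recovered exactly: every
chain survives the criterion (the planted hydrogen-bond motif sits at
about −21.4 kJ/mol against a thermal penalty of about +14.7 kJ/mol at
λ = 0.655 and 673 K) and no spurious inter-cluster edge forms. The fitted
intercept A ≈ 12.8 matches the 12 planted monomers.

A command-line interface wrapping the same functions is installed at
`exec/scwnet` (subcommands `simulate`, `build-network`, `metrics`,
`components`, `fit-powerlaw`, `calibrate-lambda`, `select-frames`,
`classify-bcp`, `compare-groups`; every output JSON carries a
`parameters` block with the effective settings).

See `vignettes/interaction-networks.Rmd` for the full account of the
model, its assumptions, and the package's numerical choices.

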