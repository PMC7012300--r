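# treestab

Tree **stability** and **reproducibility** statistics for duplicated gene
families, built on neighbor joining over p-distances (NJp) with
bootstrap resampling.

After a genome duplication, two paralogous gene families evolve along the
*same* species history. If a tree inferred from one family is real signal
rather than noise, the other family should reproduce it. `treestab`
quantifies this with three bootstrap-based percentages:

- **Pb** — per-branch bootstrap support: the percentage of bootstrap
  replicates in which an interior branch (leaf bipartition) of the NJp tree
  reappears.
- **Ps** — *tree stability* of a clade: the clade plus its closest outgroup
  is extracted from each bootstrap replicate's NJp tree, the rooted ingroup
  topology is recorded, and Ps is the percentage held by the modal topology.
  A tree can have every Pb near 100 yet a low Ps, because Ps must get the
  *entire* ingroup topology right at once.
- **Pr** — *tree reproducibility* between two families A and B related by a
  species-level label map. Pr1 is the percentage of A's bootstrap replicates
  whose ingroup topology equals family B's point-estimate topology
  (transported through the map); Pr2 is the converse; Pr = (Pr1 + Pr2) / 2.

All topologies are compared as canonical keys — deterministic,
label-order-independent string encodings of rooted (or outgroup-rooted)
topologies — so equality of keys is exactly topological identity.

The package also ships a JC69 sequence simulator for generating concordant
and deliberately discordant family pairs, and a command-line interface.

## Worked example

Simulate a concordant pair of gene families (1,000 sites each, JC69) on the
bundled 9-taxon primate-like species tree, then compute all three
statistics with 500 bootstrap replicates:

```r
library(treestab)

tr   <- example_species_tree()
pair <- make_family_pair(tr, agree = TRUE, n_sites = 1000, seed = 1)
cfg  <- bootstrap_config(500, seed = 1)

labs    <- alignment_labels(pair$alignment_a)
clade_a <- clade_spec(setdiff(labs, "A_pro1"), "A_pro1")
clade_b <- clade_spec(setdiff(alignment_labels(pair$alignment_b), "B_pro1"),
                      "B_pro1")

compute_ps(pair$alignment_a, clade_a, cfg)
#> Ps = 100.0%  (modal topology ((((A_hom1,A_hom2),A_hom3),((A_owm1,A_owm2),A_owm3)),(A_nwm1,A_nwm2)); 500 replicates, outgroup A_pro1)

compute_pb(pair$alignment_a, cfg)
#> NJp bootstrap support (Pb): 500 replicates, seed 1, complete deletion
#>                                       bipartition count  pb
#>                                     A_owm1|A_owm2   500 100
#>                              A_owm1|A_owm2|A_owm3   500 100
#>         A_nwm1|A_nwm2|A_owm1|A_owm2|A_owm3|A_pro1   500 100
#>  A_hom3|A_nwm1|A_nwm2|A_owm1|A_owm2|A_owm3|A_pro1   500 100
#>                              A_nwm1|A_nwm2|A_pro1   500 100
#>                                     A_nwm1|A_nwm2   500 100

compute_pr(pair$alignment_a, clade_a, pair$alignment_b, clade_b,
           pair$map, cfg)
#> Pr1 = 100.0%  Pr2 = 100.0%  Pr = 100.0%
#>   T1 = ((((A_hom1,A_hom2),A_hom3),((A_owm1,A_owm2),A_owm3)),(A_nwm1,A_nwm2)) (outgroup A_pro1)
#>   T2 = ((((B_hom1,B_hom2),B_hom3),((B_owm1,B_owm2),B_owm3)),(B_nwm1,B_nwm2)) (outgroup B_pro1)
#>   500 replicates, seed 1, T1/T2 from subtree
```

Now make family B's topology differ from A's by one
nearest-neighbor-interchange around the `hom1`/`hom2` cherry.
Reproducibility collapses even though the data are otherwise just as clean:

```r
pd <- make_family_pair(tr, agree = FALSE, n_sites = 1000, seed = 2,
                       nni_node = ape::getMRCA(tr, c("hom1", "hom2")),
                       partner = "hom1")
compute_pr(pd$alignment_a, clade_a, pd$alignment_b, clade_b, pd$map, cfg)
#> Pr1 = 0.0%  Pr2 = 0.0%  Pr = 0.0%
#>   T1 = ((((A_hom1,A_hom2),A_hom3),((A_owm1,A_owm2),A_owm3)),(A_nwm1,A_nwm2)) (outgroup A_pro1)
#>   T2 = ((((B_hom2,B_hom3),B_hom1),((B_owm1,B_owm2),B_owm3)),(B_nwm1,B_nwm2)) (outgroup B_pro1)
#>   500 replicates, seed 1, T1/T2 from subtree
```

Real alignments enter through `read_fasta()` or `read_phylip()`;
species-level maps between paralog label sets can be built with
`build_species_map()` or read from a two-column TSV with
`read_label_map()`.

## Command-line interface

`inst/cli/treestab.R` (installed under `system.file("cli", "treestab.R")`)
exposes the same pipeline as subcommands, each writing result files plus a
JSON manifest:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","treestab.R",package="treestab"))')" \
  simulate --out sim --seed 5 --sites 1000
# sim.A.fasta sim.B.fasta sim.map.tsv sim.manifest.json

...treestab.R build-tree --in sim.A.fasta --out tree           # tree.nwk
...treestab.R pb  --in sim.A.fasta --out pb --replicates 1000  # pb.pb.tsv
...treestab.R ps  --in sim.A.fasta --clades clades.tsv --out ps
...treestab.R pr  --in sim.A.fasta --in-b sim.B.fasta \
                  --clade-a A_hom1,A_hom2,A_hom3 --clade-b B_hom1,B_hom2,B_hom3 \
                  --out pr
...treestab.R pr-matrix --families fams.tsv --out mat
```

## Design notes

- NJ joins are tie-broken by the lexicographically smallest cluster
  representatives, and every label sort uses C-locale (`radix`) order, so
  all results are independent of input record order and of the session
  locale.
- Negative NJ branch lengths are clamped to zero in the output tree only;
  the distance algebra is untouched.
- The default site-deletion mode is `complete`; `pairwise` is available
  throughout.
- See `vignettes/methods.Rmd` for the statistical model, parameter
  defaults, and limitations.
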