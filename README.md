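# phorekin

Ligand-based virtual screening and GPCR signaling kinetics in R, built
around GPR142 — a pancreatic beta-cell receptor whose agonists enhance
glucose-dependent insulin secretion and are of interest in type 2
diabetes. The package is for computational chemists and systems biologists
who need a transparent, fully testable implementation of two workflows that
usually live inside opaque commercial suites:

1. **Common pharmacophore hypothesis generation and 3D database matching.**
   Typed features (acceptor A, donor D, hydrophobe H, negative N, positive
   P, aromatic ring R) are perceived from 3D molecules via a replaceable
   SMARTS table, or read from abstract site-set JSON. Arrangements shared
   by a required number of actives are discovered by inter-site distance
   matching, superposed (Kabsch), and ranked with the survival score

   *S = W_site·S_site + W_vec·S_vec + W_vol·S_vol + W_sel·S_sel + W_rew·f(m)*

   with S_site an alignment score, S_vec the mean direction-cosine of
   paired vector features, S_vol a van der Waals volume-overlap score,
   S_sel a selectivity score (default weight 0), and f(m) a reward in the
   number of matching actives minus one. Retained hypotheses must keep
   their aligned actives within 1.20 Å pairwise RMSD and a vector score
   above 0.50. Conformer databases (up to 100 conformers per molecule) are
   searched for type-preserving, distance-compatible site assignments and
   ranked by a fitness score in [0, 3].

2. **An ODE model of the GPR142 signaling network.** Agonist binding
   activates Gq (PLC → PIP2 → DAG + IP3 → PKC / Ca²⁺ → insulin granule
   release) and Gi (saturable inhibition of adenylyl cyclase → lower cAMP →
   PKA/Epac). Rate laws are irreversible Michaelis–Menten
   (*V = Vm·S/(Km+S)*) and mass action (*V = k·∏ Sᵢ*), integrated with a
   stiff solver. The model predicts response *directions*: insulin up and
   cAMP down under Gq-dominant agonism, insulin down for a Gi-only
   (NPY-type) receptor. Dose scans, effect-table classification, SBML
   Level 3 export/import, and rate-parameter recovery from noisy
   trajectories are included, along with synthetic-data generators for
   planted-pharmacophore and kinetic-recovery studies and a PDB
   receptor–ligand contact annotator.

## Worked example

```r
library(phorekin)

# Plant a five-site ADPRR arrangement in 10 actives among 20 decoys,
# then recover it with the full discovery pipeline.
dat <- plant_pharmacophore(plant_spec(variant = "ADPRR", seed = 7))
hy  <- discover_hypotheses(dat$actives, min_match = 10)
hy$summary[1, c("variant", "n_matched", "s_site", "s_vec", "s_vol", "survival")]
#>   variant n_matched    s_site     s_vec     s_vol survival
#> 1   ADPRR        10 0.9380699 0.9997757 0.8726807 11.81053
```

The top hypothesis is the planted ADPRR variant, matched by all 10 actives
(`m = 9`, so the linear matches reward contributes 9 of the 11.8 survival
points; the site, vector and volume scores are each near their maximum of
1 because the planted sites carry only 0.1 Å positional noise).

```r
# Screen a conformer database against the recovered hypothesis.
db <- build_screen_db(c(dat$actives, dat$decoys))
head(match_hypothesis(db, hy$results[[1]]$hypothesis, dist_tol = 1.0), 3)
#>   molecule_id conformer_id         rmsd   vec_cos vol_jaccard  fitness
#> 1   active_06            0 2.691232e-15 1.0000000   1.0000000 3.000000
#> 2   active_04            0 6.681255e-02 0.9998808   0.9412025 2.874271
#> 3   active_05            0 1.042256e-01 0.9998143   0.9283201 2.823909
```

The hypothesis's own source conformer matches itself at RMSD 0 with the
maximal fitness of 3; no decoy matches at this tolerance.

```r
# Simulate the GPR142 network and classify the agonist effect at 0.036 uM.
m   <- build_model(network_fixture("gpr142_compound2"))
tab <- read_effect_table()
classify_effect(m, tab[tab$ligand == "Compound2", ])
#> [1] "stimulatory"
#> attr(,"ratio")
#> [1] 11.16898
```

Secreted insulin at 600 s is 11.2-fold the ligand-free baseline
(stimulatory), while the same simulation lowers cAMP to about 7% of
baseline — the dissociation expected from simultaneous Gq activation and
Gi-mediated adenylyl cyclase inhibition.

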