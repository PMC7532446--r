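# druminfo

Woodpeckers advertise species identity with drumming — rapid, rhythmic
beak-striking on resonant substrates. Because a drum is a nearly pure pulse
train, how much *species-identity information* such a signal carries, and how
that information budget evolved as the clade radiated, can be quantified
exactly with information theory. `druminfo` implements that analysis chain
for R users working on bioacoustic signal evolution: it measures the mutual
information between a drum and the species that produced it, reconstructs
drumming types and information content along a time-calibrated phylogeny,
and asks whether ecological communities and sympatry reshape signal
discriminability.

Everything runs on synthetic data generated inside the package (pulse-train
drums for ~92 species with 3–39 drums each, ultrametric birth–death trees,
rectangular geographic ranges), so the full pipeline is testable without any
download; user-supplied drums (long-format CSV) and trees (Newick) drop in
at the same interfaces.

## The statistic at the core

Drums are summarized by 22 temporal/amplitude features, z-scored and reduced
by PCA (components with eigenvalue > 1). A leave-one-out linear discriminant
classification with a uniform class prior yields a row-stochastic confusion
matrix of conditional probabilities p(X_M | X_A) (model species given actual
species). From it:

- local mutual information of species A (bits):
  `MI_L(X_A) = Σ_M p(X_M|X_A) · log2[ p(X_M|X_A) / p(X_M) ]`
- overall information `MI = (1/n_S) Σ_A MI_L(X_A)`, with ceiling
  `log2(n_S)` and normalized MI = MI / ceiling;
- the percent-correct p_c equivalent of an MI value under random
  misclassification,
  `MI = log2 n_s − (1−p_c) log2(n_s−1) + p_c log2 p_c + (1−p_c) log2(1−p_c)`,
  inverted numerically by `pc_from_mi()`;
- the pairwise Classification Index
  `CI(A,B) = ([p(A|A) − p(B|A)] + [p(B|B) − p(A|B)]) / 2 × 100` in
  [−100, 100].

Around this sit: Ward.D2 clustering of species acoustic profiles into
drumming types with majority-rule selection of k; Mk-type ancestral state
reconstruction under six rate models (ER, SYM, ARD and three sequential
models on the order SF↔SS↔DK↔AC↔RS↔IS) averaged by Akaike weights, with
tip priors for uncertain states; Brownian-motion ancestral states and
Pagel's λ; information-through-time bootstrap trajectories; analytic
strong/no diversifying-selection scenarios; and community-level analyses
(sympatry from range overlap, virtual communities, a species-level
permutation test for character displacement).

## Worked example

```r
library(druminfo)

ds <- generate_dataset(n_species = 40, drums_per_species = c(3, 12), seed = 11)
ds <- standardize_and_pca(feature_matrix(ds))
ds <- species_profiles(ds)
ds
#> drum_dataset: 40 species, 258 drums, 6 ground-truth types
#>   features + PCA attached (5 PCs retained, 89% variance)

sc <- pc_scores(ds)
cm <- loo_confusion(sc$scores, sc$labels)
info_summary(cm)
#> MI = 4.153 bits (ceiling 5.322, normalized 78.0%), n = 40 species

permuted_dfa(sc$scores, sc$labels, n_perm = 199, seed = 12)$p_value
#> [1] 0.005                      # classification far above the 2.5% chance level

classification_index(cm, "sp001", "sp002")
#> [1] 41.07317                   # this pair is mutually well classified

# analytic anchors of the information layer
pc_from_mi(2.48, 92)             # 2.48 bits among 92 species ...
#> [1] 0.5318696                  # ... implies 53% correct classification
scenario_trajectory(0.80, 2:3, mode = "none")$p_c[2]
#> [1] 0.64                       # third species, no diversifying selection
```

The clean synthetic clade is far easier to classify than a real one (78%
normalized MI here versus ~38% for real drums); the generator's
`separation` dial moves it continuously toward indistinguishability.

The full chain — generator, features, typing, information, ancestral
reconstruction, information-through-time, communities — is one call:

```r
run_pipeline(run_config(seed = 7), "out/")   # CSV + Newick + JSON outputs
```

or, from a shell, `Rscript inst/scripts/run_pipeline.R --seed 7 --out out/`.

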