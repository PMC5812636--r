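# myofuse

Automated quantitation of myoblast differentiation from double
fluorescent labeling.

Live myoblast cultures (e.g. C2C12) can be engineered to carry one
fluorophore in the cytoplasm and a second, histone-fused fluorophore in
the nucleus, so that myotube formation and nuclei are imaged
simultaneously, in the same fields, day after day — no fixing, no
immunostaining. `myofuse` is for researchers running such assays (drug
screening, myogenesis regulators, scaffold biology) who need the image
analysis automated and testable:

* **nuclei count** per field — detected as sub-pixel blob centroids in
  the nucleus channel (a proxy for growth),
* **fusion index** — the percentage of all nuclei inside fused fibers,

  FI = 100 · (Σ<sub>fibers with ≥3 nuclei</sub> n<sub>nuclei</sub>) / N<sub>total</sub>,

  where a fiber counts as fused only with **three or more** nuclei (two
  nuclei are indistinguishable from a dividing cell),
* **object contrast** for label-combination and scaffold work,
  Contrast = (S − bgd)/bgd with S the mean object intensity and bgd the
  mean background intensity,
* **condition comparison** — per-day one-way ANOVA with
  Bonferroni-adjusted pairwise t-tests (α = 0.05), wells as replicates,
  plus time-to-maximal-fusion summaries of the dynamics.

A built-in simulator renders synthetic double-labeled scenes and whole
plate experiments (growth, saturating fusion kinetics, drug-exposure
schedules, scaffold autofluorescence, camera noise) with exact ground
truth, so the entire pipeline is validated end to end without any
external data.

## Worked example

```r
library(myofuse)

# one synthetic double-labeled field at day 7 of differentiation
sim <- simulateScene(simulationParams(seed = 11), day = 7)
sim$scene
#> Scene: well A1, day 7, condition 'ND', field 0 (384 x 384 px)
sim$groundTruth
#> GroundTruth: 130 nuclei, 15 fiber mask(s), true fusion index 45.4%

# run the full pipeline: detect nuclei, segment fibers, assign, score
sceneMetrics(sim$scene)
#> FusionResult: 130 nuclei, 59 fused (45.4%), 12 fused fiber(s)

# detection quality against the ground truth
det <- detectNuclei(nucleus(sim$scene))
m <- matchDetections(det, trueNuclei(sim$groundTruth), maxDistPx = 3)
c(recall = m$recall, precision = m$precision)
#>    recall precision
#>         1         1
```

The scene holds 130 true nuclei of which 59 sit in fibers of ≥ 3 nuclei
(45.4% fusion); the automated pipeline recovers every nucleus and
reproduces the fusion index exactly on this field. (The 15 ground-truth
masks include ambiguous two-nucleus fibers, which correctly contribute
nothing; 12 fibers are fused.)

Plate-level workflow:

```r
p <- simulationParams(seed = 1)
blocked <- p; blocked@drugEffect <- 0
conds <- list(ND  = list(params = p,       schedule = exposureSchedule("ND")),
              TNF = list(params = blocked, schedule = exposureSchedule("continuous")))
plate <- simulatePlate(conds, nWells = 3, days = c(3L, 7L, 10L), seed = 1)
# ... sceneMetrics() per scene, then:
# tcs <- aggregateResults(resultsTable(results, meta), plate$manifest)
# compareConditions(tcs, day = 10)
```

There is also a command-line interface with `simulate`, `detect`,
`segment`, `analyze`, `contrast` and `compare` subcommands
(`myofuse::runCLI()`; wrapper script in `inst/scripts/myofuse`):

```sh
myofuse simulate --config demo.yaml --out plate/ --seed 5
myofuse analyze plate/ --out results.csv
myofuse compare results.csv plate/manifest.json --day 10 --out cmp
```

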