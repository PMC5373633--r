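# replicyte

Quantitative analysis of nucleoside-analogue DNA-replication labelling
experiments (BrdU/EdU immunofluorescence) in R.

When cells are pulse-labelled with a thymidine analogue such as BrdU, only
S-phase nuclei incorporate it, and the strength and specificity of the
immunofluorescent signal depend critically on the detection protocol — in
particular on how fast the analogue–antibody complex dissociates during
post-antibody washes and whether it is stabilised by a brief formaldehyde
post-fixation. `replicyte` implements the image- and flow-cytometry
quantification used to study these effects, for microscopists and
cytometrists who need a reproducible, scriptable version of the analysis:

* **Nucleus segmentation** from the DAPI channel (Otsu threshold, hole
  filling, watershed splitting of touching nuclei; built on EBImage) and
  **per-nucleus measurement** of mean replication signal and integrated
  DAPI intensity (a DNA-content proxy).
* **The R/non-R ratio**, the core statistic. With labelled fraction *F* and
  *n* nuclei evaluated,

  *R/non-R = mean signal of the (F − 0.1)·n most-labelled nuclei ÷
  mean signal of the (0.9 − F)·n least-labelled nuclei.*

  The 0.1 trimming buffers on both sides exclude borderline nuclei. Ratios
  above 3–4 indicate clear separation of replicating from non-replicating
  cells. The labelled fraction can also be estimated from the data
  (`estimate_f()`, Otsu on log signal, with a reliability flag keyed to
  that 3–4 guideline).
* **Antibody dissociation kinetics**: first-order decay of the specific
  signal during washing, `retained = exp(−k_off · t)`; a least-squares
  fitter for `k_off`; and a formaldehyde concentration–response curve for
  stabilisation efficiency.
* **Bivariate cell-cycle gating** of (replication signal, DNA content)
  events into G1/S/G2M, shared by the image and flow paths.
* A **synthetic-data generator** that simulates labelled populations
  (default: 44% replicating fraction), renders two-channel 16-bit images
  with ground-truth label masks, and emits flow-style event tables — so
  every stage of the pipeline is testable against known truth.

## Worked example

```r
library(replicyte)

truth <- generate_population(population_params(n_cells = 10000, seed = 1),
                             cell_cycle_params())
r_nonr_ratio(truth$true_signal, f = 0.44)
#> R/non-R ratio: 22.509 (f = 0.44)
#>   R group:     n = 3400, mean = 2173.23 a.u.
#>   non-R group: n = 4600, mean = 96.55 a.u.
#>   nuclei evaluated: 10000
```

At *F* = 0.44 and 10,000 nuclei the replicating group holds the 3,400
most-labelled nuclei and the non-replicating group the 4,600
least-labelled; their mean-signal ratio of ~22 is far above the 3–4
separation guideline, as expected for a well-separated simulated
population whose S-phase nuclei average 2,000 a.u. over a 100 a.u.
background.

```r
estimate_f(truth$true_signal)
#> Estimated labelled fraction F = 0.431
#>   threshold = 144.1 a.u.; class-mean separation = 19.93 (reliable)

ev <- generate_flow_events(truth, noise_cv = 0.05, seed = 2)
gate_phases(ev)
#> Cell-cycle gating of 10000 events (G1 peak at 98.3 a.u.)
#>   G1     4549  (45.5%)
#>   S      4315  (43.1%)
#>   G2M    1136  (11.4%)
```

Both the data-driven estimate of the labelled fraction (0.431) and the
gated S fraction (43.1%) recover the simulated 44% replicating fraction;
the G1 peak is found at 98.3 a.u., close to the 100 a.u. 2N setting, so
G2/M events sit near a scaled DNA content of 2.

```r
retained_fraction(log(5) / 5, c(5, 30))
#> [1] 0.2 0.000064
```

With the default dissociation rate (calibrated so a 5-minute wash loses
80% of the specific signal), a 30-minute wash retains essentially nothing
— washing unstabilised samples for half an hour erases the replication
signal, which is why the 0.2% formaldehyde post-fixation step matters.

A full simulate → segment → measure → statistic → gate run, with a JSON
manifest and provenance-stamped CSVs, is one call
(`run_pipeline(default_config(seed = 1), "out/")`) or one shell command
(`Rscript inst/cli/replicyte.R run --seed 1 --out-dir out/`).

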