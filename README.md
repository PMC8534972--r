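# angioflow

Image-based volumetric blood-flow quantification for dialysis (vascular)
access from time-resolved 2-D angiographic sequences — DSA or pulsed
fluoroscopy — using indicator-dilution bolus tracking.

Dialysis fistulas and grafts need roughly 400–600 mL/min to remain usable;
patent accesses run about 300–1000 mL/min. The angiography suite already
films a power-injected contrast bolus during salvage procedures, and those
sequences contain everything needed to estimate flow without extra hardware:

```
Q  =  Ā · d / τ · 60        [mL/min]
```

* **τ** — bolus transit time between two regions of interest (ROIs) on the
  flight path, from the time-density curves `P(t)` at each ROI. Two
  estimators: peak-to-peak (difference of curve-maximum times) and
  cross-correlation (lag maximising `φ(τ) = (1/N) Σ P₁(t)·P₂(t+τ)`), both
  evaluated on a ×100 upsampled grid.
* **d** — traversal distance along the vessel centerline, from row-wise edge
  detection on the maximum-opacification image (12 % relative threshold,
  sub-pixel crossings, stations every 25 px).
* **Ā** — mean circular cross-sectional area over the stations.

Because raw curves are noisy and temporally quantised, a parametric
reference curve is fitted first and evaluated continuously: a **gamma
variate** `Ka(t−AT)^α e^{−(t−AT)/β}`, a **lagged normal** (exponentially
modified Gaussian), or a **6th-degree polynomial**; `none` uses the raw
samples. Fits minimise RMSE by a coarse grid plus pattern-search refinement,
with the linear scale solved in closed form.

The package also ships a seeded synthetic **flow phantom** (straight,
angular, loop tube configurations; plug flow with longitudinal dispersion;
projection rendering with modality-specific noise) whose ground-truth flow,
geometry and timing are known exactly, plus the agreement statistics used to
benchmark methods: absolute percent quantification error (mean ± SEM,
95 % CI), Bland–Altman bias and limits of agreement, Pearson r, paired
t tests.

## Worked example

```r
library(angioflow)

cfg <- phantom_config(true_flow_ml_min = 600, seed = 42)   # DSA, 6 F/s
ph  <- render_sequence(cfg)
rois <- default_rois(ph$truth)          # 20 % and 80 % of the flight path

res <- measure_flow(ph$sequence, rois[[1]], rois[[2]],
                    algorithm = "cc", fit_model = "gamma_variate")
res
#> flow_result: 604.7 mL/min (CC + gamma_variate, DSA at 6 samples/s)
#>   tau = 0.4917 s, distance = 16.77 cm, mean area = 0.2955 cm^2

true_transit_s(ph$truth)
#> [1] 0.4738213
absolute_percent_error(res$flow_ml_min, 600)
#> [1] 0.7834947
```

The phantom carries 600 mL/min; the pipeline recovers 604.7 mL/min (0.8 %
error): the bolus needed 0.49 s for the 16.8 cm between the ROIs through a
measured mean lumen of 0.30 cm².

Method comparison on a shared set of noisy acquisitions:

```r
cond <- data.frame(shape = "straight", modality = "DSA", sampling_rate = 6)
meth <- data.frame(algorithm = c("cc", "pp"),
                   fit_model = c("gamma_variate", "gamma_variate"))
bench <- run_benchmark(cond, meth, n_reps = 20, seed = 1)
summarize_benchmark(bench)
```

A thin command-line wrapper is provided for shell use:

```sh
Rscript scripts/angioflow.R simulate --shape straight --flow 600 --rate 6 --seed 42 --out phantom.afs
# phantom_truth.json lists the ground truth and the default ROI boxes:
Rscript scripts/angioflow.R measure --input phantom.afs --roi1 195,206,75,86 \
    --roi2 754,765,75,86 --algorithm cc --fit gv --out result.json
Rscript scripts/angioflow.R evaluate --config grid.cfg --out bench.csv
```

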