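# trijunct

Spatially resolved quantification of tricellular tight-junction (tTJ)
maturity in epithelial monolayers, from multichannel fluorescence images.

## The problem

Epithelial monolayers mature through a **jamming transition**: cells
densify, become rounder and stop moving, and their junctions mature. At
every vertex where three cells meet, a tricellular tight junction forms as
**tricellulin** concentrates from the bicellular junctions into a punctate
vertex pattern. The degree of that concentration is a per-vertex readout
of junctional maturity, complementary to the classic cell-shape
descriptors of jamming. `trijunct` is for cell biologists and biophysicists
who image monolayers (MDCK and similar) with a junctional marker (e.g.
ZO-1), a tricellular marker (e.g. tricellulin) and a nuclear stain, and
want unbiased, spatially resolved maturity maps instead of qualitative
inspection.

## The measurement

The junctional channel is binarized and thinned to a one-pixel skeleton;
crossings of the skeleton are the candidate tricellular nodes, refined to
the nearest tricellular point source. Cells are segmented as the
components of the skeleton complement and summarized by the jamming
descriptors

- apical shape index  *q*<sub>a</sub> = *p*<sub>a</sub> / √*A*<sub>a</sub>
  (isoperimetric floor 2√π ≈ 3.545; lower and more uniform = more jammed),
- aspect ratio AR and its SD across the monolayer,
- density σ in cells/mm².

Each vertex gets the **tricellulin localization score**

> *T*<sub>L</sub> = *I*<sub>tri</sub> / (*I*<sub>tri</sub> + *I*<sub>bi</sub>) ∈ [0, 1]

where *I*<sub>tri</sub> is the mean contrast-adjusted tricellular
intensity in a small disc at the vertex and *I*<sub>bi</sub> the mean
along its incident bicellular junctions. 0.5 means no enrichment, values
toward 1 mean mature, punctate tTJs, values toward 0 mean exclusion from
the vertex (e.g. leader cells at a wound edge). Group analyses cover
wound-front rows (leader = row 1, followers ranked by adjacency
distance), cell-cycle triplets, Kolmogorov–Smirnov comparisons and
normalization to a control group.

A synthetic epithelium generator (centroidal Voronoi tessellations with
rendered boundary lines, vertex punctae of controllable enrichment,
nuclei, noise, and optional z-stacks with per-block focus variation)
provides exact ground truth — true vertices, polygons, adjacency and a
rendered-image score oracle — so the whole pipeline is testable without
microscopy data.

## Worked example

```r
library(trijunct)

spec <- tessellation_spec(n_cells = 25, image_size = c(256, 256), seed = 3,
                          enrichment = 2, noise_sd = 10)
out <- run_pipeline(run_config(simulation = spec, pixel_size = 0.3))
out$summary
#>  n_cells    sigma mean_q_a  mean_AR     sd_AR mean_area_um2
#>       10 4381.007 4.043524 1.392008 0.1758949       218.295

vs <- out$vertex_scores
sprintf("scored %d of %d vertices; median T_L = %.3f",
        sum(!vs$unscorable), nrow(vs), median(vs$T_L, na.rm = TRUE))
#> "scored 30 of 33 vertices; median T_L = 0.679"

head(out$geometry[!out$geometry$border, c("id", "A_um2", "p_um", "q_a", "AR")], 3)
#>    id   A_um2     p_um      q_a       AR
#> 7   7 203.580 55.91663 3.918984 1.435587
#> 8   8 184.095 53.19314 3.920439 1.190710
#> 10 10 217.530 56.78527 3.850137 1.187070
```

The monolayer here is simulated at enrichment ρ = 2 (puncta peak twice the
boundary intensity), and the recovered median *T*<sub>L</sub> ≈ 0.68
matches the generator's rendered-image oracle for that enrichment. The 10
interior cells sit at σ ≈ 4400 cells/mm² with mean *q*<sub>a</sub> ≈ 4.0 —
compact, near-jammed geometry. `render_map()` draws the per-cell
*q*<sub>a</sub> or *T*<sub>L</sub> maps; `assign_rows()`,
`rowwise_profile()`, `triplet_by_label()`, `compare_groups()` and
`normalize_to_control()` cover the group analyses.

Real images enter through `run_config(zo1 =, tric =, nuclei =)` with
single- or multi-page TIFFs; z-stacks are reduced by the ZO-1-guided
block projection automatically. A thin CLI wraps the same functions:

```sh
Rscript exec/trijunct simulate --n-cells 25 --size 512 --rho 2 --seed 1 --out sim/
Rscript exec/trijunct run --simulate --n-cells 25 --size 512 --rho 2 --noise-sd 10 --seed 1 --out results/
```

## Documentation

The methods vignette (`vignettes/trijunct-methods.Rmd`) describes the
model and its assumptions, every tunable parameter with units and
defaults, the estimator calibrations, what the synthetic generator does
and does not emulate, and known limitations.
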