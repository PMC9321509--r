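# espmcr

Construction of **ecological security patterns** (ESP) from raster
landscapes with the **minimum cumulative resistance** (MCR) model.

Landscape planners identify the "point–line–plane" skeleton that keeps a
region's ecological processes connected: large high-value habitat patches
(*ecological sources*), the least-cost movement routes between them
(*ecological corridors*), the bottlenecks where movement concentrates
(*pinch points / ecological nodes*), and a zoning of the territory by
ecological safety. `espmcr` implements that entire workflow as composable R
functions, plus a seeded synthetic-landscape generator so the pipeline can
be exercised and tested end to end without any external data.

## The method

1. **Multi-criteria evaluation.** Six factor rasters are graded onto the
   ordinal scale {1, 3, 5, 7, 9} and combined into three ecological
   sensitivity indices — sensitivity to soil-and-water loss
   `SSWL = (R·K·LS·C)^{1/4}`, soil-erosion sensitivity
   `SSE = mean(LS, R, K, C)`, and land-desertification sensitivity
   `SLD = (I·W·K·C)^{1/4}` — where `R` is rainfall erosivity
   (`R = Σ_i (−2.6398 + 0.3046·P_i)` over the twelve mean monthly
   rainfalls), `K` soil texture, `LS` topographic relief (37×37-cell focal
   range of the DEM), `C` vegetation coverage, `I` aridity and `W`
   sand-blowing days. Three ecosystem-service importance indices are
   computed from normalized inputs: water retention
   `WR = NPP·F_sic·F_pre·(1−F_sio)`, soil conservation
   `Spro = NPP·(1−K)·(1−F_sio)` and biodiversity maintenance
   `Sbio = NPP·F_pre·F_tem·(1−F_alt)`.
2. **AHP weighting.** Composite layers use Analytic-Hierarchy-Process
   weights (sensitivity 0.43/0.39/0.18, services 0.45/0.30/0.25) with full
   Saaty consistency diagnostics: `CI = (λ_max − n)/(n − 1)`,
   `CR = CI/RI(n)`, acceptable when `CR < 0.1`.
3. **Sources.** The superposed environment score is classified into five
   classes by Jenks natural breaks (Fisher's optimal partition);
   extremely-important patches closer than 500 m are merged, and merged
   patches larger than 8 km² become ecological sources.
4. **Resistance and corridors.** Five factors (land use, vegetation
   coverage, slope, distance to county roads, distance to highways) are
   reclassified to resistance values {1, 20, 40, 60, 80, 100} and overlaid
   with weights (0.095, 0.213, 0.236, 0.118, 0.173). Cost distance
   `MCR = min Σ D_ij · R_i` is computed by multi-source Dijkstra over the
   8-connected cell graph; corridors are least-cost paths between
   allocation-adjacent sources.
5. **Pinch points and zoning.** Each corridor's low-cost swath is solved as
   a resistive network (sparse graph-Laplacian solve) to map current flow;
   important nodes are high-current patches above 1 km². The cumulative
   cost surface is classified into five ecological-safety zones and mapped
   to conservation / control / restoration policy areas.

## Worked example

```r
library(espmcr)

# AHP diagnostics of the five-factor resistance comparison matrix
ahp_consistency(resistance_comparison_matrix())
#> AHP: lambda_max = 5.1883, CI = 0.0471, CR = 0.0420 (consistent, CR < 0.1)
#> weights: 0.0477 0.3160 0.3705 0.1021 0.1637

# full pipeline on a 200 x 200 synthetic landscape (1 km cells)
cfg <- default_pipeline_config()
cfg$seed <- 42L
man <- run_pipeline(cfg)
man$stages$sources$n_sources        # 5   sources recovered
man$stages$sources$total_area_km2   # 221 km2 of source area
man$stages$corridors$n_corridors    # 8   least-cost corridors
man$stages$corridors$n_important_nodes  # 14 pinch-point patches
unlist(man$stages$zones$policy_percent)
#> conservation      control  restoration
#>       14.363       50.542       35.095
```

The generator plants five high-value habitat patches (elevated NPP,
rainfall and relief); the run above recovers exactly those five as
ecological sources, links them with eight corridors, and partitions the
landscape into safety zones whose areas sum to 100%.

A command-line wrapper is included at `inst/exec/esp-pipeline.R`
(`--config`, `--stages`, `--seed`, `--out`).

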