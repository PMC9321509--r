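#' Default pipeline configuration
#'
#' All tunable parameters of the ecological-security-pattern pipeline with
#' their default values: composite weights (sensitivity 0.43/0.39/0.18,
#' service 0.45/0.30/0.25, superposition 0.5/0.5), grading and resistance
#' band tables, the source rules (patches merged below a 500 m gap, kept
#' above 8 km2), relief window (37 cells), corridor mode and swath slack,
#' node area threshold (1 km2), number of classes (5) and the zone-to-policy
#' mapping. Synthetic-run fields (`seed`, `n_rows`, `n_cols`, `cellsize`)
#' control generation when no `input_dir` is given.
#'
#' @return a named list; override entries before passing to [run_pipeline()]
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L, n_rows = 200L, n_cols = 200L, cellsize = 1000,
    input_dir = NULL, out_dir = NULL,
    sensitivity_weights = c(0.43, 0.39, 0.18),
    service_weights = c(0.45, 0.30, 0.25),
    superposition_weights = c(0.5, 0.5),
    classes = 5L,
    relief_window = 37L,
    merge_gap_m = 500,
    min_source_area_km2 = 8,
    corridor_mode = "adjacent_pairs",
    swath_percentile = 0.05,
    node_min_area_km2 = 1,
    zone_policy = c("conservation", "control", "control",
                    "restoration", "restoration"),
    resistance_weights = NULL   # NULL = printed defaults
  )
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over [default_pipeline_config()];
#' unknown keys are rejected.
#'
#' @param path YAML file path
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  cfg
}

read_bundle <- function(dir) {
  grids <- list()
  for (nm in c("dem", "npp", "temperature", "aridity", "wind_days",
               "soil_texture", "landuse", "vegcover"))
    grids[[nm]] <- read_grid(file.path(dir, paste0(nm, ".asc")))
  grids$monthly_precip <- lapply(1:12, function(m)
    read_grid(file.path(dir, sprintf("precip_%02d.asc", m))))
  grids$roads <- list(
    county = read_segments(file.path(dir, "roads_county.txt")),
    highway = read_segments(file.path(dir, "roads_highway.txt")))
  grids$truth <- NULL
  class(grids) <- "esp_landscape"
  grids
}

#' Run the ecological-security-pattern pipeline
#'
#' Executes the requested stages in framework order: `assess` (sensitivity,
#' service importance and their superposition), `sources` (extremely
#' important patches, merged and area-filtered), `resistance`
#' (reclassified factors and weighted overlay), `corridors` (cost
#' distance, least-cost network, per-corridor current flow, node
#' extraction) and `zones` (safety zoning and policy partition). Inputs
#' come from `config$input_dir` if set, otherwise a synthetic landscape is
#' generated from `config$seed`. When `config$out_dir` is set, the key
#' intermediate grids are written as ASCII grids, later stages can restart
#' from them, and the manifest is saved as YAML.
#'
#' A requested stage whose prerequisite was neither requested nor found on
#' disk fails with an error naming the stage to run first. Two runs with
#' the same configuration produce identical outputs (and checksums).
#'
#' @param config configuration list, see [default_pipeline_config()]
#' @param stages character subset of
#'   `c("assess", "sources", "resistance", "corridors", "zones")`
#' @return the manifest: parameters, per-stage summaries, and file
#'   checksums when `out_dir` is set
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         stages = c("assess", "sources", "resistance",
                                    "corridors", "zones")) {
  all_stages <- c("assess", "sources", "resistance", "corridors", "zones")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  emit <- function(grid, name) {
    if (!is.null(out)) write_grid(grid, file.path(out, paste0(name, ".asc")))
  }
  need <- function(stage, dep, loader) {
    # prerequisite product: computed this run, or reloadable from out_dir
    file_first <- if (!is.null(out)) loader() else NULL
    if (!is.null(file_first)) return(file_first)
    stop(sprintf("stage '%s' needs the output of stage '%s'; run '%s' first",
                 stage, dep, dep), call. = FALSE)
  }
  maybe_read <- function(name) {
    if (is.null(out)) return(NULL)
    p <- file.path(out, paste0(name, ".asc"))
    if (file.exists(p)) read_grid(p) else NULL
  }

  bundle <- if (!is.null(config$input_dir)) read_bundle(config$input_dir)
            else make_landscape(config$seed, config$n_rows, config$n_cols,
                                config$cellsize)
  manifest <- list(parameters = config[setdiff(names(config), "out_dir")],
                   stages = list())

  assessment <- NULL; sources <- NULL; surface <- NULL
  network <- NULL; nodes <- NULL

  if ("assess" %in% stages) {
    r_raw <- rainfall_erosivity(bundle$monthly_precip)
    ls_raw <- focal_range(bundle$dem, config$relief_window)
    annual_precip <- Reduce(`+`, bundle$monthly_precip)
    slope <- slope_from_dem(bundle$dem)

    g <- list(R = grade_factor(r_raw, "R"),
              LS = grade_factor(ls_raw, "LS"),
              C = grade_factor(bundle$vegcover, "C"),
              K = grade_factor(bundle$soil_texture, "soil_texture"),
              I = grade_factor(bundle$aridity, "I"),
              W = grade_factor(bundle$wind_days, "W"))
    s1 <- sswl(g$R, g$K, g$LS, g$C)
    s2 <- sse(g$LS, g$R, g$K, g$C)
    s3 <- sld(g$I, g$W, g$K, g$C)
    sens <- composite_sensitivity(s1, s2, s3, config$sensitivity_weights)

    npp_n <- minmax_normalize(bundle$npp)
    fpre <- minmax_normalize(annual_precip)
    ftem <- minmax_normalize(bundle$temperature)
    falt <- minmax_normalize(bundle$dem)
    fsic <- fsic_from_texture(bundle$soil_texture)
    fsio <- grid_like(slope, slope$values / 90)
    k_norm <- grid_like(g$K$grid, g$K$grid$values / 9)
    wr <- water_retention(npp_n, fsic, fpre, fsio)
    spro <- soil_conservation(npp_n, k_norm, fsio)
    sbio <- biodiversity_service(npp_n, fpre, ftem, falt)
    imp <- composite_importance(wr, spro, sbio, config$service_weights)

    assessment <- superpose_environment(sens, imp,
                                        config$superposition_weights,
                                        config$classes)
    emit(sens, "sensitivity"); emit(imp, "importance")
    emit(assessment$environment_class, "environment_class")
    cls_share <- function(g) {
      tab <- table(g$values)
      stats::setNames(round(100 * as.numeric(tab) / sum(tab), 2), names(tab))
    }
    manifest$stages$assess <- list(
      sensitivity_class_percent = as.list(cls_share(assessment$sensitivity_class)),
      importance_class_percent = as.list(cls_share(assessment$importance_class)),
      environment_class_percent = as.list(cls_share(assessment$environment_class)))
  }

  if ("sources" %in% stages) {
    env_class <- if (!is.null(assessment)) assessment$environment_class
                 else need("sources", "assess",
                           function() maybe_read("environment_class"))
    patches <- label_patches(env_class, config$classes)
    merged <- merge_nearby(patches, config$merge_gap_m)
    sources <- filter_by_area(merged, config$min_source_area_km2)
    comp <- landuse_composition(sources, bundle$landuse)
    emit(sources$label_grid, "sources")
    manifest$stages$sources <- list(
      n_sources = nrow(sources$patches),
      total_area_km2 = sum(sources$patches$area_km2),
      landuse_percent = stats::setNames(as.list(round(comp$percent, 2)),
                                        paste0("class_", comp$class)))
  }

  if ("resistance" %in% stages) {
    slope <- slope_from_dem(bundle$dem)
    road_all <- bundle$roads
    d_county <- euclidean_distance(bundle$dem, road_all$county)
    d_highway <- euclidean_distance(bundle$dem, road_all$highway)
    factors <- list(
      landuse = reclass_factor(bundle$landuse, "landuse"),
      vegcover = reclass_factor(bundle$vegcover, "vegcover"),
      slope = reclass_factor(slope, "slope"),
      dist_county_road = reclass_factor(d_county, "dist_county_road"),
      dist_highway = reclass_factor(d_highway, "dist_highway"))
    w <- if (is.null(config$resistance_weights)) resistance_weights()
         else config$resistance_weights
    surface <- weighted_overlay(factors, w)
    emit(surface$grid, "resistance")
    v <- surface$grid$values
    manifest$stages$resistance <- list(
      weights = as.list(surface$weights),
      min = min(v, na.rm = TRUE), max = max(v, na.rm = TRUE))
  }

  if ("corridors" %in% stages) {
    if (is.null(sources)) {
      src_grid <- need("corridors", "sources", function() maybe_read("sources"))
      sources <- new_patchset(src_grid, src_grid$cellsize)
    }
    if (is.null(surface)) {
      surf_grid <- need("corridors", "resistance",
                        function() maybe_read("resistance"))
      surface <- structure(list(grid = surf_grid,
                                weights = resistance_weights()),
                           class = "esp_resistance")
    }
    network <- corridor_network(surface, sources, config$corridor_mode)
    lab <- sources$label_grid$values
    currents <- lapply(Filter(function(co) !isTRUE(co$disconnected),
                              network$corridors),
                       function(co) current_flow(surface, lab == co$a,
                                                 lab == co$b,
                                                 config$swath_percentile))
    nodes <- if (length(currents))
      extract_nodes(currents, config$node_min_area_km2) else NULL
    if (!is.null(nodes)) emit(nodes$current, "current")
    if (!is.null(network$costdist)) emit(network$costdist$cost, "cost")
    manifest$stages$corridors <- list(
      n_corridors = network$n_corridors,
      total_length_m = network$total_length_m,
      n_important_nodes = if (is.null(nodes)) 0L
                          else nrow(nodes$important_nodes$patches))
  }

  if ("zones" %in% stages) {
    cd_cost <- if (!is.null(network) && !is.null(network$costdist)) {
      network$costdist$cost
    } else if (!is.null(sources) && !is.null(surface)) {
      cost_distance(surface, sources)$cost
    } else {
      need("zones", "corridors", function() maybe_read("cost"))
    }
    zones <- safety_zones(cd_cost, config$classes)
    policy <- policy_partition(zones, config$zone_policy)
    emit(zones$zone_grid, "zones"); emit(policy$policy_grid, "policy")
    manifest$stages$zones <- list(
      zone_percent = stats::setNames(as.list(round(zones$areas$percent, 3)),
                                     paste0("zone_", zones$areas$zone)),
      policy_percent = stats::setNames(as.list(round(policy$areas$percent, 3)),
                                       policy$areas$policy))
  }

  if (!is.null(out)) {
    files <- sort(list.files(out, pattern = "\\.asc$", full.names = TRUE))
    manifest$checksums <- as.list(tools::md5sum(files))
    names(manifest$checksums) <- basename(files)
    yaml::write_yaml(manifest, file.path(out, "manifest.yml"))
  }
  invisible(manifest)
}
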