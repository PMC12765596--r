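#' Full-pipeline configuration
#'
#' Bundles every stage's parameters with paper-grade defaults: MSPA with
#' foreground connectivity 4 and edge width 1; the six-indicator niche
#' overlay with a 0.4 optimal-source threshold; the seven-factor weighted
#' resistance table; all-pairs least-cost corridors with 95% containment
#' deduplication; 95th-percentile ridge/valley channels with a 2-cell node
#' merge radius; and 200-m altitudinal bands.
#'
#' @param landscape an [landscape_config()] (its `seed` is the run seed).
#' @param mspa an [mspa_params()].
#' @param niche an [niche_config()].
#' @param resistance an [resistance_config()].
#' @param foreground_classes land-use codes forming the MSPA foreground.
#' @param min_area_km2 minimum source-patch area (km^2).
#' @param containment corridor-containment dedup threshold.
#' @param channel_percentile ridge/valley accumulation percentile.
#' @param merge_radius_cells node merge radius (cells).
#' @param band_width_m altitudinal band width (m).
#' @return an object of class `esp_run_config`.
#' @export
esp_config <- function(landscape = landscape_config(),
                       mspa = mspa_params(),
                       niche = niche_config(),
                       resistance = resistance_config(),
                       foreground_classes = ecological_classes(),
                       min_area_km2 = 0.5,
                       containment = 0.95,
                       channel_percentile = 95,
                       merge_radius_cells = 2,
                       band_width_m = 200) {
  structure(as.list(environment()), class = "esp_run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full ESP comparison pipeline
#'
#' Executes, end to end: landscape generation (or a supplied bundle), MSPA
#' classification of the ecological-land foreground, the niche-suitability
#' overlay, the three source strategies (ESP1 connectivity, ESP2 reserves,
#' ESP3 integrated + niche filter), the resistance surface, per-strategy
#' corridors, ridge/valley ecological nodes, connectivity indices and
#' altitudinal profiles. When `out_dir` is given every artefact is written
#' (ESRI ASCII rasters, GeoJSON vectors, CSV tables) together with a
#' manifest of MD5 checksums; identical config and seed reproduce identical
#' checksums. A failing stage aborts with the stage name and leaves a
#' `FAILED` marker in the output directory.
#'
#' @param config an [esp_config()].
#' @param bundle optional pre-built `esp_landscape` (skips generation).
#' @param out_dir optional output directory.
#' @param strategies subset of `c("ESP1", "ESP2", "ESP3")` to run.
#' @return an `esp_run` list: bundle, mspa grid, niche result, per-strategy
#'   sources, corridors, nodes, indices (one data.frame row per strategy),
#'   profiles, and the manifest (when written).
#' @export
run_esp <- function(config = esp_config(), bundle = NULL, out_dir = NULL,
                    strategies = c("ESP1", "ESP2", "ESP3")) {
  stopifnot(inherits(config, "esp_run_config"))
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  on_fail_marker <- function() {
    if (!is.null(out_dir))
      writeLines("pipeline failed; partial outputs retained",
                 file.path(out_dir, "FAILED"))
  }
  run <- tryCatch({
    if (is.null(bundle))
      bundle <- stage("generate", generate_landscape(config$landscape))

    fg <- stage("mspa", {
      lu <- bundle$landuse$values
      grid_like(bundle$landuse,
                matrix(as.numeric(!is.na(lu) &
                                    lu %in% config$foreground_classes),
                       nrow(lu), ncol(lu)))
    })
    mspa_grid <- stage("mspa", classify_mspa(fg, config$mspa))

    niche <- stage("niche", comprehensive_niche(
      compute_indicators(bundle), config$niche))

    esp1 <- stage("sources", sources_connectivity(mspa_grid,
                                                  config$min_area_km2))
    esp2 <- stage("sources", sources_reserves(bundle$reserves, bundle$dem))
    esp3 <- stage("sources", sources_integrated(esp1, esp2, niche,
                                                config$min_area_km2))
    sources <- list(ESP1 = esp1, ESP2 = esp2, ESP3 = esp3)

    resistance <- stage("resistance", build_resistance(
      resistance_factors(bundle, mspa_grid, config$resistance),
      config$resistance))

    ridge <- stage("nodes", extract_channels(resistance, invert = TRUE,
                                             config$channel_percentile))
    valley <- stage("nodes", extract_channels(resistance, invert = FALSE,
                                              config$channel_percentile))

    corridors <- list(); nodes <- list(); indices <- list()
    profiles <- list()
    for (s in strategies) {
      corridors[[s]] <- stage(paste0("corridors ", s),
                              extract_corridors(sources[[s]], resistance,
                                                config$containment))
      nodes[[s]] <- stage(paste0("nodes ", s),
                          locate_nodes(corridors[[s]], ridge, bundle$roads,
                                       valley, config$merge_radius_cells))
      net <- stage(paste0("metrics ", s),
                   build_network(corridors[[s]], sources[[s]]))
      idx <- connectivity_indices(net)
      idx$strategy <- s
      idx$source_area_km2 <- sources[[s]]$total_area_km2
      idx$n_sources <- length(sources[[s]]$patch_ids)
      idx$n_nodes <- nrow(nodes[[s]])
      indices[[s]] <- idx
      profiles[[s]] <- stage(paste0("zonation ", s),
                             band_profile(bundle$dem, sources[[s]],
                                          corridors[[s]], nodes[[s]],
                                          bundle$landuse,
                                          config$band_width_m))
    }
    list(bundle = bundle, mspa = mspa_grid, niche = niche,
         sources = sources, resistance = resistance, ridge = ridge,
         valley = valley, corridors = corridors, nodes = nodes,
         indices = do.call(rbind, indices), profiles = profiles,
         config = config)
  }, error = function(e) { on_fail_marker(); stop(e) })

  if (!is.null(out_dir)) run$manifest <- write_run(run, out_dir)
  class(run) <- "esp_run"
  run
}

#' @export
print.esp_run <- function(x, ...) {
  cat("<esp_run>\n")
  print(x$indices[, c("strategy", "L", "V", "C_km", "alpha", "beta",
                      "gamma", "cost_ratio")], row.names = FALSE)
  invisible(x)
}

# serialize every artefact and return the checksum manifest
write_run <- function(run, out_dir) {
  paths <- character(0)
  wg <- function(g, name) {
    p <- file.path(out_dir, name)
    write_grid(g, p)
    paths <<- c(paths, p)
  }
  wf <- function(f, name) {
    p <- file.path(out_dir, name)
    write_features(f, p)
    paths <<- c(paths, p)
  }
  wc <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  b <- run$bundle
  for (nm in c("dem", "landuse", "ndvi", "npp", "temperature",
               "precipitation", "soil_k", "soil_texture", "nightlight",
               "rainfall_erosivity", "sandstorm_days", "dryness"))
    wg(b[[nm]], paste0(nm, ".asc"))
  wf(b$roads, "roads.geojson")
  wf(b$reserves, "reserves.geojson")
  wg(run$mspa, "mspa_classes.asc")
  wc(mspa_summary(run$mspa), "mspa_summary.csv")
  wg(run$niche$niche, "niche.asc")
  wg(run$niche$mask, "niche_mask.asc")
  wg(run$resistance, "resistance.asc")
  wg(run$ridge, "ridge_lines.asc")
  wg(run$valley, "valley_lines.asc")
  for (s in names(run$sources)) {
    wg(run$sources[[s]]$label_grid, paste0("sources_", tolower(s), ".asc"))
    comp <- source_composition(run$sources[[s]], b$landuse)
    wc(comp$overall, paste0("composition_", tolower(s), ".csv"))
  }
  for (s in names(run$corridors)) {
    wf(corridors_to_features(run$corridors[[s]]),
       paste0("corridors_", tolower(s), ".geojson"))
    if (nrow(run$nodes[[s]]))
      wf(nodes_to_features(run$nodes[[s]]),
         paste0("nodes_", tolower(s), ".geojson"))
    wc(run$profiles[[s]], paste0("zonation_", tolower(s), ".csv"))
  }
  wc(run$indices, "metrics.csv")
  sums <- tools::md5sum(paths)
  manifest <- data.frame(file = basename(names(sums)), md5 = unname(sums),
                         row.names = NULL)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}
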