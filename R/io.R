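#' Default resolved configuration
#'
#' All model constants default to their printed values: activation sigma 8
#' and mu 1/2; LTD/LTP rates 4e-6 and 0.3e-6 per step; spontaneous CF rate
#' 0.05; control period 10 ms; per-hemisphere populations 257 MF / 27 GO /
#' 4000 GC / 267 BC / 1 PC; the per-plant PD gains and MF scaling gains.
#'
#' @return nested named list
#' @export
default_config <- function() {
  list(
    cells = list(MF = 257L, GO = 27L, GC = 4000L, BC = 267L, PC = 1L),
    cube_edge_um = 100,
    activation = list(sigma = 8, mu = 0.5),
    plasticity = list(gamma_ltd = 4e-6, gamma_ltp = 0.3e-6,
                      cf_spont = 0.05),
    control = list(dt = 0.01, n_sub = 10L, noise_sd = 0),
    seeds = list(placement = 1L, connectivity = 1L, weights = 1L,
                 knockdown = 1L, noise = 1L),
    plant = list(
      dc_motor = c(unclass(dc_motor_params())[-1],
                   pd_gains("dc_motor"), list(g_cb = 0.5, g_pref = 1.0)),
      robot = c(unclass(robot_params())[-1],
                pd_gains("robot"), list(g_cb = 2.0, g_pref = 10)),
      quad = c(unclass(quad_params())[-1],
               pd_gains("quad"), list(g_cb = 1.0, g_pref = 5))
    )
  )
}

# Recursive merge of an override list into defaults; unknown keys are
# rejected with their full path.
merge_config <- function(defaults, overrides, path = "") {
  for (key in names(overrides)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      stop("unknown configuration key: ", full)
    }
    if (is.list(defaults[[key]]) && is.list(overrides[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], overrides[[key]],
                                      full)
    } else {
      old <- defaults[[key]]
      new <- overrides[[key]]
      if (is.numeric(old) && !is.numeric(new)) {
        stop("configuration key ", full, " expects a numeric value")
      }
      defaults[[key]] <- new
    }
  }
  defaults
}

#' Load a configuration file
#'
#' Reads a YAML file of overrides and resolves it against
#' [default_config()]. An empty or missing-override file yields pure
#' defaults; unknown keys raise an error naming the key.
#'
#' @param path YAML file path, or NULL for pure defaults
#' @return resolved configuration list
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  ov <- yaml::read_yaml(path)
  if (is.null(ov)) return(cfg)
  merge_config(cfg, ov)
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Serialize a hemisphere network to plain-text tables
#'
#' Writes three files into `dir`: `cells.csv` (kind, index, x, y, z),
#' `edges.csv` (projection, target, source, weight_raw printed to full
#' double precision) and `meta.json` (counts, cube edge, seeds, activation
#' parameters, knockdown state, fan-in table). [read_network()] restores a
#' bit-identical network.
#'
#' @param net a `hemisphere_net`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_network <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cells <- do.call(rbind, lapply(cell_kinds(), function(k) {
    p <- net$layouts[[k]]$positions
    if (nrow(p) == 0L) return(NULL)
    data.frame(kind = k, index = seq_len(nrow(p)),
               x = fmt17(p[, 1]), y = fmt17(p[, 2]), z = fmt17(p[, 3]))
  }))
  data.table::fwrite(cells, file.path(dir, "cells.csv"))
  edges <- do.call(rbind, lapply(names(net$syn), function(p) {
    g <- net$syn[[p]]
    n_t <- nrow(g$conn)
    if (n_t == 0L) return(NULL)
    data.frame(projection = p,
               target = rep(seq_len(n_t), ncol(g$conn)),
               source = as.integer(g$conn),
               weight_raw = fmt17(g$raw), sign = g$sign)
  }))
  data.table::fwrite(edges, file.path(dir, "edges.csv"))
  meta <- list(counts = as.list(net$counts), edge_um = net$edge_um,
               seeds = net$seeds, sigma = net$sigma, mu = net$mu,
               active = which(net$active), comp_scale = net$comp_scale,
               fan_tab = net$fan_tab)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Restore a hemisphere network written by [write_network()]
#'
#' @param dir directory holding `cells.csv`, `edges.csv`, `meta.json`
#' @return a `hemisphere_net`
#' @export
read_network <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  cells <- data.table::fread(file.path(dir, "cells.csv"),
                             colClasses = list(character = c("x", "y",
                                                             "z")))
  edges <- data.table::fread(file.path(dir, "edges.csv"),
                             colClasses = list(character = "weight_raw"))
  counts <- vapply(cell_kinds(), function(k)
    as.integer(meta$counts[[k]]), integer(1))
  layouts <- list()
  for (k in cell_kinds()) {
    sub <- cells[cells$kind == k, ]
    sub <- sub[order(sub$index), ]
    pos <- cbind(x = as.numeric(sub$x), y = as.numeric(sub$y),
                 z = as.numeric(sub$z))
    layouts[[k]] <- structure(list(kind = k, count = counts[[k]],
                                   positions = pos,
                                   edge_um = meta$edge_um),
                              class = "population_layout")
  }
  fan_tab <- as.data.frame(meta$fan_tab)
  d_tab <- normalizers(fan_tab)
  syn <- list()
  for (i in seq_len(nrow(fan_tab))) {
    p <- fan_tab$proj[i]
    sub <- edges[edges$projection == p, ]
    n_t <- max(sub$target)
    f <- fan_tab$fan_in[i]
    conn <- matrix(0L, n_t, f)
    raw <- matrix(0, n_t, f)
    # edges.csv stores column-major order of the original matrices
    conn[] <- sub$source
    raw[] <- as.numeric(sub$weight_raw)
    d <- d_tab[[paste(fan_tab$dst[i], fan_tab$sign[i], sep = ".")]]
    syn[[p]] <- list(proj = p, sign = fan_tab$sign[i], conn = conn,
                     raw = raw, d = d, w = raw * d)
  }
  active <- rep(FALSE, counts[["GC"]])
  active[unlist(meta$active)] <- TRUE
  # recompute the compensation exactly from the mask (JSON may round it)
  comp <- if (all(active)) 1 else counts[["GC"]] / sum(active)
  structure(list(counts = counts, edge_um = meta$edge_um,
                 seeds = meta$seeds, fan_tab = fan_tab, layouts = layouts,
                 syn = syn, sigma = as.numeric(meta$sigma),
                 mu = as.numeric(meta$mu),
                 active = active, comp_scale = comp),
            class = "hemisphere_net")
}

#' Build a run manifest
#'
#' A manifest captures everything needed to reproduce one closed-loop run
#' bit-exactly: plant, population counts, GC knockdown size, cycle count,
#' master seed and the control-gain overrides.
#'
#' @param plant one of "dc_motor", "robot", "quad"
#' @param gc_size active GCs per hemisphere
#' @param n_cycles cycles to run
#' @param base_seed master seed
#' @param counts per-hemisphere population counts
#' @param overrides optional named list of `control_config` overrides
#'   (g_cb, g_pref, g_np)
#' @return list of class `run_manifest`
#' @export
run_manifest <- function(plant, gc_size, n_cycles, base_seed = 1L,
                         counts = default_counts(), overrides = list()) {
  structure(list(
    package_version = as.character(utils::packageVersion("bicnn")),
    created = format(Sys.time(), tz = "UTC"),
    plant = plant, counts = as.list(counts),
    gc_size = as.integer(gc_size), n_cycles = as.integer(n_cycles),
    base_seed = as.integer(base_seed), overrides = overrides),
    class = "run_manifest")
}

#' Execute (or replay) a run manifest
#'
#' Builds the model from the manifest's seeds, applies the knockdown and
#' runs the trial. Replaying the same manifest reproduces every numeric
#' output bit-exactly. A manifest written by a different package version is
#' replayed best-effort with a warning.
#'
#' @param manifest a `run_manifest` (or a list read back from JSON)
#' @param record_traces,record_weights trace/weight recording flags
#' @return a `trial_record`
#' @export
replay <- function(manifest, record_traces = FALSE,
                   record_weights = FALSE) {
  cur <- as.character(utils::packageVersion("bicnn"))
  if (!identical(manifest$package_version, cur)) {
    warning("manifest written by package version ",
            manifest$package_version, ", replaying with ", cur,
            " (best effort)")
  }
  counts <- vapply(cell_kinds(), function(k)
    as.integer(manifest$counts[[k]]), integer(1))
  base <- manifest$base_seed
  model <- build_bicnn(counts,
                       seeds = list(placement = derive_seed(base, 1L),
                                    connectivity = derive_seed(base, 1L),
                                    weights = derive_seed(base, 2L)))
  model <- knockdown_bicnn(model, manifest$gc_size,
                           seed = derive_seed(base, 3L))
  params <- switch(manifest$plant, dc_motor = dc_motor_params(),
                   robot = robot_params(), quad = quad_params())
  config <- do.call(control_config,
                    c(list(plant = manifest$plant), manifest$overrides))
  run_trial(model, params, config, default_trajectory(manifest$plant),
            manifest$n_cycles, record_traces = record_traces,
            record_weights = record_weights)
}

#' Write / read a run manifest as JSON
#'
#' @param manifest a `run_manifest`
#' @param path JSON file path
#' @return `path` (write) or the parsed manifest (read)
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(m) <- "run_manifest"
  m
}
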