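# End-to-end orchestration: simulate -> occupancy/visits -> contacts ->
# density -> GFE -> sites -> report, driven by one (YAML) config.

# Analysis parameter defaults. Where the underlying method states a value
# (5 A contact cutoff, 1 A grid spacing, isovalue 0.1, 300 K, 3 kcal/mol
# cap) the default IS that value.
.analysis_defaults <- function() {
  list(cutoff = 5.0, spacing = 1.0, isovalue = 0.1, temperature = 300,
       cap = 3.0, gap_tolerance = 2L, min_duration = 1L,
       rate_window = 12.5, radius = 6.0, padding = 2.0, min_voxels = 1L,
       bulk = NULL)
}

.known_keys <- function() {
  list(top = c("seed", "out", "input", "synthetic", "regions", "species",
               "analysis", "flux"),
       analysis = names(.analysis_defaults()))
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults, checks types and ranges, and reports unknown keys
#' (with a nearest-match suggestion) as warnings. Type mismatches are
#' collected and raised together, never silently coerced.
#'
#' @param config a named list, e.g. parsed from YAML with
#'   \code{yaml::read_yaml}.
#' @return The normalized config (defaults filled), invisibly classed
#'   \code{ionsite_config}.
#' @export
validate_config <- function(config = list()) {
  if (!is.list(config)) stop("config must be a named list")
  kk <- .known_keys()
  warn_unknown <- function(keys, known, where) {
    for (k in setdiff(keys, known)) {
      sugg <- known[which.min(utils::adist(k, known))]
      warning(sprintf("unknown config key '%s'%s (did you mean '%s'?)",
                      k, where, sugg), call. = FALSE)
    }
  }
  warn_unknown(names(config), kk$top, "")
  analysis <- .analysis_defaults()
  user <- config$analysis
  if (!is.null(user)) {
    warn_unknown(names(user), kk$analysis, " in `analysis`")
    for (k in intersect(names(user), kk$analysis)) analysis[[k]] <- user[[k]]
  }
  errors <- character(0)
  chk_num <- function(key, lo = 0, strict = TRUE) {
    v <- analysis[[key]]
    if (is.null(v)) return()
    if (!is.numeric(v) || length(v) != 1) {
      errors <<- c(errors, sprintf("`analysis.%s` must be a number", key))
    } else if (if (strict) v <= lo else v < lo) {
      errors <<- c(errors, sprintf("`analysis.%s` must be %s %g",
                                   key, if (strict) ">" else ">=", lo))
    }
  }
  chk_num("cutoff"); chk_num("spacing"); chk_num("temperature")
  chk_num("cap"); chk_num("radius"); chk_num("rate_window")
  chk_num("isovalue", 0, strict = FALSE)
  chk_num("gap_tolerance", 0, strict = FALSE)
  chk_num("min_duration", 1, strict = FALSE)
  chk_num("padding", 0, strict = FALSE)
  if (!is.null(config$seed) &&
      (!is.numeric(config$seed) || length(config$seed) != 1))
    errors <- c(errors, "`seed` must be a single integer")
  if (!is.null(config$regions)) {
    if (!is.list(config$regions) || is.null(names(config$regions)))
      errors <- c(errors, "`regions` must be a named mapping")
    else for (nm in names(config$regions)) {
      r <- config$regions[[nm]]
      if (is.null(r$residues))
        errors <- c(errors, sprintf("`regions.%s.residues` is missing", nm))
      if (!is.null(r$radius) && (!is.numeric(r$radius) || r$radius <= 0))
        errors <- c(errors, sprintf("`regions.%s.radius` must be > 0", nm))
    }
  }
  if (length(errors))
    stop("invalid config:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  config$analysis <- analysis
  config$seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  class(config) <- c("ionsite_config", "list")
  invisible(config)
}

.markov_from_config <- function(sc, seed) {
  states <- lapply(sc$states, function(s) {
    if (identical(s, "bulk")) "bulk" else
      list(point = as.numeric(s$point),
           jitter = if (is.null(s$jitter)) 0.5 else s$jitter)
  })
  P <- do.call(rbind, lapply(sc$P, as.numeric))
  dimnames(P) <- list(names(states), names(states))
  markov_model(states, P, dt = sc$dt, species = unlist(sc$species),
               n_ions = unlist(sc$n_ions), box = as.numeric(sc$box),
               seed = if (is.null(seed)) sc$seed else seed,
               single_occupancy = isTRUE(sc$single_occupancy))
}

.scaffold_from_config <- function(sc) {
  if (is.null(sc$scaffold)) return(NULL)
  s <- sc$scaffold
  anchors <- as.data.frame(do.call(rbind, lapply(s$anchor_residues,
                                                 function(a) {
    # YAML 1.1 reads a bare `y` key as boolean TRUE; map it back
    names(a)[names(a) %in% c("TRUE", "yes")] <- "y"
    as.data.frame(a)
  })))
  anchors$resname <- as.character(anchors$resname)
  spec <- scaffold_spec(
    cavity_radius = s$cavity_radius, cavity_depth = s$cavity_depth,
    anchor_residues = anchors, box = as.numeric(sc$box),
    cavity_axis = if (is.null(s$cavity_axis)) c(0, 0, 1) else
      as.numeric(s$cavity_axis),
    wall_atom_spacing = if (is.null(s$wall_atom_spacing)) 2 else
      s$wall_atom_spacing)
  build_scaffold(spec)
}

.log_stage <- function(log_con, stage, t0) {
  msg <- sprintf("[ionsite] %-10s done in %.2f s", stage,
                 as.numeric(Sys.time()) - t0)
  message(msg)
  if (!is.null(log_con)) writeLines(msg, log_con)
}

#' Run the analysis pipeline end to end
#'
#' Simulates (or loads) a trajectory, then computes occupancy, visits,
#' residence/entry statistics, contact frequencies, density and GFE maps,
#' and site calls, writing a deterministic artifact set (CSV tables, DX
#' grids, a summary JSON, and a run log) to the output directory.
#'
#' @param config a config list (validated via
#'   \code{\link{validate_config}}).
#' @param out_dir output directory; overrides \code{config$out}.
#' @param stages character subset of
#'   \code{c("simulate", "occupancy", "visits", "contacts", "density",
#'   "sites")}; stages not listed are skipped (simulate/load always runs).
#' @return Invisibly, a list with the computed objects and the summary.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         stages = c("simulate", "occupancy", "visits",
                                    "contacts", "density", "sites")) {
  config <- validate_config(unclass(config))
  out_dir <- if (!is.null(out_dir)) out_dir else config$out
  if (is.null(out_dir)) stop("no output directory given (config `out`)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(log_con))
  an <- config$analysis
  result <- list(config = config)
  fail <- function(stage, e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)

  # --- simulate / load -----------------------------------------------
  t0 <- as.numeric(Sys.time())
  sim <- tryCatch({
    if (!is.null(config$input)) {
      top <- read_topology(config$input$topology)
      traj <- read_trajectory(config$input$trajectory, top,
                              dt = config$input$dt)
      list(topology = top, trajectory = traj, ground_truth = NULL)
    } else if (!is.null(config$synthetic)) {
      scaffold <- .scaffold_from_config(config$synthetic)
      model <- .markov_from_config(config$synthetic, config$seed)
      simulate_markov_ions(model, n_steps = config$synthetic$n_steps,
                           scaffold = scaffold)
    } else stop("config needs either `input` or `synthetic`")
  }, error = function(e) fail("simulate", e))
  top <- sim$topology
  traj <- sim$trajectory
  species <- if (!is.null(config$species)) unlist(config$species) else
    setdiff(unique(top$atoms$species), c("scaffold", "other"))
  if ("simulate" %in% stages && !is.null(sim$ground_truth)) {
    write_topology(top, file.path(out_dir, "system.pdb"))
    write_trajectory(traj, top, file.path(out_dir, "trajectory.xyz"))
    gt <- sim$ground_truth
    jsonlite::write_json(
      list(species = gt$species, ion_index = gt$ion_index,
           expected_residence_ns = as.list(gt$expected_residence_ns),
           seed = gt$seed, states = gt$states),
      file.path(out_dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  }
  .log_stage(log_con, "simulate", t0)

  # --- regions --------------------------------------------------------
  regions <- NULL
  if (!is.null(config$regions)) {
    regions <- tryCatch(
      lapply(names(config$regions), function(nm) {
        r <- config$regions[[nm]]
        make_region(top, nm, unlist(r$residues),
                    radius = if (is.null(r$radius)) an$radius else r$radius,
                    slab = r$slab)
      }), error = function(e) fail("regions", e))
    names(regions) <- names(config$regions)
  } else if (any(c("occupancy", "visits") %in% stages)) {
    stop("stage 'occupancy' failed: config key `regions` is missing",
         call. = FALSE)
  }

  if ("occupancy" %in% stages) {
    t0 <- as.numeric(Sys.time())
    occ <- tryCatch(occupancy_counts(traj, top, regions, species),
                    error = function(e) fail("occupancy", e))
    frac <- occupancy_fractions(occ)
    utils::write.csv(occ, file.path(out_dir, "occupancy_per_frame.csv"),
                     row.names = FALSE)
    utils::write.csv(frac, file.path(out_dir, "occupancy_fractions.csv"),
                     row.names = FALSE)
    result$occupancy <- occ
    result$fractions <- frac
    .log_stage(log_con, "occupancy", t0)
  }

  if ("visits" %in% stages) {
    t0 <- as.numeric(Sys.time())
    vis <- tryCatch({
      vl <- lapply(regions, function(reg)
        extract_visits(traj, top, reg, species = species,
                       gap_tolerance = an$gap_tolerance,
                       min_duration = an$min_duration))
      all <- do.call(rbind, vl)
      attr(all, "n_frames") <- traj$n_frames
      attr(all, "dt") <- traj$dt
      class(all) <- c("visit_table", "data.frame")
      all
    }, error = function(e) fail("visits", e))
    res_stats <- residence_stats(vis)
    entries <- count_entries(vis)
    utils::write.csv(vis, file.path(out_dir, "visits.csv"),
                     row.names = FALSE)
    utils::write.csv(res_stats, file.path(out_dir, "residence_stats.csv"),
                     row.names = FALSE)
    utils::write.csv(entries, file.path(out_dir, "entry_exchange.csv"),
                     row.names = FALSE)
    result$visits <- vis
    result$residence <- res_stats
    result$entries <- entries
    .log_stage(log_con, "visits", t0)
  }

  if ("contacts" %in% stages) {
    t0 <- as.numeric(Sys.time())
    contacts <- tryCatch(
      contact_frequencies(traj, top, species = species,
                          cutoff = an$cutoff),
      error = function(e) fail("contacts", e))
    utils::write.csv(contacts, file.path(out_dir, "contact_frequencies.csv"),
                     row.names = FALSE)
    result$contacts <- contacts
    .log_stage(log_con, "contacts", t0)
  }

  if ("density" %in% stages || "sites" %in% stages) {
    t0 <- as.numeric(Sys.time())
    dens <- tryCatch({
      lapply(stats::setNames(species, species), function(sp) {
        raw <- accumulate_density(traj, top, species = sp,
                                  spacing = an$spacing,
                                  padding = an$padding)
        normalize_density(raw, "counts_per_frame")
      })
    }, error = function(e) fail("density", e))
    for (sp in names(dens)) {
      safe <- gsub("[^A-Za-z0-9]", "", sp)
      write_grid(dens[[sp]], file.path(out_dir,
                                       sprintf("density_%s.dx", safe)))
      bulk <- if (!is.null(an$bulk)) an$bulk else
        mean(dens[[sp]]$values[dens[[sp]]$values > 0])
      gfe <- gfe_from_density(dens[[sp]], bulk = bulk,
                              temperature = an$temperature, cap = an$cap)
      write_grid(gfe, file.path(out_dir, sprintf("gfe_%s.dx", safe)))
    }
    result$density <- dens
    .log_stage(log_con, "density", t0)
  }

  if ("sites" %in% stages) {
    t0 <- as.numeric(Sys.time())
    sites <- tryCatch({
      out <- lapply(names(result$density), function(sp)
        cbind(species = sp,
              as.data.frame(detect_sites(result$density[[sp]],
                                         isovalue = an$isovalue,
                                         min_voxels = an$min_voxels))))
      do.call(rbind, out)
    }, error = function(e) fail("sites", e))
    utils::write.csv(sites, file.path(out_dir, "site_calls.csv"),
                     row.names = FALSE)
    result$sites <- sites
    .log_stage(log_con, "sites", t0)
  }

  summary <- list(
    package_version = as.character(utils::packageVersion("ionsite")),
    seed = config$seed,
    n_frames = traj$n_frames,
    n_atoms = n_atoms(top),
    species = species,
    resolved_config = config[setdiff(names(unclass(config)), "out")],
    n_sites = if (!is.null(result$sites))
      as.integer(table(factor(result$sites$species, levels = species)))
    else NULL,
    n_sites_total = if (!is.null(result$sites)) nrow(result$sites) else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  result$summary <- summary
  invisible(result)
}
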