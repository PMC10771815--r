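# End-to-end orchestration: obtain a trajectory (simulate it, generate it
# synthetically, or read it), locate the interface, then run the
# conformation and orientation analyses, leaving CSV/JSON outputs and a run
# manifest sufficient to reproduce the run.

#' Run the droplet analysis pipeline
#'
#' Stages, in dependency order: input (exactly one of `simulate`,
#' `synthetic`, `trajectory`), interface (radial profile + tanh fit +
#' asphericity), conformation (chain records, Rg distributions, contact
#' profile, segmental analysis per `n_seg`), orientation (angle records and
#' profiles per `n_seg`). Each stage writes its outputs as they complete, so
#' a failure leaves completed-stage outputs plus a diagnostic manifest
#' naming the failed stage.
#'
#' @param config configuration as a named list, or the path of a YAML file
#'   with the same structure; see the package vignette for the schema and
#'   all defaults
#' @param out_dir output directory (created if absent)
#' @return the run manifest, invisibly (also written to `manifest.json`)
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  icfg <- config$input %||% stop("config$input is required")
  mode <- icfg$mode %||% stop("config$input$mode is required")
  if (!mode %in% c("simulate", "synthetic", "trajectory"))
    stop("input mode must be one of simulate / synthetic / trajectory")

  manifest <- list(package_version = as.character(utils::packageVersion("polydroplet")),
                   seed = seed, config = config, stages = list(),
                   outputs = list(), warnings = list())
  warn_push <- function(w) manifest$warnings[[length(manifest$warnings) + 1L]] <<- w
  finish <- function(status, stage = NULL, message = NULL) {
    manifest$status <<- status
    if (!is.null(stage)) manifest$failed_stage <<- stage
    if (!is.null(message)) manifest$error <<- message
    paths <- unlist(manifest$outputs)
    if (length(paths) > 0) {
      h <- tools::md5sum(paths)
      names(h) <- basename(paths)
      manifest$hashes <<- as.list(h)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out_file <- function(name) {
    p <- file.path(out_dir, name)
    manifest$outputs[[name]] <<- p
    p
  }
  run_stage <- function(stage, expr) {
    res <- tryCatch(withCallingHandlers(expr, warning = function(w) {
      warn_push(paste0(stage, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }), error = function(e) e)
    if (inherits(res, "error")) {
      finish("failed", stage, conditionMessage(res))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    manifest$stages[[stage]] <<- "ok"
    res
  }

  # ---- validation before any compute ----
  chain_length <- switch(mode,
    synthetic = icfg$chain_length %||% 20,
    simulate = icfg$chain_length %||% 20,
    trajectory = icfg$chain_length)
  nsegs <- config$conformation$n_seg %||% c(5, 10)
  if (!is.null(chain_length) && any(nsegs > chain_length))
    stop("config error: n_seg (", paste(nsegs, collapse = ","),
         ") exceeds chain_length (", chain_length, ")")

  # ---- input stage ----
  traj <- run_stage("input", {
    if (mode == "synthetic") {
      sp <- synthetic_droplet_spec(
        chain_length = chain_length, b = icfg$b %||% 1.5,
        c_dense = icfg$c_dense %||% 500, c_dilute = icfg$c_dilute %||% 0,
        d_mid = icfg$d_mid %||% 60, delta = icfg$delta %||% 12,
        n_chains = icfg$n_chains,
        end_enrichment = icfg$end_enrichment %||% 0,
        orientation_mode = icfg$orientation_mode %||% "isotropic",
        seed = seed)
      generate_synthetic_droplet(sp, n_frames = icfg$n_frames %||% 20)
    } else if (mode == "simulate") {
      units <- icfg$units %||% "reduced"
      ff <- do.call(force_field,
                    c(list(units = units),
                      icfg$force_field %||% list()))
      topo <- build_linear_topology(icfg$n_chains %||% 20, chain_length)
      st <- sim_settings(
        temperature = icfg$temperature %||% if (units == "reduced") 0.7 else 300,
        dt = icfg$dt %||% if (units == "reduced") 0.005 else 10,
        friction = icfg$friction %||% 1,
        n_steps = icfg$n_steps %||% 50000,
        save_every = icfg$save_every %||% 500, seed = seed)
      start <- init_droplet_configuration(
        topo, ff, seed = seed,
        concentration = icfg$concentration,
        density = icfg$density %||% if (units == "reduced") 0.45 else NULL,
        box = icfg$box)
      tr <- run_langevin(start, topo, ff, st)
      n_eq <- icfg$discard_frames %||% floor(length(tr$frames) / 2)
      tr$frames <- tr$frames[(n_eq + 1):length(tr$frames)]
      tr
    } else {
      if (is.null(icfg$path)) stop("trajectory input needs a path")
      topo <- if (!is.null(icfg$n_chains) && !is.null(chain_length))
        build_linear_topology(icfg$n_chains, chain_length) else NULL
      read_trajectory(icfg$path, icfg$format %||% "xyz", topology = topo)
    }
  })

  # ---- interface stage ----
  ifc <- config$interface %||% list()
  lenu <- if (traj$metadata$units == "reduced") 1 else 5
  fit <- run_stage("interface", {
    prof <- radial_concentration_profile(
      traj, bin_width = ifc$bin_width %||% lenu,
      r_max = ifc$r_max, cluster_cutoff = ifc$cluster_cutoff)
    write_records(data.frame(bin_lo = prof$bin_edges[-length(prof$bin_edges)],
                             bin_hi = prof$bin_edges[-1],
                             counts = prof$counts,
                             concentration_mM = prof$concentration),
                  out_file("profile.csv"),
                  meta = list(n_frames = prof$n_frames))
    ft <- fit_tanh_profile(prof, coverage = ifc$coverage %||% 0.8)
    asp <- vapply(traj$frames, function(fr) as.numeric(asphericity(fr)),
                  numeric(1))
    jsonlite::write_json(
      list(c_dense = ft$c_dense, c_dilute = ft$c_dilute, d_mid = ft$d_mid,
           delta = ft$delta, uncertainties = as.list(ft$param_uncertainties),
           r_half = ft$r_half, inner_bound = ft$inner_bound,
           outer_bound = ft$outer_bound, coverage = ft$coverage,
           residual_norm = ft$residual_norm,
           clipped_dilute = ft$clipped_dilute,
           asphericity_mean = mean(asp)),
      out_file("fit.json"), auto_unbox = TRUE, digits = NA)
    ft
  })

  # ---- conformation stage ----
  ccfg <- config$conformation %||% list()
  clcut <- ifc$cluster_cutoff
  run_stage("conformation", {
    ch <- chain_records(traj, fit = fit, cluster_cutoff = clcut)
    write_records(ch, out_file("chains.csv"))
    bw <- ccfg$bin_width %||% (3 * lenu)
    edges <- seq(0, max(ch$d_com) + bw, by = bw)
    cp <- contact_profile(traj,
                          contact_cutoff = ccfg$contact_cutoff %||% (1.5 * lenu),
                          intra_exclusion = ccfg$intra_exclusion %||% 2,
                          bin_width = bw, cluster_cutoff = clcut)
    write_records(cp, out_file("contact_profile.csv"),
                  meta = list(contact_cutoff = ccfg$contact_cutoff %||% (1.5 * lenu),
                              intra_exclusion = ccfg$intra_exclusion %||% 2))
    for (ns in nsegs) {
      sr <- segment_records(traj, ns, fit = fit, cluster_cutoff = clcut)
      write_records(sr, out_file(sprintf("segments_n%d.csv", ns)))
      occ_int <- try(segment_occupancy(sr, "interior"), silent = TRUE)
      occ_ifc <- try(segment_occupancy(sr, "interface"), silent = TRUE)
      occ <- do.call(rbind, Filter(Negate(is.null), list(
        if (!inherits(occ_int, "try-error")) cbind(region = "interior", occ_int),
        if (!inherits(occ_ifc, "try-error")) cbind(region = "interface", occ_ifc))))
      if (!is.null(occ))
        write_records(occ, out_file(sprintf("occupancy_n%d.csv", ns)))
      prof_all <- segmental_rg_profile(sr, edges, "all", fit = fit)
      write_records(prof_all, out_file(sprintf("segmental_rg_n%d.csv", ns)))
    }
    invisible(NULL)
  })

  # ---- orientation stage ----
  ocfg <- config$orientation %||% list()
  run_stage("orientation", {
    for (ns in nsegs[nsegs >= 2]) {
      orc <- orientation_records(traj, ns, fit = fit, cluster_cutoff = clcut,
                                 origin = ocfg$origin %||% "com")
      if (attr(orc, "skipped") > 0)
        warning(attr(orc, "skipped"), " degenerate segments skipped")
      bw <- ocfg$bin_width %||% (3 * lenu)
      edges <- seq(0, max(orc$d_com) + bw, by = bw)
      ap <- angle_profile(orc, edges)
      write_records(ap, out_file(sprintf("angle_profile_n%d.csv", ns)),
                    meta = list(isotropic_reference = isotropic_mean_angle(),
                                origin = ocfg$origin %||% "com"))
    }
    invisible(NULL)
  })

  if (!is.null(traj$metadata$truth)) manifest$truth <- traj$metadata$truth
  finish("ok")
  invisible(manifest)
}
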