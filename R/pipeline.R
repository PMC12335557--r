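# Pipeline driver: YAML-configurable stages tying the analysis modules
# together. Each stage writes TSV/JSON artifacts into the configured output
# directory; `report` collates the stage outputs into one JSON summary.
# Machine-readable output goes only to files; log messages go to stderr.

#' Default pipeline configuration
#'
#' Every parameter of every stage, with the conventional defaults: DPV
#' cylinder radius 7 angstrom, top face 12 angstrom below the SF COM, height
#' 5 angstrom; Fermi smoothing 3 angstrom; wet/dry threshold 5 waters;
#' 3.6 angstrom SF-contact cutoff; 6 angstrom lipid contact cutoff;
#' restrained windows with k = 1 kcal/mol, 2000 ps burn-in, 100 ps blocks;
#' 300 K. A config file (YAML) is merged over these defaults.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    schema_version = 1L,
    output_dir = "poregate_out",
    seed = 1L,
    input = list(structure = NULL, trajectory = NULL, stride = 1L, dt = 0.02),
    selections = list(
      water = "resname TIP3 and name OH2",
      lipid_tails = "resname POPC and name C2* C3*",
      lipids = "resname POPC",
      sf = "resname SFM",
      reference = "resname REF",
      innermost_k = "resname POT and name K",
      protein = "resname SHL",
      r329 = "resname ARG and name CZ",
      k392 = "resname LYS and name NZ",
      s6 = list("segid S6A and name CA", "segid S6B and name CA",
                "segid S6C and name CA", "segid S6D and name CA")
    ),
    dpv = list(radius = 7, z_top = -12, height = 5),
    sphere_radius = 7,
    fermi_lambda = 3,
    analysis = list(t_min = 0, wet_threshold = 5, contact_cutoff = 6,
                    sf_cutoff = 3.6, temperature = 300, block_frames = 5L),
    radius = list(z_range = c(-20, 0), dz = 0.5, grid = 0.2,
                  search_radius = 5, cap = 12),
    tilt = list(residue_window = NULL),
    rmd = list(windows_manifest = NULL, method = "euler",
               abscissa = "target", reference = 1L),
    metad = list(cv_file = NULL, hills_file = NULL, bins = 61L,
                 temperature = 300),
    fixture = list(n_frames = 25L, pore_radius = 5, n_water_dpv = 14,
                   n_lipids = 4,
                   lipid_entry = list(frame = 13L, lipid = 1L,
                                      tail = "unsaturated", n_carbons = 3L),
                   water_exit = list(frame = 13L, n = 13L))
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]) &&
        !is.null(names(override[[k]]))) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Load a YAML pipeline configuration merged over the defaults
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

#' Write a configuration to YAML (round-trips losslessly through [load_config()])
#' @param config configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

pipeline_log <- function(...) message("[poregate] ", ...)

load_input_series <- function(config) {
  inp <- config$input
  if (is.null(inp$structure) || is.null(inp$trajectory)) {
    stop("missing input: config$input$structure and $trajectory are required")
  }
  structure_frame <- load_structure(inp$structure)
  load_trajectory(structure_frame, inp$trajectory,
                  stride = inp$stride %||% 1L, dt = inp$dt %||% 0.02)
}

#' Run one pipeline stage
#'
#' Stages: `fixture` (generate the synthetic channel fixture), `radius`
#' (averaged radius profiles, protein-only and protein+lipid), `occupancy`
#' (DPV counts, wet/dry states, summary statistics), `tilt` (S6 tilt
#' distribution), `rmd-fe` (mean forces + TI profile from a windows
#' manifest), `metad-fe` (reweighted profile from CV + hills files),
#' `contacts` (annular-lipid contact table), `report` (collate stage outputs
#' into `report.json`). Partial outputs are removed when a stage fails.
#'
#' @param name stage name.
#' @param config configuration list (see [default_config()], [load_config()]).
#' @return named list of written artifact paths, invisibly.
#' @export
run_subcommand <- function(name, config = default_config()) {
  stages <- c("fixture", "radius", "occupancy", "tilt", "rmd-fe", "metad-fe",
              "contacts", "report")
  if (!(name %in% stages)) {
    stop("unknown subcommand '", name, "'; expected one of: ",
         paste(stages, collapse = ", "))
  }
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  note <- function(p) {
    written <<- c(written, p)
    p
  }
  result <- tryCatch({
    switch(
      name,
      "fixture" = {
        fx <- do.call(build_channel_fixture,
                      c(config$fixture, list(seed = config$seed,
                                             write_dir = out_dir)))
        for (p in fx$paths) note(p)
        pipeline_log("fixture: ", fx$manifest$n_atoms, " atoms x ",
                     fx$manifest$n_frames, " frames")
        fx$paths
      },
      "radius" = {
        series <- load_input_series(config)
        sel <- config$selections
        rp <- config$radius
        run_set <- function(expr, label) {
          profs <- lapply(seq_len(n_frames(series)), function(i) {
            fr <- get_frame(series, i)
            ax <- pore_axis(fr, select_atoms(fr, sel$sf),
                            reference = select_atoms(fr, sel$reference))
            radius_profile(fr, ax, z_range = unlist(rp$z_range), dz = rp$dz,
                           include = select_atoms(fr, expr),
                           grid_spacing = rp$grid,
                           search_radius = rp$search_radius, cap = rp$cap,
                           label = label)
          })
          avg <- average_radius_profile(
            profs, block_length = min(config$analysis$block_frames,
                                      n_frames(series)))
          note(write_radius_profile(
            avg, file.path(out_dir, paste0("radius_", label, ".tsv"))))
          avg
        }
        pr <- run_set(sel$protein, "protein")
        pl <- run_set(paste0("(", sel$protein, ") or (", sel$lipid_tails, ")"),
                      "protein_lipid")
        pipeline_log("radius: min protein-only r = ",
                     sprintf("%.2f", min(pr$r)), " A")
        list(protein = pr, protein_lipid = pl)
      },
      "occupancy" = {
        series <- load_input_series(config)
        sel <- config$selections
        occ <- occupancy_series(
          series, water = sel$water, lipid = sel$lipid_tails, sf = sel$sf,
          reference = sel$reference,
          region_args = list(radius = config$dpv$radius,
                             z_top = config$dpv$z_top,
                             height = config$dpv$height))
        thr <- config$analysis$wet_threshold
        note(write_occupancy(occ, file.path(out_dir, "occupancy.tsv"), thr))
        st <- occupancy_stats(occ, t_min = config$analysis$t_min)
        states <- wet_dry_classify(occ, thr)
        summary <- list(
          n_frames = nrow(occ), n_used = st$n_used,
          mean_water = st$mean_water, sd_water = st$sd_water,
          mean_lipid = st$mean_lipid, sd_lipid = st$sd_lipid,
          correlation = st$correlation,
          wet_fraction = mean(states == "wet"),
          switch_frames = attr(states, "switches")
        )
        jsonlite::write_json(summary,
                             note(file.path(out_dir, "occupancy_summary.json")),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        pipeline_log("occupancy: mean n_water = ",
                     sprintf("%.2f", st$mean_water))
        summary
      },
      "tilt" = {
        series <- load_input_series(config)
        td <- tilt_distribution(series, config$selections$s6,
                                residue_window = config$tilt$residue_window)
        utils::write.table(td$angles,
                           note(file.path(out_dir, "tilt.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(td$kde)) {
          utils::write.table(data.frame(theta_deg = td$kde$x,
                                        density = td$kde$y),
                             note(file.path(out_dir, "tilt_kde.tsv")),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        }
        pipeline_log("tilt: ", nrow(td$angles), " angles, mean ",
                     sprintf("%.1f", mean(td$angles$theta_deg)), " deg")
        td
      },
      "rmd-fe" = {
        mp <- config$rmd$windows_manifest
        if (is.null(mp)) stop("missing input: config$rmd$windows_manifest")
        windows <- read_windows(mp)
        forces <- lapply(windows, mean_force)
        ftab <- do.call(rbind, lapply(forces, function(p) {
          data.frame(target = p$target, mean_force = p$mean_force, se = p$se,
                     mean_position = p$mean_position)
        }))
        utils::write.table(ftab, note(file.path(out_dir, "mean_forces.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        prof <- integrate_profile(forces, method = config$rmd$method,
                                  reference = config$rmd$reference,
                                  abscissa = config$rmd$abscissa)
        note(write_profile(prof, file.path(out_dir, "fe_rmd.tsv")))
        pipeline_log("rmd-fe: ", nrow(ftab), " windows integrated (",
                     config$rmd$method, ", ", config$rmd$abscissa, ")")
        prof
      },
      "metad-fe" = {
        mc <- config$metad
        if (is.null(mc$cv_file)) stop("missing input: config$metad$cv_file")
        cv <- utils::read.table(mc$cv_file, header = FALSE,
                                comment.char = "#")
        hills <- if (!is.null(mc$hills_file) && file.exists(mc$hills_file) &&
                     file.size(mc$hills_file) > 0) {
          read_hills(mc$hills_file)
        } else NULL
        trace <- metad_trace(cv[[1]], cv[[ncol(cv)]], hills = hills,
                             temperature = mc$temperature)
        prof <- metad_reweight(trace, bins = mc$bins)
        note(write_profile(prof, file.path(out_dir, "fe_metad.tsv")))
        pipeline_log("metad-fe: ", length(trace$s), " samples, ",
                     nrow(trace$hills), " hills")
        prof
      },
      "contacts" = {
        series <- load_input_series(config)
        sel <- config$selections
        rows <- list()
        for (i in seq_len(n_frames(series))) {
          fr <- get_frame(series, i)
          ax <- pore_axis(fr, select_atoms(fr, sel$sf),
                          reference = select_atoms(fr, sel$reference))
          dpv <- dpv_region(ax, radius = config$dpv$radius,
                            z_top = config$dpv$z_top,
                            height = config$dpv$height)
          s6_all <- paste(vapply(sel$s6, function(e) paste0("(", e, ")"),
                                 character(1)), collapse = " or ")
          rec <- annular_lipid_contacts(
            fr, lipids = sel$lipids, r329 = sel$r329, k392 = sel$k392,
            s6 = s6_all, dpv = dpv, cutoff = config$analysis$contact_cutoff)
          if (nrow(rec)) rows[[length(rows) + 1L]] <- cbind(frame = i, rec)
        }
        tab <- if (length(rows)) do.call(rbind, rows) else
          data.frame(frame = integer(), segid = character(),
                     resid = integer(), tail = character(),
                     d_phosphate_r329 = numeric(), d_head_k392 = numeric(),
                     penetration = logical())
        utils::write.table(tab, note(file.path(out_dir, "contacts.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        pipeline_log("contacts: ", nrow(tab), " records")
        tab
      },
      "report" = {
        rep <- list(schema_version = config$schema_version)
        occ_p <- file.path(out_dir, "occupancy_summary.json")
        if (file.exists(occ_p)) rep$occupancy <- jsonlite::fromJSON(occ_p)
        for (lab in c("protein", "protein_lipid")) {
          p <- file.path(out_dir, paste0("radius_", lab, ".tsv"))
          if (file.exists(p)) {
            tab <- utils::read.table(p, header = FALSE, skip = 2, sep = "\t")
            rep[[paste0("radius_", lab)]] <- list(
              min_radius = min(tab[[2]]),
              z_at_min = tab[[1]][which.min(tab[[2]])])
          }
        }
        tp <- file.path(out_dir, "tilt.tsv")
        if (file.exists(tp)) {
          ta <- utils::read.table(tp, header = TRUE, sep = "\t")
          kde <- stats::density(ta$theta_deg, bw = "nrd")
          rep$tilt <- list(mean_deg = mean(ta$theta_deg),
                           modes_deg = density_modes(kde)$x)
        }
        for (fe in c("fe_rmd", "fe_metad")) {
          p <- file.path(out_dir, paste0(fe, ".tsv"))
          if (file.exists(p)) {
            tab <- utils::read.table(p, header = FALSE, skip = 2, sep = "\t")
            prof <- free_energy_profile(tab[[1]], tab[[2]])
            ft <- profile_features(prof)
            rep[[fe]] <- list(minima = ft$minima,
                              barriers = ft$barriers,
                              global_min = ft$global_min)
          }
        }
        if (length(rep) == 1L) stop("report: no stage outputs found in ",
                                    out_dir)
        jsonlite::write_json(rep, note(file.path(out_dir, "report.json")),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE,
                             dataframe = "columns")
        pipeline_log("report: ", length(rep) - 1L, " sections")
        rep
      }
    )
  }, error = function(e) {
    for (p in written) if (file.exists(p)) unlink(p)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}
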