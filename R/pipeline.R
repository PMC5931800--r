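#' Configuration for a two-genotype physiology experiment
#'
#' Default parameters describe a wild-type-like genotype and a mutant-like
#' genotype whose ooDSGCs spike more in the null direction (larger
#' `null_rate`) and whose ON and OFF preferred directions are less coherent
#' (larger `delta_phi_sd`) — the mechanism by which a disrupted circuit
#' broadens and weakens direction tuning.
#'
#' @param experiment experiment name.
#' @param seed master seed; all stages derive sub-seeds from it.
#' @param contrasts protocol contrasts used (two high contrasts suffice for
#'   the ON/OFF boundary and the tuning metrics).
#' @param n_trials trials per condition.
#' @param genotypes named list; each entry a list with `n_cells`,
#'   `ds_fraction`, `kappa` (values sampled per cell), `gain`, `null_rate`,
#'   `pref_dir_sd` (scatter of preferred directions about the cardinal
#'   axes, degrees) and `delta_phi_sd` (ON-OFF misalignment SD, degrees).
#' @return List of class `physiology_config`.
#' @export
physiology_config <- function(experiment = "synthetic-ds-tuning",
                              seed = 1L,
                              contrasts = c(150, 300),
                              n_trials = 8,
                              genotypes = list(
                                wildtype = list(n_cells = 120,
                                                ds_fraction = 0.15,
                                                kappa = c(1, 2, 4),
                                                gain = 30, null_rate = 0.5,
                                                pref_dir_sd = 10,
                                                delta_phi_sd = 5),
                                mutant = list(n_cells = 120,
                                              ds_fraction = 0.15,
                                              kappa = c(1, 2, 4),
                                              gain = 30, null_rate = 3,
                                              pref_dir_sd = 10,
                                              delta_phi_sd = 20))) {
  stopifnot(length(genotypes) >= 1, !is.null(names(genotypes)))
  structure(list(experiment = experiment, seed = as.integer(seed),
                 contrasts = contrasts, n_trials = n_trials,
                 genotypes = genotypes),
            class = c("physiology_config", "list"))
}

## One genotype's synthetic truth: DS cells with cardinal preferred
## directions, non-DS cells untuned with modest gain.
build_genotype_truth <- function(g, protocol, seed, prefix) {
  n_ds <- round(g$n_cells * g$ds_fraction)
  with_seed(seed, {
    cells <- lapply(seq_len(g$n_cells), function(i) {
      id <- sprintf("%s_%03d", prefix, i)
      if (i <= n_ds) {
        card <- sample(c(0, 90, 180, 270), 1)
        mu_on <- (card + rnorm(1, 0, g$pref_dir_sd)) %% 360
        mu_off <- (mu_on + rnorm(1, 0, g$delta_phi_sd)) %% 360
        cell_params(id, is_ds = TRUE, mu_on = mu_on, mu_off = mu_off,
                    kappa_on = sample(g$kappa, 1),
                    kappa_off = sample(g$kappa, 1),
                    gain = g$gain, null_rate = g$null_rate)
      } else {
        cell_params(id, is_ds = FALSE, gain = g$gain / 3,
                    null_rate = min(g$null_rate, g$gain / 3))
      }
    })
  })
  synthetic_truth(cells, protocol, seed = derive_seed(seed, 9999))
}

#' Run an end-to-end synthetic physiology experiment
#'
#' For each genotype: generate a population, apply spike-train quality
#' control, gate DS cells on the DSI distribution, isolate ooDSGCs by their
#' bilobed ON/OFF response, compute per-cell tuning metrics, and assign
#' cardinal subtypes; then compare the genotype distributions of tuning
#' width, strength and ON-OFF preferred-direction difference with the
#' two-sample KS test. Stage-level cell counts are logged in the returned
#' summary.
#'
#' @param cfg a [physiology_config()].
#' @param outdir optional directory; when given, metrics/label tables
#'   (CSV), the comparison report and a JSON run manifest are written.
#' @param verbose print stage logs.
#' @return List with `metrics` (per-cell data frame across genotypes),
#'   `labels`, `comparisons` (data frame: metric, ks_statistic, p_value,
#'   n per group), `gates`, `stage_counts`, `config`.
#' @export
run_physiology_experiment <- function(cfg = physiology_config(),
                                      outdir = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "physiology_config"))
  protocol <- stimulus_protocol(contrasts = cfg$contrasts,
                                n_trials = cfg$n_trials)
  say <- function(...) if (verbose) message(...)
  all_metrics <- list(); all_labels <- list(); gates <- list()
  counts <- list()
  for (gi in seq_along(cfg$genotypes)) {
    gname <- names(cfg$genotypes)[gi]
    g <- cfg$genotypes[[gi]]
    truth <- build_genotype_truth(g, protocol,
                                  derive_seed(cfg$seed, gi), gname)
    rs <- generate_population(truth)
    say(gname, ": generated ", length(rs$cells), " cells, ",
        nrow(rs$spikes), " spikes")
    total_t <- length(protocol$directions) * length(protocol$contrasts) *
      protocol$n_trials * protocol$trial_duration_s
    trial_key <- interaction(rs$spikes$direction_deg,
                             rs$spikes$contrast_pct, rs$spikes$trial,
                             drop = FALSE)
    qc <- vapply(rs$cells, function(cl) {
      sel <- rs$spikes$cell_id == cl
      trains <- split(rs$spikes$spike_time_s[sel], trial_key[sel])
      qc_filter(trains, duration_s = total_t)$qc_pass
    }, logical(1))
    kept <- rs$cells[qc]
    say(gname, ": ", sum(qc), "/", length(qc), " cells pass QC")
    dsi <- vapply(kept, function(cl)
      compute_dsi(compute_tuning_curve(rs, cl, max(cfg$contrasts))),
      numeric(1))
    gate <- gate_dsgc(dsi, seed = derive_seed(cfg$seed, 100 + gi))
    ds_cells <- kept[gate$is_ds]
    say(gname, ": ", length(ds_cells), " DS cells (threshold ",
        signif(gate$threshold, 3), ")")
    oods <- isolate_oods(rs, ds_cells)
    oods_cells <- oods$cell_id[oods$is_oods]
    say(gname, ": ", length(oods_cells), " ooDSGCs")
    met <- if (length(oods_cells)) {
      m <- cell_metrics(rs, contrast = max(cfg$contrasts),
                        cells = oods_cells)
      m$genotype <- gname
      if (nrow(m) >= 4) {
        sub <- assign_subtypes(m$pref_dir_deg)
        m$subtype <- sub$cluster
      } else m$subtype <- NA_integer_
      m
    } else NULL
    lab <- data.frame(cell_id = rs$cells, genotype = gname,
                      qc_pass = qc,
                      dsi = NA_real_, is_ds = FALSE, is_oods = FALSE)
    lab$dsi[match(kept, lab$cell_id)] <- dsi
    lab$is_ds[match(ds_cells, lab$cell_id)] <- TRUE
    lab$is_oods[match(oods_cells, lab$cell_id)] <- TRUE
    all_metrics[[gname]] <- met
    all_labels[[gname]] <- lab
    gates[[gname]] <- gate
    counts[[gname]] <- c(generated = length(rs$cells), qc_pass = sum(qc),
                         ds = length(ds_cells),
                         oods = length(oods_cells))
  }
  metrics <- do.call(rbind, all_metrics)
  labels <- do.call(rbind, all_labels)
  rownames(metrics) <- rownames(labels) <- NULL
  comparisons <- NULL
  if (length(cfg$genotypes) == 2 && !is.null(metrics) &&
      all(table(metrics$genotype) > 0)) {
    gn <- names(cfg$genotypes)
    cmp_one <- function(col) {
      a <- metrics[[col]][metrics$genotype == gn[1]]
      b <- metrics[[col]][metrics$genotype == gn[2]]
      cp <- compare_populations(a, b)
      data.frame(metric = col, ks_statistic = cp$ks_statistic,
                 p_value = cp$p_value, n_a = cp$n_a, n_b = cp$n_b)
    }
    comparisons <- do.call(rbind, lapply(
      c("width_deg", "strength", "delta_phi_deg"), cmp_one))
  }
  out <- list(metrics = metrics, labels = labels,
              comparisons = comparisons, gates = gates,
              stage_counts = counts, config = cfg)
  if (!is.null(outdir)) write_experiment(out, outdir, "physiology")
  out
}

#' Configuration for a two-genotype mosaic experiment
#'
#' @param experiment experiment name.
#' @param seed master seed.
#' @param bounds field rectangle, micrometers.
#' @param density cells per mm^2.
#' @param n_animals,n_fields animals per genotype and imaged fields per
#'   animal.
#' @param null_sims simulations for the density-matched random envelope.
#' @param genotypes named list; each entry a list with `process`
#'   (`"lattice_jitter"`, `"hardcore"` or `"poisson"`), and process
#'   parameters `jitter_sd` / `d_min`.
#' @return List of class `mosaic_config`.
#' @export
mosaic_config <- function(experiment = "synthetic-mosaic",
                          seed = 1L,
                          bounds = c(0, 0, 636.5, 636.5),
                          density = 600,
                          n_animals = 4, n_fields = 3,
                          null_sims = 99,
                          genotypes = list(
                            wildtype = list(process = "lattice_jitter",
                                            jitter_sd = 8, d_min = 8),
                            mutant = list(process = "hardcore",
                                          jitter_sd = 0, d_min = 8))) {
  structure(list(experiment = experiment, seed = as.integer(seed),
                 bounds = bounds, density = density,
                 n_animals = n_animals, n_fields = n_fields,
                 null_sims = null_sims, genotypes = genotypes),
            class = c("mosaic_config", "list"))
}

#' Run an end-to-end synthetic mosaic experiment
#'
#' Generates `n_fields` mosaics for each of `n_animals` synthetic animals
#' per genotype, scores each field's VDRI and density, summarizes per
#' animal, simulates the density-matched random null envelope, and (with
#' two or more genotypes) tests the genotype effect on per-animal VDRI by
#' one-way ANOVA.
#'
#' @param cfg a [mosaic_config()].
#' @param outdir optional output directory (CSV tables + JSON manifest).
#' @param verbose print stage logs.
#' @return List with `fields` (per-field data frame), `animals` (per-animal
#'   means), `null` (from [random_null()]), `anova_p`, `config`.
#' @export
run_mosaic_experiment <- function(cfg = mosaic_config(), outdir = NULL,
                                  verbose = FALSE) {
  stopifnot(inherits(cfg, "mosaic_config"))
  rows <- list(); arow <- list()
  k <- 0
  for (gi in seq_along(cfg$genotypes)) {
    gname <- names(cfg$genotypes)[gi]
    g <- cfg$genotypes[[gi]]
    for (an in seq_len(cfg$n_animals)) {
      vres <- list()
      for (fi in seq_len(cfg$n_fields)) {
        k <- k + 1
        m <- generate_mosaic(g$process, density = cfg$density,
                             bounds = cfg$bounds,
                             d_min = if (is.null(g$d_min)) 8 else g$d_min,
                             jitter_sd = if (is.null(g$jitter_sd)) 2
                                         else g$jitter_sd,
                             seed = derive_seed(cfg$seed, k))
        v <- voronoi_domains(m)
        vres[[fi]] <- v
        rows[[k]] <- data.frame(genotype = gname, animal = an, field = fi,
                                vdri = v$vdri,
                                density_mm2 = v$density_mm2,
                                n_interior = v$n_interior)
      }
      s <- per_animal_summary(vres)
      arow[[length(arow) + 1]] <-
        data.frame(genotype = gname, animal = an,
                   mean_vdri = s$mean_vdri,
                   mean_density_mm2 = s$mean_density_mm2)
      if (verbose) message(gname, " animal ", an, ": VDRI ",
                           signif(s$mean_vdri, 4))
    }
  }
  fields <- do.call(rbind, rows)
  animals <- do.call(rbind, arow)
  nul <- random_null(cfg$density, cfg$bounds, d_min = 8,
                     n_sims = cfg$null_sims,
                     seed = derive_seed(cfg$seed, 10^6))
  anova_p <- NA_real_
  if (length(unique(animals$genotype)) >= 2 && cfg$n_animals >= 2) {
    fit <- aov(mean_vdri ~ genotype, data = animals)
    anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  }
  out <- list(fields = fields, animals = animals, null = nul,
              anova_p = anova_p, config = cfg)
  if (!is.null(outdir)) write_experiment(out, outdir, "mosaic")
  out
}

## Persist an experiment's tables and a JSON run manifest.
write_experiment <- function(out, outdir, kind) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(out)) {
    if (is.data.frame(out[[nm]]) && nrow(out[[nm]]) > 0)
      write.csv(out[[nm]], file.path(outdir, paste0(kind, "_", nm, ".csv")),
                row.names = FALSE)
  }
  manifest <- list(kind = kind,
                   package_version =
                     as.character(utils::packageVersion("dscircuit")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   config = unclass(out$config))
  jsonlite::write_json(manifest, file.path(outdir, paste0(kind,
                                                          "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Read or write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param cfg a `physiology_config` or `mosaic_config`.
#' @return `read_run_config()` returns the config object (the `kind` field
#'   selects the class); `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  kind <- raw$kind
  raw$kind <- NULL
  if (identical(kind, "mosaic")) {
    do.call(mosaic_config, raw)
  } else {
    do.call(physiology_config, raw)
  }
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  kind <- if (inherits(cfg, "mosaic_config")) "mosaic" else "physiology"
  yaml::write_yaml(c(list(kind = kind), unclass(cfg)), path)
  invisible(path)
}
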