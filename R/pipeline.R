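#' Default pipeline configuration
#'
#' Nested list consumed by [run_pipeline()]. Override any entry by passing
#' a partial list (or a YAML file) to `run_pipeline`; unnamed entries keep
#' their defaults.
#'
#' Structure: `seed`; `out_dir`; `stages` (character subset of
#' `"simulate"`, `"morphometry"`, `"stats"`, `"transcriptomics"`);
#' `subjects`; `timepoints`; `sections_per_subject` (ROI replicates);
#' `section` (overrides for [section_spec()]); `effects` (per-timepoint
#' multipliers applied to selected section parameters, named by parameter,
#' each a vector over timepoints); `metrics` (which morphometry metrics to
#' compute); `thickness_probes` (`n`, `spacing_um`); `arc_section_um`;
#' `roi_um` (dermal ROI edge length); `expression` (arguments to
#' [generate_expression_dataset()]); `figures` (logical).
#'
#' @return The default configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "scarmorph-out",
    stages = c("simulate", "morphometry", "stats", "transcriptomics"),
    subjects = 3L,
    timepoints = c(0, 2, 4, 6),
    sections_per_subject = 2L,
    section = list(
      width_um = 450, height_um = 260, pixel_size_um = 1,
      epidermal_thickness_um = 50, edj_amplitude_um = 8,
      edj_period_um = 90, nuclei_density_per_mm2 = 700,
      ki67_fraction = 0.05, vessel_area_fraction = 0.06,
      fibre_widths_um = c(6, 14), fibre_width_weights = c(0.48, 0.52),
      orientation_kappa = 4, fibre_area_fraction = 0.2
    ),
    effects = list(),
    section_cv = 0.08,
    metrics = c("epidermal_thickness", "ki67_fraction", "arc_chord",
                "bm_width", "bm_peak", "cell_density", "vessel_density",
                "collagen_fraction", "thick_proportion",
                "alignment_coefficient", "normalized_shg_intensity"),
    thickness_probes = list(n = 4L, spacing_um = 100),
    arc_section_um = 90,
    roi_um = 150,
    expression = list(n_genes = 1000, n_per_timepoint = 3,
                      n_unique = c(20, 20, 20), n_core = 20,
                      effect_log2 = 1.5, noise_sd = 0.4),
    figures = TRUE
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

apply_effects <- function(section, effects, timepoint, timepoints) {
  ti <- match(timepoint, timepoints)
  for (par in names(effects)) {
    mult <- effects[[par]]
    stopifnot(length(mult) == length(timepoints))
    section[[par]] <- section[[par]] * mult[ti]
  }
  section
}

section_metrics <- function(img, truth, cfg) {
  psz <- img$pixel_size_um
  d <- dim(img$channels[[1]])
  w_um <- d[2] * psz
  met <- list()
  want <- function(m) m %in% cfg$metrics

  top <- boundary_curve(c(0, w_um), rep(truth$top_margin_um, 2))
  edj <- boundary_curve(truth$edj$x_um, truth$edj$y_um)

  if (want("epidermal_thickness")) {
    th <- epidermal_thickness(top, edj, n_probes = cfg$thickness_probes$n,
                              spacing_um = cfg$thickness_probes$spacing_um)
    met$epidermal_thickness <- th$mean_um
  }
  if (want("arc_chord"))
    met$arc_chord <- arc_chord_ratio(edj, cfg$arc_section_um)$mean_ratio

  if (want("ki67_fraction")) {
    nuc <- detect_nuclei(img$channels$DAPI, psz)
    epi_reg <- matrix(FALSE, d[1], d[2])
    rows <- seq_len(max(1L, floor(um_to_row(truth$dermis_top_um, psz))))
    epi_reg[rows, ] <- TRUE
    kf <- ki67_fraction(nuc, img$channels$Ki67, psz, region = epi_reg)
    met$ki67_fraction <- kf$pooled_fraction
  }
  if (want("bm_width") || want("bm_peak")) {
    prof <- edj_profiles(img$channels$COLIV, psz, edj,
                         n_trajectories = 12)
    wp <- lapply(prof, profile_width_peak)
    met$bm_width <- mean(vapply(wp, `[[`, numeric(1), "width_um"),
                         na.rm = TRUE)
    met$bm_peak <- mean(vapply(wp, `[[`, numeric(1), "peak"))
  }

  dermis_roi <- c((w_um - cfg$roi_um) / 2, truth$dermis_top_um,
                  (w_um + cfg$roi_um) / 2,
                  truth$dermis_top_um + cfg$roi_um)
  if (want("cell_density")) {
    nuc_all <- detect_nuclei(img$channels$DAPI, psz)
    met$cell_density <- cell_density(nuc_all, dermis_roi)
  }
  if (want("vessel_density")) {
    vm <- vessel_mask(img$channels$COLIV, psz, dermis_roi)
    met$vessel_density <- vessel_density(vm, pixel_size_um = psz)
  }
  need_seg <- any(vapply(c("collagen_fraction", "thick_proportion",
                           "alignment_coefficient",
                           "normalized_shg_intensity"), want, logical(1)))
  if (need_seg) {
    # collagen analysis is confined to the dermal ROI, like the SHG ROIs
    # of real sections
    der_rows <- ceiling(um_to_row(truth$dermis_top_um, psz)):d[1]
    shg <- img$channels$SHG[der_rows, , drop = FALSE]
    fcm <- segment_fibres(shg, psz)
    cf <- collagen_fractions(fcm)
    if (want("collagen_fraction")) met$collagen_fraction <-
        cf$collagen_fraction
    if (want("thick_proportion")) met$thick_proportion <-
        cf$thick_proportion
    if (want("alignment_coefficient") && any(fcm$mask)) {
      of <- orientation_field(shg, fcm$mask, psz)
      met$alignment_coefficient <- alignment_coefficient(of)
    }
    if (want("normalized_shg_intensity") && any(fcm$mask))
      met$normalized_shg_intensity <-
        normalized_shg_intensity(shg, fcm$mask, !fcm$mask)
  }
  met
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates simulate -> segment/morphometry -> statistics ->
#' transcriptomics over a configured synthetic study (subjects x
#' timepoints x ROI replicates) and writes tidy CSVs, per-metric
#' statistical results, optional figures (metric versus timepoint with
#' grand-mean lines), and a provenance JSON recording the seed,
#' thresholds and package version. Output is deterministic for a fixed
#' configuration and seed.
#'
#' @param config partial configuration list or path to a YAML file; merged
#'   over [default_pipeline_config()].
#' @return Invisibly, a list with `records` (tidy morphometry
#'   data.frame), `stats` (per-metric `stat_result`s), `transcriptomics`
#'   (DE results, Venn partition, clustering), and `out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- cfg$stages
  records <- NULL
  stat_res <- list()
  tx <- NULL

  if ("simulate" %in% stages && "morphometry" %in% stages) {
    idx <- 0L
    for (subj in seq_len(cfg$subjects)) {
      for (tp in cfg$timepoints) {
        sect <- apply_effects(cfg$section, cfg$effects, tp,
                              cfg$timepoints)
        for (rep_i in seq_len(cfg$sections_per_subject)) {
          idx <- idx + 1L
          sect_i <- sect
          sect_i$seed <- cfg$seed * 100000L + idx
          if (cfg$section_cv > 0) {
            # biological between-section variability: lognormal jitter
            set.seed(sect_i$seed + 7L)
            jit <- function(v, cap = Inf)
              pmin(cap, v * exp(rnorm(1, 0, cfg$section_cv)))
            for (par in c("epidermal_thickness_um", "edj_amplitude_um",
                          "nuclei_density_per_mm2"))
              sect_i[[par]] <- jit(sect_i[[par]])
            sect_i$vessel_area_fraction <-
              jit(sect_i$vessel_area_fraction, 0.5)
            # cap below the rejection-packing jamming limit
            sect_i$fibre_area_fraction <-
              jit(sect_i$fibre_area_fraction, 0.24)
          }
          spec <- do.call(section_spec, sect_i)
          gen <- generate_section_image(spec)
          met <- section_metrics(gen$image, gen$truth, cfg)
          if (length(met) > 0)
            records <- rbind(records, data.frame(
              subject = sprintf("subj%02d", subj),
              timepoint = tp,
              roi = sprintf("roi%02d", rep_i),
              metric = names(met),
              value = as.numeric(unlist(met)),
              row.names = NULL))
        }
      }
    }
    write.csv(records, file.path(cfg$out_dir, "morphometry.csv"),
              row.names = FALSE)
  }

  if ("stats" %in% stages && !is.null(records)) {
    stat_rows <- NULL
    for (m in unique(records$metric)) {
      sub <- records[records$metric == m & is.finite(records$value), ]
      if (length(unique(sub$timepoint)) < 2) next
      if (min(table(sub$timepoint)) < 3) next
      # outlier screen per (metric, timepoint) group
      flagged <- unlist(lapply(split(seq_len(nrow(sub)), sub$timepoint),
                               function(ix) {
        g <- grubbs_test(sub$value[ix])
        if (!is.na(g$outlier_index)) ix[g$outlier_index] else integer(0)
      }))
      if (length(flagged) > 0) sub <- sub[-flagged, ]
      if (min(table(sub$timepoint)) < 3) next
      sr <- tryCatch(
        select_and_run_test(sub[, c("value", "timepoint", "subject")],
                            design = "two-way"),
        error = function(e) {
          message("stats skipped for ", m, ": ", conditionMessage(e))
          NULL
        })
      if (is.null(sr)) next
      stat_res[[m]] <- sr
      stat_rows <- rbind(stat_rows, data.frame(
        metric = m, test = sr$test, statistic = sr$statistic,
        p_value = sr$p_value, branch = sr$trace$branch,
        n_outliers_removed = length(flagged)))
    }
    if (!is.null(stat_rows))
      write.csv(stat_rows, file.path(cfg$out_dir, "stats.csv"),
                row.names = FALSE)
  }

  if ("transcriptomics" %in% stages) {
    ex_args <- cfg$expression
    ex_args$seed <- cfg$seed
    gen <- do.call(generate_expression_dataset, ex_args)
    ds <- baseline_transform(gen$dataset)
    de <- anova_de_filter(ds)
    sets <- lapply(c(2, 4, 6), function(t) pairwise_de(ds, t))
    vp <- venn_core(sets[[1]], sets[[2]], sets[[3]])
    passing <- de$gene[de$pass]
    cl <- if (length(passing) >= 2)
      hierarchical_cluster(ds, genes = passing) else NULL
    write.csv(as.data.frame(de), file.path(cfg$out_dir, "de_anova.csv"),
              row.names = FALSE)
    venn_df <- do.call(rbind, lapply(
      c("unique2", "unique4", "unique6", "core"),
      function(r) if (length(vp[[r]]) > 0)
        data.frame(region = r, gene = vp[[r]]) else NULL))
    if (!is.null(venn_df))
      write.csv(venn_df, file.path(cfg$out_dir, "venn.csv"),
                row.names = FALSE)
    if (!is.null(cl))
      write_dendrogram_newick(cl, file.path(cfg$out_dir,
                                            "dendrogram.nwk"))
    tx <- list(de = de, pairwise = sets, venn = vp, clustering = cl,
               truth = gen$truth)
  }

  if (isTRUE(cfg$figures) && !is.null(records))
    plot_metric_panels(records, cfg$out_dir)

  prov <- list(
    package = "scarmorph",
    version = as.character(utils::packageVersion("scarmorph")),
    seed = cfg$seed,
    stages = stages,
    section = cfg$section,
    effects = cfg$effects,
    de_thresholds = list(fc = 1.5, p = 0.01, fdr = 0.01),
    grubbs_alpha = 0.05
  )
  jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(records = records, stats = stat_res,
                 transcriptomics = tx, out_dir = cfg$out_dir))
}

# metric-vs-timepoint scatter panels with grand-mean lines
plot_metric_panels <- function(records, out_dir) {
  for (m in unique(records$metric)) {
    sub <- records[records$metric == m & is.finite(records$value), ]
    if (nrow(sub) == 0) next
    gm <- stats::aggregate(value ~ timepoint, data = sub, FUN = mean)
    p <- ggplot2::ggplot(sub, ggplot2::aes(
      x = factor(timepoint), y = value)) +
      ggplot2::geom_jitter(width = 0.12, alpha = 0.7,
                           ggplot2::aes(colour = subject)) +
      ggplot2::geom_crossbar(
        data = gm, ggplot2::aes(x = factor(timepoint), y = value,
                                ymin = value, ymax = value),
        width = 0.45, linewidth = 0.4, colour = "black") +
      ggplot2::labs(x = "months post-transplant", y = m,
                    title = m) +
      ggplot2::theme_minimal()
    fp <- file.path(out_dir, paste0("fig_", m, ".png"))
    grDevices::png(fp, width = 900, height = 650, res = 150)
    print(p)
    grDevices::dev.off()
  }
  invisible(NULL)
}
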