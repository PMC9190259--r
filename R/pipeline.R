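## End-to-end orchestration: demo-panel generation and the staged analysis run
## (interactions -> CDR sampling -> affinity correlations).
##
## Each stage is an exported function over a single config list, so the
## numbered analysis drivers and run_pipeline() share one code path. Synthetic
## per-CDR conformational ensembles are regenerated at run time from the
## planted state counts recorded in the config; a rerun with the same config
## and seed reproduces the report bit for bit.

#' Write a complete synthetic demo panel
#'
#' Builds a seeded antibody panel with a planted ln(K_d) vs non-solvent
#' percentage relationship, writes per-antibody holo and apo PDB ensembles,
#' an affinity table and a pipeline config, and records the planted per-CDR
#' apo/holo state counts that the sampling stage will regenerate.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed controlling the whole panel.
#' @param n_antibodies panel size.
#' @param noise_sd noise on the planted ln(K_d) relation.
#' @param outlier index of an antibody whose ln(K_d) is shifted off the
#'   planted line (0 = none).
#' @return path of the written config file.
#' @export
make_demo <- function(dir, seed = 1, n_antibodies = 8, noise_sd = 0.5,
                      outlier = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- panel_spec(n_antibodies = n_antibodies, noise_sd = noise_sd,
                     outlier = outlier, seed = seed)
  panel <- generate_panel(spec, build_complexes = TRUE)
  aff <- data.frame(antibody_id = vapply(panel, `[[`, "", "antibody_id"),
                    kd_nM = vapply(panel, `[[`, 0, "kd_nM"),
                    koff = vapply(panel, `[[`, 0, "koff"))
  # one antibody without an affinity value, as real panels have
  if (n_antibodies >= 5) aff$kd_nM[n_antibodies] <- NA
  utils::write.csv(aff, file.path(dir, "affinities.csv"), row.names = FALSE)
  antibodies <- list()
  cdr_plan <- list()
  with_seed(seed + 1000L, {
    for (i in seq_along(panel)) {
      id <- panel[[i]]$antibody_id
      holo_path <- file.path(dir, paste0(id, "_holo.pdb"))
      write_ensemble(panel[[i]]$holo, holo_path)
      apo <- build_toy_complex(complex_spec(
        solvent = panel[[i]]$planted_counts[["solvent"]] +
          panel[[i]]$planted_counts[["bridge"]]))
      apo_path <- file.path(dir, paste0(id, "_apo.pdb"))
      write_ensemble(apo, apo_path)
      antibodies[[id]] <- list(holo = basename(holo_path),
                               apo = basename(apo_path))
      # planted per-CDR state counts: mostly equal, some more-apo, rarely
      # more-holo sampling (antigen-bound CDRs are usually the rigid ones)
      plan <- lapply(CDR_LOOPS, function(l) {
        holo_k <- sample(1:2, 1)
        apo_k <- holo_k + sample(0:2, 1, prob = c(0.6, 0.3, 0.1))
        if (stats::runif(1) < 0.04) { tmp <- apo_k; apo_k <- holo_k; holo_k <- tmp + 1 }
        list(apo_k = apo_k, holo_k = min(holo_k, 4L))
      })
      names(plan) <- CDR_LOOPS
      cdr_plan[[id]] <- plan
    }
  })
  cfg <- list(
    seed = seed,
    chains = list(H = "heavy", L = "light", A = "antigen"),
    water_names = c("HOH", "WAT", "SOL"),
    ion_names = c("NA", "CL"),
    mode = "fluctuating_interface",
    bin_width = 10,
    peak_bin_fraction = 0.015,
    rare_state_fraction = 0.01,
    similarity_threshold = 0.8,
    cluster_threshold = 11,
    dres_samples = 2000,
    dihedral_frames = 2000,
    cartesian_frames = 120,
    n_dihedrals = 4,
    affinities = "affinities.csv",
    antibodies = antibodies,
    cdr_plan = cdr_plan
  )
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  cfg_path
}

# deterministic small sub-seed for a labelled pipeline stage
.stage_seed <- function(seed, i, j = 0L) {
  (as.integer(seed) * 1009L + i * 101L + j) %% 2147483647L
}

.validate_inputs <- function(cfg, base_dir) {
  for (ab in names(cfg$antibodies)) {
    for (f in unlist(cfg$antibodies[[ab]])) {
      if (!file.exists(file.path(base_dir, f))) {
        stop("validation error: missing input file ", f, " for ", ab)
      }
    }
  }
  invisible(TRUE)
}

#' Stage 1: interface interactions per antibody
#'
#' Reads each antibody's holo ensemble, summarises all intermolecular
#' interaction kinds per frame and derives the non-solvent percentages.
#'
#' @param cfg config list (see [read_config()] / [make_demo()]).
#' @param base_dir directory the config's relative paths resolve against.
#' @param out_dir if non-NULL, interactions.csv is written there.
#' @return data.frame, one row per antibody.
#' @export
stage_interactions <- function(cfg, base_dir, out_dir = NULL) {
  criteria <- do.call(interaction_criteria, cfg$criteria %||% list())
  rows <- list()
  for (ab in names(cfg$antibodies)) {
    holo <- read_ensemble(file.path(base_dir, cfg$antibodies[[ab]]$holo), cfg)
    summ <- summarize_trajectory(holo,
                                 mode = cfg$mode %||% "fluctuating_interface",
                                 criteria = criteria,
                                 stride = cfg$stride %||% 1L)
    ns <- nonsolvent_fraction(summ)
    rows[[ab]] <- data.frame(antibody_id = ab, t(ns), t(summ$mean),
                             check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_dir)) write_table(out, file.path(out_dir, "interactions.csv"))
  out
}

#' Stage 2: per-CDR conformational sampling
#'
#' For every antibody and CDR loop, regenerates seeded dihedral and Cartesian
#' ensembles from the planted state counts in `cfg$cdr_plan`, builds
#' histogram-peak states, matches apo/holo states by circular similarity, and
#' runs the PCA / average-linkage / DRES analysis.
#'
#' @inheritParams stage_interactions
#' @return data.frame, one row per antibody x CDR.
#' @export
stage_cdr_sampling <- function(cfg, out_dir = NULL) {
  seed <- cfg$seed %||% 1L
  per_cdr <- list()
  ab_ids <- names(cfg$antibodies)
  base <- build_toy_complex(complex_spec(hbond = 1))
  cdr_idx <- select_atoms(base, chain = "H", resid = 1, backbone = TRUE)
  for (i in seq_along(ab_ids)) {
    ab <- ab_ids[i]
    plan <- cfg$cdr_plan[[ab]]
    for (j in seq_along(CDR_LOOPS)) {
      loop <- CDR_LOOPS[j]
      ka <- plan[[loop]]$apo_k; kh <- plan[[loop]]$holo_k
      gen <- function(k, sub) {
        generate_dihedral_ensemble(
          n_dihedrals = cfg$n_dihedrals %||% 4,
          populations = rep(1 / k, k),
          n_frames = cfg$dihedral_frames %||% 2000,
          spread = 8, seed = .stage_seed(seed, i, 10L * j + sub),
          cdr_id = loop)
      }
      mk_states <- function(g) {
        build_states(g$series,
                     peak_bin_fraction = cfg$peak_bin_fraction %||% 0.015,
                     rare_state_fraction = cfg$rare_state_fraction %||% 0.01,
                     bin_width = cfg$bin_width %||% 10)
      }
      apo_states <- mk_states(gen(ka, 1L))
      holo_states <- mk_states(gen(kh, 2L))
      mr <- match_states(apo_states, holo_states,
                         threshold = cfg$similarity_threshold %||% 0.8)
      centers_for <- function(k) lapply(seq_len(k), function(c3)
        c((c3 - 1) * 12, 0, 0))
      nf <- cfg$cartesian_frames %||% 120
      apo_cart <- generate_cartesian_ensemble(base, cdr_idx, centers_for(ka),
                                              spread = 0.5, n_frames = nf,
                                              seed = .stage_seed(seed, i, 10L * j + 3L))
      holo_cart <- generate_cartesian_ensemble(base, cdr_idx, centers_for(kh),
                                               spread = 0.5, n_frames = nf,
                                               seed = .stage_seed(seed, i, 10L * j + 4L))
      pca <- fit_pca(apo_cart$ensemble, holo_cart$ensemble, cdr_idx)
      pr_a <- project_ensemble(pca, apo_cart$ensemble, source = "apo")
      pr_h <- project_ensemble(pca, holo_cart$ensemble, source = "holo")
      cl_a <- cluster_projections(pr_a, threshold = cfg$cluster_threshold %||% 11)
      cl_h <- cluster_projections(pr_h, threshold = cfg$cluster_threshold %||% 11)
      dr <- dres(pr_a, pr_h, n_samples = cfg$dres_samples %||% 2000,
                 seed = .stage_seed(seed, i, 10L * j + 5L))
      per_cdr[[length(per_cdr) + 1]] <- data.frame(
        antibody_id = ab, cdr = loop,
        apo_pca_clusters = cl_a$n_clusters, holo_pca_clusters = cl_h$n_clusters,
        apo_dash_states = n_states(apo_states),
        holo_dash_states = n_states(holo_states),
        apo_rare_fraction = apo_states$rare_fraction,
        holo_rare_fraction = holo_states$rare_fraction,
        matched_states = nrow(mr$pairs),
        dres = dr$value)
    }
  }
  out <- do.call(rbind, per_cdr)
  if (!is.null(out_dir)) write_table(out, file.path(out_dir, "per_cdr.csv"))
  out
}

#' Stage 3: metric aggregation, correlations, sampling classes, report
#'
#' @inheritParams stage_interactions
#' @param interactions result of [stage_interactions()].
#' @param per_cdr result of [stage_cdr_sampling()].
#' @return report list (metrics, correlations, sampling_percentages, settings).
#' @export
stage_correlations <- function(cfg, base_dir, interactions, per_cdr,
                               out_dir = NULL) {
  affinities <- utils::read.csv(file.path(base_dir, cfg$affinities))
  metrics <- build_metric_table(per_cdr,
                                interactions[, c("antibody_id", "nonsolvent_pct",
                                                 "nonsolvent_nonhydrophobic_pct",
                                                 "hydrophobic_pct")],
                                affinities)
  ok <- metrics$has_affinity
  corr_of <- function(xcol, ycol) {
    tryCatch(pearson_r2(metrics[[xcol]][ok], metrics[[ycol]][ok],
                        x_name = xcol, y_name = ycol),
             error = function(e) NULL)
  }
  correlations <- Filter(Negate(is.null), list(
    nonsolvent_vs_lnkd = corr_of("nonsolvent_pct", "ln_kd"),
    nonsolvent_nonhydrophobic_vs_lnkd =
      corr_of("nonsolvent_nonhydrophobic_pct", "ln_kd"),
    nonsolvent_vs_lnkoff = if ("ln_koff" %in% names(metrics))
      corr_of("nonsolvent_pct", "ln_koff") else NULL,
    holo_pca_vs_lnkd = corr_of("mean_holo_pca_clusters", "ln_kd"),
    holo_dash_vs_lnkd = corr_of("mean_holo_dash_states", "ln_kd"),
    dres_vs_lnkd = corr_of("mean_dres", "ln_kd")))
  classes <- data.frame(
    method = rep(c("pca", "dash"), each = nrow(per_cdr)),
    class = c(mapply(compare_sampling, per_cdr$apo_pca_clusters,
                     per_cdr$holo_pca_clusters),
              mapply(compare_sampling, per_cdr$apo_dash_states,
                     per_cdr$holo_dash_states)))
  pct <- lapply(split(classes$class, classes$method),
                sampling_class_percentages)
  pct_df <- do.call(rbind, lapply(names(pct), function(m)
    data.frame(method = m, more_apo = pct[[m]][["more_apo"]],
               equal = pct[[m]][["equal"]],
               more_holo = pct[[m]][["more_holo"]])))
  criteria <- do.call(interaction_criteria, cfg$criteria %||% list())
  report <- list(
    schema_version = "1.0",
    settings = list(seed = cfg$seed %||% 1L,
                    mode = cfg$mode %||% "fluctuating_interface",
                    bin_width = cfg$bin_width %||% 10,
                    peak_bin_fraction = cfg$peak_bin_fraction %||% 0.015,
                    rare_state_fraction = cfg$rare_state_fraction %||% 0.01,
                    similarity_threshold = cfg$similarity_threshold %||% 0.8,
                    cluster_threshold = cfg$cluster_threshold %||% 11,
                    criteria = unclass(criteria)[
                      !names(unclass(criteria)) %in% "cation_pi_angle_windows"]),
    metrics = metrics,
    correlations = lapply(correlations, unclass),
    sampling_percentages = pct_df)
  if (!is.null(out_dir)) {
    write_table(metrics, file.path(out_dir, "metrics.csv"))
    corr_df <- do.call(rbind, lapply(correlations, function(cr)
      data.frame(x = cr$x_name, y = cr$y_name, n = cr$n,
                 r_squared = cr$r_squared, slope = cr$slope,
                 intercept = cr$intercept,
                 max_delta_point = cr$max_delta_point,
                 r_squared_omitting_max = cr$r_squared_omitting_max)))
    write_table(corr_df, file.path(out_dir, "correlations.csv"))
    write_table(pct_df, file.path(out_dir, "sampling_classes.csv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Run the full analysis pipeline from a config file
#'
#' Validates inputs, then runs [stage_interactions()],
#' [stage_cdr_sampling()] and [stage_correlations()], writing all tables plus
#' report.json to `out_dir`.
#'
#' @param config_path path to a config written by [make_demo()] (or
#'   hand-edited with the same schema).
#' @param out_dir output directory (default: directory of the config).
#' @return the report, invisibly.
#' @export
run_pipeline <- function(config_path, out_dir = dirname(config_path)) {
  cfg <- read_config(config_path)
  base_dir <- dirname(config_path)
  .validate_inputs(cfg, base_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  interactions <- stage_interactions(cfg, base_dir, out_dir)
  per_cdr <- stage_cdr_sampling(cfg, out_dir)
  report <- stage_correlations(cfg, base_dir, interactions, per_cdr, out_dir)
  invisible(report)
}
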