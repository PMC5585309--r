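# Results-level analysis: per-cluster summaries, group comparisons,
# correlations, neuropil-context stratification, and the end-to-end
# pipeline runner.

#' Summarise synaptic targets per bouton cluster
#'
#' One summary row per cluster: counts and spiny/smooth proportions
#' (unclassified targets are excluded from the proportions but
#' reported), PSD statistics, and mean dendrite radius by target class.
#' Rows are sorted by ascending SI with unknown SIs last.
#'
#' @param table synapse-level data.frame with at least
#'   \code{cluster_id, cluster_kind, si, target_class}; optionally
#'   \code{neuron_id, psd_area_um2, dendrite_radius_um,
#'   soma_depth_norm}.
#' @return data.frame, one row per cluster.
#' @export
summarize_clusters <- function(table) {
  if (!nrow(table)) stop("empty synapse table")
  stopifnot(all(c("cluster_id", "cluster_kind", "si", "target_class") %in%
                  names(table)))
  opt <- function(cl, col, f) {
    if (col %in% names(table)) f(table[[col]][table$cluster_id == cl]) else NA
  }
  ids <- unique(table$cluster_id)
  out <- do.call(rbind, lapply(ids, function(cl) {
    rows <- table[table$cluster_id == cl, ]
    n_spiny <- sum(rows$target_class == "spiny")
    n_smooth <- sum(rows$target_class == "smooth")
    n_uncl <- sum(!rows$target_class %in% c("spiny", "smooth"))
    n_known <- n_spiny + n_smooth
    rad <- if ("dendrite_radius_um" %in% names(table))
      rows$dendrite_radius_um else rep(NA_real_, nrow(rows))
    data.frame(
      cluster_id = cl,
      neuron_id = if ("neuron_id" %in% names(rows)) rows$neuron_id[1]
                  else NA_character_,
      cluster_kind = rows$cluster_kind[1],
      si = rows$si[1],
      n = nrow(rows),
      n_spiny = n_spiny, n_smooth = n_smooth, n_unclassified = n_uncl,
      prop_spiny = if (n_known > 0) n_spiny / n_known else NA_real_,
      prop_smooth = if (n_known > 0) n_smooth / n_known else NA_real_,
      pct_spiny = if (n_known > 0) round(100 * n_spiny / n_known)
                  else NA_real_,
      mean_psd = opt(cl, "psd_area_um2", function(x) mean(x, na.rm = TRUE)),
      sd_psd = opt(cl, "psd_area_um2", function(x) stats::sd(x[!is.na(x)])),
      mean_radius_spiny = mean(rad[rows$target_class == "spiny"],
                               na.rm = TRUE),
      mean_radius_smooth = mean(rad[rows$target_class == "smooth"],
                                na.rm = TRUE),
      soma_depth_norm = if ("soma_depth_norm" %in% names(rows))
        rows$soma_depth_norm[1] else NA_real_,
      stringsAsFactors = FALSE)
  }))
  out <- out[order(is.na(out$si), out$si), ]
  rownames(out) <- NULL
  out
}

#' Compare dendrite radii between local and distal clusters
#'
#' Welch two-sample two-tailed t-test of target-dendrite radii, local
#' vs distal clusters, run separately for spiny and smooth targets.
#'
#' @param table synapse-level data.frame with \code{cluster_kind},
#'   \code{target_class} and \code{dendrite_radius_um}.
#' @return data.frame with one row per target class: group sizes,
#'   means, standard errors, t, df and p.
#' @export
compare_radii <- function(table) {
  stopifnot(all(c("cluster_kind", "target_class", "dendrite_radius_um") %in%
                  names(table)))
  one <- function(cls) {
    x <- table$dendrite_radius_um[table$cluster_kind == "local" &
                                    table$target_class == cls]
    y <- table$dendrite_radius_um[table$cluster_kind == "distal" &
                                    table$target_class == cls]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) {
      stop("need >= 2 radii per group for class ", cls)
    }
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      tt <- list(statistic = c(t = 0), parameter = c(df = NA_real_),
                 p.value = if (mean(x) == mean(y)) 1 else 0)
    } else {
      tt <- stats::t.test(x, y, var.equal = FALSE)
    }
    data.frame(target_class = cls,
               n_local = length(x), n_distal = length(y),
               mean_local = mean(x), mean_distal = mean(y),
               se_local = stats::sd(x) / sqrt(length(x)),
               se_distal = stats::sd(y) / sqrt(length(y)),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(c("spiny", "smooth"), one))
  rownames(out) <- NULL
  out
}

#' Pearson correlation between two synapse-table fields
#'
#' Pairwise deletion of missing values; requires at least 3 complete
#' pairs and non-constant margins.
#'
#' @param table data.frame.
#' @param x_field,y_field column names.
#' @return list with \code{r}, \code{n}, \code{p}.
#' @export
correlate <- function(table, x_field, y_field) {
  x <- table[[x_field]]; y <- table[[y_field]]
  if (is.null(x) || is.null(y)) stop("fields not found in table")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: constant field")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), n = length(x), p = ct$p.value)
}

#' Neuropil composition around labeled synapses, stratified
#'
#' Each labeled synapse carries disector counts of the unlabeled
#' synaptic targets in its surrounding neuropil (columns
#' \code{n_spine, n_shaft, n_soma}). The mean neuropil composition is
#' reported stratified (a) by the labeled synapse's own target class
#' and (b) by whether the labeled synapse's cluster formed more or at
#' most \code{threshold} of its synapses with smooth neurons.
#'
#' @param table data.frame with one row per labeled synapse:
#'   \code{cluster_id}, \code{target_class}, \code{n_spine},
#'   \code{n_shaft}, \code{n_soma}.
#' @param threshold cluster smooth-share cut (default 0.2).
#' @return list with \code{by_target_class},
#'   \code{by_cluster_smooth_share} (mean composition data.frames) and
#'   \code{threshold}.
#' @export
neuropil_context <- function(table, threshold = 0.2) {
  need <- c("cluster_id", "target_class", "n_spine", "n_shaft", "n_soma")
  stopifnot(all(need %in% names(table)))
  tot <- table$n_spine + table$n_shaft + table$n_soma
  if (any(tot < 1)) {
    stop("every labeled synapse needs at least one surrounding count")
  }
  comp <- cbind(spine = table$n_spine, shaft = table$n_shaft,
                soma = table$n_soma) / tot
  mean_comp <- function(sel, label) {
    data.frame(stratum = label, n_synapses = sum(sel),
               t(colMeans(comp[sel, , drop = FALSE])),
               stringsAsFactors = FALSE)
  }
  by_class <- do.call(rbind, lapply(
    intersect(c("spiny", "smooth"), unique(table$target_class)),
    function(cl) mean_comp(table$target_class == cl,
                           paste0("labeled_target_", cl))))
  smooth_share <- tapply(table$target_class == "smooth", table$cluster_id,
                         mean)
  hi <- table$cluster_id %in% names(smooth_share)[smooth_share > threshold]
  strata <- list()
  if (any(hi)) strata[[length(strata) + 1L]] <-
    mean_comp(hi, sprintf("cluster_smooth_share_gt_%.2g", threshold))
  if (any(!hi)) strata[[length(strata) + 1L]] <-
    mean_comp(!hi, sprintf("cluster_smooth_share_le_%.2g", threshold))
  list(by_target_class = by_class,
       by_cluster_smooth_share = do.call(rbind, strata),
       threshold = threshold)
}

#' Run the full analysis pipeline
#'
#' Executes the chain: synthetic orientation map, morphology placed in
#' chosen domains, similarity indices of local and distal clusters,
#' fixture-table cluster summaries, random-walk null model and
#' variance comparison against the observed per-cluster smooth
#' fractions, morphometric comparisons (radius t-tests, PSD-volume and
#' depth-smoothness correlations), and conduction-velocity estimates.
#' Writes \code{cluster_summary.csv}, \code{walk_fractions.csv},
#' \code{si.csv} and a \code{report.json} manifest into
#' \code{config$out_dir}; outputs are byte-identical under identical
#' config and seed.
#'
#' @param config named list (or path to a JSON file): \code{seed},
#'   \code{out_dir} (required), optional \code{map}
#'   (\code{size_px, pixel_um, bandpass}), \code{morphology}
#'   (\code{local_domain_deg, distal_domain_deg, distal_offset_um}),
#'   \code{neuropil} (\code{density, cube_um, class_fractions}),
#'   \code{walk} (\code{n_reps, n_synapses_stop, capture_radius_um,
#'   step_um, persistence_kappa}).
#' @return list of all computed results, invisibly written to disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("configuration error: no such file: ",
                                   config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$out_dir)) stop("configuration error: out_dir required")
  if (is.null(config$seed)) stop("configuration error: seed required")
  gp <- function(block, field, default) {
    v <- config[[block]][[field]]
    if (is.null(v)) default else v
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  cf <- synth_config(
    seed = config$seed,
    map_size_px = gp("map", "size_px", c(128L, 128L)),
    pixel_um = gp("map", "pixel_um", 20),
    map_bandpass = gp("map", "bandpass", c(0.5, 1.5)),
    neuropil_density = gp("neuropil", "density", 0.3),
    cube_um = gp("neuropil", "cube_um", 500))

  map <- make_orientation_map(cf)
  morph <- make_morphology(
    cf, map,
    local_domain_deg = gp("morphology", "local_domain_deg", 0),
    distal_domain_deg = gp("morphology", "distal_domain_deg", 90),
    distal_offset_um = gp("morphology", "distal_offset_um",
                          0.3 * cf$map_size_px[2] * cf$pixel_um))
  dend <- morphology_sample(morph, "dendrites")
  si_local <- similarity_index(map, dend, morphology_sample(morph, "local"))
  si_distal <- similarity_index(map, dend, morphology_sample(morph, "distal"))
  si_tab <- data.frame(cluster = c("local", "distal"),
                       si = c(si_local, si_distal),
                       class = classify_si(c(si_local, si_distal)))

  fx <- fixture_tables()
  summary_tab <- summarize_clusters(fx$synapse_table[
    fx$synapse_table$cluster_kind != "linear", ])

  field <- make_neuropil_field(cf)
  wcfg <- walk_config(
    n_synapses_stop = gp("walk", "n_synapses_stop",
                         round(stats::median(summary_tab$n))),
    cube_um = cf$cube_um,
    capture_radius_um = gp("walk", "capture_radius_um", 1),
    n_reps = gp("walk", "n_reps", 10000L),
    step_um = gp("walk", "step_um", 1),
    persistence_kappa = gp("walk", "persistence_kappa", 20),
    seed = child_seed(config$seed, "pipeline_walk"))
  wres <- run_walk(field, wcfg)
  vcmp <- variance_comparison(summary_tab$prop_smooth, wres,
                              seed = child_seed(config$seed, "pipeline_null"))

  radii <- compare_radii(fx$synapse_table)
  spine_rows <- fx$synapse_table[fx$synapse_table$target_structure == "spine", ]
  cors <- list(
    psd_volume_local = correlate(
      spine_rows[spine_rows$cluster_kind == "local", ],
      "psd_area_um2", "spine_volume_um3"),
    psd_volume_distal = correlate(
      spine_rows[spine_rows$cluster_kind == "distal", ],
      "psd_area_um2", "spine_volume_um3"),
    depth_smooth = correlate(summary_tab, "soma_depth_norm", "prop_smooth"))

  d0 <- fx$myelin$velocity_reference_diameter_um
  v_my <- conduction_velocity_myelinated(d0)
  v_un <- conduction_velocity_unmyelinated(d0)
  biophys <- list(
    diameter_um = d0,
    velocity_myelinated_ms = v_my,
    velocity_unmyelinated_ms = v_un,
    transit_diff_1mm_ms = transit_time_ms(1, v_un) - transit_time_ms(1, v_my))

  utils::write.csv(summary_tab,
                   file.path(config$out_dir, "cluster_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(rep = seq_along(wres$per_rep_smooth_fraction),
                              smooth_fraction = wres$per_rep_smooth_fraction,
                              synapses = wres$per_rep_synapses,
                              steps = wres$per_rep_steps),
                   file.path(config$out_dir, "walk_fractions.csv"),
                   row.names = FALSE)
  utils::write.csv(si_tab, file.path(config$out_dir, "si.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = config$seed,
         package = "daisynet",
         version = as.character(utils::packageVersion("daisynet")),
         si = si_tab,
         variance_comparison = vcmp[c("observed_var", "mc_p")],
         radii = radii, correlations = cors, biophysics = biophys,
         truncated_reps = wres$truncated_reps,
         notes = c("disector height = reference-to-lookup separation",
                   "no multiple-comparison correction applied")),
    file.path(config$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(map = map, morphology = morph, si = si_tab,
                 cluster_summary = summary_tab, walk = wres,
                 variance_comparison = vcmp, radii = radii,
                 correlations = cors, biophysics = biophys))
}
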