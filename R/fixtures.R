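#' Packaged fixture tables of the published synapse counts
#'
#' Builds, deterministically and entirely in code, a synapse-level
#' dataset that reproduces every printed count marginal of the study:
#' 233 synapses in all (174 on spines, 54 on shafts, 5 on somata; 182
#' with spiny neurons), sampled from five local clusters, five distal
#' clusters and four linear axonal segments; 50 linear-segment
#' swellings of which 28 form synapses (22 on spines, 6 on smooth
#' shafts); distal-cluster spiny-target percentages
#' \{50, 65, 72, 82, 100\} and local range 52-95; local SIs 0.77-0.88,
#' known distal SIs \{0.14, 0.21, 0.68\} with two distal clusters
#' unreliable (map edge, SI = NA); per-cluster sample sizes within
#' 14-23.
#'
#' Quantities the text prints only as marginals (the soma spiny/smooth
#' split, the three intermediate local percentages, per-synapse PSD
#' areas, spine volumes, dendrite radii, soma depths) belong to a
#' clearly flagged reconstructed tier (\code{si_source} /
#' \code{reconstructed} columns): they are synthetic values engineered
#' to be consistent with the printed summaries (linear-segment PSD
#' means/SDs 0.14/0.09 and 0.11/0.07; PSD-vs-spine-volume Pearson r of
#' 0.63 local and 0.68 distal; depth-vs-smooth-fraction r near 0.67;
#' the four quadruplet PSD areas 0.18, 0.16, 0.15, 0.14) and should
#' never be read as measured data.
#'
#' @return list with \code{synapse_table}, \code{cluster_table},
#'   \code{linear_segment_table}, \code{quadruplet_psd_areas} and
#'   \code{myelin} (the printed fiber-calibre summary scalars used by
#'   the conduction-velocity worked example).
#' @export
fixture_tables <- function() {
  clusters <- data.frame(
    cluster_id = c(paste0("D", 1:5), paste0("L", 1:5)),
    neuron_id = c("N1", "N5", "N4", "N3", "N2",
                  "N1", "N2", "N3", "N4", "N5"),
    cluster_kind = rep(c("distal", "local"), each = 5),
    si = c(0.14, 0.21, NA, NA, 0.68,
           0.77, 0.79, 0.82, 0.85, 0.88),
    si_source = c("printed", "printed", "edge-of-map", "edge-of-map",
                  "printed", "printed", "printed",
                  "reconstructed-from-figure", "reconstructed-from-figure",
                  "printed"),
    spine = c(11, 21, 13, 13, 17, 11, 16, 17, 16, 17),
    shaft_spiny = c(0, 1, 0, 0, 1, 0, 1, 1, 1, 1),
    shaft_smooth = c(10, 0, 6, 5, 4, 9, 3, 2, 2, 1),
    soma_spiny = c(0, 1, 0, 0, 0, 0, 0, 0, 0, 1),
    soma_smooth = c(1, 0, 1, 0, 0, 1, 0, 0, 0, 0),
    stringsAsFactors = FALSE)

  segments <- data.frame(
    cluster_id = paste0("LS", 1:4),
    neuron_id = paste0("N", 1:4),
    n_swellings = c(13, 13, 12, 12),
    spine = c(6, 5, 6, 5),
    shaft_smooth = c(1, 2, 1, 2),
    stringsAsFactors = FALSE)

  depths <- c(N1 = 0.73, N2 = 0.20, N3 = 0.24, N4 = 0.17, N5 = 0.34)

  expand_cluster <- function(cl) {
    structure_ <- c(rep("spine", cl$spine),
                    rep("shaft", cl$shaft_spiny),
                    rep("shaft", cl$shaft_smooth),
                    rep("soma", cl$soma_spiny),
                    rep("soma", cl$soma_smooth))
    class_ <- c(rep("spiny", cl$spine),
                rep("spiny", cl$shaft_spiny),
                rep("smooth", cl$shaft_smooth),
                rep("spiny", cl$soma_spiny),
                rep("smooth", cl$soma_smooth))
    data.frame(cluster_id = cl$cluster_id, neuron_id = cl$neuron_id,
               cluster_kind = cl$cluster_kind, si = cl$si,
               target_structure = structure_, target_class = class_,
               stringsAsFactors = FALSE)
  }
  syn <- do.call(rbind, lapply(seq_len(nrow(clusters)), function(i)
    expand_cluster(clusters[i, ])))

  lin <- do.call(rbind, lapply(seq_len(nrow(segments)), function(i) {
    sg <- segments[i, ]
    data.frame(cluster_id = sg$cluster_id, neuron_id = sg$neuron_id,
               cluster_kind = "linear", si = NA_real_,
               target_structure = c(rep("spine", sg$spine),
                                    rep("shaft", sg$shaft_smooth)),
               target_class = c(rep("spiny", sg$spine),
                                rep("smooth", sg$shaft_smooth)),
               stringsAsFactors = FALSE)
  }))
  syn <- rbind(syn, lin)
  syn$synapse_id <- sprintf("S%03d", seq_len(nrow(syn)))
  syn$soma_depth_norm <- unname(depths[syn$neuron_id])

  # --- reconstructed per-synapse measurements (fixed internal stream) ---
  syn <- with_seed(child_seed(20170227L, "fixture_measurements"), {
    n <- nrow(syn)
    psd <- stats::rlnorm(n, meanlog = log(0.12), sdlog = 0.45)
    big <- syn$target_class == "smooth" & syn$target_structure == "shaft"
    psd[big] <- psd[big] * 1.25   # a few very large PSDs sit on smooth shafts
    syn$psd_area_um2 <- round(psd, 4)

    # quadruplet of synapses on one apical dendrite (distal cluster)
    quad <- which(syn$cluster_id == "D5" & syn$target_structure == "spine")[1:4]
    syn$psd_area_um2[quad] <- c(0.18, 0.16, 0.15, 0.14)

    # linear-segment PSDs: exact printed means/SDs
    lin_sp <- which(syn$cluster_kind == "linear" &
                      syn$target_structure == "spine")
    lin_sm <- which(syn$cluster_kind == "linear" &
                      syn$target_structure == "shaft")
    syn$psd_area_um2[lin_sp] <-
      set_moments(stats::rlnorm(length(lin_sp), sdlog = 0.55), 0.14, 0.09)
    syn$psd_area_um2[lin_sm] <-
      set_moments(stats::rlnorm(length(lin_sm), sdlog = 0.5), 0.11, 0.07)

    # spine volumes correlated with PSD area, exact sample r per kind
    syn$spine_volume_um3 <- NA_real_
    for (kk in c("local", "distal")) {
      idx <- which(syn$cluster_kind == kk & syn$target_structure == "spine")
      r <- if (kk == "local") 0.63 else 0.68
      z <- exact_cor_score(syn$psd_area_um2[idx], r)
      syn$spine_volume_um3[idx] <- 0.12 + 0.03 * z
    }

    # dendrite radii: smooth targets thicker in distal clusters
    syn$dendrite_radius_um <- NA_real_
    sm <- syn$target_class == "smooth" & syn$target_structure == "shaft"
    sp <- syn$target_structure %in% c("spine", "shaft") & !sm
    is_distal <- syn$cluster_kind == "distal"
    syn$dendrite_radius_um[sm & !is_distal] <-
      pmax(0.12, stats::rnorm(sum(sm & !is_distal), 0.35, 0.07))
    syn$dendrite_radius_um[sm & is_distal] <-
      pmax(0.12, stats::rnorm(sum(sm & is_distal), 0.55, 0.09))
    syn$dendrite_radius_um[sm & syn$cluster_kind == "linear"] <-
      pmax(0.12, stats::rnorm(sum(sm & syn$cluster_kind == "linear"),
                              0.45, 0.09))
    syn$dendrite_radius_um[sp] <- pmax(0.12, stats::rnorm(sum(sp), 0.40, 0.10))
    syn
  })
  syn$reconstructed <- TRUE  # all per-synapse measurements are synthetic
  rownames(syn) <- NULL
  syn <- syn[, c("synapse_id", "neuron_id", "cluster_id", "cluster_kind",
                 "si", "target_structure", "target_class", "psd_area_um2",
                 "spine_volume_um3", "dendrite_radius_um",
                 "soma_depth_norm", "reconstructed")]

  cluster_table <- summarize_clusters(syn[syn$cluster_kind != "linear", ])
  cluster_table$si_source <-
    clusters$si_source[match(cluster_table$cluster_id, clusters$cluster_id)]

  # --- linear-segment swelling table: 50 swellings, 28 synaptic ---
  lseg <- do.call(rbind, lapply(seq_len(nrow(segments)), function(i) {
    sg <- segments[i, ]
    n_syn <- sg$spine + sg$shaft_smooth
    data.frame(segment_id = sg$cluster_id,
               swelling_id = sprintf("%s_w%02d", sg$cluster_id,
                                     seq_len(sg$n_swellings)),
               has_synapse = seq_len(sg$n_swellings) <= n_syn,
               target_structure = c(rep("spine", sg$spine),
                                    rep("shaft", sg$shaft_smooth),
                                    rep("none", sg$n_swellings - n_syn)),
               target_class = c(rep("spiny", sg$spine),
                                rep("smooth", sg$shaft_smooth),
                                rep(NA_character_, sg$n_swellings - n_syn)),
               stringsAsFactors = FALSE)
  }))
  lin_idx <- which(syn$cluster_kind == "linear")
  lseg$psd_area_um2 <- NA_real_
  lseg$psd_area_um2[lseg$has_synapse] <- syn$psd_area_um2[lin_idx]
  rownames(lseg) <- NULL

  list(synapse_table = syn,
       cluster_table = cluster_table,
       linear_segment_table = lseg,
       quadruplet_psd_areas = c(0.18, 0.16, 0.15, 0.14),
       myelin = list(total_diameter_mean_um = 0.30,
                     total_diameter_range_um = c(0.15, 0.56),
                     n_measurements = 34L,
                     sheath_thickness_mean_um = 0.048,
                     sheath_thickness_range_um = c(0.040, 0.080),
                     velocity_reference_diameter_um = 0.35,
                     shrinkage_fraction = 0.11))
}

# rescale x to have exactly the given sample mean and sd
set_moments <- function(x, m, s) {
  m + s * (x - mean(x)) / stats::sd(x)
}

# standardized score with exact sample Pearson correlation r against x
exact_cor_score <- function(x, r) {
  zx <- as.numeric(scale(x))
  e <- stats::rnorm(length(x))
  ze <- stats::residuals(stats::lm(e ~ zx))
  ze <- as.numeric(scale(ze))
  r * zx + sqrt(1 - r^2) * ze
}
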