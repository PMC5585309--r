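# File formats: orientation maps as float TIFF + JSON sidecar, neuron
# morphologies as SWC, tabular interchange as CSV.

#' Write an orientation map as TIFF plus JSON sidecar
#'
#' The map is stored as a two-sample 32-bit float TIFF (sample 1:
#' angle / 180 so values lie in [0, 1); sample 2: magnitude / max
#' magnitude). The sidecar \code{<path>.json} records \code{pixel_um}
#' and the magnitude scale so the map round-trips. A third page holds
#' the defined-angle mask (undefined pixels store angle 0, mask 0).
#'
#' @param map an [orientation_map()].
#' @param path output TIFF path; the sidecar is written to
#'   \code{paste0(path, ".json")}.
#' @return \code{path}, invisibly.
#' @export
write_orientation_map <- function(map, path) {
  stopifnot(inherits(map, "orientation_map"))
  d <- dim(map$angle_deg)
  mag_scale <- max(map$magnitude, 0)
  a <- map$angle_deg / 180
  mask <- matrix(as.numeric(!is.na(a)), d[1], d[2])
  a[is.na(a)] <- 0
  m <- if (mag_scale > 0) map$magnitude / mag_scale else map$magnitude
  tiff::writeTIFF(list(a, m, mask), path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(pixel_um = map$pixel_um, magnitude_scale = mag_scale,
         angle_units = "deg/180", format = "daisynet orientation_map v1"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an orientation map written by [write_orientation_map()]
#' @param path TIFF path with \code{<path>.json} sidecar alongside.
#' @return an [orientation_map()].
#' @export
read_orientation_map <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  img <- tiff::readTIFF(path, all = TRUE)
  if (length(img) < 3L) stop("expected a three-page orientation-map TIFF")
  a <- img[[1]] * 180
  a[img[[3]] < 0.5] <- NA_real_
  m <- img[[2]] * side$magnitude_scale
  orientation_map(wrap180_keep_na(a), m, side$pixel_um)
}

# wrap but preserve NA (undefined-angle pixels)
wrap180_keep_na <- function(a) {
  ok <- !is.na(a)
  a[ok] <- a[ok] %% 180
  a
}

#' Write a morphology in SWC format
#'
#' Standard 7-column SWC (\code{id type x y z radius parent}), positions
#' in micrometres. Node types: 1 soma, 2 axon, 3 dendrite; bouton
#' markers use the custom codes 7 (local-cluster bouton) and 8
#' (distal-cluster bouton), recorded in the header comment.
#'
#' @param morph a [morphology()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_swc <- function(morph, path) {
  stopifnot(inherits(morph, "morphology"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# SWC morphology (daisynet)",
    "# types: 1 soma, 2 axon, 3 dendrite, 7 local-cluster bouton, 8 distal-cluster bouton",
    "# units: um"), con)
  df <- morph$nodes
  lines <- sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                   df$id, df$type, df$x, df$y, df$z, df$radius, df$parent)
  writeLines(lines, con)
  invisible(path)
}

#' Read an SWC morphology file
#' @param path SWC path.
#' @return a [morphology()].
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("empty SWC file")
  fields <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  if (ncol(fields) != 7L) stop("SWC requires exactly 7 columns")
  morphology(data.frame(
    id = as.integer(fields[, 1]), type = as.integer(fields[, 2]),
    x = fields[, 3], y = fields[, 4], z = fields[, 5],
    radius = fields[, 6], parent = as.integer(fields[, 7])))
}

#' Write a serial-section profile stack to CSV
#'
#' One row per synapse profile: \code{section, id, x, y, type, target,
#' class}. The section thickness is stored in a commented key line that
#' [read_section_stack()] understands.
#'
#' @param stack a [section_stack()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_section_stack <- function(stack, path) {
  stopifnot(inherits(stack, "section_stack"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# section_thickness_nm=%.17g",
                       stack$section_thickness_nm),
               sprintf("# n_sections=%d", stack$n_sections)), con)
  utils::write.csv(stack$profiles, con, row.names = FALSE)
  invisible(path)
}

#' Read a serial-section profile stack from CSV
#' @param path CSV written by [write_section_stack()].
#' @return a [section_stack()].
#' @export
read_section_stack <- function(path) {
  hdr <- readLines(path, n = 2L)
  grab <- function(key, default) {
    ln <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(ln)) as.numeric(sub(paste0("^# ", key, "="), "", ln[1]))
    else default
  }
  df <- utils::read.csv(path, comment.char = "#")
  section_stack(df, section_thickness_nm = grab("section_thickness_nm", 50),
                n_sections = grab("n_sections", max(df$section)))
}
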