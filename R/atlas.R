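# ROI atlas for the two social-brain networks: Theory of Mind (ToM) and the
# Social Pain Matrix (SPM, not the software). The atlas fixes ROI order, and
# that order defines row/column order of every matrix downstream.

#' Construct a network atlas
#'
#' An atlas is a data frame with one row per spherical ROI, columns
#' `name`, `network` (`"ToM"` or `"SPM"`), MNI center `x`, `y`, `z`
#' (millimetres) and `radius_mm`. Row order is meaningful: it defines the
#' row/column order of connectivity matrices and the ROI order of every
#' timecourse matrix.
#'
#' @param name character vector of unique ROI identifiers.
#' @param network character vector, each `"ToM"` or `"SPM"`.
#' @param x,y,z numeric MNI coordinates of the sphere centers (mm).
#' @param radius_mm positive sphere radius (recycled).
#' @return a `network_atlas` data frame.
#' @export
network_atlas <- function(name, network, x, y, z, radius_mm = 9) {
  atlas <- data.frame(
    name = as.character(name),
    network = as.character(network),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    radius_mm = rep_len(as.numeric(radius_mm), length(name)),
    stringsAsFactors = FALSE
  )
  .check(!anyDuplicated(atlas$name), "duplicate ROI names in atlas")
  .check(all(atlas$network %in% c("ToM", "SPM")),
         "network must be 'ToM' or 'SPM'")
  .check(all(atlas$radius_mm > 0), "radius_mm must be positive")
  class(atlas) <- c("network_atlas", "data.frame")
  atlas
}

#' Default ToM / SPM atlas
#'
#' The 13 published peak coordinates for the Theory-of-Mind network (6 ROIs:
#' bilateral TPJ, precuneus, and dorsal/middle/ventral medial prefrontal
#' cortex) and the Social Pain Matrix (7 ROIs: bilateral secondary
#' somatosensory cortex, bilateral insula, bilateral middle frontal gyrus,
#' anterior middle cingulate cortex), in their canonical printed order.
#' Spheres default to a 9 mm radius.
#'
#' @param radius_mm sphere radius in mm (default 9).
#' @return a `network_atlas` with 13 rows (6 ToM then 7 SPM).
#' @export
load_default_atlas <- function(radius_mm = 9) {
  network_atlas(
    name = c("RTPJ", "LTPJ", "PC", "DMPFC", "MMPFC", "VMPFC",
             "RS2", "LS2", "Rinsula", "Linsula", "RMFG", "LMFG", "AMCC"),
    network = c(rep("ToM", 6), rep("SPM", 7)),
    x = c(48, -48,   0,  -6,  -4,  -4,  60, -62,  42, -42,  50, -46,  0),
    y = c(-60, -62, -54,  54,  58,  56, -28, -32,   6,  -2,  42,  36,  2),
    z = c(30,  30,  34,  36,  16, -16,  38,  34,  -6,  -4,  12,  14, 42),
    radius_mm = radius_mm
  )
}

#' Read an atlas from a TSV file
#'
#' Expects columns `name`, `network`, `x`, `y`, `z`, `radius_mm`.
#'
#' @param path TSV file path.
#' @return a `network_atlas`.
#' @export
read_atlas <- function(path) {
  df <- .read_tsv(path)
  need <- c("name", "network", "x", "y", "z", "radius_mm")
  .check(all(need %in% names(df)),
         "atlas file must have columns: %s", paste(need, collapse = ", "))
  network_atlas(df$name, df$network, df$x, df$y, df$z, df$radius_mm)
}

#' Write an atlas to TSV
#' @param atlas a `network_atlas`.
#' @param path output file.
#' @export
write_atlas <- function(atlas, path) {
  .write_tsv(as.data.frame(atlas), path)
}

# indices of the ROIs belonging to a network (or all)
atlas_indices <- function(atlas, which = c("ToM", "SPM", "all")) {
  which <- match.arg(which)
  if (which == "all") seq_len(nrow(atlas)) else which(atlas$network == which)
}
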