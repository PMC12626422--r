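# Subject-level ROI timecourses: construction, sphere extraction from NIfTI
# volumes, z-normalization, network averaging, and the TSV + JSON sidecar
# interchange format shared by all modules and by synthetic fixtures.

#' Construct a subject timecourse
#'
#' @param subject_id character scalar.
#' @param group `"child"` or `"adult"`.
#' @param data numeric ROI-by-time matrix; rows must follow atlas order and
#'   row names, when present, must match the atlas ROI names.
#' @param tr_seconds repetition time in seconds (positive).
#' @param dyad_id optional dyad identifier.
#' @param zscored logical; `TRUE` once each row has been z-normalized.
#' @return a `subject_timecourse` object.
#' @export
subject_timecourse <- function(subject_id, group, data, tr_seconds,
                               dyad_id = NA_character_, zscored = FALSE) {
  .check(is.matrix(data) && is.numeric(data), "data must be a numeric matrix")
  .check(all(is.finite(data)), "timecourse data contains non-finite entries")
  .check(is.numeric(tr_seconds) && tr_seconds > 0, "tr_seconds must be > 0")
  .check(group %in% c("child", "adult"), "group must be 'child' or 'adult'")
  structure(
    list(subject_id = as.character(subject_id), group = group,
         dyad_id = as.character(dyad_id), data = data,
         tr_seconds = as.numeric(tr_seconds), zscored = isTRUE(zscored)),
    class = "subject_timecourse"
  )
}

#' @export
print.subject_timecourse <- function(x, ...) {
  cat(sprintf("<subject_timecourse> %s (%s)%s: %d ROIs x %d TRs, TR = %gs, %s\n",
              x$subject_id, x$group,
              if (is.na(x$dyad_id)) "" else paste0(" dyad ", x$dyad_id),
              nrow(x$data), ncol(x$data), x$tr_seconds,
              if (x$zscored) "z-scored" else "raw"))
  invisible(x)
}

#' Extract mean sphere timecourses from a 4-D volume
#'
#' For each atlas ROI, averages (unweighted) the voxels whose centers lie at
#' Euclidean distance `<= radius_mm` from the ROI's MNI center, per volume.
#' Voxel centers are mapped to world (MNI) coordinates through the image's
#' voxel-to-world affine.
#'
#' @param volumes a 4-D `niftiImage` (see [RNifti::readNifti()]), or a path
#'   to a NIfTI file.
#' @param atlas a `network_atlas`.
#' @param subject_id,group,tr_seconds,dyad_id metadata for the returned
#'   timecourse; `tr_seconds = NULL` takes the TR from the NIfTI header.
#' @return a `subject_timecourse` with `zscored = FALSE`.
#' @export
extract_sphere_timecourses <- function(volumes, atlas, subject_id = "subject",
                                       group = "adult", tr_seconds = NULL,
                                       dyad_id = NA_character_) {
  if (is.character(volumes)) volumes <- RNifti::readNifti(volumes)
  dims <- dim(volumes)
  .check(length(dims) == 4L, "expected a 4-D image, got %d dims", length(dims))
  affine <- tryCatch(structure(RNifti::xform(volumes), class = NULL),
                     error = function(e) NULL)
  .check(!is.null(affine) && all(is.finite(affine)) &&
           abs(det(affine[1:3, 1:3])) > 1e-12,
         "image has a missing or degenerate voxel-to-world affine")
  if (is.null(tr_seconds)) {
    pd <- RNifti::pixdim(volumes)
    tr_seconds <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 2.0
  }

  # world coordinates of every voxel center (0-based indices per NIfTI)
  grid <- as.matrix(expand.grid(i = seq_len(dims[1]) - 1L,
                                j = seq_len(dims[2]) - 1L,
                                k = seq_len(dims[3]) - 1L))
  world <- grid %*% t(affine[1:3, 1:3])
  world <- sweep(world, 2L, affine[1:3, 4], "+")

  arr <- as.array(volumes)
  vox <- matrix(arr, nrow = prod(dims[1:3]), ncol = dims[4])
  out <- matrix(NA_real_, nrow = nrow(atlas), ncol = dims[4],
                dimnames = list(atlas$name, NULL))
  for (r in seq_len(nrow(atlas))) {
    d2 <- (world[, 1] - atlas$x[r])^2 + (world[, 2] - atlas$y[r])^2 +
      (world[, 3] - atlas$z[r])^2
    inside <- d2 <= atlas$radius_mm[r]^2
    .check(any(inside), "ROI '%s': no voxel center within %g mm of (%g, %g, %g)",
           atlas$name[r], atlas$radius_mm[r], atlas$x[r], atlas$y[r], atlas$z[r])
    out[r, ] <- colMeans(vox[inside, , drop = FALSE])
  }
  subject_timecourse(subject_id, group, out, tr_seconds, dyad_id,
                     zscored = FALSE)
}

#' Z-normalize each ROI timecourse
#'
#' Each row is transformed to mean 0 and unit sample standard deviation
#' (denominator n - 1). A constant row is an error: a flat BOLD trace
#' indicates an extraction fault, not a real signal.
#'
#' @param tc a `subject_timecourse`.
#' @return the timecourse with `zscored = TRUE`.
#' @export
znormalize <- function(tc) {
  sds <- apply(tc$data, 1L, stats::sd)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad) > 0) {
    nm <- rownames(tc$data)
    lab <- if (is.null(nm)) paste("row", bad) else nm[bad]
    stop(sprintf("constant (zero-variance) timecourse for ROI: %s",
                 paste(lab, collapse = ", ")), call. = FALSE)
  }
  tc$data <- (tc$data - rowMeans(tc$data)) / sds
  tc$zscored <- TRUE
  tc
}

#' Network-mean timecourse
#'
#' Unweighted mean over the ROI rows of one network (or all 13 ROIs) at each
#' TR. Requires z-scored data so ROIs contribute on a common scale.
#'
#' @param tc a z-scored `subject_timecourse`.
#' @param which `"ToM"`, `"SPM"`, or `"all"`.
#' @param atlas the atlas defining network membership (default atlas by
#'   default); only its `network` column and row count are used.
#' @return numeric vector of length `ncol(tc$data)`.
#' @export
network_mean_timecourse <- function(tc, which = c("ToM", "SPM", "all"),
                                    atlas = load_default_atlas()) {
  which <- match.arg(which)
  .check(tc$zscored, "timecourse must be z-scored first (see znormalize())")
  .check(nrow(tc$data) == nrow(atlas),
         "timecourse has %d rows but atlas has %d ROIs",
         nrow(tc$data), nrow(atlas))
  idx <- atlas_indices(atlas, which)
  colMeans(tc$data[idx, , drop = FALSE])
}

#' Write a subject timecourse as TSV + JSON sidecar
#'
#' The TSV has a first column `roi` and one column per TR (`TR_0` ...);
#' the sidecar `<stem>.json` records `subject_id`, `group`, `dyad_id`,
#' `tr_seconds` and `zscored`. This is the canonical interchange format for
#' all downstream modules and synthetic fixtures.
#'
#' @param tc a `subject_timecourse`.
#' @param stem output path without extension; writes `<stem>.tsv` and
#'   `<stem>.json`.
#' @return the stem, invisibly.
#' @export
write_timecourse <- function(tc, stem) {
  df <- data.frame(roi = rownames(tc$data), stringsAsFactors = FALSE)
  mat <- as.data.frame(tc$data)
  names(mat) <- paste0("TR_", seq_len(ncol(tc$data)) - 1L)
  .write_tsv(cbind(df, mat), paste0(stem, ".tsv"))
  meta <- list(subject_id = tc$subject_id, group = tc$group,
               dyad_id = if (is.na(tc$dyad_id)) NULL else tc$dyad_id,
               tr_seconds = tc$tr_seconds, zscored = tc$zscored)
  jsonlite::write_json(meta, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Read a subject timecourse written by [write_timecourse()]
#'
#' @param stem path without extension.
#' @return a `subject_timecourse`.
#' @export
read_timecourse <- function(stem) {
  df <- .read_tsv(paste0(stem, ".tsv"))
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  data <- as.matrix(df[, -1, drop = FALSE])
  rownames(data) <- df$roi
  colnames(data) <- NULL
  subject_timecourse(meta$subject_id, meta$group, data, meta$tr_seconds,
                     dyad_id = if (is.null(meta$dyad_id)) NA_character_
                               else meta$dyad_id,
                     zscored = isTRUE(meta$zscored))
}
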