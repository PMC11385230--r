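# Assignment of bipolar channels to labeled networks from an atlas volume.

#' Assign channels to atlas labels
#'
#' Each channel midpoint (MNI mm) receives the label of its containing
#' voxel if that voxel is labeled; otherwise the label of the nearest
#' labeled voxel center within `tolerance_mm` (Euclidean distance in mm
#' world space); otherwise it is unassigned. An exact distance tie between
#' two different labels yields an unassigned channel with a warning.
#'
#' @param midpoints numeric matrix (n x 3) of channel midpoints, mm.
#' @param atlas list with `data` (3-D integer array, 0 = unlabeled),
#'   `affine` (4x4 voxel-to-world matrix, 0-based voxel indices) and
#'   `labels` (data frame: `index`, `name`). See [synthetic_atlas()] and
#'   [read_atlas()].
#' @param tolerance_mm maximum midpoint-to-voxel distance (default 10,
#'   inclusive).
#' @return data frame with one row per channel: `label` (network name or
#'   `NA`), `distance` (mm to the nearest labeled voxel center; 0 iff the
#'   midpoint lies inside a labeled voxel).
#' @export
assign_channels <- function(midpoints, atlas, tolerance_mm = 10) {
  midpoints <- as.matrix(midpoints)
  stopifnot(ncol(midpoints) == 3)
  A <- atlas$affine
  stopifnot(is.matrix(A), all(dim(A) == c(4, 4)))
  Ainv <- solve(A)
  dims <- dim(atlas$data)
  lab_idx <- which(atlas$data != 0)
  if (length(lab_idx) == 0) stop("atlas contains no labeled voxels")
  vox <- arrayInd(lab_idx, dims) - 1 # 0-based
  world <- cbind(vox, 1) %*% t(A)
  world <- world[, 1:3, drop = FALSE]
  lab_val <- atlas$data[lab_idx]
  name_of <- function(v) {
    i <- match(v, atlas$labels$index)
    if (is.na(i)) as.character(v) else atlas$labels$name[i]
  }
  out <- data.frame(label = rep(NA_character_, nrow(midpoints)),
                    distance = rep(NA_real_, nrow(midpoints)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(midpoints))) {
    p <- midpoints[i, ]
    # containing voxel
    v <- round(Ainv %*% c(p, 1))[1:3]
    inside <- all(v >= 0) && all(v < dims)
    if (inside) {
      val <- atlas$data[matrix(v + 1, ncol = 3)]
      if (val != 0) {
        out$label[i] <- name_of(val)
        out$distance[i] <- 0
        next
      }
    }
    d2 <- (world[, 1] - p[1])^2 + (world[, 2] - p[2])^2 + (world[, 3] - p[3])^2
    dmin <- sqrt(min(d2))
    out$distance[i] <- dmin
    if (dmin <= tolerance_mm) {
      near <- lab_val[sqrt(d2) <= dmin + 1e-9]
      if (length(unique(near)) > 1) {
        warning(sprintf("channel %d: exact distance tie between labels; unassigned", i))
      } else {
        out$label[i] <- name_of(near[1])
      }
    }
  }
  out
}

#' Synthetic two-network atlas
#'
#' Builds a small labeled volume in code with two spherical blobs, label 1
#' (`"DMN"`) and label 2 (`"DAN"`), centered on the coordinates the
#' synthetic cohort generator uses for its two channel groups. Intended as
#' a test fixture so that no atlas download is required.
#'
#' @param voxel_mm isotropic voxel size (default 2 mm).
#' @param radius_mm blob radius (default 12 mm).
#' @return atlas list accepted by [assign_channels()].
#' @export
synthetic_atlas <- function(voxel_mm = 2, radius_mm = 12) {
  centers <- rbind(DMN = c(-6, -52, 26), DAN = c(26, -62, 52))
  lo <- apply(centers, 2, min) - radius_mm - 4
  hi <- apply(centers, 2, max) + radius_mm + 4
  dims <- as.integer(ceiling((hi - lo) / voxel_mm)) + 1L
  affine <- diag(c(rep(voxel_mm, 3), 1))
  affine[1:3, 4] <- lo
  data <- array(0L, dims)
  g <- expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1), k = 0:(dims[3] - 1))
  w <- cbind(as.matrix(g), 1) %*% t(affine)
  for (l in 1:2) {
    d2 <- (w[, 1] - centers[l, 1])^2 + (w[, 2] - centers[l, 2])^2 +
      (w[, 3] - centers[l, 3])^2
    data[d2 <= radius_mm^2 & data == 0] <- l
  }
  list(data = data, affine = affine,
       labels = data.frame(index = 1:2, name = c("DMN", "DAN"),
                           stringsAsFactors = FALSE))
}

#' Read a NIfTI atlas volume and label lookup table
#'
#' @param nifti_path path to a NIfTI label volume.
#' @param lookup_path path to a TSV with columns `index` and `name`.
#' @return atlas list accepted by [assign_channels()].
#' @export
read_atlas <- function(nifti_path, lookup_path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI atlases requires the RNifti package")
  img <- RNifti::readNifti(nifti_path)
  labels <- utils::read.delim(lookup_path, stringsAsFactors = FALSE)
  list(data = array(as.integer(round(img)), dim(img)),
       affine = structure(RNifti::xform(img), class = "matrix",
                          dim = c(4, 4)),
       labels = labels)
}
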