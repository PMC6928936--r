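#' Build a sensor montage from an electrode-position file
#'
#' Reads a plain-text electrode file (one `label x y z` row per electrode,
#' `#` comments allowed), projects every position onto the unit sphere and
#' attaches named channel subsets.  The packaged default is an idealized
#' spherical 10-10 layout with the 64 labels of the Biosemi ActiveTwo system;
#' the default subsets reduce it to 32, 16, 8 and 4 channels, with the 32- and
#' 16-channel sets following the corresponding Biosemi caps, the 8-channel set
#' spread evenly over the head and the 4-channel set confined to the central
#' region.
#'
#' @param layout_file path to the electrode position file.  Default: the
#'   packaged Biosemi-64 layout.
#' @param subsets named list of character vectors, one per reduced channel
#'   count.  Every label must occur in the full montage and the sizes must be
#'   taken from `{32, 16, 8, 4}` (the full 64-channel set needs no subset).
#' @return An object of class `sensor_montage` with elements `labels`
#'   (length 64), `positions` (64 x 3 unit vectors) and `subsets`.
#' @examples
#' mon <- build_montage()
#' mon
#' sapply(mon$subsets, length)
#' @export
build_montage <- function(layout_file = NULL, subsets = default_subsets()) {
  if (is.null(layout_file)) {
    layout_file <- system.file("extdata", "biosemi64.sfp", package = "eegsr")
  }
  tab <- utils::read.table(layout_file, header = FALSE, comment.char = "#",
                           col.names = c("label", "x", "y", "z"),
                           stringsAsFactors = FALSE)
  labels <- as.character(tab$label)
  if (anyDuplicated(labels)) stop("duplicate electrode label in ", layout_file)
  pos <- as.matrix(tab[, c("x", "y", "z")])
  nrm <- sqrt(rowSums(pos^2))
  if (any(nrm == 0)) stop("electrode at the origin cannot be projected")
  pos <- pos / nrm
  rownames(pos) <- labels

  subsets <- lapply(subsets, as.character)
  for (nm in names(subsets)) {
    ss <- subsets[[nm]]
    if (anyDuplicated(ss)) stop("duplicate label in subset ", nm)
    missing <- setdiff(ss, labels)
    if (length(missing)) {
      stop("subset ", nm, " has labels not in the montage: ",
           paste(missing, collapse = ", "))
    }
    if (!length(ss) %in% c(64L, 32L, 16L, 8L, 4L)) {
      stop("subset ", nm, " has size ", length(ss),
           "; allowed sizes are 64, 32, 16, 8, 4")
    }
  }
  structure(list(labels = labels, positions = pos, subsets = subsets),
            class = "sensor_montage")
}

#' @export
print.sensor_montage <- function(x, ...) {
  cat(sprintf("<sensor_montage> %d channels on the unit sphere; subsets: %s\n",
              length(x$labels),
              paste(sprintf("%s(%d)", names(x$subsets),
                            lengths(x$subsets)), collapse = ", ")))
  invisible(x)
}

#' Default channel subsets for the Biosemi-64 layout
#'
#' The 32- and 16-channel sets are the standard Biosemi 32/16 cap labels.
#' The 8-channel set covers frontal, central, parietal and occipital sites in
#' both hemispheres; the 4-channel set sits on the central strip (C3, C1, C2,
#' C4) and deliberately leaves the head boundary uncovered.
#'
#' @return named list of character vectors with elements `"32"`, `"16"`,
#'   `"8"`, `"4"`.
#' @export
default_subsets <- function() {
  list(
    "32" = c("Fp1", "AF3", "F7", "F3", "FC1", "FC5", "T7", "C3", "CP1",
             "CP5", "P7", "P3", "Pz", "PO3", "O1", "Oz", "O2", "PO4", "P4",
             "P8", "CP6", "CP2", "C4", "T8", "FC6", "FC2", "F4", "F8",
             "AF4", "Fp2", "Fz", "Cz"),
    "16" = c("Fp1", "Fp2", "F4", "Fz", "F3", "T7", "C3", "Cz", "C4", "T8",
             "P4", "Pz", "P3", "O1", "Oz", "O2"),
    "8"  = c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2"),
    "4"  = c("C3", "C1", "C2", "C4")
  )
}

#' Look up the labels of a channel subset
#' @param montage a [build_montage()] result.
#' @param k subset size: 64 returns the full label set, otherwise one of the
#'   declared subset sizes (by default 32, 16, 8, 4).
#' @return character vector of channel labels.
#' @export
montage_subset <- function(montage, k) {
  stopifnot(inherits(montage, "sensor_montage"))
  if (k == length(montage$labels)) return(montage$labels)
  key <- as.character(k)
  if (!key %in% names(montage$subsets)) {
    stop("no declared subset of size ", k, "; available: ",
         paste(names(montage$subsets), collapse = ", "))
  }
  montage$subsets[[key]]
}

# Geodesic (great-circle) distances between unit-sphere positions, in radians.
geodesic_dist <- function(a, b) {
  d <- tcrossprod(a, b)
  d[] <- pmin(1, pmax(-1, d))   # clamp in place to keep the dim attribute
  acos(d)
}
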