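#' Electrode montage
#'
#' An ordered set of channel labels (10-20 system strings) with optional 2-D
#' scalp coordinates. Channel order is montage order everywhere in the
#' package: every matrix, tensor and rank list is indexed consistently with
#' `labels`.
#'
#' @param labels character vector of unique channel names, length >= 2.
#' @param positions optional numeric matrix `length(labels) x 2` of scalp
#'   coordinates (x to the right, y to the front), used only for exporting
#'   weight tables consumable by topography tools.
#' @return an object of class `"montage"`.
#' @examples
#' m <- montage(c("Fz", "Cz", "Pz"))
#' length(m$labels)
#' @export
montage <- function(labels, positions = NULL) {
  labels <- as.character(labels)
  check_that(length(labels) >= 2, "montage needs >= 2 channels, got %d", length(labels))
  check_that(!anyDuplicated(labels), "montage labels must be unique")
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    check_that(nrow(positions) == length(labels) && ncol(positions) == 2,
               "positions must be a %d x 2 matrix", length(labels))
    rownames(positions) <- labels
  }
  structure(list(labels = labels, positions = positions), class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", length(x$labels), " channels: ",
      paste(x$labels, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
length.montage <- function(x) length(x$labels)

#' Standard montages
#'
#' `default_montage(32)` is the common 32-electrode 10-20 extension used in
#' P300 spelling studies; `default_montage(16)` is a 16-channel subset
#' covering frontal, central, temporal, parietal and occipital sites,
#' the default for simulations.
#'
#' @param n_channels 16 or 32, or any smaller number (the first `n` labels
#'   of the 32-channel layout are used).
#' @return a [montage()].
#' @export
default_montage <- function(n_channels = 16) {
  lab32 <- c("Fp1", "AF3", "F7", "F3", "FC1", "FC5", "T7", "C3",
             "CP1", "CP5", "P7", "P3", "Pz", "PO3", "O1", "Oz",
             "O2", "PO4", "P4", "P8", "CP6", "CP2", "C4", "T8",
             "FC6", "FC2", "F4", "F8", "AF4", "Fp2", "Fz", "Cz")
  lab16 <- c("Fz", "Cz", "Pz", "Oz", "C3", "C4", "T7", "T8",
             "P3", "P4", "P7", "P8", "FC1", "FC2", "PO3", "PO4")
  if (n_channels == 16) return(montage(lab16))
  if (n_channels == 32) return(montage(lab32))
  check_that(n_channels >= 2 && n_channels <= 32,
             "default_montage supports 2..32 channels, got %d", n_channels)
  montage(lab32[seq_len(n_channels)])
}
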