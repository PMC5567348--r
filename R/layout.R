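#' Standard 8x8 multi-electrode array layout
#'
#' Builds the geometry of a planar 60-electrode MEA: an 8x8 grid on a 200 um
#' pitch with the four corner positions absent. Electrode labels follow the
#' column-row convention (`"12"` = column 1, row 2, ... `"87"`). One
#' electrode serves as the internal reference and is not available for
#' recording, leaving 59 recording sites.
#'
#' @param pitch_um Center-to-center electrode spacing in micrometres.
#' @param reference Label of the internal reference electrode (excluded from
#'   recording).
#' @return An object of class `mea_layout`: a data frame with columns
#'   `label`, `col`, `row`, `x`, `y` (um), plus attributes `pitch_um` and
#'   `excluded`.
#' @examples
#' lay <- mea_layout()
#' nrow(lay)                  # 60 electrode positions
#' length(recording_electrodes(lay))  # 59 usable for recording
#' @export
mea_layout <- function(pitch_um = 200, reference = "15") {
  grid <- expand.grid(col = 1:8, row = 1:8)
  corners <- (grid$col %in% c(1, 8)) & (grid$row %in% c(1, 8))
  grid <- grid[!corners, , drop = FALSE]
  lay <- data.frame(
    label = paste0(grid$col, grid$row),
    col = grid$col,
    row = grid$row,
    x = (grid$col - 1) * pitch_um,
    y = (grid$row - 1) * pitch_um,
    stringsAsFactors = FALSE
  )
  lay <- lay[order(lay$label), ]
  rownames(lay) <- lay$label
  if (!reference %in% lay$label) {
    stop("reference electrode '", reference, "' is not a valid layout label")
  }
  attr(lay, "pitch_um") <- pitch_um
  attr(lay, "excluded") <- reference
  class(lay) <- c("mea_layout", "data.frame")
  lay
}

#' Labels of electrodes usable for recording
#'
#' @param layout An [mea_layout()].
#' @return Character vector of recording-electrode labels (layout labels
#'   minus the internal reference).
#' @export
recording_electrodes <- function(layout) {
  setdiff(layout$label, attr(layout, "excluded"))
}

#' Euclidean distance between two electrodes
#'
#' @param layout An [mea_layout()].
#' @param a,b Electrode labels.
#' @return Distance in micrometres.
#' @export
electrode_distance <- function(layout, a, b) {
  stopifnot(a %in% layout$label, b %in% layout$label)
  sqrt((layout[a, "x"] - layout[b, "x"])^2 +
       (layout[a, "y"] - layout[b, "y"])^2)
}

assert_labels <- function(labels, layout, what = "electrode") {
  bad <- setdiff(unique(labels), layout$label)
  if (length(bad) > 0) {
    stop("unknown ", what, " label(s): ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
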