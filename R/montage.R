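#' Standard scalp electrode montages
#'
#' Returns a montage layout: the ordered set of 10-20 / 10-10 electrode
#' labels the pipeline recognizes, together with schematic 2D scalp
#' coordinates (top view, nose up, unit head circle).  Two montages are
#' provided: the full 64-channel BioSemi-style layout and a reduced
#' 16-channel 10-20 subset used for fast experiments.
#'
#' Coordinates are derived from the label structure (row letter gives the
#' anterior-posterior position, the numeric suffix the lateral position;
#' odd = left hemisphere, even = right, `z` = midline).  They are
#' schematic: adequate for plotting and for the layout invariants, not for
#' source modelling.
#'
#' @param name `"biosemi64"` (default) or `"reduced16"`.
#' @return An object of class `montage_layout`: a list with `name`,
#'   `labels` (ordered character vector) and `positions` (data.frame with
#'   columns `label`, `x`, `y`).
#' @examples
#' m <- standard_montage("reduced16")
#' m$labels
#' @export
standard_montage <- function(name = c("biosemi64", "reduced16")) {
  name <- match.arg(name)
  labels <- if (name == "biosemi64") .biosemi64_labels else .reduced16_labels
  pos <- .montage_positions(labels)
  structure(list(name = name, labels = labels, positions = pos),
            class = "montage_layout")
}

# BioSemi 64-channel label order (A1..A32, B1..B32 in 10-10 names)
.biosemi64_labels <- c(
  "Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3", "FC1",
  "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1", "P3", "P5",
  "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz", "Pz", "CPz",
  "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4", "F6", "F8", "FT8",
  "FC6", "FC4", "FC2", "FCz", "Cz", "C2", "C4", "C6", "T8", "TP8", "CP6",
  "CP4", "CP2", "P2", "P4", "P6", "P8", "P10", "PO8", "PO4", "O2")

# classic 16-channel 10-20 subset
.reduced16_labels <- c(
  "Fp1", "Fp2", "F3", "Fz", "F4", "T7", "C3", "Cz", "C4", "T8",
  "P3", "Pz", "P4", "O1", "Oz", "O2")

# anterior-posterior coordinate per row prefix
.row_y <- c(Fp = 0.90, AF = 0.70, F = 0.50, FT = 0.25, FC = 0.25,
            C = 0.00, T = 0.00, TP = -0.25, CP = -0.25, P = -0.50,
            PO = -0.70, O = -0.90, I = -1.00)

# lateral coordinate per numeric suffix (sign from parity)
.col_x <- c("1" = 0.15, "2" = 0.15, "3" = 0.35, "4" = 0.35,
            "5" = 0.55, "6" = 0.55, "7" = 0.78, "8" = 0.78,
            "9" = 0.95, "10" = 0.95)

.montage_positions <- function(labels) {
  parse_one <- function(lab) {
    m <- regmatches(lab, regexec("^([A-Za-z]+?)(z|[0-9]+)$", lab))[[1]]
    if (length(m) != 3L) stop("unparseable electrode label: ", lab)
    row <- m[2]; col <- m[3]
    y <- .row_y[[row]]
    if (col == "z") {
      x <- 0
    } else {
      x <- .col_x[[col]]
      if (as.integer(col) %% 2L == 1L) x <- -x  # odd = left hemisphere
      # temporal chains (T/FT/TP, and the 9/10 ring) sit on the head rim
      x <- x * sqrt(max(0.1, 1 - y^2))
    }
    c(x = x, y = y)
  }
  xy <- t(vapply(labels, parse_one, c(x = 0, y = 0)))
  data.frame(label = labels, x = xy[, "x"], y = xy[, "y"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.montage_layout <- function(x, ...) {
  cat("<montage_layout>", x$name, "-", length(x$labels), "electrodes\n")
  invisible(x)
}

#' Check which channel labels a montage resolves
#'
#' @param labels character vector of channel labels.
#' @param montage a [standard_montage()] layout.
#' @return logical vector, `TRUE` where the label is part of the montage.
#' @keywords internal
montage_resolves <- function(labels, montage) {
  labels %in% montage$labels
}
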