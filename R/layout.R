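#' Channel layout
#'
#' A channel layout names the electrodes of an epidural grid and places them
#' on the skull in millimetres relative to bregma (`ap`: rostro-caudal,
#' positive rostral; `ml`: medio-lateral, positive right). Labels must be
#' unique and coordinates finite.
#'
#' @param labels character vector of unique channel names.
#' @param ap,ml numeric coordinates (mm) of each channel.
#' @return An object of class `channel_layout` (a data frame with columns
#'   `label`, `ap`, `ml`).
#' @export
channel_layout <- function(labels, ap, ml) {
  stopifnot(length(labels) == length(ap), length(labels) == length(ml))
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (!all(is.finite(ap)) || !all(is.finite(ml)))
    stop("channel coordinates must be finite")
  out <- data.frame(label = as.character(labels), ap = as.numeric(ap),
                    ml = as.numeric(ml), stringsAsFactors = FALSE)
  class(out) <- c("channel_layout", "data.frame")
  out
}

#' Standard 16-channel rat epidural grid
#'
#' Eight bilateral sites, mirror-symmetric about the sagittal suture:
#' rostral/caudal secondary motor cortex (M2_R, M2_C), the M2/M1 border,
#' primary somatosensory (S1), lateral parietal (PA), retrosplenial/parietal
#' (RS/PA), posteromedial retrosplenial/secondary visual (RS/V2) and primary
#' visual (V1) cortex. Labels carry an ` L`/` R` hemisphere suffix.
#'
#' @return A [channel_layout] with 16 rows.
#' @export
rat_layout <- function() {
  areas <- c("M2_R", "M2_C", "M2/M1", "S1", "PA", "RS/PA", "RS/V2", "V1")
  ap <- c(4.0, 2.0, 0.5, -1.5, -4.0, -4.5, -7.0, -7.0)
  ml <- c(1.0, 1.2, 1.8, 4.0, 3.5, 1.2, 1.5, 4.0)
  channel_layout(
    labels = c(paste(areas, "L"), paste(areas, "R")),
    ap = c(ap, ap),
    ml = c(-ml, ml)
  )
}

# cortical area (label without the hemisphere suffix) and hemisphere
layout_area <- function(layout) sub(" [LR]$", "", layout$label)
layout_hemi <- function(layout) sub("^.* ", "", layout$label)

# Euclidean distance (mm) of every electrode from a reference site.
layout_distance <- function(layout, ref_label) {
  i <- match(ref_label, layout$label)
  if (is.na(i)) stop("unknown reference channel: ", ref_label)
  sqrt((layout$ap - layout$ap[i])^2 + (layout$ml - layout$ml[i])^2)
}
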