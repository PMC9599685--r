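#' Analysis montage: 30 channels of the international 10-20 system
#'
#' The acquisition montage carries 32 positions; A1/A2 sit on the mastoids
#' and serve as the (linked) reference, leaving 30 scalp channels for
#' analysis. Order is fixed and used everywhere a channel dimension appears.
#'
#' @return Character vector of 30 channel labels.
#' @export
montage_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6",
    "T7", "C3", "Cz", "C4", "T8",
    "CP5", "CP1", "CP2", "CP6",
    "P7", "P3", "Pz", "P4", "P8",
    "PO3", "PO4", "O1", "Oz", "O2")
}

#' Default scalp region map
#'
#' Non-overlapping groups of montage channels used for region-level
#' summaries. Laterality follows standard 10-20 conventions (odd = left,
#' even = right).
#'
#' @return Named list mapping region name to a character vector of channels.
#' @export
default_region_map <- function() {
  list(
    frontal         = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8"),
    fronto_central  = c("FC5", "FC1", "FC2", "FC6"),
    central         = c("C3", "Cz", "C4"),
    left_temporal   = "T7",
    right_temporal  = "T8",
    centro_parietal = c("CP5", "CP1", "CP2", "CP6"),
    parietal        = c("P7", "P3", "Pz", "P4", "P8"),
    occipital       = c("PO3", "PO4", "O1", "Oz", "O2")
  )
}

validate_region_map <- function(regions, channels = montage_channels()) {
  all_ch <- unlist(regions, use.names = FALSE)
  bad <- setdiff(all_ch, channels)
  if (length(bad))
    stop("region map names channels absent from the montage: ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(all_ch))
    stop("region map assigns a channel to more than one region")
  invisible(regions)
}
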