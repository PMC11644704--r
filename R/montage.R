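#' Standard 64-channel acquisition montage
#'
#' The 10-20 system electrode set of a 64-channel ANT-style cap as used for
#' lower-limb motor-imagery recordings: 61 scalp EEG electrodes plus the two
#' mastoid reference sites `M1`/`M2` and one `EOG` channel.  CPz is absent
#' because it serves as the online reference.
#'
#' @return Character vector of 64 channel names.
#' @export
macnet_montage <- function() {
  c("Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "M1", "T7", "C3", "Cz", "C4", "T8", "M2",
    "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8", "POz",
    "O1", "O2", "EOG", "AF7", "AF3", "AF4", "AF8", "F5", "F1", "F2", "F6",
    "FC3", "FCz", "FC4", "C5", "C1", "C2", "C6", "CP3", "CP4",
    "P5", "P1", "P2", "P6", "PO5", "PO3", "PO4", "PO6",
    "FT7", "FT8", "TP7", "TP8", "PO7", "PO8", "Oz")
}

#' Motor-imagery task labels
#'
#' The four lower-limb motor-imagery classes: sit-to-stand, stand-to-sit,
#' walking, and standing (the baseline condition that keeps full mu power).
#'
#' @return Character vector of 4 class labels.
#' @export
macnet_classes <- function() c("S-ST", "ST-S", "walking", "standing")

#' Default sensorimotor (motor-strip) channels
#'
#' Central electrodes over the sensorimotor cortex that carry the mu rhythm
#' in the synthetic generator.
#'
#' @return Character vector of channel names.
#' @export
motor_channels_default <- function() {
  c("Cz", "C1", "C2", "C3", "C4", "FCz", "CP1", "CP2")
}

# Center-out ordering over the scalp: sensorimotor strip first, then
# progressively more frontal/posterior/lateral rows.  Used by the channel
# reduction experiment; subsets are nested prefixes of this order.
channel_reduction_order <- function(channel_names,
                                    motor = motor_channels_default()) {
  prefix_rank <- function(ch) {
    p <- sub("[0-9]*z?$", "", ch)  # strip trailing digits / z
    ranks <- c(C = 0, FC = 1, CP = 1, F = 2, P = 2, FT = 3, TP = 3,
               AF = 4, PO = 4, T = 5, Fp = 6, O = 6, M = 7, EOG = 8)
    r <- ranks[p]
    ifelse(is.na(r), 9, r)
  }
  digit_rank <- function(ch) {
    d <- sub("^[A-Za-z]+", "", ch)
    ifelse(d == "" | d == "z", 0, suppressWarnings(as.numeric(d)))
  }
  in_motor <- !(channel_names %in% motor)
  ord <- order(in_motor, prefix_rank(channel_names),
               digit_rank(channel_names), channel_names)
  channel_names[ord]
}
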