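#' Packaged noise-frequency set for the three-tag configuration
#'
#' The 22 noise frequencies (Hz) used as the reference distribution of the
#' per-voxel tagging t-test when the tagging frequencies are 0.06, 0.08 and
#' 0.10 Hz: bands of bins around each tag, sparing the tags themselves and a
#' guard zone. The generative rule [noise_frequency_set()] with its default
#' parameters reproduces this set's structure (5/6/6/5 bins across the four
#' inter-tag bands) on the 1/540 Hz grid.
#'
#' @format Numeric vector of 22 frequencies in Hz.
#' @export
swift_noise_freqs <- c(
  0.0464, 0.0483, 0.0501, 0.0520, 0.0538,
  0.0650, 0.0668, 0.0687, 0.0705, 0.0724, 0.0742,
  0.0854, 0.0872, 0.0891, 0.0910, 0.0928, 0.0947,
  0.1058, 0.1077, 0.1095, 0.1114, 0.1132
)

#' Default tagging frequencies
#'
#' Semantic revelation rates (Hz) for the three image categories in the
#' composite-stimulus design: faces 0.10 Hz, scenes 0.06 Hz, objects
#' 0.08 Hz.
#'
#' @format Named numeric vector.
#' @export
swift_tag_freqs <- c(faces = 0.10, scenes = 0.06, objects = 0.08)
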