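#' Default 38-channel 10-10 scalp montage
#'
#' Channel labels and approximate 2-D layout coordinates (top view, nose up,
#' unit head radius) for the 38-electrode 10-10 montage used throughout the
#' pipeline. The coordinates are only used to emit importance topographies as
#' tabular channel/position/score records.
#'
#' @return A data.frame with columns `channel`, `x`, `y` and `region`
#'   (frontal/central/temporal/parietal/occipital grouping used by the
#'   synthetic effect map).
#' @export
#' @examples
#' head(default_montage())
default_montage <- function() {
  df <- data.frame(
    channel = c("Fp1", "Fpz", "Fp2",
                "AF3", "AF4",
                "F7", "F3", "Fz", "F4", "F8",
                "FT7", "FC3", "FCz", "FC4", "FT8",
                "T7", "C3", "Cz", "C4", "T8",
                "TP7", "CP3", "CPz", "CP4", "TP8",
                "P7", "P3", "Pz", "P4", "P8",
                "PO7", "PO3", "POz", "PO4", "PO8",
                "O1", "Oz", "O2"),
    stringsAsFactors = FALSE
  )
  # angular scheme: y = front-back ring, x spread within ring
  ring <- c(Fp = 1, AF = 0.8, F = 0.6, FT = 0.4, FC = 0.4, T = 0, C = 0,
            TP = -0.4, CP = -0.4, P = -0.6, PO = -0.8, O = -1)
  pref <- sub("(z|[0-9]+)$", "", df$channel)
  num <- sub("^[A-Za-z]+", "", df$channel)
  side <- ifelse(num == "z", 0, ifelse(as.numeric(num) %% 2 == 1, -1, 1))
  mag <- ifelse(num == "z", 0, ceiling(as.numeric(ifelse(num == "z", 0, num)) / 2))
  df$y <- unname(ring[pref])
  df$x <- side * mag / 4 * sqrt(pmax(0, 1 - df$y^2) + 0.25)
  df$region <- c(Fp = "frontal", AF = "frontal", F = "frontal",
                 FT = "temporal", FC = "central", T = "temporal",
                 C = "central", TP = "temporal", CP = "central",
                 P = "parietal", PO = "occipital", O = "occipital")[pref]
  rownames(df) <- NULL
  df
}

#' Default occipital channels used for individual alpha frequency estimation
#' @return Character vector of channel labels.
#' @export
occipital_channels <- function() c("O1", "Oz", "O2")

#' Channels belonging to a named scalp region of the default montage
#' @param region One of "frontal", "central", "temporal", "parietal",
#'   "occipital".
#' @return Character vector of channel labels.
#' @export
region_channels <- function(region) {
  m <- default_montage()
  region <- match.arg(region, unique(m$region))
  m$channel[m$region == region]
}
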