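#' Biosemi 32-channel montage
#'
#' Channel names of the Biosemi 32-electrode cap in its native A1--A32 order,
#' following the 10--20 international naming convention, together with
#' approximate 2-D scalp-projection coordinates (head seen from above, nose up,
#' unit head radius). Coordinates are used only to join statistical maps to
#' scalp locations for topography tables/plots; they are not a head model.
#'
#' @return A data.frame with columns `channel`, `x`, `y`.
#' @export
#' @examples
#' head(biosemi32_montage())
biosemi32_montage <- function() {
  # (x, y) from the standard 10-20 angular layout, radius 1 = head circumference
  tab <- matrix(c(
    "Fp1", -0.309,  0.951,
    "AF3", -0.275,  0.762,
    "F7",  -0.809,  0.588,
    "F3",  -0.373,  0.545,
    "FC1", -0.217,  0.300,
    "FC5", -0.669,  0.339,
    "T7",  -1.000,  0.000,
    "C3",  -0.500,  0.000,
    "CP1", -0.217, -0.300,
    "CP5", -0.669, -0.339,
    "P7",  -0.809, -0.588,
    "P3",  -0.373, -0.545,
    "Pz",   0.000, -0.500,
    "PO3", -0.275, -0.762,
    "O1",  -0.309, -0.951,
    "Oz",   0.000, -1.000,
    "O2",   0.309, -0.951,
    "PO4",  0.275, -0.762,
    "P4",   0.373, -0.545,
    "P8",   0.809, -0.588,
    "CP6",  0.669, -0.339,
    "CP2",  0.217, -0.300,
    "C4",   0.500,  0.000,
    "T8",   1.000,  0.000,
    "FC6",  0.669,  0.339,
    "FC2",  0.217,  0.300,
    "F4",   0.373,  0.545,
    "F8",   0.809,  0.588,
    "AF4",  0.275,  0.762,
    "Fp2",  0.309,  0.951,
    "Fz",   0.000,  0.500,
    "Cz",   0.000,  0.000), ncol = 3, byrow = TRUE)
  data.frame(channel = tab[, 1],
             x = as.numeric(tab[, 2]),
             y = as.numeric(tab[, 3]),
             stringsAsFactors = FALSE)
}

#' Channel groups carrying the planted state effects
#'
#' The scalp regions where attentional state modulates band amplitude:
#' alpha increases over left frontal sites, theta over left parietal sites,
#' and delta decreases over central sites during attention.
#'
#' @return Named list of character vectors of channel names.
#' @export
effect_channel_groups <- function() {
  list(left_frontal  = c("Fp1", "AF3", "F3", "F7"),
       left_parietal = c("P3", "P7", "CP5"),
       central       = c("Cz", "C3", "C4"))
}

#' Default frontal channels used as ocular/blink proxies
#' @return Character vector of channel names.
#' @export
frontal_proxy_channels <- function() c("Fp1", "Fp2", "AF3", "AF4")
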