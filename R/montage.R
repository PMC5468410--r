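#' Standard channel sets used by the workload feature domain
#'
#' The discriminant features are restricted to frontal and parietal sites of
#' the 10-10 system; a small parieto-occipital set is kept for estimating the
#' individual alpha frequency from eyes-closed rest.
#'
#' @return Character vector of channel labels.
#' @name montage
NULL

#' @rdname montage
#' @export
frontal_channels <- function() {
  c("AF7", "AF3", "AF8", "AF4", "F7", "F5", "F3", "F1", "Fz",
    "F2", "F4", "F6", "F8")
}

#' @rdname montage
#' @export
parietal_channels <- function() {
  c("P1", "P3", "P5", "P7", "Pz", "P2", "P4", "P6", "P8")
}

#' @rdname montage
#' @export
posterior_channels <- function() {
  c("POz", "O1", "O2")
}

#' @rdname montage
#' @export
default_montage <- function() {
  c(frontal_channels(), parietal_channels(), posterior_channels())
}
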