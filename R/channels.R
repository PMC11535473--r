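#' Measurement channels of a fed-batch CHO culture
#'
#' Every observation in a culture table references one of fifteen enumerated
#' channels: viable cell density, antibody titer, six extracellular
#' metabolites, four intracellular nucleotide sugar donors (NSDs) and three
#' glycan fractions. The `role` column records how the data-driven soft
#' sensors use each channel: the six extracellular metabolites are the factor
#' (predictor) block, everything else is a response.
#'
#' @return A tibble with columns `channel`, `units`, `class`
#'   (`"culture"`, `"metabolite"`, `"nsd"`, `"glycan"`) and `role`
#'   (`"factor"` or `"response"`).
#' @examples
#' culture_channels()
#' @export
culture_channels <- function() {
  tibble::tribble(
    ~channel,      ~units,      ~class,       ~role,
    "VCD",         "cells/mL",  "culture",    "response",
    "TITER",       "mg/L",      "culture",    "response",
    "GLC",         "mM",        "metabolite", "factor",
    "GLN",         "mM",        "metabolite", "factor",
    "GLU",         "mM",        "metabolite", "factor",
    "LAC",         "mM",        "metabolite", "factor",
    "NH4",         "mM",        "metabolite", "factor",
    "GAL",         "mM",        "metabolite", "factor",
    "UDP_GLC",     "mM",        "nsd",        "response",
    "UDP_GAL",     "mM",        "nsd",        "response",
    "UDP_GLCNAC",  "mM",        "nsd",        "response",
    "UDP_GALNAC",  "mM",        "nsd",        "response",
    "G0F",         "%",         "glycan",     "response",
    "G1F",         "%",         "glycan",     "response",
    "G2F",         "%",         "glycan",     "response"
  )
}

#' @rdname culture_channels
#' @export
factor_channels <- function() {
  ch <- culture_channels()
  ch$channel[ch$role == "factor"]
}

#' @rdname culture_channels
#' @export
response_channels <- function() {
  ch <- culture_channels()
  ch$channel[ch$role == "response"]
}

#' @rdname culture_channels
#' @export
glycan_channels <- function() c("G0F", "G1F", "G2F")

#' @rdname culture_channels
#' @export
nsd_channels <- function() c("UDP_GLC", "UDP_GAL", "UDP_GLCNAC", "UDP_GALNAC")
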