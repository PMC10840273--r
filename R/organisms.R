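#' Read a common-commensal organism list
#'
#' One organism code per line; blank lines and lines starting with \code{#}
#' are ignored. Codes are opaque species-level strings, matched exactly
#' after trimming and case-folding — no taxonomy expansion is attempted.
#'
#' @param path path to the list file; defaults to the representative subset
#'   of the CDC common-commensal list shipped with the package. The shipped
#'   list is illustrative configuration, not code: replace it with the
#'   institutional list for production use.
#' @return character vector of normalised organism codes.
#' @export
read_commensal_list <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "commensals.txt", package = "cvcbsi")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("commensal list file not found: ", path, call. = FALSE)
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("commensal list is empty: ", path, call. = FALSE)
  unique(norm_code(lines))
}

default_commensal_list <- function() read_commensal_list()

#' Classify an isolate as recognised pathogen or common commensal
#'
#' The split between recognised pathogen and contaminant drives the
#' bloodstream-infection confirmation rule: one positive culture suffices
#' for a pathogen, while a commensal needs a second culture of the same
#' species within the pairing window (plus symptoms, under the
#' symptom-using algorithm variant). Class is determined solely by
#' membership of the code in the commensal list.
#'
#' @param organism_code character vector of species-level organism codes.
#' @param commensal_list character vector of codes on the common-commensal
#'   list.
#' @return character vector, \code{"commensal"} or \code{"pathogen"}.
#' @examples
#' classify_isolate("Staphylococcus epidermidis",
#'                  c("staphylococcus epidermidis"))
#' classify_isolate("staphylococcus aureus",
#'                  c("staphylococcus epidermidis"))
#' @export
classify_isolate <- function(organism_code, commensal_list) {
  if (any(is.na(organism_code) | !nzchar(trimws(organism_code)))) {
    stop("organism_code must be non-empty", call. = FALSE)
  }
  ifelse(norm_code(organism_code) %in% norm_code(commensal_list),
         "commensal", "pathogen")
}
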