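#' Parse AHL acronyms into acyl chain length and C3 substitution
#'
#' N-acyl homoserine lactones (AHLs) are conventionally named by the length of
#' their acyl side chain and the substitution at the C3 position, e.g.
#' `C6-HSL` (N-hexanoyl, unsubstituted), `3OC8-HSL` (N-(3-oxooctanoyl)) and
#' `3OHC12-HSL` (N-(3-hydroxydodecanoyl)). Chain length and substitution drive
#' both the degradation specificity of quenching communities and the LC-MS/MS
#' transitions used for identification, so most quorumflow outputs carry these
#' two fields alongside the acronym.
#'
#' @param acronym Character vector of AHL acronyms such as `"3OC8-HSL"`.
#' @return A tibble with columns `ahl`, `chain_length` (number of carbons in
#'   the acyl chain) and `substitution` (one of `"unsubstituted"`, `"3-oxo"`,
#'   `"3-hydroxy"`). Unparseable acronyms give `NA` fields with a warning.
#' @examples
#' ahl_info(c("C6-HSL", "3OC12-HSL", "3OHC12-HSL"))
#' @export
ahl_info <- function(acronym) {
  stopifnot(is.character(acronym), length(acronym) > 0)
  m <- stringr::str_match(toupper(acronym), "^(3O|3OH)?C(\\d+)-HSL$")
  sub <- dplyr::case_when(
    is.na(m[, 1]) ~ NA_character_,
    is.na(m[, 2]) ~ "unsubstituted",
    m[, 2] == "3O" ~ "3-oxo",
    m[, 2] == "3OH" ~ "3-hydroxy"
  )
  if (anyNA(m[, 1])) {
    warn(sprintf("Unrecognised AHL acronym(s): %s",
                 paste(unique(acronym[is.na(m[, 1])]), collapse = ", ")))
  }
  tibble(
    ahl = acronym,
    chain_length = as.integer(m[, 3]),
    substitution = sub
  )
}
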