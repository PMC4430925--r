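#' Parse protein changes in HGVS-p short form
#'
#' Decomposes strings such as `"p.A123T"`, `"p.R465*"`, `"p.Q1802fs"` or
#' `"p.K2049del"` into protein position, reference and alternate residues, and
#' a change kind. The parser is total: malformed or empty strings yield a row
#' of `NA`s with `change_kind = "unknown"` and never raise an error (real
#' MAF-like tables carry empty protein changes for intronic calls).
#'
#' Change kinds follow the usual conventions: a simple residue substitution is
#' `"substitution"`; an alternate of `"*"` is `"nonsense"`; an `fs` suffix is
#' `"frameshift"` (the alternate residue is reported as `NA`, the shifted
#' sequence being undefined); `del`/`ins`/`dup` without `fs` are
#' `"inframe_indel"`.
#'
#' @param hgvsp Character vector of protein-change strings; the leading
#'   `"p."` is optional.
#' @return A tibble with one row per input and columns `protein_position`
#'   (integer), `ref_aa`, `alt_aa` (single characters or `NA`; `"*"` for
#'   stop) and `change_kind` (one of `substitution`, `nonsense`,
#'   `frameshift`, `inframe_indel`, `unknown`).
#' @examples
#' parse_protein_change(c("p.A123T", "p.Q1802fs", "p.R465*", "p.K2049del", ""))
#' @export
parse_protein_change <- function(hgvsp) {
  hgvsp <- as.character(hgvsp)
  n <- length(hgvsp)
  out <- tibble::tibble(
    protein_position = rep(NA_integer_, n),
    ref_aa = rep(NA_character_, n),
    alt_aa = rep(NA_character_, n),
    change_kind = rep("unknown", n)
  )
  if (n == 0L) return(out)

  s <- stringr::str_remove(stringr::str_trim(hgvsp), "^p\\.")
  s[is.na(s)] <- ""
  aa <- "[A-Za-z]"

  # frameshift: p.Q1802fs, p.Q1802Pfs*12 ...
  m <- stringr::str_match(s, paste0("^(", aa, ")(\\d+)", aa, "?fs.*$"))
  hit <- !is.na(m[, 1])
  out$protein_position[hit] <- as.integer(m[hit, 3])
  out$ref_aa[hit] <- toupper(m[hit, 2])
  out$change_kind[hit] <- "frameshift"

  # nonsense: p.R465*
  m <- stringr::str_match(s, paste0("^(", aa, ")(\\d+)\\*$"))
  hit <- !is.na(m[, 1]) & out$change_kind == "unknown"
  out$protein_position[hit] <- as.integer(m[hit, 3])
  out$ref_aa[hit] <- toupper(m[hit, 2])
  out$alt_aa[hit] <- "*"
  out$change_kind[hit] <- "nonsense"

  # in-frame del/ins/dup: p.K2049del, p.A12_G13insV, p.E55dup
  m <- stringr::str_match(
    s, paste0("^(", aa, ")(\\d+)(?:_", aa, "\\d+)?(?:del|ins|dup).*$")
  )
  hit <- !is.na(m[, 1]) & out$change_kind == "unknown"
  out$protein_position[hit] <- as.integer(m[hit, 3])
  out$ref_aa[hit] <- toupper(m[hit, 2])
  out$change_kind[hit] <- "inframe_indel"

  # substitution: p.A123T
  m <- stringr::str_match(s, paste0("^(", aa, ")(\\d+)(", aa, ")$"))
  hit <- !is.na(m[, 1]) & out$change_kind == "unknown"
  out$protein_position[hit] <- as.integer(m[hit, 3])
  out$ref_aa[hit] <- toupper(m[hit, 2])
  out$alt_aa[hit] <- toupper(m[hit, 4])
  out$change_kind[hit] <- "substitution"

  # positions must be >= 1; degrade bad ones to unknown
  bad <- !is.na(out$protein_position) & out$protein_position < 1L
  if (any(bad)) {
    out$protein_position[bad] <- NA_integer_
    out$ref_aa[bad] <- NA_character_
    out$alt_aa[bad] <- NA_character_
    out$change_kind[bad] <- "unknown"
  }
  out
}
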