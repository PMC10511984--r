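#' ICD-10 bleeding code maps
#'
#' A code map links ICD-10 codes (or prefixes) to bleed categories. Matching
#' is by prefix after normalisation (uppercasing and dot-stripping), so an
#' entry `K92.0` matches a recorded `k920` and an entry `I61` matches
#' `I61.9`. When several entries match a code the most specific (longest)
#' prefix wins. No code may map to two categories.
#'
#' `default_bleed_code_map()` ships a clinically plausible default covering
#' intracranial (I60-I62, S06.4-S06.6), eye (H35.6, H43.1, H45.0),
#' gastrointestinal (varices, ulcers with haemorrhage/perforation, K29.0,
#' K62.5, K92.0-K92.2) and other bleeding (epistaxis, haemoptysis,
#' haematuria, vaginal, unspecified). It is a replaceable configuration
#' default, not a validated clinical code list: supply your own map for real
#' analyses.
#'
#' @param entries data.frame with columns `code` (ICD-10 code or prefix,
#'   letter + 2 digits with optional dot and further characters),
#'   `category` (one of `"intracranial"`, `"eye"`, `"gastrointestinal"`,
#'   `"other"`, or `"sve"` for vascular-event maps) and optionally
#'   `subsite` (e.g. `"upper"`/`"lower"` for gastrointestinal codes).
#' @return An object of class `code_map` (a validated data.frame with a
#'   `norm` column holding the normalised prefix).
#' @examples
#' m <- default_bleed_code_map()
#' match_icd10(c("I61.9", "K920", "J18.9"), m)$category
#' @export
bleed_code_map <- function(entries) {
  stopifnot(is.data.frame(entries), all(c("code", "category") %in% names(entries)))
  entries$code <- toupper(as.character(entries$code))
  if (is.null(entries$subsite)) entries$subsite <- NA_character_
  entries$norm <- normalize_icd10(entries$code)
  bad <- !grepl("^[A-Z][0-9]+$", entries$norm)
  if (any(bad))
    stop2("code map entries not letter+digits (after dot removal): ",
          paste(entries$code[bad], collapse = ", "))
  dup <- duplicated(entries$norm)
  conflict <- entries$norm %in% entries$norm[dup]
  if (any(conflict)) {
    tab <- tapply(entries$category[conflict], entries$norm[conflict],
                  function(x) length(unique(x)))
    if (any(tab > 1))
      stop2("code map assigns a code to two categories: ",
            paste(names(tab)[tab > 1], collapse = ", "))
    entries <- entries[!dup, ]
  }
  structure(entries[, c("code", "category", "subsite", "norm")],
            class = c("code_map", "data.frame"))
}

#' @rdname bleed_code_map
#' @export
default_bleed_code_map <- function() {
  e <- rbind(
    data.frame(code = c("I60", "I61", "I62", "S06.4", "S06.5", "S06.6"),
               category = "intracranial", subsite = NA_character_),
    data.frame(code = c("H35.6", "H43.1", "H45.0"),
               category = "eye", subsite = NA_character_),
    data.frame(code = c("I85.0", "K22.6", "K25.0", "K25.2", "K25.4", "K25.6",
                        "K26.0", "K26.2", "K26.4", "K26.6",
                        "K27.0", "K27.2", "K27.4", "K27.6",
                        "K28.0", "K28.2", "K28.4", "K28.6",
                        "K29.0", "K92.0", "K92.1"),
               category = "gastrointestinal", subsite = "upper"),
    data.frame(code = c("K62.5"), category = "gastrointestinal",
               subsite = "lower"),
    data.frame(code = c("K92.2"), category = "gastrointestinal",
               subsite = "unspecified"),
    data.frame(code = c("R04.0", "R04.2", "R31", "N93.8", "N95.0", "R58"),
               category = "other", subsite = NA_character_)
  )
  bleed_code_map(e)
}

#' @rdname bleed_code_map
#' @export
sve_code_map <- function() {
  bleed_code_map(data.frame(
    code = c("I21", "I22", "I63", "I64", "G45"),
    category = "sve", subsite = NA_character_))
}

normalize_icd10 <- function(codes) {
  gsub("[. ]", "", toupper(trimws(as.character(codes))))
}

#' Match ICD-10 codes against a code map
#'
#' @param codes character vector of recorded ICD-10 codes.
#' @param map a [bleed_code_map()].
#' @return data.frame with one row per input code: `category` and `subsite`
#'   (`NA` where unmatched) and logical `malformed` flagging strings that are
#'   not syntactically valid ICD-10 codes (these never match).
#' @export
match_icd10 <- function(codes, map) {
  stopifnot(inherits(map, "code_map"))
  norm <- normalize_icd10(codes)
  malformed <- !grepl("^[A-Z][0-9]{2}", norm)
  category <- rep(NA_character_, length(codes))
  subsite <- rep(NA_character_, length(codes))
  # longest-prefix-wins: try map entries from most to least specific
  ord <- order(-nchar(map$norm))
  for (i in ord) {
    hit <- !malformed & is.na(category) & startsWith(norm, map$norm[i])
    category[hit] <- map$category[i]
    subsite[hit] <- map$subsite[i]
  }
  data.frame(category = category, subsite = subsite, malformed = malformed)
}
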