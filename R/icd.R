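# ICD-9 / ICD-10 cause-of-death classification for the two study causes.
#
# Septicaemia: ICD-9 rubric 038 (all sub-codes); ICD-10 A40, A41, A02.1,
# A22.7, A26.7, A32.7.
# Pneumonia not specified as bacterial: ICD-9 480, 485-486 (480 is
# configurable, see `include_icd9_480`); ICD-10 J12.x, J16.x, J17.x, J18.x.
# Matching is prefix-based on normalized codes (dots stripped, upper case;
# ICD-9 numeric rubrics zero-padded to three digits so "38.9" == "0389").

.icd_prefixes <- list(
  "9" = list(
    septicaemia = "038",
    pneumonia = c("480", "485", "486"),
    pneumonia_no480 = c("485", "486")
  ),
  "10" = list(
    septicaemia = c("A40", "A41", "A021", "A227", "A267", "A327"),
    pneumonia = c("J12", "J16", "J17", "J18")
  )
)

normalize_icd <- function(code, icd_version) {
  code <- toupper(trimws(as.character(code)))
  if (icd_version == 9L) {
    # zero-pad the numeric rubric so "38", "38.9", "038.9" normalize alike
    parts <- strsplit(code, ".", fixed = TRUE)
    code <- vapply(parts, function(p) {
      if (length(p) == 0L) return("")
      if (grepl("^[0-9]+$", p[1])) p[1] <- sprintf("%03d", as.integer(p[1]))
      paste(p, collapse = "")
    }, character(1))
  } else {
    code <- gsub(".", "", code, fixed = TRUE)
  }
  code
}

#' Classify an ICD cause-of-death code
#'
#' Assigns each code to `"septicaemia"`, `"pneumonia"` (not specified as
#' bacterial) or `"other"`, using prefix matching against the study's ICD-9 and
#' ICD-10 code sets. ICD-9 three-digit rubrics match all their four/five-digit
#' children (038.9 falls under rubric 038); ICD-10 codes are matched with dots
#' stripped (A41.9 is treated as A419).
#'
#' @param code Character vector of ICD codes (non-empty).
#' @param icd_version 9 or 10 (scalar or vector recycled against `code`).
#' @param include_icd9_480 Include ICD-9 rubric 480 in the pneumonia set
#'   (default `TRUE`). The code lists in circulation differ on whether 480
#'   belongs with 485-486, so this is exposed as a switch.
#' @return Character vector in `c("septicaemia", "pneumonia", "other")`.
#' @examples
#' classify_cause("038.9", 9)   # septicaemia
#' classify_cause("J18.9", 10)  # pneumonia
#' classify_cause("C50", 10)    # other
#' @export
classify_cause <- function(code, icd_version, include_icd9_480 = TRUE) {
  if (length(code) == 0L) return(character(0))
  if (any(!nzchar(trimws(as.character(code))))) {
    stop("empty ICD code")
  }
  icd_version <- as.integer(icd_version)
  if (any(is.na(icd_version)) || !all(icd_version %in% c(9L, 10L))) {
    stop("unknown icd_version: must be 9 or 10")
  }
  if (length(icd_version) == 1L) icd_version <- rep(icd_version, length(code))
  if (length(icd_version) != length(code)) {
    stop("icd_version must have length 1 or length(code)")
  }
  out <- character(length(code))
  for (v in c(9L, 10L)) {
    sel <- icd_version == v
    if (!any(sel)) next
    norm <- normalize_icd(code[sel], v)
    sets <- .icd_prefixes[[as.character(v)]]
    pneu <- if (v == 9L && !include_icd9_480) sets$pneumonia_no480 else
      sets$pneumonia
    is_sep <- has_any_prefix(norm, sets$septicaemia)
    is_pneu <- !is_sep & has_any_prefix(norm, pneu)
    res <- rep("other", sum(sel))
    res[is_sep] <- "septicaemia"
    res[is_pneu] <- "pneumonia"
    out[sel] <- res
  }
  out
}

has_any_prefix <- function(x, prefixes) {
  hit <- rep(FALSE, length(x))
  for (p in prefixes) hit <- hit | startsWith(x, p)
  hit
}
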