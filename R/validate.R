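#' Curated reference list of diabetic complications
#'
#' Twenty-two 3-character ICD-10 codes for major, well-established
#' diabetic complications (transient cerebral ischemia, hypertension,
#' ischemic heart disease, heart failure, cerebrovascular and peripheral
#' vascular disease, osteomyelitis and kidney failure), shipped as a
#' plain-text fixture. The list is deliberately recall-oriented: it is
#' known to be incomplete (e.g. depression and pancreatic cancer are
#' absent), so it supports recall but not precision.
#'
#' @param path optional path to an alternative reference file (one code
#'   per line, `#` comments allowed).
#' @return character vector of ICD-10 codes.
#' @export
reference_comorbidities <- function(path = NULL) {
  path <- path %||% system.file("extdata", "reference_comorbidities.txt",
                                package = "comorbrisk", mustWork = TRUE)
  lines <- trimws(readLines(path))
  codes <- lines[!startsWith(lines, "#") & nzchar(lines)]
  bad <- which(!is_icd3(codes))
  if (length(bad)) stopf("malformed reference code '%s'", codes[bad[1]])
  if (!length(codes)) stopf("reference list is empty")
  codes
}

#' Recall of a comorbidity list against a reference list
#'
#' The probability that a reference-list comorbidity is also identified
#' by the co-occurrence screen: `|reference intersect found| / |reference|`.
#'
#' @param comorbidity_list character vector of identified comorbidity
#'   codes (e.g. `run_cooccurrence(...)$comorbidities$union`).
#' @param reference character vector of reference codes; defaults to the
#'   packaged list.
#' @return recall in `[0, 1]`.
#' @export
recall <- function(comorbidity_list, reference = reference_comorbidities()) {
  if (length(reference) == 0L) stopf("reference list is empty")
  length(intersect(unique(reference), unique(comorbidity_list))) /
    length(unique(reference))
}
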