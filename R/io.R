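# File interchange. TSV (UTF-8, tab separated, header row, '.' decimal) is
# the dialect for peak lists, schemes, ratios, summaries and frequency
# tables; proteins travel as FASTA.

#' Read / write centroid peak lists
#'
#' The centroid TSV dialect has columns `run_id`, `rt_min`, `mz`,
#' `intensity` (tab separated, header row, '.' decimal point).
#'
#' @param path File path.
#' @return `read_peaks()` returns the peak tibble sorted by
#'   (run, rt, mz).
#' @export
read_peaks <- function(path) {
  pk <- readr::read_tsv(
    path,
    col_types = readr::cols(
      run_id = readr::col_character(),
      rt_min = readr::col_double(),
      mz = readr::col_double(),
      intensity = readr::col_double()
    )
  )
  dplyr::arrange(pk, .data$run_id, .data$rt_min, .data$mz)
}

#' @rdname read_peaks
#' @param peaks Peak tibble.
#' @export
write_peaks <- function(peaks, path) {
  readr::write_tsv(peaks[c("run_id", "rt_min", "mz", "intensity")], path)
  invisible(path)
}

#' Read / write a labeling scheme
#'
#' Columns `run_id`, `tag`, `condition`, `replicate`; tags must be unique
#' within a run.
#'
#' @param path File path.
#' @export
read_scheme <- function(path) {
  s <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ))
  validate_scheme(s)
  s
}

#' @rdname read_scheme
#' @param scheme Scheme tibble.
#' @export
write_scheme <- function(scheme, path) {
  validate_scheme(scheme)
  readr::write_tsv(scheme, path)
  invisible(path)
}

#' Read / write a proteome as FASTA
#'
#' @param path File path.
#' @return `read_proteome_fasta()` returns a tibble with `protein_id`
#'   (first word of the FASTA header) and `sequence`.
#' @export
read_proteome_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  tibble::tibble(
    protein_id = sub("\\s.*$", "", names(ss)),
    sequence = unname(as.character(ss))
  )
}

#' @rdname read_proteome_fasta
#' @param proteome Tibble with `protein_id`, `sequence`.
#' @export
write_proteome_fasta <- function(proteome, path) {
  ss <- Biostrings::AAStringSet(
    stats::setNames(proteome$sequence, proteome$protein_id)
  )
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read / write peptide identification tables
#'
#' Columns `sequence`, `protein_id`, `n_term_acetylated` (logical, written
#' as TRUE/FALSE) and optionally `peptide_id`.
#'
#' @param path File path.
#' @export
read_identifications <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sequence = readr::col_character(),
    protein_id = readr::col_character(),
    n_term_acetylated = readr::col_logical(),
    .default = readr::col_character()
  ))
}

#' @rdname read_identifications
#' @param identifications Identification tibble.
#' @export
write_identifications <- function(identifications, path) {
  readr::write_tsv(identifications, path)
  invisible(path)
}
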