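#' Distinct outer-envelope marker domains present in a genome
#'
#' Presence/absence at the genome level: a marker counts once no matter how
#' many genes (or copies) carry it.
#'
#' @param genome A [genome_annotation()] or a genes tibble with a `domains`
#'   list column.
#' @param marker_set Non-empty character vector of marker accessions.
#' @return Sorted character vector of the markers found.
#' @export
count_marker_domains <- function(genome, marker_set) {
  if (is.null(marker_set) || !length(marker_set)) {
    abort("marker_set must be a non-empty vector of accessions")
  }
  genes <- as_gene_table(genome)
  found <- intersect(unique(unlist(genes$domains)), marker_set)
  sort(found)
}

#' Classify a genome's cell envelope from marker domains
#'
#' Counts distinct outer-envelope marker domains and applies a conservative
#' three-way rule: at least `config$diderm_min_markers` (default 10) distinct
#' markers give a `diderm` verdict; at most `config$monoderm_max_markers`
#' (default 2) give `monoderm_consistent`; intermediate counts are
#' `ambiguous`, reflecting genomes (such as lineages with atypical
#' envelopes) that carry a handful of markers without a classical outer
#' membrane. Genomes with estimated completeness below
#' `config$completeness_min` or unknown get a `low_completeness` caveat:
#' absence of markers from an incomplete genome is weak evidence.
#'
#' @param genome A [genome_annotation()].
#' @param marker_set Marker accessions; defaults to `config$marker_set`.
#' @param config A [her_config()].
#' @return One-row tibble: `genome_id`, `marker_count`, `markers_found`
#'   (list column), `verdict`, `caveats` (list column).
#' @examples
#' cohort <- generate_cohort(2, seed = 1, envelope_labels = c("diderm", "monoderm"))
#' classify_envelope(cohort$annotations[[1]])
#' @export
classify_envelope <- function(genome, marker_set = NULL,
                              config = her_config()) {
  stopifnot(inherits(genome, "genome_annotation"))
  marker_set <- marker_set %||% config$marker_set
  found <- count_marker_domains(genome, marker_set)
  k <- length(found)
  verdict <- if (k >= config$diderm_min_markers) {
    "diderm"
  } else if (k <= config$monoderm_max_markers) {
    "monoderm_consistent"
  } else {
    "ambiguous"
  }
  caveats <- character(0)
  if (is.na(genome$completeness) ||
      genome$completeness < config$completeness_min) {
    caveats <- c(caveats, "low_completeness")
  }
  tibble(
    genome_id = genome$genome_id, marker_count = k,
    markers_found = list(found), verdict = verdict, caveats = list(caveats)
  )
}

#' @rdname classify_envelope
#' @param genomes A list of [genome_annotation()] objects.
#' @return `classify_envelopes()`: one row per genome.
#' @export
classify_envelopes <- function(genomes, marker_set = NULL,
                               config = her_config()) {
  map(genomes, classify_envelope, marker_set = marker_set, config = config) |>
    list_rbind()
}
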