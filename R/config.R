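#' Pipeline configuration
#'
#' Collects every numeric threshold and switch used across the pipeline in a
#' single object, so that an analysis is reproducible from its configuration
#' alone. Defaults follow the published screening and context-analysis
#' criteria for heliorhodopsin surveys; each entry can be overridden by name.
#'
#' @param ... Named overrides for any of the defaults listed below.
#'
#' @details
#' The defaults are:
#' \describe{
#'   \item{`evalue_max = 1e-3`}{Domain hits with E-value at or above this are
#'     discarded (strict `<` comparison).}
#'   \item{`required_tm = 7`}{Transmembrane helix count required of a bona
#'     fide rhodopsin.}
#'   \item{`her_motif = "SxxxK"`, `type1_motif = "DxxxK"`}{Helix-7 anchor
#'     motifs for heliorhodopsins and type-1 (proteo-)rhodopsins; lowercase
#'     `x` is a wildcard.}
#'   \item{`motif_pad = 3`}{Residues by which the helix-7 window is extended
#'     on each side when locating the motif, absorbing imprecise predicted
#'     helix boundaries.}
#'   \item{`marker_set`}{Accessions of outer-envelope marker domains; the
#'     default is a synthetic placeholder set of 27 slots (`OMM001`..`OMM027`)
#'     standing in for a curated marker list supplied by the user.}
#'   \item{`diderm_min_markers = 10`}{Distinct markers required for a diderm
#'     verdict.}
#'   \item{`monoderm_max_markers = 2`}{Distinct markers at or below which a
#'     genome is called monoderm-consistent; counts in between are
#'     ambiguous.}
#'   \item{`completeness_min = 0.8`}{Genomes below this estimated
#'     completeness (or with unknown completeness) get a `low_completeness`
#'     caveat on envelope calls.}
#'   \item{`contig_min_len = 5000`}{Minimum contig length (bp) for taxonomy
#'     assignment.}
#'   \item{`taxonomy_min_frac = 0.60`}{Fraction of a contig's genes that must
#'     give best hits to one phylum for assignment (inclusive).}
#'   \item{`taxonomy_hits_only = FALSE`}{If `TRUE`, the voting denominator is
#'     genes with any best hit rather than all genes on the contig.}
#'   \item{`operon_max_gap = 10`}{Intergenic distance (bp) strictly below
#'     which a same-strand neighbor is a cotranscription candidate.}
#'   \item{`operon_transitive = TRUE`}{Extend cotranscription chains
#'     transitively while consecutive pairs qualify; `FALSE` restricts the
#'     chain to direct neighbors of the anchor.}
#'   \item{`context_window = 10000`}{Half-width (bp) of the window-mode gene
#'     neighborhood around an anchor.}
#'   \item{`flank_min_genes = 10`}{Genes required on *each* side of an anchor
#'     for enrichment eligibility.}
#'   \item{`draw_size = 20`}{Number of neighborhood genes forming the
#'     hypergeometric draw; always `2 * flank_min_genes`.}
#'   \item{`fdr_alpha = 0.05`}{Benjamini-Hochberg FDR threshold for calling a
#'     domain significant in a genome.}
#'   \item{`prevalence_min = 0.10`}{Fraction of eligible genomes in which a
#'     domain must be significant to be selected.}
#'   \item{`selection_mode = "significant"`}{`"significant"` requires the
#'     domain to be *significant* in at least `prevalence_min` of genomes;
#'     `"present"` requires presence near the anchor in that fraction plus
#'     significance in at least one genome.}
#'   \item{`bh_scope = "run"`}{BH adjustment family: all tests of a run
#'     together (`"run"`) or within each genome (`"genome"`).}
#'   \item{`phylum_min_genomes = 5`}{Eligible genomes a phylum needs for a
#'     per-phylum enrichment rerun.}
#'   \item{`loop_min_len = 50`}{Inter-helix loops are reported as extension
#'     regions only when strictly longer than this (aa).}
#'   \item{`zn_spacer = 17`}{Residues between the two CxxC half-motifs of a
#'     zinc ribbon; a length-2 vector gives an inclusive range.}
#'   \item{`her_accession = "PF18761"`}{Domain accession marking
#'     heliorhodopsin genes when anchors are picked from annotations.}
#'   \item{`hydropathy_window = 19`, `hydropathy_min = 1.6`,
#'     `tm_merge_gap = 3`, `tm_min_len = 15`}{Parameters of the fallback
#'     sliding-window topology predictor.}
#'   \item{`hit_columns`}{Column mapping for the minimal 5-column hit-table
#'     dialect, in the order protein_id, accession, evalue, ali_start,
#'     ali_end.}
#' }
#'
#' @return A named list with class `"her_config"`.
#' @examples
#' cfg <- her_config(fdr_alpha = 0.01)
#' cfg$operon_max_gap
#' @export
her_config <- function(...) {
  cfg <- list(
    evalue_max = 1e-3,
    required_tm = 7L,
    her_motif = "SxxxK",
    type1_motif = "DxxxK",
    motif_pad = 3L,
    marker_set = sprintf("OMM%03d", 1:27),
    diderm_min_markers = 10L,
    monoderm_max_markers = 2L,
    completeness_min = 0.8,
    contig_min_len = 5000L,
    taxonomy_min_frac = 0.60,
    taxonomy_hits_only = FALSE,
    operon_max_gap = 10L,
    operon_transitive = TRUE,
    context_window = 10000L,
    flank_min_genes = 10L,
    draw_size = 20L,
    fdr_alpha = 0.05,
    prevalence_min = 0.10,
    selection_mode = "significant",
    bh_scope = "run",
    phylum_min_genomes = 5L,
    loop_min_len = 50L,
    zn_spacer = 17L,
    her_accession = "PF18761",
    hydropathy_window = 19L,
    hydropathy_min = 1.6,
    tm_merge_gap = 3L,
    tm_min_len = 15L,
    hit_columns = c(1L, 2L, 3L, 4L, 5L)
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad) || is.null(names(over)) || any(names(over) == "")) {
      abort(paste0("unknown or unnamed config entries: ",
                   paste(bad, collapse = ", ")))
    }
    cfg[names(over)] <- over
  }
  validate_config(cfg)
  structure(cfg, class = "her_config")
}

validate_config <- function(cfg) {
  num <- c("evalue_max", "required_tm", "motif_pad", "diderm_min_markers",
           "completeness_min", "contig_min_len", "taxonomy_min_frac",
           "operon_max_gap", "context_window", "flank_min_genes",
           "draw_size", "fdr_alpha", "prevalence_min", "phylum_min_genomes",
           "loop_min_len", "hydropathy_window", "tm_min_len")
  for (nm in num) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0) {
      abort(paste0("config entry '", nm, "' must be a single positive number"))
    }
  }
  if (cfg$draw_size != 2L * cfg$flank_min_genes) {
    abort("draw_size must equal 2 * flank_min_genes")
  }
  if (!cfg$selection_mode %in% c("significant", "present")) {
    abort("selection_mode must be 'significant' or 'present'")
  }
  if (!cfg$bh_scope %in% c("run", "genome")) {
    abort("bh_scope must be 'run' or 'genome'")
  }
  if (cfg$monoderm_max_markers >= cfg$diderm_min_markers) {
    abort("monoderm_max_markers must be below diderm_min_markers")
  }
  invisible(cfg)
}

#' @export
print.her_config <- function(x, ...) {
  cat("<her_config>\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    if (length(val) > 4) val <- c(val[1:3], "...")
    cat("  ", nm, ": ", paste(val, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path File path.
#' @return `read_config()` returns a [her_config()] object;
#'   `write_config()` returns `path` invisibly.
#' @examples
#' p <- tempfile(fileext = ".yml")
#' write_config(her_config(), p)
#' read_config(p)$draw_size
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(her_config, vals)
}

#' @rdname read_config
#' @param config A [her_config()] object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "her_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
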