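#' Build a genome annotation object
#'
#' The central container of the pipeline: an ordered, stranded gene model for
#' one genome (one or more contigs), with per-gene protein-domain accessions.
#' Coordinates are 1-based and inclusive throughout, the GFF3 convention;
#' contigs are treated as linear.
#'
#' @param genome_id Genome identifier.
#' @param genes A data frame with columns `gene_id`, `contig_id`, `start`,
#'   `end`, `strand` (`"+"` or `"-"`), and optionally `domains` (a list
#'   column of character vectors of domain accessions) and `product`.
#' @param contigs Optional data frame with columns `contig_id` and `length`
#'   (bp). Lengths missing or omitted are inferred as the maximum gene end on
#'   the contig.
#' @param completeness Estimated genome completeness in `[0, 1]`, or `NA`
#'   when unknown.
#' @param phylum Phylum label, or `NA` when unknown.
#' @param proteins Optional named character vector of amino-acid sequences
#'   keyed by `gene_id`.
#'
#' @return A list with class `"genome_annotation"` and elements `genome_id`,
#'   `completeness`, `phylum`, `contigs` (tibble), `genes` (tibble, sorted by
#'   contig then start/end) and `proteins`.
#' @examples
#' g <- tibble::tibble(
#'   gene_id = c("g1", "g2"), contig_id = "c1",
#'   start = c(1L, 500L), end = c(300L, 900L), strand = c("+", "+")
#' )
#' genome_annotation("gnm1", g)
#' @export
genome_annotation <- function(genome_id, genes, contigs = NULL,
                              completeness = NA_real_, phylum = NA_character_,
                              proteins = NULL) {
  genes <- as_tibble(genes)
  req <- c("gene_id", "contig_id", "start", "end", "strand")
  miss <- setdiff(req, names(genes))
  if (length(miss)) {
    abort(paste0("genes table is missing columns: ", paste(miss, collapse = ", ")))
  }
  if (!"domains" %in% names(genes)) genes$domains <- list(character(0))
  if (!"product" %in% names(genes)) genes$product <- NA_character_
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (!is.list(genes$domains)) genes$domains <- as.list(genes$domains)
  genes$domains <- map(genes$domains, function(d) {
    d <- as.character(d)
    sort(unique(d[!is.na(d) & nzchar(d)]))
  })
  genes <- genes[order(genes$contig_id, genes$start, genes$end), , drop = FALSE]
  genes <- select(genes, dplyr::all_of(req), "domains", "product")

  if (is.null(contigs)) {
    contigs <- tibble(contig_id = unique(genes$contig_id), length = NA_integer_)
  }
  contigs <- as_tibble(contigs)
  if (!"length" %in% names(contigs)) contigs$length <- NA_integer_
  inferred <- genes |>
    group_by(.data$contig_id) |>
    summarise(max_end = max(.data$end), .groups = "drop")
  contigs <- left_join(contigs, inferred, by = "contig_id")
  contigs$length <- as.integer(ifelse(is.na(contigs$length),
                                      contigs$max_end, contigs$length))
  contigs$max_end <- NULL
  contigs <- arrange(contigs, .data$contig_id)

  ann <- structure(
    list(genome_id = as.character(genome_id),
         completeness = as.numeric(completeness),
         phylum = as.character(phylum),
         contigs = contigs, genes = genes,
         proteins = proteins),
    class = "genome_annotation"
  )
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  g <- ann$genes
  if (anyDuplicated(g$gene_id)) {
    dup <- unique(g$gene_id[duplicated(g$gene_id)])
    abort(paste0("duplicate gene_id: ", paste(head(dup, 5), collapse = ", ")))
  }
  bad <- which(g$end < g$start | g$start < 1L)
  if (length(bad)) {
    abort(paste0("invalid coordinates (end < start or start < 1) for gene(s): ",
                 paste(head(g$gene_id[bad], 5), collapse = ", ")))
  }
  if (!all(g$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-' for every gene")
  }
  if (anyDuplicated(ann$contigs$contig_id)) {
    abort(paste0("duplicate contig_id in genome ", ann$genome_id))
  }
  len <- setNames(ann$contigs$length, ann$contigs$contig_id)
  over <- which(g$end > len[g$contig_id])
  if (length(over)) {
    abort(paste0("gene(s) extend beyond contig length: ",
                 paste(head(g$gene_id[over], 5), collapse = ", ")))
  }
  if (!is.na(ann$completeness) &&
      (ann$completeness < 0 || ann$completeness > 1)) {
    abort("completeness must lie in [0, 1] or be NA")
  }
  ann
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation> ", x$genome_id, "\n", sep = "")
  cat("  contigs: ", nrow(x$contigs), ", genes: ", nrow(x$genes), "\n", sep = "")
  cat("  completeness: ", ifelse(is.na(x$completeness), "unknown",
                                 format(x$completeness)),
      ", phylum: ", ifelse(is.na(x$phylum), "unknown", x$phylum), "\n", sep = "")
  if (!is.null(x$proteins)) cat("  proteins: ", length(x$proteins), "\n", sep = "")
  invisible(x)
}

#' Gene table of one contig
#'
#' @param ann A [genome_annotation()].
#' @param contig_id Contig identifier.
#' @return Tibble of genes on that contig, sorted by start.
#' @export
contig_genes <- function(ann, contig_id) {
  stopifnot(inherits(ann, "genome_annotation"))
  if (!contig_id %in% ann$contigs$contig_id) {
    abort(paste0("contig '", contig_id, "' not in genome ", ann$genome_id))
  }
  filter(ann$genes, .data$contig_id == !!contig_id)
}

# resolve a genes argument that may be a genome_annotation or a genes tibble
as_gene_table <- function(x) {
  if (inherits(x, "genome_annotation")) return(x$genes)
  as_tibble(x)
}
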