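#' Tally best-hit phylum votes for one contig
#'
#' Genes without a best hit contribute to the denominator used downstream
#' but to no phylum.
#'
#' @param contig Genes tibble of one contig (or a one-contig
#'   [genome_annotation()]).
#' @param besthits Best-hit tibble (`gene_id`, `subject_phylum`; `NA` = no
#'   hit), at most one row per gene.
#' @return Tibble `phylum`, `n`, sorted by decreasing count.
#' @export
contig_phylum_votes <- function(contig, besthits) {
  genes <- as_gene_table(contig)
  hits <- besthits |>
    filter(.data$gene_id %in% genes$gene_id, !is.na(.data$subject_phylum))
  if (!nrow(hits)) return(tibble(phylum = character(), n = integer()))
  hits |>
    count(phylum = .data$subject_phylum, name = "n") |>
    arrange(desc(.data$n), .data$phylum)
}

#' Assign phylum-level taxonomy to contigs by best-hit voting
#'
#' A contig of at least `config$contig_min_len` bp (default 5 kb) is
#' assigned to a phylum only when at least `config$taxonomy_min_frac`
#' (default 60%, inclusive) of its genes give best hits to that phylum — a
#' strict concordance rule, not majority rule. Shorter contigs are excluded
#' (`excluded_reason = "too_short"`). By default the denominator is all
#' predicted genes on the contig, so genes without any hit dilute support;
#' set `config$taxonomy_hits_only = TRUE` to count only genes with hits.
#'
#' @param ann A [genome_annotation()] (its contigs are each voted on), or a
#'   genes tibble accompanied by `contig_lengths`.
#' @param besthits Best-hit tibble (`gene_id`, `subject_phylum`).
#' @param config A [her_config()].
#' @param contig_lengths Optional named vector of contig lengths, needed only
#'   when `ann` is a plain genes tibble.
#' @return Tibble with one row per contig: `contig_id`, `phylum` (`NA` when
#'   unassigned), `support_frac`, `n_genes`, `excluded_reason` (`NA` when
#'   assessed).
#' @examples
#' cohort <- generate_cohort(1, seed = 3)
#' ann <- cohort$annotations[[1]]
#' bh <- generate_besthits(ann, concordance = 0.8,
#'                         phylum = "Actinobacteriota", seed = 4)
#' assign_taxonomy(ann, bh)
#' @export
assign_taxonomy <- function(ann, besthits, config = her_config(),
                            contig_lengths = NULL) {
  if (inherits(ann, "genome_annotation")) {
    genes <- ann$genes
    contig_lengths <- setNames(ann$contigs$length, ann$contigs$contig_id)
  } else {
    genes <- as_tibble(ann)
    if (is.null(contig_lengths)) {
      abort("contig_lengths is required when 'ann' is a plain genes table")
    }
  }
  split(genes, genes$contig_id) |>
    imap(function(cg, cid) {
      n_genes <- nrow(cg)
      len <- unname(contig_lengths[cid])
      if (is.na(len) || len < config$contig_min_len) {
        return(tibble(contig_id = cid, phylum = NA_character_,
                      support_frac = NA_real_, n_genes = n_genes,
                      excluded_reason = "too_short"))
      }
      votes <- contig_phylum_votes(cg, besthits)
      denom <- if (config$taxonomy_hits_only) sum(votes$n) else n_genes
      if (!nrow(votes) || denom == 0) {
        return(tibble(contig_id = cid, phylum = NA_character_,
                      support_frac = 0, n_genes = n_genes,
                      excluded_reason = NA_character_))
      }
      top <- votes[1, ]
      frac <- top$n / denom
      tibble(
        contig_id = cid,
        phylum = if (frac >= config$taxonomy_min_frac) top$phylum
                 else NA_character_,
        support_frac = frac, n_genes = n_genes,
        excluded_reason = NA_character_
      )
    }) |>
    list_rbind() |>
    arrange(.data$contig_id)
}

#' Drop exact duplicate contigs before taxonomy voting
#'
#' A light stand-in for upstream sequence dereplication: contigs whose gene
#' tables are identical in coordinates, strands and domains keep only their
#' first occurrence (by contig id).
#'
#' @param anns List of [genome_annotation()] objects.
#' @return The list with exact-duplicate contigs removed.
#' @export
drop_duplicate_contigs <- function(anns) {
  seen <- character(0)
  map(anns, function(ann) {
    keys <- map_chr(split(ann$genes, ann$genes$contig_id), function(g) {
      paste(g$start, g$end, g$strand,
            map_chr(g$domains, paste, collapse = "|"), collapse = ";")
    })
    dup <- character(0)
    for (cid in names(keys)) {
      if (keys[[cid]] %in% seen) {
        dup <- c(dup, cid)
      } else {
        seen <<- c(seen, keys[[cid]])
      }
    }
    if (length(dup)) {
      ann$genes <- filter(ann$genes, !.data$contig_id %in% dup)
      ann$contigs <- filter(ann$contigs, !.data$contig_id %in% dup)
    }
    ann
  })
}
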