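#' Intergenic distance between two genes on one contig
#'
#' Defined as `downstream$start - upstream$end - 1`: abutting genes (no
#' shared base, no gap) give 0, and overlapping genes give a negative
#' distance.
#'
#' @param upstream,downstream One-row gene data frames (as in
#'   [genome_annotation()]`$genes`) on the same contig, with
#'   `downstream$start >= upstream$start`.
#' @return Integer distance in bp, negative iff the genes overlap.
#' @examples
#' g <- tibble::tibble(gene_id = c("a", "b"), contig_id = "c",
#'                     start = c(1L, 103L), end = c(100L, 400L),
#'                     strand = "+")
#' intergenic_distance(g[1, ], g[2, ])  # 2
#' @export
intergenic_distance <- function(upstream, downstream) {
  if (upstream$contig_id != downstream$contig_id) {
    abort("genes lie on different contigs")
  }
  if (downstream$start < upstream$start) {
    abort("'downstream' starts before 'upstream'")
  }
  as.integer(downstream$start - upstream$end - 1L)
}

# vectorized distance between consecutive rows of a sorted gene table
consecutive_gaps <- function(genes) {
  if (nrow(genes) < 2) return(integer(0))
  as.integer(genes$start[-1] - genes$end[-nrow(genes)] - 1L)
}

#' Extract the gene neighborhood around an anchor gene
#'
#' Two modes, matching the two ways heliorhodopsin contexts are examined:
#' `"by_genes"` takes up to `config$flank_min_genes` genes on each side of
#' the anchor in positional order (the subset drawn for enrichment testing);
#' `"by_window"` takes every gene overlapping the anchor extended by
#' `config$context_window` bp (default 10 kb) up- and downstream. The anchor
#' itself is never a member. A by-genes neighborhood is flagged eligible for
#' enrichment only when the full flank exists on both sides.
#'
#' @param ann A [genome_annotation()] (the anchor's contig is used) or a
#'   genes tibble of one contig.
#' @param anchor_id Gene id of the anchor.
#' @param mode `"by_genes"` or `"by_window"`.
#' @param config A [her_config()].
#' @return A list with class `"her_neighborhood"`: `anchor` (one-row
#'   tibble), `members` (tibble, positional order), `mode`, `eligible`
#'   (by-genes mode: full flank on both sides), `n_upstream`/`n_downstream`,
#'   and `domain_counts` (tibble `accession`, `n_genes`; each member gene
#'   counts once per distinct domain).
#' @export
extract_neighborhood <- function(ann, anchor_id,
                                 mode = c("by_genes", "by_window"),
                                 config = her_config()) {
  mode <- match.arg(mode)
  genes <- as_gene_table(ann)
  if (!anchor_id %in% genes$gene_id) {
    abort(paste0("anchor gene '", anchor_id, "' not found"))
  }
  anchor <- genes[genes$gene_id == anchor_id, ]
  cg <- genes[genes$contig_id == anchor$contig_id, , drop = FALSE]
  cg <- cg[order(cg$start, cg$end), , drop = FALSE]
  idx <- which(cg$gene_id == anchor_id)

  if (mode == "by_genes") {
    k <- config$flank_min_genes
    up <- cg[seq_len(idx - 1L), , drop = FALSE]
    up <- tail(up, k)
    down <- cg[seq_len(nrow(cg)) > idx, , drop = FALSE]
    down <- head(down, k)
    members <- bind_rows(up, down)
    n_up <- nrow(up); n_down <- nrow(down)
    eligible <- n_up >= k && n_down >= k
  } else {
    lo <- anchor$start - config$context_window
    hi <- anchor$end + config$context_window
    members <- cg[cg$end >= lo & cg$start <= hi & cg$gene_id != anchor_id, ,
                  drop = FALSE]
    n_up <- sum(members$start < anchor$start)
    n_down <- sum(members$start > anchor$start)
    eligible <- NA
  }
  members <- members[order(members$start, members$end), , drop = FALSE]

  dom <- unlist(map(members$domains, unique))
  domain_counts <- if (length(dom)) {
    tibble(accession = dom) |>
      count(.data$accession, name = "n_genes") |>
      arrange(.data$accession)
  } else {
    tibble(accession = character(), n_genes = integer())
  }

  structure(list(anchor = anchor, members = members, mode = mode,
                 eligible = eligible, n_upstream = n_up,
                 n_downstream = n_down, domain_counts = domain_counts),
            class = "her_neighborhood")
}

#' @export
print.her_neighborhood <- function(x, ...) {
  cat("<her_neighborhood> anchor ", x$anchor$gene_id, " (", x$mode, ")\n",
      "  members: ", nrow(x$members), " (", x$n_upstream, " up, ",
      x$n_downstream, " down)",
      if (isTRUE(x$eligible)) ", eligible for enrichment" else "", "\n",
      sep = "")
  invisible(x)
}

#' Detect the cotranscription (operon) candidate around an anchor gene
#'
#' Applies the strict two-part criterion for a gene potentially transcribed
#' with the anchor: the intergenic distance must be strictly below
#' `config$operon_max_gap` bp (default 10; overlapping genes, with negative
#' distance, qualify) and the gene must lie on the same strand. By default
#' the chain is extended transitively in both directions while each
#' consecutive pair qualifies, yielding one maximal chain per anchor;
#' `config$operon_transitive = FALSE` restricts it to the anchor's direct
#' neighbors.
#'
#' @param ann A [genome_annotation()] or a genes tibble of one contig.
#' @param anchor_id Gene id of the anchor.
#' @param config A [her_config()].
#' @return A tibble of the chain's genes in positional order (`gene_id`,
#'   `start`, `end`, `strand`, `is_anchor`, `gap_after` — intergenic bp to
#'   the next chain member, `NA` for the last). Zero rows when no neighbor
#'   qualifies.
#' @export
find_operon_candidates <- function(ann, anchor_id, config = her_config()) {
  genes <- as_gene_table(ann)
  if (!anchor_id %in% genes$gene_id) {
    abort(paste0("anchor gene '", anchor_id, "' not found"))
  }
  anchor <- genes[genes$gene_id == anchor_id, ]
  cg <- genes[genes$contig_id == anchor$contig_id, , drop = FALSE]
  cg <- cg[order(cg$start, cg$end), , drop = FALSE]
  idx <- which(cg$gene_id == anchor_id)
  gaps <- consecutive_gaps(cg)  # gaps[i] between gene i and i+1
  ok_pair <- function(i) {
    cg$strand[i] == cg$strand[i + 1L] && gaps[i] < config$operon_max_gap
  }

  lo <- idx; hi <- idx
  if (config$operon_transitive) {
    while (lo > 1L && ok_pair(lo - 1L)) lo <- lo - 1L
    while (hi < nrow(cg) && ok_pair(hi)) hi <- hi + 1L
  } else {
    if (lo > 1L && ok_pair(lo - 1L)) lo <- lo - 1L
    if (hi < nrow(cg) && ok_pair(hi)) hi <- hi + 1L
  }
  if (lo == hi) {
    return(tibble(gene_id = character(), start = integer(), end = integer(),
                  strand = character(), is_anchor = logical(),
                  gap_after = integer()))
  }
  chain <- cg[lo:hi, c("gene_id", "start", "end", "strand")]
  chain$is_anchor <- chain$gene_id == anchor_id
  chain$gap_after <- c(gaps[lo:(hi - 1L)], NA_integer_)
  chain
}
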