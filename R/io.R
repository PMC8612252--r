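#' Read a genome annotation from GFF3 (and optional protein FASTA)
#'
#' Parses CDS (or, failing that, gene) features into a [genome_annotation()].
#' Domain accessions stored in a `domains` attribute and free-text `product`
#' attributes are preserved. Contig lengths come from `##sequence-region`
#' pragmas when present and are otherwise inferred as the maximum gene end.
#'
#' @param gff3_path Path to a GFF3 file.
#' @param fasta_path Optional protein FASTA whose record names (first
#'   whitespace-delimited token) are gene ids.
#' @param genome_id Genome identifier; defaults to the GFF3 file name.
#' @param completeness,phylum Genome metadata, `NA` when unknown.
#' @return A [genome_annotation()].
#' @export
read_annotations <- function(gff3_path, fasta_path = NULL,
                             genome_id = NULL,
                             completeness = NA_real_, phylum = NA_character_) {
  if (!file.exists(gff3_path)) abort(paste0("no such file: ", gff3_path))
  genome_id <- genome_id %||%
    sub("\\.gff3?$", "", basename(gff3_path), ignore.case = TRUE)

  raw <- readLines(gff3_path, warn = FALSE)
  feat <- raw[!startsWith(raw, "#") & nzchar(trimws(raw))]
  if (length(feat)) {
    parts <- strsplit(feat, "\t", fixed = TRUE)
    s <- suppressWarnings(as.integer(map_chr(parts, function(p) p[4] %||% NA_character_)))
    e <- suppressWarnings(as.integer(map_chr(parts, function(p) p[5] %||% NA_character_)))
    bad <- which(!is.na(s) & !is.na(e) & e < s)
    if (length(bad)) {
      abort(paste0("GFF3 feature with end < start: ",
                   substr(feat[bad[1]], 1, 120)))
    }
  }

  gr <- rtracklayer::import(gff3_path, format = "gff3")
  types <- as.character(gr$type)
  keep <- if (any(types == "CDS")) types == "CDS" else types == "gene"
  gr <- gr[keep]
  if (!length(gr)) abort(paste0("no CDS or gene features in ", gff3_path))

  ids <- gr$ID
  if (is.null(ids)) ids <- rep(NA_character_, length(gr))
  if ("Name" %in% names(S4Vectors::mcols(gr))) {
    ids <- ifelse(is.na(ids), gr$Name, ids)
  }
  if (anyNA(ids)) abort("GFF3 feature(s) without an ID attribute")

  doms <- if ("domains" %in% names(S4Vectors::mcols(gr))) {
    as.list(gr$domains)
  } else {
    rep(list(character(0)), length(gr))
  }
  prod <- if ("product" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$product)
  } else {
    rep(NA_character_, length(gr))
  }

  genes <- tibble(
    gene_id = as.character(ids),
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    domains = doms,
    product = prod
  )
  if (any(genes$strand == "*")) {
    abort(paste0("feature(s) without strand: ",
                 paste(head(genes$gene_id[genes$strand == "*"], 5),
                       collapse = ", ")))
  }

  contigs <- parse_sequence_regions(raw)

  proteins <- NULL
  if (!is.null(fasta_path)) {
    aa <- Biostrings::readAAStringSet(fasta_path)
    nm <- map_chr(strsplit(names(aa), "\\s+"), 1)
    proteins <- setNames(as.character(aa), nm)
  }

  genome_annotation(genome_id, genes, contigs = contigs,
                    completeness = completeness, phylum = phylum,
                    proteins = proteins)
}

parse_sequence_regions <- function(lines) {
  sr <- lines[startsWith(lines, "##sequence-region")]
  if (!length(sr)) return(NULL)
  parts <- strsplit(trimws(sr), "\\s+")
  tibble(
    contig_id = map_chr(parts, 2),
    length = as.integer(map_chr(parts, 4))
  )
}

#' Write a genome annotation to GFF3 (and optional protein FASTA)
#'
#' The writer is deterministic: identical annotations produce byte-identical
#' files. Contig lengths are emitted as `##sequence-region` pragmas and the
#' `domains` / `product` columns as GFF3 attributes, so
#' `read_annotations(write_annotations(x))` round-trips.
#'
#' @param ann A [genome_annotation()].
#' @param gff3_path Output GFF3 path.
#' @param fasta_path Optional output path for the protein FASTA (only written
#'   when the annotation carries protein sequences).
#' @return `gff3_path`, invisibly.
#' @export
write_annotations <- function(ann, gff3_path, fasta_path = NULL) {
  stopifnot(inherits(ann, "genome_annotation"))
  g <- ann$genes
  attrs <- paste0("ID=", gff3_escape(g$gene_id))
  has_dom <- lengths(g$domains) > 0
  dom_str <- map_chr(g$domains, function(d) paste(gff3_escape(d), collapse = ","))
  attrs <- ifelse(has_dom, paste0(attrs, ";domains=", dom_str), attrs)
  has_prod <- !is.na(g$product) & nzchar(g$product)
  attrs <- ifelse(has_prod,
                  paste0(attrs, ";product=", gff3_escape(g$product)), attrs)
  rows <- paste(g$contig_id, "heliocontext", "CDS", g$start, g$end, ".",
                g$strand, "0", attrs, sep = "\t")
  header <- c("##gff-version 3",
              sprintf("##sequence-region %s 1 %d",
                      ann$contigs$contig_id, ann$contigs$length))
  writeLines(c(header, rows), gff3_path)
  if (!is.null(fasta_path) && !is.null(ann$proteins)) {
    writeLines(paste0(">", names(ann$proteins), "\n", unname(ann$proteins)),
               fasta_path)
  }
  invisible(gff3_path)
}

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x
}

#' Read a protein domain-hit table
#'
#' Two dialects are supported: a minimal tab/whitespace-delimited table
#' (default column order protein_id, accession, evalue, ali_start, ali_end;
#' remappable via `config$hit_columns`) and the per-domain tabular output of
#' profile-HMM searches (`dialect = "domtblout"`, whitespace-delimited with
#' `#` comments; the independent E-value column is used). Only hits with
#' E-value strictly below `config$evalue_max` are retained. Rows whose
#' E-value cannot be parsed are skipped with one warning giving the count.
#'
#' @param path Path to the hit table.
#' @param config A [her_config()].
#' @param dialect `"tsv"` or `"domtblout"`.
#' @return Tibble with columns `protein_id`, `accession`, `evalue`,
#'   `ali_start`, `ali_end`.
#' @export
read_domain_hits <- function(path, config = her_config(),
                             dialect = c("tsv", "domtblout")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(lines)) {
    return(tibble(protein_id = character(), accession = character(),
                  evalue = numeric(), ali_start = integer(),
                  ali_end = integer()))
  }
  parts <- strsplit(trimws(lines), "\\s+")
  pick <- function(idx) map_chr(parts, function(p) p[idx] %||% NA_character_)
  if (dialect == "tsv") {
    cc <- config$hit_columns
    hits <- tibble(
      protein_id = pick(cc[1]), accession = pick(cc[2]),
      evalue_chr = pick(cc[3]),
      ali_start = suppressWarnings(as.integer(pick(cc[4]))),
      ali_end = suppressWarnings(as.integer(pick(cc[5])))
    )
  } else {
    # HMMER --domtblout: target name (1), query accession (5; falls back to
    # query name, 4), independent E-value (13), ali coords (18, 19)
    acc <- pick(5)
    acc <- ifelse(acc == "-", pick(4), acc)
    hits <- tibble(
      protein_id = pick(1), accession = acc, evalue_chr = pick(13),
      ali_start = suppressWarnings(as.integer(pick(18))),
      ali_end = suppressWarnings(as.integer(pick(19)))
    )
  }
  hits$evalue <- suppressWarnings(as.numeric(hits$evalue_chr))
  n_bad <- sum(is.na(hits$evalue))
  if (n_bad > 0) {
    warn(paste0("skipped ", n_bad, " hit row(s) with unparseable E-value"))
  }
  hits |>
    filter(!is.na(.data$evalue), .data$evalue < config$evalue_max) |>
    select("protein_id", "accession", "evalue", "ali_start", "ali_end")
}

#' Attach domain hits to a genome annotation
#'
#' Adds the accessions of `hits` to each gene's `domains` set, matching
#' `protein_id` to `gene_id`. Presence is set-valued: duplicate accessions on
#' one gene collapse to one.
#'
#' @param ann A [genome_annotation()].
#' @param hits A hit table from [read_domain_hits()] (or any data frame with
#'   `protein_id` and `accession`).
#' @return The updated [genome_annotation()].
#' @export
attach_domain_hits <- function(ann, hits) {
  stopifnot(inherits(ann, "genome_annotation"))
  by_gene <- split(hits$accession, hits$protein_id)
  ann$genes$domains <- map2(ann$genes$domains, ann$genes$gene_id, function(d, id) {
    sort(unique(c(d, by_gene[[id]])))
  })
  ann
}

#' Read a best-hit table
#'
#' @param path Two-column TSV (`gene_id`, `subject_phylum`); an empty or `NA`
#'   phylum field means the gene had no hit.
#' @return Tibble with columns `gene_id`, `subject_phylum` (`NA` = no hit).
#' @export
read_besthits <- function(path) {
  bh <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  names(bh)[1:2] <- c("gene_id", "subject_phylum")
  if (anyDuplicated(bh$gene_id)) {
    abort("best-hit table has more than one row for some gene_id")
  }
  bh$subject_phylum[!is.na(bh$subject_phylum) &
                      !nzchar(bh$subject_phylum)] <- NA_character_
  as_tibble(bh[, c("gene_id", "subject_phylum")])
}

#' Read a transmembrane-topology table
#'
#' @param path TSV with columns `protein_id`, `index`, `start`, `end`,
#'   `n_terminus_side`.
#' @return A named list of [topology_model()] objects keyed by protein id.
#' @export
read_topology <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = "c", index = "i", start = "i", end = "i",
    n_terminus_side = "c"
  ))
  split(tab, tab$protein_id) |>
    map(function(d) {
      topology_model(
        segments = tibble(index = d$index, start = d$start, end = d$end),
        n_terminus_side = d$n_terminus_side[1],
        protein_id = d$protein_id[1]
      )
    })
}

#' Read a marker-domain list
#'
#' @param path Text file with one accession per line; blank lines and lines
#'   starting with `#` are ignored.
#' @return Character vector of accessions.
#' @export
read_marker_set <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (!length(x)) abort(paste0("marker list is empty: ", path))
  unique(x)
}

#' Write result tables as TSV reports
#'
#' One TSV per element of `results`, named `<name>.tsv`. Rows are sorted by
#' every column left to right and list columns are comma-collapsed, so equal
#' inputs give byte-identical files.
#'
#' @param results Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(results, out_dir) {
  if (is.data.frame(results)) results <- list(results = results)
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    abort("results must be a named list of data frames")
  }
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0) {
    abort(paste0("cannot write to directory: ", out_dir))
  }
  paths <- imap(results, function(df, nm) {
    df <- as_tibble(df)
    df <- mutate(df, across(dplyr::where(is.list),
                            ~ map_chr(.x, function(v) {
                              paste(as.character(v), collapse = ",")
                            })))
    if (nrow(df) > 0 && ncol(df) > 0) {
      df <- df[do.call(order, as.list(df)), , drop = FALSE]
    }
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(df, p, na = "")
    p
  })
  invisible(unlist(paths))
}
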