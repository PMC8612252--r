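#' Find heliorhodopsin anchor genes in annotated genomes
#'
#' Anchors can come from an explicit table (e.g. screen verdicts) or, when
#' `anchors = NULL`, from the annotations themselves: every gene whose
#' domain set contains `config$her_accession`.
#'
#' @param genomes List of [genome_annotation()] objects.
#' @param anchors Optional tibble (`genome_id`, `anchor_id`).
#' @param config A [her_config()].
#' @return Tibble `genome_id`, `anchor_id`.
#' @export
find_anchor_genes <- function(genomes, anchors = NULL,
                              config = her_config()) {
  if (!is.null(anchors)) {
    anchors <- as_tibble(anchors)
    stopifnot(all(c("genome_id", "anchor_id") %in% names(anchors)))
    return(anchors[, c("genome_id", "anchor_id")])
  }
  map(genomes, function(ann) {
    hit <- map_lgl(ann$genes$domains, function(d) config$her_accession %in% d)
    if (!any(hit)) return(NULL)
    tibble(genome_id = ann$genome_id, anchor_id = ann$genes$gene_id[hit])
  }) |>
    list_rbind()
}

#' Enumerate anchor loci eligible for neighborhood enrichment
#'
#' A locus is eligible when its anchor has at least `config$flank_min_genes`
#' genes on *each* side on the same contig, guaranteeing a full draw of
#' `config$draw_size` neighborhood genes.
#'
#' @inheritParams find_anchor_genes
#' @return Tibble `genome_id`, `contig_id`, `anchor_id`, `n_upstream`,
#'   `n_downstream`, `eligible`.
#' @export
eligible_loci <- function(genomes, anchors = NULL, config = her_config()) {
  anchors <- find_anchor_genes(genomes, anchors, config)
  by_id <- setNames(genomes, map_chr(genomes, "genome_id"))
  pmap(list(anchors$genome_id, anchors$anchor_id), function(gid, aid) {
    ann <- by_id[[gid]]
    if (is.null(ann)) abort(paste0("no annotation for genome ", gid))
    nb <- extract_neighborhood(ann, aid, mode = "by_genes", config = config)
    tibble(genome_id = gid, contig_id = nb$anchor$contig_id, anchor_id = aid,
           n_upstream = nb$n_upstream, n_downstream = nb$n_downstream,
           eligible = nb$eligible)
  }) |>
    list_rbind()
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` domain-carrying genes when `n` genes are drawn without
#' replacement from a genome of `N` genes of which `K` carry the domain.
#' `k = 0` returns exactly 1. Vectorized over its arguments.
#'
#' @param k Observed carriers in the draw, `0 <= k <= min(n, K)`.
#' @param K Carriers in the genome.
#' @param n Draw size.
#' @param N Genome size (genes); `K <= N`, `n <= N`.
#' @return Numeric vector of probabilities in `(0, 1]`.
#' @examples
#' hypergeometric_upper_tail(5, K = 6, n = 20, N = 30)
#' @export
hypergeometric_upper_tail <- function(k, K, n, N) {
  bad <- k < 0 | K < 0 | n < 0 | N < 0 | K > N | n > N | k > pmin(n, K)
  if (any(bad)) {
    abort("hypergeometric bounds violated: need 0 <= k <= min(n, K), K <= N, n <= N")
  }
  ifelse(k == 0, 1, phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic BH: `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned
#' in the input order. Input values must lie in `(0, 1]`.
#'
#' @param p_values Numeric vector of p-values.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Hypergeometric enrichment tests for one anchor neighborhood
#'
#' For an eligible anchor locus, takes the `config$draw_size`-gene
#' neighborhood (the anchor's flanking genes; the anchor itself is excluded)
#' and, for every distinct domain present in it, computes the upper-tail
#' hypergeometric probability of seeing that many carrier genes in a random
#' draw of the same size from the genome. `k` counts neighborhood member
#' genes carrying the domain, `K` carrier genes genome-wide, `n` the draw
#' size and `N` all protein-coding genes in the genome; a gene carrying two
#' copies of a domain counts once.
#'
#' @param ann A [genome_annotation()].
#' @param anchor_id Anchor gene id (must form an eligible locus).
#' @param config A [her_config()].
#' @return Tibble with one row per domain: `genome_id`, `anchor_id`,
#'   `accession`, `k`, `K`, `n`, `N`, `p` (the q column is added by the
#'   run-level adjustment in [run_enrichment()]).
#' @export
test_neighborhood_domains <- function(ann, anchor_id, config = her_config()) {
  stopifnot(inherits(ann, "genome_annotation"))
  nb <- extract_neighborhood(ann, anchor_id, mode = "by_genes", config = config)
  if (!isTRUE(nb$eligible)) {
    abort(paste0("locus ", anchor_id, " in genome ", ann$genome_id,
                 " is not eligible (needs ", config$flank_min_genes,
                 " genes on each side)"))
  }
  dc <- nb$domain_counts
  if (!nrow(dc)) {
    return(tibble(genome_id = character(), anchor_id = character(),
                  accession = character(), k = integer(), K = integer(),
                  n = integer(), N = integer(), p = numeric()))
  }
  N <- nrow(ann$genes)
  n <- nrow(nb$members)
  genome_carriers <- ann$genes$domains |>
    map(unique) |>
    unlist()
  K_tab <- table(genome_carriers)
  K <- as.integer(K_tab[dc$accession])
  tibble(
    genome_id = ann$genome_id, anchor_id = anchor_id,
    accession = dc$accession, k = dc$n_genes, K = K,
    n = as.integer(n), N = as.integer(N),
    p = hypergeometric_upper_tail(dc$n_genes, K, n, N)
  )
}

#' Cross-genome selection of neighborhood-enriched domains
#'
#' A genome counts as significant for a domain when any of its anchor loci
#' has a BH-adjusted value below `config$fdr_alpha`. Under the default
#' `selection_mode = "significant"` a domain is selected when it is
#' significant in at least `config$prevalence_min` (default 10%) of eligible
#' genomes; under `"present"` it must merely occur near the anchor in that
#' fraction of genomes and be significant in at least one.
#'
#' @param records Enrichment records carrying a `q` column.
#' @param n_genomes_eligible Number of genomes with at least one eligible
#'   locus in the run (must be positive).
#' @param config A [her_config()].
#' @return Tibble per domain: `accession`, `n_genomes_eligible`,
#'   `n_genomes_present`, `n_genomes_significant`, `selected`; sorted with
#'   selected domains first.
#' @export
summarize_selection <- function(records, n_genomes_eligible,
                                config = her_config()) {
  if (n_genomes_eligible <= 0) {
    abort("no eligible genomes in this run")
  }
  if (!nrow(records)) {
    return(tibble(accession = character(),
                  n_genomes_eligible = integer(),
                  n_genomes_present = integer(),
                  n_genomes_significant = integer(), selected = logical()))
  }
  stopifnot("q" %in% names(records))
  out <- records |>
    group_by(.data$accession) |>
    summarise(
      n_genomes_present = dplyr::n_distinct(.data$genome_id),
      n_genomes_significant = dplyr::n_distinct(
        .data$genome_id[.data$q < config$fdr_alpha]),
      .groups = "drop"
    ) |>
    mutate(
      n_genomes_eligible = as.integer(n_genomes_eligible),
      selected = if (config$selection_mode == "significant") {
        .data$n_genomes_significant / n_genomes_eligible >= config$prevalence_min
      } else {
        .data$n_genomes_present / n_genomes_eligible >= config$prevalence_min &
          .data$n_genomes_significant >= 1L
      }
    ) |>
    select("accession", "n_genomes_eligible", "n_genomes_present",
           "n_genomes_significant", "selected") |>
    arrange(desc(.data$selected), desc(.data$n_genomes_significant),
            .data$accession)
  out
}

#' Run the full neighborhood-enrichment procedure
#'
#' For every eligible heliorhodopsin locus across the supplied genomes,
#' tests each neighborhood domain with the upper-tail hypergeometric
#' distribution, adjusts all tests of the run together with
#' Benjamini-Hochberg (or within each genome, per `config$bh_scope`), and
#' selects domains recurrently enriched across genomes. With
#' `per_phylum = TRUE` the whole procedure is rerun within every phylum
#' contributing at least `config$phylum_min_genomes` eligible genomes.
#'
#' @param genomes List of [genome_annotation()] objects.
#' @param anchors Optional anchor tibble (`genome_id`, `anchor_id`);
#'   `NULL` selects genes annotated with `config$her_accession`.
#' @param config A [her_config()].
#' @param per_phylum Also rerun per phylum?
#' @return An object of class `"her_enrichment"`: a list with `records`
#'   (per-test tibble incl. `q`), `summaries` (per-domain tibble), `loci`,
#'   `n_genomes_eligible`, `per_phylum` (named list of summary tibbles or
#'   `NULL`) and `config`. Use [tidy()], [glance()] and [autoplot()] on it.
#' @examples
#' cohort <- generate_cohort(6, seed = 11, genome_frac = 1)
#' fit <- run_enrichment(cohort$annotations)
#' glance(fit)
#' @export
run_enrichment <- function(genomes, anchors = NULL, config = her_config(),
                           per_phylum = FALSE) {
  loci <- eligible_loci(genomes, anchors, config)
  ok <- filter(loci, .data$eligible)
  n_elig <- dplyr::n_distinct(ok$genome_id)
  if (n_elig == 0) abort("no eligible loci in any genome")
  by_id <- setNames(genomes, map_chr(genomes, "genome_id"))

  records <- pmap(list(ok$genome_id, ok$anchor_id), function(gid, aid) {
    test_neighborhood_domains(by_id[[gid]], aid, config)
  }) |>
    list_rbind() |>
    arrange(.data$genome_id, .data$anchor_id, .data$accession)

  if (nrow(records)) {
    if (config$bh_scope == "run") {
      records$q <- bh_adjust(records$p)
    } else {
      records <- records |>
        group_by(.data$genome_id) |>
        mutate(q = bh_adjust(.data$p)) |>
        ungroup()
    }
  } else {
    records$q <- numeric(0)
  }

  summaries <- summarize_selection(records, n_elig, config)

  pp <- NULL
  if (per_phylum) {
    pp <- per_phylum_runs(genomes, anchors, config)
  }

  structure(list(records = records, summaries = summaries, loci = loci,
                 n_genomes_eligible = n_elig, per_phylum = pp,
                 config = config),
            class = "her_enrichment")
}

#' Per-phylum enrichment reruns
#'
#' Repeats the whole selection procedure (tests, BH adjustment and
#' cross-genome selection) independently within each phylum whose genomes
#' contribute at least `config$phylum_min_genomes` eligible genomes; phyla
#' below the floor are skipped with a message.
#'
#' @inheritParams run_enrichment
#' @return Named list (by phylum) of per-domain summary tibbles.
#' @export
per_phylum_runs <- function(genomes, anchors = NULL, config = her_config()) {
  phyla <- map_chr(genomes, function(a) a$phylum %||% NA_character_)
  keep <- !is.na(phyla)
  groups <- split(genomes[keep], phyla[keep])
  out <- list()
  for (ph in sort(names(groups))) {
    sub <- groups[[ph]]
    loci <- eligible_loci(sub, anchors = restrict_anchors(anchors, sub),
                          config = config)
    n_elig <- dplyr::n_distinct(loci$genome_id[loci$eligible])
    if (n_elig < config$phylum_min_genomes) {
      message("phylum ", ph, " skipped: ", n_elig,
              " eligible genome(s), fewer than ", config$phylum_min_genomes)
      next
    }
    fit <- run_enrichment(sub, anchors = restrict_anchors(anchors, sub),
                          config = config, per_phylum = FALSE)
    out[[ph]] <- fit$summaries
  }
  out
}

restrict_anchors <- function(anchors, genomes) {
  if (is.null(anchors)) return(NULL)
  ids <- map_chr(genomes, "genome_id")
  filter(as_tibble(anchors), .data$genome_id %in% ids)
}

#' @export
print.her_enrichment <- function(x, ...) {
  cat("<her_enrichment>\n")
  cat("  eligible genomes: ", x$n_genomes_eligible,
      ", loci tested: ", sum(x$loci$eligible),
      ", tests: ", nrow(x$records), "\n", sep = "")
  cat("  domains selected: ", sum(x$summaries$selected), " of ",
      nrow(x$summaries), "\n", sep = "")
  if (!is.null(x$per_phylum)) {
    cat("  per-phylum runs: ", paste(names(x$per_phylum), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
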