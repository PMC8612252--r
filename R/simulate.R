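#' Generate a synthetic protein with a planted transmembrane architecture
#'
#' Builds an amino-acid sequence of hydrophobic (Leu/Ile/Val/Phe-rich)
#' helices separated by hydrophilic loops, optionally embedding an anchor
#' motif (e.g. `SxxxK`) inside a chosen helix, and returns the planted
#' topology as ground truth. Loops on the requested cytoplasmic side are
#' lysine/arginine-rich so that the positive-inside rule recovers the
#' planted orientation; loops on the other side carry no K/R.
#'
#' @param n_helix Number of transmembrane helices.
#' @param helix_len Helix length in residues (scalar or length `n_helix`).
#' @param loop_len Loop lengths, length `n_helix + 1` (N terminus, the
#'   `n_helix - 1` inter-helix loops, C terminus); scalars are recycled with
#'   a longer default N terminus.
#' @param motif Anchor pattern to embed, or `NULL` for none.
#' @param motif_helix Helix (1-based from the N terminus) carrying the
#'   motif.
#' @param n_terminus_side Planted orientation, `"in"` or `"out"`.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (as when called from [generate_cohort()]).
#' @return List: `sequence`, `topology` (a [topology_model()] with the
#'   planted segments), `motif_pos` (absolute residue coordinate or `NA`).
#' @examples
#' p <- generate_protein(seed = 1)
#' nchar(p$sequence)
#' @export
generate_protein <- function(n_helix = 7, helix_len = 21, loop_len = NULL,
                             motif = "SxxxK", motif_helix = 7,
                             n_terminus_side = "in", seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  stopifnot(n_helix >= 1)
  helix_len <- rep_len(helix_len, n_helix)
  if (is.null(loop_len)) {
    loop_len <- c(20L, rep(15L, n_helix - 1L), 15L)
  } else {
    loop_len <- rep_len(loop_len, n_helix + 1L)
  }
  if (!is.null(motif)) {
    if (motif_helix > n_helix) abort("motif_helix exceeds n_helix")
    if (nchar(motif) + 10L > helix_len[motif_helix]) {
      abort("motif (plus safety margin) is longer than the target helix")
    }
  }

  helix_pool <- c("L", "I", "V", "F")
  helix_prob <- c(0.4, 0.25, 0.2, 0.15)
  in_pool <- c("K", "R", "S", "G", "T", "N", "Q", "D", "E", "P")
  in_prob <- c(0.2, 0.12, 0.12, 0.12, 0.1, 0.08, 0.08, 0.08, 0.05, 0.05)
  out_pool <- c("S", "G", "T", "N", "Q", "D", "E", "P")

  # loop j (0-based: j = 0 is the N terminus) is cytoplasmic when j is even
  # and the N terminus is inside, or j odd and the N terminus is outside
  loop_seq <- function(j) {
    len <- loop_len[j + 1L]
    if (len == 0L) return(character(0))
    inside <- (j %% 2L == 0L) == (n_terminus_side == "in")
    if (inside) {
      s <- sample(in_pool, len, replace = TRUE, prob = in_prob)
      if (len >= 2L) s[2L] <- "K"  # guarantee positive-inside signal
      s
    } else {
      sample(out_pool, len, replace = TRUE)
    }
  }

  res <- character(0)
  seg_start <- integer(n_helix)
  seg_end <- integer(n_helix)
  motif_pos <- NA_integer_
  for (h in seq_len(n_helix)) {
    res <- c(res, loop_seq(h - 1L))
    hx <- sample(helix_pool, helix_len[h], replace = TRUE, prob = helix_prob)
    if (!is.null(motif) && h == motif_helix) {
      pat <- strsplit(motif, "")[[1]]
      span <- length(pat)
      # keep the motif >= 5 residues from either helix edge so hydropathy
      # segmentation is not perturbed at the boundaries
      off <- sample(6:(helix_len[h] - span - 4L), 1L)
      fixed <- pat != "x"
      hx[off:(off + span - 1L)][fixed] <- toupper(pat[fixed])
      motif_pos <- length(res) + off
    }
    seg_start[h] <- length(res) + 1L
    res <- c(res, hx)
    seg_end[h] <- length(res)
  }
  res <- c(res, loop_seq(n_helix))

  topo <- topology_model(
    tibble(index = seq_len(n_helix), start = seg_start, end = seg_end),
    n_terminus_side = n_terminus_side
  )
  list(sequence = paste(res, collapse = ""), topology = topo,
       motif_pos = motif_pos)
}

#' Generate a synthetic cohort of annotated genomes with planted truth
#'
#' Emulates the inputs of the whole pipeline: each genome is one linear
#' contig of `n_genes_range` ordered, stranded genes (lengths
#' `gene_len_range` bp) organised into cotranscription units whose internal
#' intergenic gaps are drawn from -20..9 bp (overlaps included) while unit
#' boundaries carry either a wide gap (30..300 bp) or a small-gap decoy with
#' a strand flip. Every gene receives background domain annotations
#' (each of `length(domain_pool)` accessions independently at
#' `background_freq`); one heliorhodopsin anchor per genome (domain
#' `config$her_accession`, at least `config$flank_min_genes` genes on each
#' flank) optionally has `enriched_accession` planted at `neighborhood_freq`
#' among its 2 x flank neighborhood genes. Envelope labels plant 10-27
#' distinct marker domains (diderm) or 0-2 (monoderm). Everything is
#' deterministic given `seed`.
#'
#' @param n_genomes Number of genomes.
#' @param seed Integer seed; the generator draws from a single stream keyed
#'   by it.
#' @param config A [her_config()].
#' @param n_genes_range,gene_len_range Inclusive integer ranges.
#' @param plant_enrichment Plant a neighborhood-enriched domain?
#' @param enriched_accession Accession of the planted domain.
#' @param neighborhood_freq,background_freq Per-gene planting frequencies in
#'   the anchor neighborhood vs genome-wide (both in `[0, 1]`).
#' @param genome_frac Fraction of genomes (first `ceiling(frac * n)`) that
#'   carry the planted enrichment.
#' @param envelope_labels `"diderm"`/`"monoderm"` per genome (recycled), or
#'   `NULL` to draw labels at random.
#' @param phyla Phylum labels: length `n_genomes` for direct assignment,
#'   otherwise a pool sampled per genome.
#' @param domain_pool Background domain accessions.
#' @param proteins `"anchor"` generates a planted 7-TM SxxxK protein per
#'   anchor; `"none"` skips sequences.
#' @param operon_decoy_prob Probability that a unit boundary is a small-gap,
#'   strand-flip decoy.
#' @return List with `annotations` (list of [genome_annotation()]) and
#'   `truth` (list, one entry per genome: `genome_id`, `anchor_id`,
#'   `planted_rhodopsins`, `planted_operon` (gene ids of the anchor's
#'   cotranscription unit; `NULL` when the anchor is monocistronic),
#'   `planted_enriched_domains`, `envelope_label`, `planted_markers`,
#'   `phylum`).
#' @examples
#' cohort <- generate_cohort(2, seed = 42)
#' cohort$annotations[[1]]
#' @export
generate_cohort <- function(n_genomes, seed, config = her_config(),
                            n_genes_range = c(100L, 400L),
                            gene_len_range = c(300L, 3000L),
                            plant_enrichment = TRUE,
                            enriched_accession = "PF99901",
                            neighborhood_freq = 0.4,
                            background_freq = 0.02,
                            genome_frac = 0.3,
                            envelope_labels = NULL,
                            phyla = c("Actinobacteriota", "Firmicutes",
                                      "Chloroflexota", "Bacteroidota",
                                      "Cyanobacteriota"),
                            domain_pool = sprintf("PF%05d", 1:50),
                            proteins = c("anchor", "none"),
                            operon_decoy_prob = 0.15) {
  stopifnot(n_genomes >= 1)
  proteins <- match.arg(proteins)
  if (neighborhood_freq > 1 || neighborhood_freq < 0 ||
      background_freq > 1 || background_freq < 0) {
    abort("planting frequencies must lie in [0, 1]")
  }
  if (enriched_accession %in% domain_pool) {
    abort("enriched_accession must not collide with the background pool")
  }
  withr::local_seed(seed)

  flank <- config$flank_min_genes
  if (n_genes_range[1] < 2L * flank + 1L) {
    abort("n_genes_range too small to flank an anchor on both sides")
  }
  env_lab <- if (is.null(envelope_labels)) {
    sample(c("monoderm", "diderm"), n_genomes, replace = TRUE)
  } else {
    rep_len(envelope_labels, n_genomes)
  }
  phy <- if (length(phyla) == n_genomes) phyla else {
    sample(phyla, n_genomes, replace = TRUE)
  }
  n_planted <- if (plant_enrichment) ceiling(genome_frac * n_genomes) else 0L

  annotations <- vector("list", n_genomes)
  truth <- vector("list", n_genomes)
  for (g in seq_len(n_genomes)) {
    gid <- sprintf("GNM%03d", g)
    n_genes <- sample(n_genes_range[1]:n_genes_range[2], 1L)
    sim <- sim_contig_layout(n_genes, gene_len_range, operon_decoy_prob)
    gene_id <- sprintf("%s_g%04d", gid, seq_len(n_genes))
    contig_id <- paste0(gid, "_c1")

    anchor_idx <- sample((flank + 1L):(n_genes - flank), 1L)
    neighbors <- c((anchor_idx - flank):(anchor_idx - 1L),
                   (anchor_idx + 1L):(anchor_idx + flank))

    # background domain annotation: gene x accession Bernoulli draws
    pres <- matrix(runif(n_genes * length(domain_pool)) < background_freq,
                   nrow = n_genes)
    domains <- apply(pres, 1L, function(r) domain_pool[r], simplify = FALSE)

    planted_enr <- list()
    if (plant_enrichment && g <= n_planted) {
      has_bg <- runif(n_genes) < background_freq
      has_bg[neighbors] <- runif(length(neighbors)) < neighborhood_freq
      has_bg[anchor_idx] <- FALSE
      domains <- map2(domains, has_bg, function(d, p) {
        if (p) c(d, enriched_accession) else d
      })
      planted_enr <- list(list(accession = enriched_accession,
                               neighborhood_freq = neighborhood_freq,
                               background_freq = background_freq))
    }
    domains[[anchor_idx]] <- c(domains[[anchor_idx]], config$her_accession)

    n_mark <- if (env_lab[g] == "diderm") sample(10:27, 1L) else sample(0:2, 1L)
    markers <- sort(sample(config$marker_set, n_mark))
    for (m in markers) {
      i <- sample(n_genes, 1L)
      domains[[i]] <- c(domains[[i]], m)
    }

    genes <- tibble(
      gene_id = gene_id, contig_id = contig_id,
      start = sim$start, end = sim$end, strand = sim$strand,
      domains = domains,
      product = ifelse(seq_len(n_genes) == anchor_idx,
                       "heliorhodopsin", "hypothetical protein")
    )
    contigs <- tibble(contig_id = contig_id,
                      length = sim$end[n_genes] + sample(50:500, 1L))

    prot <- NULL
    planted_rho <- list()
    if (proteins == "anchor") {
      pr <- generate_protein(n_helix = config$required_tm,
                             motif = config$her_motif,
                             motif_helix = 7, n_terminus_side = "in")
      prot <- setNames(pr$sequence, gene_id[anchor_idx])
      planted_rho <- list(list(protein_id = gene_id[anchor_idx],
                               class = "heliorhodopsin",
                               motif_pos = pr$motif_pos))
    }

    unit_members <- which(sim$unit == sim$unit[anchor_idx])
    planted_operon <- if (length(unit_members) > 1L) {
      gene_id[unit_members]
    } else {
      NULL
    }

    annotations[[g]] <- genome_annotation(
      gid, genes, contigs = contigs,
      completeness = round(runif(1, 0.8, 1), 2),
      phylum = phy[g], proteins = prot
    )
    truth[[g]] <- list(
      genome_id = gid, anchor_id = gene_id[anchor_idx],
      planted_rhodopsins = planted_rho,
      planted_operon = planted_operon,
      planted_enriched_domains = planted_enr,
      envelope_label = env_lab[g],
      planted_markers = markers,
      phylum = phy[g]
    )
  }
  list(annotations = annotations, truth = truth)
}

# gene coordinates, strands and cotranscription-unit assignment for one
# contig; unit-internal gaps are < 10 bp on a shared strand, unit
# boundaries are either wide gaps or small-gap decoys with a strand flip
sim_contig_layout <- function(n_genes, gene_len_range, decoy_prob) {
  sizes <- integer(0)
  while (sum(sizes) < n_genes) {
    sizes <- c(sizes, sample(1:4, 1L, prob = c(0.55, 0.2, 0.15, 0.1)))
  }
  excess <- sum(sizes) - n_genes
  if (excess > 0) sizes[length(sizes)] <- sizes[length(sizes)] - excess
  sizes <- sizes[sizes > 0]

  unit <- rep(seq_along(sizes), sizes)
  strand <- character(n_genes)
  gap_before <- integer(n_genes)  # gap between gene i-1 and i
  unit_strand <- character(length(sizes))
  unit_strand[1] <- sample(c("+", "-"), 1L)
  for (u in seq_along(sizes)[-1]) {
    if (runif(1) < decoy_prob) {
      unit_strand[u] <- setdiff(c("+", "-"), unit_strand[u - 1L])
      attr(unit_strand, "decoy_gap") <- c(attr(unit_strand, "decoy_gap"), u)
    } else {
      unit_strand[u] <- sample(c("+", "-"), 1L)
    }
  }
  decoy_units <- attr(unit_strand, "decoy_gap") %||% integer(0)

  first_of_unit <- match(seq_along(sizes), unit)
  for (i in seq_len(n_genes)) {
    strand[i] <- unit_strand[unit[i]]
    if (i == 1L) {
      gap_before[i] <- sample(1:100, 1L)
    } else if (unit[i] == unit[i - 1L]) {
      gap_before[i] <- sample(-20:9, 1L)
    } else if (unit[i] %in% decoy_units) {
      gap_before[i] <- sample(0:9, 1L)
    } else {
      gap_before[i] <- sample(30:300, 1L)
    }
  }
  len <- sample(gene_len_range[1]:gene_len_range[2], n_genes, replace = TRUE)
  start <- integer(n_genes)
  end <- integer(n_genes)
  pos <- 0L
  for (i in seq_len(n_genes)) {
    start[i] <- pos + gap_before[i] + 1L
    end[i] <- start[i] + len[i] - 1L
    pos <- end[i]
  }
  list(start = start, end = end, strand = strand, unit = unit)
}

#' Generate a best-hit table with controlled phylum concordance
#'
#' Exactly `ceiling(concordance * n_genes)` genes (a random subset) give
#' best hits to the target phylum; the remainder are split between decoy
#' phyla and no-hits. Deterministic given `seed`.
#'
#' @param contig A [genome_annotation()] or genes tibble.
#' @param concordance Fraction in `[0, 1]`.
#' @param phylum Target phylum label.
#' @param seed Optional integer seed (`NULL`: current RNG stream).
#' @param decoy_phyla Labels used for discordant hits.
#' @param no_hit_frac Probability that a discordant gene has no hit at all.
#' @return Tibble `gene_id`, `subject_phylum` (`NA` = no hit).
#' @export
generate_besthits <- function(contig, concordance, phylum, seed = NULL,
                              decoy_phyla = c("DecoyPhylumA", "DecoyPhylumB"),
                              no_hit_frac = 0.3) {
  if (concordance < 0 || concordance > 1) {
    abort("concordance must lie in [0, 1]")
  }
  if (phylum %in% decoy_phyla) abort("decoy phyla must differ from target")
  if (!is.null(seed)) withr::local_seed(seed)
  genes <- as_gene_table(contig)
  n <- nrow(genes)
  n_conc <- as.integer(ceiling(concordance * n))
  conc <- sample(n, n_conc)
  subject <- character(n)
  subject[conc] <- phylum
  rest <- setdiff(seq_len(n), conc)
  for (i in rest) {
    subject[i] <- if (runif(1) < no_hit_frac) {
      NA_character_
    } else {
      sample(decoy_phyla, 1L)
    }
  }
  tibble(gene_id = genes$gene_id, subject_phylum = subject)
}

#' Write a synthetic cohort to disk
#'
#' One GFF3 (plus a protein FASTA when sequences were generated) per genome
#' and a single `truth.json`; all files are byte-identical across runs with
#' the same cohort.
#'
#' @param cohort Result of [generate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- map_chr(cohort$annotations, function(ann) {
    p <- file.path(out_dir, paste0(ann$genome_id, ".gff3"))
    fp <- if (!is.null(ann$proteins)) {
      file.path(out_dir, paste0(ann$genome_id, "_proteins.faa"))
    }
    write_annotations(ann, p, fasta_path = fp)
    p
  })
  tj <- file.path(out_dir, "truth.json")
  jsonlite::write_json(cohort$truth, tj, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(c(paths, tj))
}
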