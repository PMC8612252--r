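test_that("intergenic distance follows start - end - 1", {
  g <- make_genes(c(1, 103), c(100, 400))
  expect_equal(intergenic_distance(g[1, ], g[2, ]), 2L)

  g0 <- make_genes(c(1, 101), c(100, 400))
  expect_equal(intergenic_distance(g0[1, ], g0[2, ]), 0L)  # abutting

  gneg <- make_genes(c(1, 95), c(100, 400))
  expect_equal(intergenic_distance(gneg[1, ], gneg[2, ]), -6L)  # overlap

  other <- make_genes(50, 400, contig = "ctgZ")
  expect_error(intergenic_distance(g[1, ], other[1, ]), "different contigs")
})

test_that("by-genes neighborhoods take up to 10 genes per side", {
  ann <- make_contig_ann(31)           # anchor in the middle: 15 each side
  nb <- extract_neighborhood(ann, "g16", mode = "by_genes")
  expect_equal(nrow(nb$members), 20)
  expect_true(nb$eligible)
  expect_false("g16" %in% nb$members$gene_id)
  expect_equal(nb$n_upstream, 10)
  expect_equal(nb$n_downstream, 10)

  nb_first <- extract_neighborhood(ann, "g01", mode = "by_genes")
  expect_equal(nrow(nb_first$members), 10)
  expect_false(nb_first$eligible)

  expect_error(extract_neighborhood(ann, "nope"), "not found")
})

test_that("window neighborhoods collect genes overlapping anchor +/- 10 kb", {
  # 1 kb genes, 1 kb gaps: each neighbor occupies a 2 kb slot
  ann <- make_contig_ann(41, len = 1000L, gap = 1000L)
  nb <- extract_neighborhood(ann, "g21", mode = "by_window")
  # genes starting within 10 kb on each side: 5 per side
  expect_equal(nrow(nb$members), 10)
  st <- nb$members$start
  anchor <- nb$anchor
  expect_true(all(st <= anchor$end + 10000 &
                    nb$members$end >= anchor$start - 10000))
})

test_that("neighborhood domain multiset counts genes once per distinct domain", {
  doms <- rep(list(character(0)), 25)
  doms[[12]] <- c("PFA", "PFA", "PFB")  # duplicate accession on one gene
  doms[[14]] <- "PFA"
  doms[[13]] <- "PFANCHOR"              # anchor domain must not count
  ann <- make_contig_ann(25, domains = doms)
  nb <- extract_neighborhood(ann, "g13", mode = "by_genes")
  expect_equal(nb$domain_counts,
               tibble::tibble(accession = c("PFA", "PFB"), n_genes = c(2L, 1L)))
})

test_that("neighborhood membership is invariant under coordinate mirroring", {
  cohort <- generate_cohort(1, seed = 405)
  ann <- cohort$annotations[[1]]
  anchor <- cohort$truth[[1]]$anchor_id
  L <- ann$contigs$length

  mirrored <- ann$genes
  s <- L - mirrored$end + 1L
  e <- L - mirrored$start + 1L
  mirrored$start <- s
  mirrored$end <- e
  mirrored$strand <- ifelse(mirrored$strand == "+", "-", "+")
  ann_m <- genome_annotation("mirror", mirrored, contigs = ann$contigs)

  for (mode in c("by_genes", "by_window")) {
    nb <- extract_neighborhood(ann, anchor, mode = mode)
    nb_m <- extract_neighborhood(ann_m, anchor, mode = mode)
    expect_setequal(nb_m$members$gene_id, nb$members$gene_id)
  }
})

test_that("operon criteria: same strand and strictly < 10 bp", {
  base <- function(gap, strand2) {
    make_genes(c(1, 1000 + gap + 1), c(1000, 2000 + gap),
               strands = c("+", strand2))
  }
  ch5 <- find_operon_candidates(base(5, "+"), "g01")
  expect_equal(ch5$gene_id, c("g01", "g02"))
  expect_equal(ch5$gap_after, c(5L, NA))

  expect_equal(nrow(find_operon_candidates(base(10, "+"), "g01")), 0)
  expect_equal(nrow(find_operon_candidates(base(2, "-"), "g01")), 0)

  # overlapping same-strand genes qualify (negative distance < 10)
  ov <- make_genes(c(1, 995), c(1000, 1900), strands = "+")
  expect_equal(nrow(find_operon_candidates(ov, "g01")), 2)
})

test_that("chains extend transitively and are maximal", {
  # g1 -(3)- g2 -(0)- g3 -(25)- g4 ; all same strand
  g <- make_genes(c(1, 1004, 2005, 3030), c(1000, 2000, 3000, 4000))
  ch <- find_operon_candidates(g, "g02")
  expect_equal(ch$gene_id, c("g01", "g02", "g03"))
  # no gene adjacent to the chain qualifies (maximality)
  expect_equal(nrow(find_operon_candidates(g, "g04")), 0)

  # direct-neighbor-only mode stops at the anchor's neighbors
  ch_direct <- find_operon_candidates(g, "g03",
                                      her_config(operon_transitive = FALSE))
  expect_equal(ch_direct$gene_id, c("g02", "g03"))
  ch_trans <- find_operon_candidates(g, "g03")
  expect_equal(ch_trans$gene_id, c("g01", "g02", "g03"))
})

test_that("planted cotranscription chains are recovered exactly", {
  cohort <- generate_cohort(8, seed = 406)
  for (g in seq_along(cohort$annotations)) {
    tr <- cohort$truth[[g]]
    ch <- find_operon_candidates(cohort$annotations[[g]], tr$anchor_id)
    got <- if (nrow(ch)) ch$gene_id else NULL
    expect_identical(got, tr$planted_operon)
    if (nrow(ch)) {
      expect_length(unique(ch$strand), 1)
      expect_true(all(ch$gap_after[-nrow(ch)] < 10))
    }
  }
})
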