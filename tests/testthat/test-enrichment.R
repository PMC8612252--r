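test_that("eligibility requires 10 genes on both sides", {
  ann <- make_contig_ann(40)
  pick <- function(i) tibble::tibble(genome_id = "gnmT",
                                     anchor_id = sprintf("g%02d", i))
  loci11 <- eligible_loci(list(ann), pick(11))
  expect_true(loci11$eligible)    # exactly 10 upstream, 29 downstream
  loci10 <- eligible_loci(list(ann), pick(10))
  expect_false(loci10$eligible)   # 9 upstream only

  two <- eligible_loci(list(ann), dplyr::bind_rows(pick(11), pick(5)))
  expect_equal(sum(two$eligible), 1)
})

test_that("upper-tail hypergeometric matches the combinatorial oracle", {
  # frozen oracle value for (k=5, K=6, n=20, N=30), computed by summing
  # C(6,j) C(24,20-j) / C(30,20) over j = 5, 6
  expect_equal(hypergeometric_upper_tail(5, 6, 20, 30),
               0.32638625742074018, tolerance = 1e-14)

  expect_identical(hypergeometric_upper_tail(0, 6, 20, 30), 1)
  expect_equal(hypergeometric_upper_tail(13, 30, 20, 30), 1)  # K = N

  for (N in c(5, 17, 33)) {
    for (K in c(0, 2, N %/% 2, N)) {
      for (n in c(1, N %/% 3 + 1, N)) {
        for (k in 0:min(n, K)) {
          expect_equal(hypergeometric_upper_tail(k, K, n, N),
                       hyper_oracle(k, K, n, N), tolerance = 1e-12)
        }
      }
    }
  }
  expect_error(hypergeometric_upper_tail(7, 6, 20, 30), "bounds")
  expect_error(hypergeometric_upper_tail(1, 31, 20, 30), "bounds")
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # q_i = min_{j >= i} p_(j) m / j on a worked vector
  p <- c(0.005, 0.009, 0.05, 0.5)
  expect_equal(bh_adjust(p), c(0.018, 0.018, 2 / 30, 0.5))
  # input order preserved
  expect_equal(bh_adjust(rev(p)), rev(bh_adjust(p)))

  set.seed(407)
  x <- runif(50)
  q <- bh_adjust(x)
  expect_true(all(q >= x))
  expect_true(all(q <= 1))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("neighborhood tests report k, K, n, N consistently", {
  # 30-gene genome; domain PFX on 5 of the 20 neighbors plus 1 outside
  doms <- rep(list(character(0)), 30)
  neigh <- c(6:15, 17:26)
  doms[neigh[c(1, 5, 9, 14, 20)]] <- list("PFX")
  doms[[29]] <- "PFX"
  doms[[16]] <- "ANCH"
  ann <- make_contig_ann(30, domains = doms)

  rec <- test_neighborhood_domains(ann, "g16")
  row <- rec[rec$accession == "PFX", ]
  expect_equal(c(row$k, row$K, row$n, row$N), c(5L, 6L, 20L, 30L))
  expect_equal(row$p, hypergeometric_upper_tail(5, 6, 20, 30))
  # domains absent from the neighborhood yield no record
  expect_false("PFY" %in% rec$accession)
  # the anchor's own domain counts zero neighbors, so no ANCH record either
  expect_false("ANCH" %in% rec$accession)

  expect_error(test_neighborhood_domains(ann, "g05"), "not eligible")
})

test_that("a strongly planted domain has the smallest p in its genome", {
  cohort <- generate_cohort(4, seed = 408, genome_frac = 1,
                            neighborhood_freq = 0.5)
  for (g in seq_along(cohort$annotations)) {
    tr <- cohort$truth[[g]]
    rec <- test_neighborhood_domains(cohort$annotations[[g]], tr$anchor_id)
    planted <- tr$planted_enriched_domains[[1]]$accession
    expect_equal(rec$accession[which.min(rec$p)], planted)
  }
})

test_that("selection arithmetic follows the 10%-of-genomes rule", {
  rec <- tibble::tibble(
    genome_id = sprintf("G%02d", 1:20), anchor_id = "a",
    accession = "PFS", k = 5L, K = 6L, n = 20L, N = 200L,
    p = 0.001, q = c(rep(0.01, 3), rep(0.5, 17))
  )
  s <- summarize_selection(rec, n_genomes_eligible = 20)
  expect_equal(s$n_genomes_significant, 3L)
  expect_true(s$selected)            # 3/20 = 0.15 >= 0.10

  rec1 <- dplyr::mutate(rec, q = c(0.01, rep(0.5, 19)))
  expect_false(summarize_selection(rec1, 20)$selected)  # 1/20 < 0.10

  # alternative reading: present in >= 10% plus one significant genome
  s_alt <- summarize_selection(rec1, 20,
                               her_config(selection_mode = "present"))
  expect_true(s_alt$selected)
  expect_error(summarize_selection(rec, 0), "eligible")
})

test_that("the full run is deterministic and order-invariant", {
  cohort <- generate_cohort(6, seed = 409, genome_frac = 1)
  fit1 <- run_enrichment(cohort$annotations)
  fit2 <- run_enrichment(rev(cohort$annotations))
  expect_identical(fit1$records, fit2$records)
  expect_identical(fit1$summaries, fit2$summaries)
  expect_true("PF99901" %in% fit1$summaries$accession[fit1$summaries$selected])
  expect_true(all(fit1$records$q >= fit1$records$p))

  g <- glance(fit1)
  expect_equal(g$n_genomes_eligible, 6)
  expect_equal(g$n_tests, nrow(tidy(fit1)))
})

test_that("per-phylum reruns respect the five-genome floor", {
  cohort <- generate_cohort(
    8, seed = 410, genome_frac = 1,
    phyla = c(rep("Actinobacteriota", 5), rep("Firmicutes", 3))
  )
  expect_message(pp <- per_phylum_runs(cohort$annotations),
                 "Firmicutes skipped")
  expect_named(pp, "Actinobacteriota")
  expect_true("PF99901" %in%
                pp$Actinobacteriota$accession[pp$Actinobacteriota$selected])
})

test_that("enrichment planted in one phylum is selected only there", {
  cfg <- her_config()
  ann_a <- generate_cohort(5, seed = 411, genome_frac = 1,
                           phyla = rep("PhylumA", 5))$annotations
  ann_b <- generate_cohort(5, seed = 412, plant_enrichment = FALSE,
                           phyla = rep("PhylumB", 5))$annotations
  # merge under unique genome ids
  ann_b <- lapply(ann_b, function(a) { a$genome_id <- paste0(a$genome_id, "b"); a })
  pp <- per_phylum_runs(c(ann_a, ann_b), config = cfg)
  sel_a <- pp$PhylumA$accession[pp$PhylumA$selected]
  sel_b <- pp$PhylumB$accession[pp$PhylumB$selected]
  expect_true("PF99901" %in% sel_a)
  expect_false("PF99901" %in% sel_b)
})
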