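test_that("fallback topology recovers planted helices within 2 residues", {
  for (s in c(101, 102, 103)) {
    for (nh in c(6, 7)) {
      p <- generate_protein(n_helix = nh, motif = NULL, seed = s)
      topo <- predict_topology_fallback(p$sequence)
      expect_equal(nrow(topo$segments), nh)
      expect_true(all(abs(topo$segments$start - p$topology$segments$start) <= 2))
      expect_true(all(abs(topo$segments$end - p$topology$segments$end) <= 2))
      expect_equal(topo$n_terminus_side, "in")
    }
  }
})

test_that("hydrophilic sequences yield no TM segments", {
  topo <- predict_topology_fallback(strrep("G", 200))
  expect_equal(nrow(topo$segments), 0)
})

test_that("non-standard residues are tolerated with a warning", {
  p <- generate_protein(motif = NULL, seed = 104)
  seq2 <- sub("L", "X", p$sequence)
  expect_warning(topo <- predict_topology_fallback(seq2), "non-standard")
  expect_equal(nrow(topo$segments), 7)
})

test_that("helix-7 motif is located, with the +/-3 boundary window", {
  # helix 7 at 200..222; S at 204, K at 208
  seq <- strrep("A", 300)
  substr(seq, 204, 204) <- "S"
  substr(seq, 208, 208) <- "K"
  topo <- topology_model(tibble::tibble(
    index = 1:7, start = c(10, 40, 70, 100, 130, 160, 200),
    end = c(30, 60, 90, 120, 150, 190, 222)
  ), "in")
  expect_equal(locate_helix7_motif(seq, topo, "SxxxK"), 204L)
  expect_true(is.na(locate_helix7_motif(seq, topo, "DxxxK")))

  # S two residues before the helix start, K inside: window rule matches
  seq2 <- strrep("A", 300)
  substr(seq2, 198, 198) <- "S"
  substr(seq2, 202, 202) <- "K"
  expect_equal(locate_helix7_motif(seq2, topo, "SxxxK"), 198L)

  # S four residues before the helix: outside the extended window
  seq3 <- strrep("A", 300)
  substr(seq3, 196, 196) <- "S"
  substr(seq3, 200, 200) <- "K"
  expect_true(is.na(locate_helix7_motif(seq3, topo, "SxxxK")))

  topo6 <- topology_model(topo$segments[1:6, ], "in")
  expect_error(locate_helix7_motif(seq, topo6, "SxxxK"), "fewer than 7")
})

test_that("classification implements the three-way screen", {
  her <- generate_protein(motif = "SxxxK", seed = 105)
  t1 <- generate_protein(motif = "DxxxK", seed = 106)
  none <- generate_protein(motif = NULL, seed = 107)
  six <- generate_protein(n_helix = 6, motif = "SxxxK", motif_helix = 6,
                          seed = 108)

  call_her <- classify_rhodopsin("a", her$sequence)
  expect_equal(call_her$verdict, "heliorhodopsin")
  expect_equal(call_her$motif_pos, her$motif_pos)
  expect_equal(call_her$reasons[[1]], character(0))

  expect_equal(classify_rhodopsin("b", t1$sequence)$verdict, "type1")

  call_none <- classify_rhodopsin("c", none$sequence)
  expect_equal(call_none$verdict, "rejected")
  expect_true("no_motif" %in% call_none$reasons[[1]])

  call_six <- classify_rhodopsin("d", six$sequence)
  expect_equal(call_six$verdict, "rejected")
  expect_true("tm_count" %in% call_six$reasons[[1]])

  expect_error(classify_rhodopsin("e", ""), "empty sequence")
})

test_that("an N-out heliorhodopsin keeps its verdict with a conflict flag", {
  p <- generate_protein(motif = "SxxxK", n_terminus_side = "out", seed = 109)
  call <- classify_rhodopsin("p", p$sequence)
  expect_equal(call$verdict, "heliorhodopsin")
  expect_true("orientation_conflict" %in% call$reasons[[1]])
  expect_equal(call$n_terminus_side, "out")
})

test_that("SxxxK takes precedence over a co-occurring DxxxK", {
  p <- generate_protein(motif = "SxxxK", seed = 110)
  topo <- p$topology
  seq <- p$sequence
  # plant a DxxxK right at the start of helix 7, upstream of the SxxxK
  s7 <- topo$segments$start[7]
  substr(seq, s7, s7) <- "D"
  substr(seq, s7 + 4L, s7 + 4L) <- "K"
  call <- classify_rhodopsin("p", seq, topology = topo)
  expect_equal(call$verdict, "heliorhodopsin")
  expect_true("ambiguous_motif" %in% call$reasons[[1]])
})

test_that("cohort screen gives exact recall and is order-invariant", {
  specs <- list(
    list(n_helix = 7, motif = "SxxxK", class = "heliorhodopsin"),
    list(n_helix = 7, motif = "DxxxK", class = "type1"),
    list(n_helix = 7, motif = NULL, class = "rejected"),
    list(n_helix = 6, motif = NULL, class = "rejected")
  )
  prots <- purrr::imap(rep(specs, 3), function(sp, i) {
    p <- generate_protein(n_helix = sp$n_helix, motif = sp$motif,
                          motif_helix = min(7, sp$n_helix), seed = 200 + i)
    tibble::tibble(protein_id = sprintf("p%02d", i), sequence = p$sequence,
                   truth = sp$class)
  }) |>
    purrr::list_rbind()

  calls <- screen_rhodopsins(prots)
  expect_equal(calls$verdict, prots$truth)
  # every input receives exactly one verdict
  expect_equal(nrow(calls), nrow(prots))
  expect_true(all(calls$verdict %in% c("heliorhodopsin", "type1", "rejected")))

  shuf <- prots[rev(seq_len(nrow(prots))), ]
  calls2 <- screen_rhodopsins(shuf)
  expect_equal(calls2$verdict,
               calls$verdict[match(calls2$protein_id, calls$protein_id)])
})

test_that("supplied topology tables are honored over the fallback", {
  p <- generate_protein(motif = "SxxxK", seed = 111)
  tf <- withr::local_tempfile(fileext = ".tsv")
  seg <- p$topology$segments
  readr::write_tsv(tibble::tibble(
    protein_id = "pX", index = seg$index, start = seg$start, end = seg$end,
    n_terminus_side = "in"
  ), tf)
  topo <- read_topology(tf)
  expect_named(topo, "pX")
  call <- screen_rhodopsins(
    tibble::tibble(protein_id = "pX", sequence = p$sequence),
    topologies = topo
  )
  expect_equal(call$verdict, "heliorhodopsin")
})
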