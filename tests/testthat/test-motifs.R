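test_that("consensus compilation fixes the span and rejects bad input", {
  m <- compile_consensus("YEGEWxNGKxHGYG")
  expect_equal(m$span, 14)
  expect_equal(length(m$fixed_pos), 12)
  expect_equal(compile_consensus("CxxC")$span, 4)
  expect_error(compile_consensus(""), "non-empty")
  expect_error(compile_consensus("Cxx9C"), "illegal")
})

test_that("every reported match length equals the compiled span", {
  set.seed(413)
  seqs <- replicate(20, paste(sample(c(LETTERS[1:20], "C", "Y"), 300,
                                     replace = TRUE), collapse = ""))
  for (s in seqs) {
    zn <- find_zinc_ribbon(s)
    if (nrow(zn)) expect_true(all(zn$end - zn$start + 1 == 25))
    mo <- find_morn_repeats(s, max_mismatch = 4)
    if (nrow(mo)) expect_true(all(mo$end - mo$start + 1 == 14))
  }
})

test_that("tandem MORN consensus copies are found non-overlapping", {
  three <- strrep("YEGEWANGKAHGYG", 3)
  hits <- find_morn_repeats(paste0("MSTA", three, "LLV"))
  expect_equal(nrow(hits), 3)
  expect_equal(hits$start, c(5L, 19L, 33L))
  expect_equal(hits$mismatches, rep(0L, 3))

  expect_equal(nrow(find_morn_repeats(strrep("ACDEFGHIKL", 30))), 0)
})

test_that("MORN mismatch budget is honored and counted", {
  one <- "YEGEWANGKAHGYG"
  mut <- sub("^YEGEW", "YAGEW", one)   # one substitution at a fixed position
  expect_equal(nrow(find_morn_repeats(mut)), 0)
  hit <- find_morn_repeats(mut, max_mismatch = 2)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$mismatches, 1L)
})

test_that("exact MORN search equals a naive wildcard-scan oracle", {
  set.seed(414)
  for (i in 1:10) {
    s <- paste(sample(c("Y", "E", "G", "W", "N", "K", "H", "A"), 200,
                      replace = TRUE), collapse = "")
    # plant one exact copy to make matches likely
    pos <- sample(1:180, 1)
    s <- paste0(substr(s, 1, pos - 1), "YEGEWANGKAHGYG",
                substr(s, pos + 14, 200))
    oracle <- naive_consensus_scan(s, "YEGEWxNGKxHGYG")
    got <- scan_consensus(s, compile_consensus("YEGEWxNGKxHGYG"),
                          overlapping = TRUE)$start
    expect_equal(got, oracle)
  }
})

test_that("zinc ribbons need an exact 17-residue spacer", {
  ok <- paste0("MA", "CAAC", strrep("G", 17), "CDDC", "KL")
  hits <- find_zinc_ribbon(ok)
  expect_equal(nrow(hits), 1)
  expect_equal(c(hits$start, hits$end), c(3L, 27L))

  short <- paste0("MA", "CAAC", strrep("G", 16), "CDDC", "KL")
  expect_equal(nrow(find_zinc_ribbon(short)), 0)

  two <- paste0(ok, strrep("A", 5), "CAAC", strrep("G", 17), "CAAC")
  expect_equal(nrow(find_zinc_ribbon(two)), 2)

  # a spacer range accepts near-canonical spacings
  cfg <- her_config(zn_spacer = c(16L, 18L))
  expect_equal(nrow(find_zinc_ribbon(short, config = cfg)), 1)
})

test_that("overlapping zinc-ribbon matches are all reported", {
  # CxxCxxC start gives two interleaved CxxC half-motifs
  s <- paste0("CAACAAC", strrep("G", 14), "CAACAAC")
  hits <- find_zinc_ribbon(s)
  expect_gte(nrow(hits), 2)
  expect_true(any(diff(sort(hits$start)) < 25))
})

test_that("extensions report termini always, loops only when > 50 aa", {
  p <- generate_protein(seed = 415, loop_len = c(80L, 60L, rep(15L, 5), 30L))
  ext <- extract_extensions(p$sequence, p$topology)
  expect_setequal(ext$label, c("ntv", "ECL1", "ctv"))
  expect_equal(ext$length[ext$label == "ntv"], 80L)
  expect_equal(ext$length[ext$label == "ECL1"], 60L)
  expect_equal(ext$length[ext$label == "ctv"], 30L)

  # a loop of exactly 50 aa is not reported (strictly > 50)
  p50 <- generate_protein(seed = 416, loop_len = c(20L, 50L, rep(15L, 5), 15L))
  ext50 <- extract_extensions(p50$sequence, p50$topology)
  expect_false(any(grepl("^ECL|^ICL", ext50$label)))

  # extracted sequences match their coordinates
  for (i in seq_len(nrow(ext))) {
    expect_equal(ext$sequence[i],
                 substr(p$sequence, ext$start[i], ext$end[i]))
  }
})

test_that("loop labels alternate from the N terminus and flip with it", {
  loops <- c(20L, 60L, 60L, 60L, 60L, 60L, 60L, 15L)
  p <- generate_protein(seed = 417, loop_len = loops)
  ext_in <- extract_extensions(p$sequence, p$topology)
  lab_in <- ext_in$label[grepl("CL", ext_in$label)]
  expect_equal(lab_in, c("ECL1", "ICL1", "ECL2", "ICL2", "ECL3", "ICL3"))

  topo_out <- topology_model(p$topology$segments, "out")
  ext_out <- extract_extensions(p$sequence, topo_out)
  lab_out <- ext_out$label[grepl("CL", ext_out$label)]
  expect_equal(lab_out, c("ICL1", "ECL1", "ICL2", "ECL2", "ICL3", "ECL3"))
  # non-loop rows unchanged
  expect_identical(ext_out[!grepl("CL", ext_out$label), ],
                   ext_in[!grepl("CL", ext_in$label), ])

  expect_error(
    extract_extensions(p$sequence,
                       topology_model(p$topology$segments, "unknown")),
    "must be known"
  )
  expect_error(
    extract_extensions(p$sequence,
                       topology_model(p$topology$segments[1:6, ], "in")),
    "7-segment"
  )
})

test_that("extension FASTA uses protein_id|label|start-end headers", {
  p <- generate_protein(seed = 418, loop_len = c(80L, rep(15L, 6), 30L))
  ext <- extract_extensions(p$sequence, p$topology, protein_id = "prX")
  f <- withr::local_tempfile(fileext = ".faa")
  write_extensions_fasta(ext, f)
  lines <- readLines(f)
  expect_equal(lines[1], sprintf(">prX|ntv|1-%d", ext$end[1]))
  expect_equal(lines[2], ext$sequence[1])
})
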