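# small in-code fixtures shared across test files

make_genes <- function(starts, ends, strands = "+", contig = "ctg1",
                       domains = NULL, ids = NULL) {
  n <- length(starts)
  ids <- ids %||% sprintf("g%02d", seq_len(n))
  tibble::tibble(
    gene_id = ids, contig_id = contig,
    start = as.integer(starts), end = as.integer(ends),
    strand = rep_len(strands, n),
    domains = domains %||% rep(list(character(0)), n),
    product = NA_character_
  )
}

# a contig of n equally spaced genes (gap bp apart, len bp long)
make_contig_ann <- function(n = 25, len = 900L, gap = 100L, strands = "+",
                            contig = "ctg1", genome_id = "gnmT",
                            domains = NULL, completeness = 0.95,
                            phylum = NA_character_) {
  starts <- 1L + (seq_len(n) - 1L) * (len + gap)
  genes <- make_genes(starts, starts + len - 1L, strands, contig, domains)
  genome_annotation(genome_id, genes, completeness = completeness,
                    phylum = phylum)
}

# exhaustive combinatorial upper-tail hypergeometric, independent of phyper
hyper_oracle <- function(k, K, n, N) {
  if (k == 0) return(1)
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# naive exact wildcard scan used as an oracle for the motif scanner
naive_consensus_scan <- function(sequence, pattern) {
  res <- strsplit(sequence, "")[[1]]
  pat <- strsplit(pattern, "")[[1]]
  span <- length(pat)
  hits <- integer(0)
  if (length(res) < span) return(hits)
  for (p in seq_len(length(res) - span + 1L)) {
    ok <- TRUE
    for (j in seq_len(span)) {
      if (pat[j] != "x" && res[p + j - 1L] != pat[j]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, p)
  }
  hits
}

`%||%` <- function(a, b) if (is.null(a)) b else a
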