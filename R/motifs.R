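#' Compile a fixed-span consensus pattern
#'
#' Patterns are written with upper-case amino-acid letters at fixed
#' positions and lowercase `x` for any residue, e.g. the 14-residue MORN
#' consensus `"YEGEWxNGKxHGYG"` or the zinc-ribbon half-motif `"CxxC"`.
#'
#' @param pattern_string The pattern.
#' @return A list with class `"consensus_matcher"`: `pattern`, `span`,
#'   `fixed_pos`, `fixed_res`.
#' @export
compile_consensus <- function(pattern_string) {
  if (is.null(pattern_string) || is.na(pattern_string) ||
      !nzchar(pattern_string)) {
    abort("pattern must be a non-empty string")
  }
  chars <- strsplit(pattern_string, "")[[1]]
  ok <- chars %in% c(LETTERS, "x")
  if (!all(ok)) {
    abort(paste0("illegal pattern character(s): ",
                 paste(unique(chars[!ok]), collapse = ", ")))
  }
  fixed <- which(chars != "x")
  structure(list(pattern = pattern_string, span = length(chars),
                 fixed_pos = fixed, fixed_res = chars[fixed]),
            class = "consensus_matcher")
}

#' @export
print.consensus_matcher <- function(x, ...) {
  cat("<consensus_matcher> ", x$pattern, " (span ", x$span, ", ",
      length(x$fixed_pos), " fixed positions)\n", sep = "")
  invisible(x)
}

#' Scan a sequence with a compiled consensus
#'
#' @param sequence Amino-acid sequence.
#' @param matcher A [compile_consensus()] matcher.
#' @param max_mismatch Substitutions allowed at fixed (non-wildcard)
#'   positions.
#' @param overlapping Report all matches (`TRUE`) or greedily take
#'   non-overlapping matches left to right (`FALSE`).
#' @param motif_name Label carried into the result.
#' @param protein_id Optional identifier carried into the result.
#' @return Tibble of matches: `protein_id`, `motif_name`, `start`, `end`,
#'   `matched_seq`, `mismatches`.
#' @export
scan_consensus <- function(sequence, matcher, max_mismatch = 0,
                           overlapping = TRUE, motif_name = matcher$pattern,
                           protein_id = NA_character_) {
  stopifnot(inherits(matcher, "consensus_matcher"))
  res <- strsplit(toupper(sequence), "")[[1]]
  L <- length(res)
  empty <- tibble(protein_id = character(), motif_name = character(),
                  start = integer(), end = integer(),
                  matched_seq = character(), mismatches = integer())
  if (L < matcher$span) return(empty)
  starts <- seq_len(L - matcher$span + 1L)
  mm <- rep(0L, length(starts))
  for (i in seq_along(matcher$fixed_pos)) {
    mm <- mm + (res[starts + matcher$fixed_pos[i] - 1L] !=
                  matcher$fixed_res[i])
  }
  hit <- starts[mm <= max_mismatch]
  if (!length(hit)) return(empty)
  if (!overlapping) {
    keep <- integer(0)
    nxt <- 1L
    for (p in hit) {
      if (p >= nxt) {
        keep <- c(keep, p)
        nxt <- p + matcher$span
      }
    }
    hit <- keep
  }
  tibble(
    protein_id = protein_id, motif_name = motif_name,
    start = as.integer(hit), end = as.integer(hit + matcher$span - 1L),
    matched_seq = map_chr(hit, function(p) {
      paste(res[p:(p + matcher$span - 1L)], collapse = "")
    }),
    mismatches = mm[match(hit, starts)]
  )
}

#' Find MORN repeats
#'
#' Scans for the 14-residue membrane occupation and recognition nexus
#' (MORN) consensus `YEGEWxNGKxHGYG`. Because MORN repeats occur in tandem
#' (typically three abutting copies at the cytoplasmic N terminus of
#' MORN-heliorhodopsin fusions), matches are taken greedily left to right
#' without overlap.
#'
#' @param sequence Amino-acid sequence.
#' @param max_mismatch Substitutions tolerated at fixed positions
#'   (default 0).
#' @param protein_id Optional identifier.
#' @return Tibble of matches (see [scan_consensus()]), `motif_name`
#'   `"MORN"`.
#' @examples
#' find_morn_repeats(strrep("YEGEWANGKAHGYG", 3))
#' @export
find_morn_repeats <- function(sequence, max_mismatch = 0,
                              protein_id = NA_character_) {
  scan_consensus(sequence, compile_consensus("YEGEWxNGKxHGYG"),
                 max_mismatch = max_mismatch, overlapping = FALSE,
                 motif_name = "MORN", protein_id = protein_id)
}

#' Find zinc-ribbon motifs
#'
#' Scans for the metal-coordinating signature of zinc-finger-like N-terminal
#' extensions of heliorhodopsins: CxxC, an exact spacer of
#' `config$zn_spacer` residues (default 17), then CxxC — a 25-residue span
#' at the default spacing. All matches are reported, including overlapping
#' ones, since cysteine spacings can nest. A length-2 `zn_spacer` gives an
#' inclusive spacer range.
#'
#' @param sequence Amino-acid sequence.
#' @param protein_id Optional identifier.
#' @param config A [her_config()].
#' @return Tibble of matches, `motif_name` `"zinc_ribbon"`.
#' @examples
#' find_zinc_ribbon(paste0("MA", "CAAC", strrep("G", 17), "CDDC", "KL"))
#' @export
find_zinc_ribbon <- function(sequence, protein_id = NA_character_,
                             config = her_config()) {
  spacers <- config$zn_spacer
  if (length(spacers) == 2) spacers <- seq(spacers[1], spacers[2])
  map(spacers, function(sp) {
    pat <- paste0("CxxC", strrep("x", sp), "CxxC")
    scan_consensus(sequence, compile_consensus(pat), max_mismatch = 0,
                   overlapping = TRUE, motif_name = "zinc_ribbon",
                   protein_id = protein_id)
  }) |>
    list_rbind() |>
    arrange(.data$start, .data$end)
}

#' Extract terminal extensions and long loops from a 7-TM topology
#'
#' Reports the N-terminal region before TM1 (`ntv`) and the C-terminal
#' region after TM7 (`ctv`) whenever they are non-empty, and every
#' inter-helix loop strictly longer than `config$loop_min_len` residues
#' (default 50). Loop sidedness alternates from the N terminus: with the N
#' terminus inside (the canonical heliorhodopsin orientation), the loop
#' after TM1 is extracellular (`ECL1`), after TM2 intracellular (`ICL1`),
#' and so on through `ECL3`/`ICL3`.
#'
#' @param sequence Amino-acid sequence.
#' @param topology A [topology_model()] with exactly 7 segments and a known
#'   `n_terminus_side`.
#' @param config A [her_config()].
#' @param protein_id Optional identifier (defaults to the topology's).
#' @return Tibble: `protein_id`, `label`, `start`, `end`, `length`,
#'   `sequence`.
#' @export
extract_extensions <- function(sequence, topology, config = her_config(),
                               protein_id = NULL) {
  stopifnot(inherits(topology, "topology_model"))
  if (nrow(topology$segments) != 7) {
    abort("extension extraction requires a 7-segment topology")
  }
  if (!topology$n_terminus_side %in% c("in", "out")) {
    abort("n_terminus_side must be known ('in' or 'out')")
  }
  protein_id <- protein_id %||% topology$protein_id
  res <- strsplit(sequence, "")[[1]]
  L <- length(res)
  seg <- topology$segments
  regions <- list()

  grab <- function(label, s, e) {
    tibble(protein_id = protein_id, label = label,
           start = as.integer(s), end = as.integer(e),
           length = as.integer(e - s + 1L),
           sequence = paste(res[s:e], collapse = ""))
  }

  if (seg$start[1] > 1) {
    regions <- c(regions, list(grab("ntv", 1L, seg$start[1] - 1L)))
  }
  # loop i sits between TM i and TM i+1; sidedness alternates from the
  # N terminus: N-in makes loop 1 extracellular
  ecl_first <- topology$n_terminus_side == "in"
  for (i in 1:6) {
    s <- seg$end[i] + 1L
    e <- seg$start[i + 1] - 1L
    len <- e - s + 1L
    if (len > config$loop_min_len) {
      outside <- xor(i %% 2 == 0, ecl_first)
      label <- paste0(if (outside) "ECL" else "ICL", ceiling(i / 2))
      regions <- c(regions, list(grab(label, s, e)))
    }
  }
  if (seg$end[7] < L) {
    regions <- c(regions, list(grab("ctv", seg$end[7] + 1L, L)))
  }
  if (!length(regions)) {
    return(tibble(protein_id = character(), label = character(),
                  start = integer(), end = integer(), length = integer(),
                  sequence = character()))
  }
  list_rbind(regions)
}

#' Write extension regions as FASTA for external clustering
#'
#' Records are named `protein_id|label|start-end`.
#'
#' @param extensions Tibble from [extract_extensions()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_extensions_fasta <- function(extensions, path) {
  hdr <- sprintf(">%s|%s|%d-%d", extensions$protein_id, extensions$label,
                 extensions$start, extensions$end)
  writeLines(paste0(hdr, "\n", extensions$sequence), path)
  invisible(path)
}
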