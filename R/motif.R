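# Condensation-domain histidine motifs.
#
# All condensation domains carry a catalytic primary motif HHxxxDG; in dual
# epimerization/condensation (E/C) domains the final glycine is replaced,
# usually by a histidine (less often alanine or asparagine), giving
# HHxxxDH/A/N. E/C domains additionally show a secondary histidine motif
# HH[I/L]xxxxGD near the N-terminus, occasionally stretched by a single
# inserted residue (histidine or proline) inside the wildcard block. In
# entolysin producers the residue immediately in front of the secondary
# motif of the module-14 domain is an extra histidine where other E/C
# domains keep a conserved leucine - the sequence feature that tracks the
# domain's intermittent epimerization activity.

#' Read condensation-domain protein sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readAAStringSet()]: record ids are the
#' first whitespace-delimited token of each header and must be unique,
#' sequences are uppercased, and records that contain letters outside the
#' 20-residue alphabet, or that look like nucleotide sequences, are flagged
#' with a warning.
#'
#' @param path FASTA file of pre-excised C-domain sequences.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_domains <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such FASTA: '%s'", path))
  set <- Biostrings::readAAStringSet(path)
  if (!length(set)) abort(sprintf("'%s': no FASTA records", path))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  dup <- ids[duplicated(ids)]
  if (length(dup)) abort(sprintf("duplicate FASTA id: '%s'", dup[1]))
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) abort(sprintf("'%s': empty FASTA record", path))
  letters_used <- unique(unlist(strsplit(seqs, "")))
  nonstd <- setdiff(letters_used, aa_alphabet())
  if (length(nonstd)) {
    warn(sprintf("non-standard letters in '%s': %s",
                 path, paste(nonstd, collapse = ", ")))
  }
  nuc_like <- vapply(strsplit(seqs, ""), function(ch) {
    all(ch %in% c("A", "C", "G", "T", "U", "N"))
  }, logical(1))
  if (any(nuc_like)) {
    warn(sprintf("record(s) %s look like nucleotide sequences",
                 paste(ids[nuc_like], collapse = ", ")))
  }
  tibble(id = ids, sequence = unname(seqs))
}

#' Classify a C-domain by its primary histidine motif
#'
#' Scans for `H-H-x-x-x-D-[G|H|A|N]`. A final `G` marks a condensation-only
#' LCL domain; `H`, `A` or `N` marks a dual E/C domain. When the motif is
#' absent the domain is `UNCLASSIFIED`; when it occurs more than once the
#' leftmost full match is kept.
#'
#' @param sequence A single protein sequence string.
#' @return A one-row tibble with columns `classification` (`"LCL"`, `"EC"`
#'   or `"UNCLASSIFIED"`), `start`, `end` (1-based, inclusive) and `motif`.
#' @export
#' @examples
#' classify_primary_motif("AAAHHILQDGAAA")  # LCL
#' classify_primary_motif("AAAHHAMQDHAAA")  # EC
classify_primary_motif <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  sequence <- toupper(sequence)
  hit <- regexpr("HH...D[GHAN]", sequence)
  if (hit == -1L) {
    return(tibble(classification = "UNCLASSIFIED",
                  start = NA_integer_, end = NA_integer_,
                  motif = NA_character_))
  }
  start <- as.integer(hit)
  end <- start + 6L
  motif <- substr(sequence, start, end)
  final <- substr(motif, 7L, 7L)
  tibble(classification = if (final == "G") "LCL" else "EC",
         start = start, end = end, motif = motif)
}

#' Locate the N-terminal secondary histidine motif of E/C domains
#'
#' Searches the first `nterm_window` residues for the consensus
#' `H-H-[I/L]-x-x-x-x-G-D`, tolerating at most one inserted residue inside
#' the wildcard block (matched span of 10 instead of 9). Candidate windows
#' are scored by the number of satisfied constrained positions (the two
#' histidines, the I/L, the G and the D; maximum 5) and a hit must match all
#' but at most one of them. Ranking is score first, then insertion-free
#' spans, then leftmost. Coordinates are 1-based and inclusive.
#'
#' The residue immediately preceding the matched span is recorded as
#' `flank_residue` (conserved leucine in typical E/C domains, an extra
#' histidine in the atypical entolysin module-14 domains); for an inserted
#' span the apparent inserted residue is reported as `insertion_offset`, the
#' position within the span of the leftmost histidine - or, failing that,
#' proline - in the wildcard block, these being the residues observed as
#' insertions.
#'
#' @param sequence A single protein sequence string.
#' @param nterm_window How many N-terminal residues count as "close to the
#'   N-terminus"; the motif must start inside this window.
#' @param min_score Minimum number of matched constrained positions
#'   (default 4 = all but one).
#' @return A one-row tibble with columns `start`, `end`, `matched_span`,
#'   `score`, `insertion`, `insertion_offset` and `flank_residue`, or a
#'   zero-row tibble when no acceptable hit exists.
#' @export
#' @examples
#' scan_secondary_motif("MKHHIAAAAGDWWWW")
scan_secondary_motif <- function(sequence, nterm_window = 120, min_score = 4) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  s <- strsplit(toupper(sequence), "")[[1]]
  len <- length(s)
  empty <- tibble(start = integer(0), end = integer(0),
                  matched_span = character(0), score = integer(0),
                  insertion = logical(0), insertion_offset = integer(0),
                  flank_residue = character(0))

  score_at <- function(starts, span) {
    # constrained positions: 1 = H, 2 = H, 3 = I/L, span-1 = G, span = D
    (s[starts] == "H") +
      (s[starts + 1L] == "H") +
      (s[starts + 2L] %in% c("I", "L")) +
      (s[starts + span - 2L] == "G") +
      (s[starts + span - 1L] == "D")
  }

  cand <- list()
  for (span in c(9L, 10L)) {
    starts <- seq_len(max(0L, min(nterm_window, len - span + 1L)))
    if (!length(starts)) next
    cand[[length(cand) + 1L]] <- tibble(
      start = starts,
      span = span,
      score = as.integer(score_at(starts, span))
    )
  }
  if (!length(cand)) return(empty)
  cand <- dplyr::bind_rows(cand)
  cand <- cand[cand$score >= min_score, ]
  if (!nrow(cand)) return(empty)
  cand <- cand[order(-cand$score, cand$span, cand$start), ]
  best <- cand[1, ]

  start <- best$start
  end <- start + best$span - 1L
  span_chars <- s[start:end]
  insertion <- best$span == 10L
  insertion_offset <- NA_integer_
  if (insertion) {
    block <- span_chars[4:8]  # wildcard block of the stretched span
    hpos <- which(block == "H")
    ppos <- which(block == "P")
    if (length(hpos)) insertion_offset <- 3L + hpos[1]
    else if (length(ppos)) insertion_offset <- 3L + ppos[1]
  }
  tibble(start = start, end = end,
         matched_span = paste(span_chars, collapse = ""),
         score = best$score,
         insertion = insertion,
         insertion_offset = insertion_offset,
         flank_residue = if (start > 1L) s[start - 1L] else NA_character_)
}

#' Flag an atypical histidine flank on a secondary-motif hit
#'
#' Typical *Pseudomonas* E/C domains carry a conserved leucine immediately
#' before the secondary histidine motif; the intermittently epi-active
#' entolysin module-14 domains carry an extra histidine there instead.
#'
#' @param hit A one-row hit from [scan_secondary_motif()].
#' @return A one-row tibble with columns `flank_residue`, `atypical`
#'   (logical: flank is histidine) and `flank_class` (`"typical"`,
#'   `"atypical"` or `"other:<residue>"`).
#' @export
flag_atypical_flank <- function(hit) {
  if (!is.data.frame(hit) || nrow(hit) != 1L ||
      !"flank_residue" %in% names(hit)) {
    abort("flag_atypical_flank() needs a single secondary-motif hit")
  }
  f <- hit$flank_residue
  flank_class <- if (is.na(f)) {
    "other:NA"
  } else if (f == "H") {
    "atypical"
  } else if (f == "L") {
    "typical"
  } else {
    paste0("other:", f)
  }
  tibble(flank_residue = f,
         atypical = !is.na(f) && f == "H",
         flank_class = flank_class)
}

#' Scan a table of C-domain sequences
#'
#' Runs [classify_primary_motif()], [scan_secondary_motif()] and
#' [flag_atypical_flank()] over every domain and assembles the per-domain
#' report the package writes for downstream tools.
#'
#' @param domains A tibble with columns `id` and `sequence`, e.g. from
#'   [read_domains()].
#' @param nterm_window Passed to [scan_secondary_motif()].
#' @return A tibble with one row per domain: `id`, `classification`,
#'   `primary_start`, `secondary_start`, `secondary_end`, `insertion`,
#'   `insertion_offset`, `flank_residue`, `atypical_flank`.
#' @export
scan_domains <- function(domains, nterm_window = 120) {
  domains <- tibble::as_tibble(domains)
  stopifnot(all(c("id", "sequence") %in% names(domains)))
  purrr::map_dfr(seq_len(nrow(domains)), function(i) {
    prim <- classify_primary_motif(domains$sequence[i])
    sec <- scan_secondary_motif(domains$sequence[i], nterm_window)
    has_sec <- nrow(sec) == 1L
    tibble(
      id = domains$id[i],
      classification = prim$classification,
      primary_start = prim$start,
      secondary_start = if (has_sec) sec$start else NA_integer_,
      secondary_end = if (has_sec) sec$end else NA_integer_,
      insertion = if (has_sec) sec$insertion else NA,
      insertion_offset = if (has_sec) sec$insertion_offset else NA_integer_,
      flank_residue = if (has_sec) sec$flank_residue else NA_character_,
      atypical_flank = if (has_sec) flag_atypical_flank(sec)$atypical else NA
    )
  })
}

#' Position frequency matrix and information content
#'
#' Builds the per-column residue frequencies of a set of equal-length,
#' pre-aligned windows together with the per-column information content
#' `IC = log2(20) - H` (Shannon entropy against a uniform 1/20 background),
#' the quantity that scales letter heights in a sequence logo.
#'
#' @param windows Character vector of equal-length amino-acid windows.
#' @return An object of class `pfm`: a list with `freq` (20 x L matrix,
#'   columns summing to 1), `ic` (length-L vector in bits) and
#'   `n_sequences`.
#' @export
#' @examples
#' pfm <- build_pfm(c("HHLAQ", "HHIAQ", "HHLSQ"))
#' pfm$ic
build_pfm <- function(windows) {
  windows <- toupper(as.character(windows))
  if (!length(windows)) abort("build_pfm() needs at least one window")
  width <- unique(nchar(windows))
  if (length(width) != 1L) abort("all windows must have equal length")
  if (width == 0L) abort("windows must be nonempty")
  chars <- do.call(rbind, strsplit(windows, ""))
  bad <- setdiff(unique(as.vector(chars)), aa_alphabet())
  if (length(bad)) {
    abort(sprintf("letters outside the amino-acid alphabet: %s",
                  paste(bad, collapse = ", ")))
  }
  freq <- vapply(seq_len(width), function(j) {
    tabulate(factor(chars[, j], levels = aa_alphabet()),
             nbins = 20L) / nrow(chars)
  }, numeric(20))
  freq <- matrix(freq, nrow = 20L,
                 dimnames = list(aa_alphabet(), seq_len(width)))
  ic <- apply(freq, 2, function(p) {
    p <- p[p > 0]
    log2(20) + sum(p * log2(p))
  })
  structure(list(freq = freq, ic = unname(ic), n_sequences = length(windows)),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm> %d columns from %d sequence(s)\n",
              ncol(x$freq), x$n_sequences))
  cat("information content (bits):",
      paste(sprintf("%.2f", x$ic), collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.pfm <- function(x, ...) {
  tibble(
    position = rep(seq_len(ncol(x$freq)), each = nrow(x$freq)),
    residue = rep(rownames(x$freq), times = ncol(x$freq)),
    freq = as.vector(x$freq),
    ic = rep(x$ic, each = nrow(x$freq))
  )
}
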