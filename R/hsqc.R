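# HSQC CH-alpha fingerprint matching.
#
# Two lipopeptides with identical covalent structure *and* identical
# configuration at every stereocenter show near-identical (1H, 13C)
# cross-peak patterns for their alpha positions; a single D/L switch
# displaces the peaks around the switched residue. Matching two peak lists
# therefore dereplicates a compound without any resonance assignment:
# pair the peaks one-to-one at minimal total combined-shift distance and
# compare the worst pair against a threshold.

#' Build a CH-alpha peak list
#'
#' @param peaks Data frame with numeric columns `delta_h` and `delta_c`
#'   (ppm) and an optional `label` column (e.g. `"Ser13"`).
#' @param solvent,field,temperature Optional free-text acquisition metadata.
#' @return A tibble of class `peak_list` with columns `label`, `delta_h`,
#'   `delta_c`.
#' @export
peak_list <- function(peaks, solvent = NA_character_, field = NA_character_,
                      temperature = NA_character_) {
  peaks <- tibble::as_tibble(peaks)
  if (!all(c("delta_h", "delta_c") %in% names(peaks))) {
    abort("a peak list needs columns 'delta_h' and 'delta_c'")
  }
  if (!"label" %in% names(peaks)) peaks$label <- NA_character_
  peaks <- peaks[c("label", "delta_h", "delta_c")]
  peaks$label <- as.character(peaks$label)
  peaks$delta_h <- as.numeric(peaks$delta_h)
  peaks$delta_c <- as.numeric(peaks$delta_c)
  if (nrow(peaks) < 1L) abort("a peak list needs at least one peak")
  if (!all(is.finite(peaks$delta_h)) || !all(is.finite(peaks$delta_c))) {
    abort("chemical shifts must be finite numbers")
  }
  if (anyDuplicated(peaks[c("delta_h", "delta_c")])) {
    abort("two peaks coincide in both coordinates")
  }
  structure(peaks,
            class = c("peak_list", class(tibble::tibble())),
            meta = list(solvent = solvent, field = field,
                        temperature = temperature))
}

#' Read a peak list from a tabular file
#'
#' Accepts CSV or TSV with header columns `delta_h`, `delta_c` and optional
#' `label` (column order is irrelevant), as well as a Sparky-style export
#' with columns `Assignment`, `w1`, `w2` (`w1` = 13C, `w2` = 1H, the usual
#' heteronuclear convention). Duplicate rows are collapsed with a warning.
#'
#' @param path File path; the delimiter is taken from the extension
#'   (`.csv` = comma, otherwise tab).
#' @return A [peak_list()].
#' @export
read_peaklist <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such peak list: '%s'", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  if (nrow(tbl) == 0L) abort(sprintf("'%s': empty peak list", path))
  nm <- tolower(names(tbl))
  if (all(c("delta_h", "delta_c") %in% nm)) {
    names(tbl) <- nm
  } else if (all(c("assignment", "w1", "w2") %in% nm)) {
    names(tbl) <- nm
    tbl <- tibble(label = tbl$assignment, delta_c = tbl$w1, delta_h = tbl$w2)
  } else {
    abort(sprintf("'%s': need columns delta_h/delta_c (or Sparky Assignment/w1/w2)",
                  path))
  }
  suppressWarnings({
    tbl$delta_h <- as.numeric(tbl$delta_h)
    tbl$delta_c <- as.numeric(tbl$delta_c)
  })
  if (anyNA(tbl$delta_h) || anyNA(tbl$delta_c)) {
    abort(sprintf("'%s': non-numeric chemical shifts", path))
  }
  dedup <- dplyr::distinct(tbl)
  if (nrow(dedup) < nrow(tbl)) {
    warn(sprintf("'%s': collapsed %d duplicate peak row(s)",
                 path, nrow(tbl) - nrow(dedup)))
  }
  peak_list(dedup)
}

#' Write a peak list to CSV/TSV
#'
#' @param peaks A [peak_list()].
#' @param path Output path (`.csv` = comma-separated, otherwise tab).
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_list"))
  tbl <- tibble::new_tibble(as.list(peaks), nrow = nrow(peaks))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(tbl, path)
  } else {
    readr::write_tsv(tbl, path)
  }
  invisible(path)
}

#' Combined 1H/13C chemical-shift distance
#'
#' The weighted Euclidean distance
#' \eqn{\sqrt{\Delta\delta_H^2 + (\Delta\delta_C / w)^2}}
#' in the style of chemical-shift perturbation analysis: carbon shifts are
#' scaled down by `carbon_weight` (default 10) so that both nuclei
#' contribute on a common, 1H-equivalent ppm scale.
#'
#' @param a,b Data frames with columns `delta_h` and `delta_c` (recycled
#'   row-wise against each other).
#' @param carbon_weight Positive carbon scale factor.
#' @return A numeric vector of nonnegative distances; zero only when both
#'   coordinates coincide.
#' @export
#' @examples
#' combined_distance(data.frame(delta_h = 4.00, delta_c = 55.0),
#'                   data.frame(delta_h = 4.03, delta_c = 55.4))  # 0.05
combined_distance <- function(a, b, carbon_weight = 10) {
  if (!is.numeric(carbon_weight) || length(carbon_weight) != 1L ||
      !is.finite(carbon_weight) || carbon_weight <= 0) {
    abort("carbon_weight must be a single positive number")
  }
  dh <- a$delta_h - b$delta_h
  dc <- (a$delta_c - b$delta_c) / carbon_weight
  sqrt(dh^2 + dc^2)
}

#' Optimally pair the peaks of two fingerprints
#'
#' Finds the one-to-one pairing of `min(|ref|, |query|)` peak pairs that
#' minimizes the total combined-shift distance (a global linear-assignment
#' optimum, not a greedy nearest-neighbour match, since near-degenerate
#' CH-alpha regions make greedy pairing order-dependent). Surplus peaks of
#' the longer list are reported unpaired. Labels, when present, are carried
#' through but never used to force the pairing, so matching works on
#' unassigned spectra.
#'
#' @param ref,query [peak_list()]s (or data frames coercible to one).
#' @param carbon_weight Carbon scale factor for [combined_distance()].
#' @return An object of class `hsqc_match`: a list with elements `pairs`
#'   (tibble sorted by distance, largest first), `unpaired_ref`,
#'   `unpaired_query`, `total_distance`, `max_distance`, `carbon_weight`,
#'   and (once [classify_match()] has run) `verdict` and `threshold`.
#' @export
pair_peaks <- function(ref, query, carbon_weight = 10) {
  if (!inherits(ref, "peak_list")) ref <- peak_list(ref)
  if (!inherits(query, "peak_list")) query <- peak_list(query)
  n_r <- nrow(ref)
  n_q <- nrow(query)
  n <- max(n_r, n_q)

  dh <- outer(ref$delta_h, query$delta_h, "-")
  dc <- outer(ref$delta_c, query$delta_c, "-") / carbon_weight
  cost <- matrix(0, n, n)  # dummy rows/cols absorb surplus peaks at no cost
  cost[seq_len(n_r), seq_len(n_q)] <- sqrt(dh^2 + dc^2)
  if (!is.numeric(carbon_weight) || carbon_weight <= 0) {
    abort("carbon_weight must be a single positive number")
  }
  sol <- solve_assignment(cost)

  ri <- seq_len(n_r)
  qi <- sol[ri]
  paired <- qi <= n_q
  pairs <- tibble(
    ref_peak = ri[paired],
    query_peak = qi[paired],
    label = dplyr::coalesce(ref$label[ri[paired]], query$label[qi[paired]],
                            paste0("peak", ri[paired])),
    delta_h_ref = ref$delta_h[ri[paired]],
    delta_c_ref = ref$delta_c[ri[paired]],
    delta_h_query = query$delta_h[qi[paired]],
    delta_c_query = query$delta_c[qi[paired]]
  )
  pairs$distance <- sqrt((pairs$delta_h_ref - pairs$delta_h_query)^2 +
                           ((pairs$delta_c_ref - pairs$delta_c_query) /
                              carbon_weight)^2)
  # deterministic report order: worst pair first, ties broken on the
  # reference coordinates so row shuffling upstream changes nothing
  ord <- order(-pairs$distance, pairs$delta_h_ref, pairs$delta_c_ref)
  pairs <- pairs[ord, ]

  structure(list(
    pairs = pairs,
    unpaired_ref = ref[!seq_len(n_r) %in% pairs$ref_peak, , drop = FALSE],
    unpaired_query = query[!seq_len(n_q) %in% pairs$query_peak, , drop = FALSE],
    total_distance = sum(pairs$distance),
    max_distance = max(pairs$distance),
    carbon_weight = carbon_weight,
    verdict = NA_character_,
    threshold = NA_real_
  ), class = "hsqc_match")
}

#' Turn a peak pairing into a match verdict
#'
#' `MATCH` requires equal peak counts (no unpaired peaks on either side) and
#' a worst per-pair combined distance no larger than `threshold`; anything
#' else is a `MISMATCH`. The default threshold of 0.03 combined-shift units
#' (about 0.03 ppm 1H-equivalent) sits well above replicate measurement
#' noise and well below the displacement caused by a D/L switch.
#'
#' @param match An `hsqc_match` from [pair_peaks()].
#' @param threshold Verdict threshold in combined-shift units.
#' @return The `hsqc_match` with `verdict` and `threshold` filled in.
#' @export
classify_match <- function(match, threshold = 0.03) {
  stopifnot(inherits(match, "hsqc_match"))
  if (!is.numeric(threshold) || threshold <= 0) {
    abort("threshold must be a single positive number")
  }
  equal_counts <- nrow(match$unpaired_ref) == 0L &&
    nrow(match$unpaired_query) == 0L
  match$verdict <- if (equal_counts && match$max_distance <= threshold) {
    "MATCH"
  } else {
    "MISMATCH"
  }
  match$threshold <- threshold
  match
}

#' Pair two fingerprints and classify in one call
#'
#' @inheritParams pair_peaks
#' @inheritParams classify_match
#' @return A classified `hsqc_match`.
#' @export
#' @examples
#' a <- peak_list(data.frame(delta_h = c(4.1, 4.5), delta_c = c(52, 58)))
#' glance(match_peaklists(a, a))
match_peaklists <- function(ref, query, carbon_weight = 10, threshold = 0.03) {
  classify_match(pair_peaks(ref, query, carbon_weight), threshold)
}

#' Per-residue differences, largest first
#'
#' Ranks the paired peaks by combined-shift distance (descending; ties are
#' broken on ascending reference 1H shift), surfacing the residues most
#' affected by a configurational difference.
#'
#' @param match An `hsqc_match`.
#' @return A tibble with columns `label` and `distance`.
#' @export
rank_residue_differences <- function(match) {
  stopifnot(inherits(match, "hsqc_match"))
  tibble(label = match$pairs$label, distance = match$pairs$distance)
}

#' @export
print.hsqc_match <- function(x, ...) {
  cat(sprintf("<hsqc_match> %d pair(s), %d + %d unpaired\n",
              nrow(x$pairs), nrow(x$unpaired_ref), nrow(x$unpaired_query)))
  cat(sprintf("total %.4f, max %.4f (carbon weight %g)\n",
              x$total_distance, x$max_distance, x$carbon_weight))
  if (!is.na(x$verdict)) {
    cat(sprintf("verdict: %s (threshold %g)\n", x$verdict, x$threshold))
  }
  print(head(x$pairs, 5), ...)
  invisible(x)
}

#' @export
tidy.hsqc_match <- function(x, ...) {
  x$pairs
}

#' @export
glance.hsqc_match <- function(x, ...) {
  tibble(
    verdict = x$verdict,
    threshold = x$threshold,
    n_pairs = nrow(x$pairs),
    n_unpaired = nrow(x$unpaired_ref) + nrow(x$unpaired_query),
    total_distance = x$total_distance,
    max_distance = x$max_distance,
    carbon_weight = x$carbon_weight
  )
}
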