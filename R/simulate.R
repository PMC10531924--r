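# Ground-truthed simulators for every pipeline stage.
#
# The generator emulates the mechanism behind diastereomeric CLiP pairs: an
# NRPS assembly line whose E/C domains are active, inactive or (for at most
# one domain) intermittently active. An intermittent domain yields two
# products that differ only at the residue it acts on, drawn at a fixed
# major:minor ratio, the major form carrying the unepimerized L residue.
# Downstream simulators derive exact Marfey's counts, CH-alpha peak lists
# with a localized D/L-switch perturbation plus Gaussian measurement noise,
# and C-domain sequences with planted histidine motifs.

SIM_RESIDUES <- c("Leu", "Ile", "Val", "Ser", "Thr", "Ala", "Gly", "Pro",
                  "Phe", "Glu", "Gln", "Asp", "Asn", "Lys")

#' Simulation settings
#'
#' One object collects every tunable of the generators. The defaults encode
#' the study conditions the package is validated under: a 14-module
#' entolysin-sized assembly line, a 3:2 major:minor product ratio,
#' replicate-level shift noise of 0.005 ppm (1H) / 0.05 ppm (13C), and a
#' D/L-switch perturbation of 0.12 ppm (1H; 10x that for 13C) decaying
#' linearly to zero over 2 residues.
#'
#' @param seed Integer master seed; all streams derive from it via
#'   [split_seed()].
#' @param n_modules Number of NRPS modules (= residues).
#' @param p_ec Probability that a non-initial C-domain is a dual E/C domain
#'   (otherwise LCL).
#' @param p_inactive Per-E/C probability of being epi-inactive.
#' @param p_intermittent Probability that the system contains one
#'   intermittently active E/C domain (chosen uniformly among its E/C
#'   domains), the configuration-heterogeneity mechanism.
#' @param major_minor_ratio Integer pair, relative abundance of the two
#'   products of an intermittent system.
#' @param noise_sigma_h,noise_sigma_c Per-peak Gaussian measurement noise,
#'   ppm.
#' @param switch_perturbation_h 1H displacement (ppm) at a D/L-switched
#'   position; the 13C displacement is 10x larger so both nuclei move
#'   comparably on the combined scale.
#' @param decay_span Residue distance over which the switch perturbation
#'   decays linearly to zero.
#' @param mutation_rate Per-residue point-mutation probability outside
#'   constrained motif positions in [simulate_domains()].
#' @param insertion_prob Probability of a single His/Pro insertion inside
#'   the secondary motif's wildcard block.
#' @param domain_length Length of simulated C-domain sequences.
#' @param nterm_window N-terminal window in which the secondary motif is
#'   planted.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_modules = 14L,
                       p_ec = 0.75,
                       p_inactive = 0.1,
                       p_intermittent = 0.15,
                       major_minor_ratio = c(3L, 2L),
                       noise_sigma_h = 0.005,
                       noise_sigma_c = 0.05,
                       switch_perturbation_h = 0.12,
                       decay_span = 2L,
                       mutation_rate = 0,
                       insertion_prob = 0.2,
                       domain_length = 300L,
                       nterm_window = 120L) {
  probs <- c(p_ec = p_ec, p_inactive = p_inactive,
             p_intermittent = p_intermittent, mutation_rate = mutation_rate,
             insertion_prob = insertion_prob)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (n_modules < 1L) abort("n_modules must be >= 1")
  if (length(major_minor_ratio) != 2L || any(major_minor_ratio < 1)) {
    abort("major_minor_ratio must be two positive integers")
  }
  if (noise_sigma_h < 0 || noise_sigma_c < 0) abort("noise sigmas must be >= 0")
  if (switch_perturbation_h < 0) abort("switch_perturbation_h must be >= 0")
  if (decay_span < 1L) abort("decay_span must be >= 1")
  if (domain_length < nterm_window + 30L) {
    abort("domain_length must exceed nterm_window + 30 to fit both motifs")
  }
  structure(list(
    seed = as.integer(seed), n_modules = as.integer(n_modules),
    p_ec = p_ec, p_inactive = p_inactive, p_intermittent = p_intermittent,
    major_minor_ratio = as.integer(major_minor_ratio),
    noise_sigma_h = noise_sigma_h, noise_sigma_c = noise_sigma_c,
    switch_perturbation_h = switch_perturbation_h,
    decay_span = as.integer(decay_span),
    mutation_rate = mutation_rate, insertion_prob = insertion_prob,
    domain_length = as.integer(domain_length),
    nterm_window = as.integer(nterm_window)
  ), class = "sim_config")
}

config_from_labels <- function(cdomain, labels, minor = FALSE) {
  n <- length(cdomain)
  conf <- character(n)
  for (i in seq_len(n - 1L)) {
    if (cdomain[i + 1L] == "LCL") {
      conf[i] <- "L"
    } else {
      conf[i] <- switch(labels[i + 1L],
                        ACTIVE = "D",
                        INACTIVE = "L",
                        INTERMITTENT = if (minor) "D" else "L",
                        "L")
    }
  }
  conf[n] <- "L"
  paste(conf, collapse = "")
}

#' Simulate an NRPS system and its ground-truth product(s)
#'
#' Draws residues, C-domain types and true epimerization activities, then
#' applies the configuration rules to obtain the product assignment(s). When
#' one E/C domain is intermittently active the system yields two products
#' differing only at the position that domain acts on (the module index
#' minus one); the major product carries the unepimerized L form there, as
#' observed for the entolysin A/B pair.
#'
#' The `system` element carries `UNKNOWN` activity labels, mimicking what an
#' annotator sees; the true labels live in `true_labels` and can be attached
#' with [apply_epi_labels()] when playing the role of a homology prior.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `clip_ground_truth`: a list with `system`
#'   ([nrps_system()]), `products` (tibble: `product`, `config`,
#'   `abundance`), `true_labels`, `switch_position` (NA when there is a
#'   single product) and `cfg`.
#' @export
#' @examples
#' gt <- simulate_system(sim_config(seed = 7))
#' gt$products
simulate_system <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(split_seed(cfg$seed, "system"))
  n <- cfg$n_modules
  residues <- sample(SIM_RESIDUES, n, replace = TRUE)
  cdomain <- c("CSTART",
               ifelse(runif(max(0L, n - 1L)) < cfg$p_ec, "EC", "LCL"))
  labels <- rep(NA_character_, n)
  ec <- which(cdomain == "EC")
  labels[ec] <- ifelse(runif(length(ec)) < cfg$p_inactive, "INACTIVE", "ACTIVE")
  switch_module <- NA_integer_
  if (length(ec) && runif(1) < cfg$p_intermittent) {
    switch_module <- ec[sample.int(length(ec), 1L)]
    labels[switch_module] <- "INTERMITTENT"
  }
  macrocycle <- sample.int(n, 1L)

  system <- nrps_system(
    tibble(index = seq_len(n), residue = residues, cdomain = cdomain,
           epi_label = ifelse(cdomain == "EC", "UNKNOWN", NA_character_)),
    macrocycle_size = macrocycle,
    name = sprintf("sim-%d", cfg$seed))

  major <- config_from_labels(cdomain, labels, minor = FALSE)
  ratio <- cfg$major_minor_ratio
  if (!is.na(switch_module)) {
    minor <- config_from_labels(cdomain, labels, minor = TRUE)
    products <- tibble(product = c("major", "minor"),
                       config = c(major, minor),
                       abundance = ratio / sum(ratio))
    switch_position <- switch_module - 1L
  } else {
    products <- tibble(product = "major", config = major, abundance = 1)
    switch_position <- NA_integer_
  }

  structure(list(
    system = system,
    products = products,
    true_labels = tibble(index = ec, epi_label = labels[ec]),
    switch_position = switch_position,
    cfg = cfg
  ), class = "clip_ground_truth")
}

#' @export
print.clip_ground_truth <- function(x, ...) {
  cat(sprintf("<clip_ground_truth> %d modules, %d product(s)",
              nrow(x$system), nrow(x$products)))
  if (!is.na(x$switch_position)) {
    cat(sprintf(", D/L switch at position %d", x$switch_position))
  }
  cat("\n")
  print(x$products, ...)
  invisible(x)
}

#' Per-position assignment table for one product
#'
#' @param x A `clip_ground_truth` or a character residue vector.
#' @param which `"major"` or `"minor"` (for a ground truth).
#' @param config D/L string (when `x` is a residue vector).
#' @return A tibble with columns `position`, `residue`, `configuration`,
#'   of class `stereo_assignment`.
#' @export
stereo_assignment <- function(x, config) {
  residues <- as.character(x)
  letters_ <- strsplit(toupper(config), "")[[1]]
  if (length(letters_) != length(residues)) {
    abort("config string and residue sequence differ in length")
  }
  if (!all(letters_ %in% c("D", "L"))) {
    abort("config may only contain letters D and L")
  }
  structure(tibble(position = seq_along(residues), residue = residues,
                   configuration = letters_),
            class = c("stereo_assignment", class(tibble::tibble())))
}

#' @rdname stereo_assignment
#' @export
product_assignment <- function(x, which = c("major", "minor")) {
  stopifnot(inherits(x, "clip_ground_truth"))
  which <- match.arg(which)
  row <- match(which, x$products$product)
  if (is.na(row)) abort(sprintf("this ground truth has no '%s' product", which))
  stereo_assignment(x$system$residue, x$products$config[row])
}

#' Exact Marfey's composition of simulated product(s)
#'
#' Tallies per-class D/L counts after pooling. The default mode is
#' error-free (Marfey's counting is treated as exact); `swap_error`
#' optionally moves one randomly chosen count from D to L (or back) to
#' exercise infeasibility reporting downstream.
#'
#' @param x A `clip_ground_truth` (returns a named list of compositions,
#'   one per product) or a [stereo_assignment()] (returns one composition).
#' @param pooling See [marfeys_pooling()].
#' @param swap_error Introduce one count-swap error?
#' @param seed Seed for the error draw.
#' @return Composition tibble(s) with columns `residue_class`, `n_D`, `n_L`.
#' @export
simulate_marfeys <- function(x, pooling = marfeys_pooling(),
                             swap_error = FALSE, seed = 1L) {
  if (inherits(x, "clip_ground_truth")) {
    out <- lapply(seq_len(nrow(x$products)), function(i) {
      simulate_marfeys(stereo_assignment(x$system$residue,
                                         x$products$config[i]),
                       pooling, swap_error, seed)
    })
    names(out) <- x$products$product
    return(out)
  }
  stopifnot(inherits(x, "stereo_assignment"))
  cls <- pool_residues(x$residue, pooling)
  classes <- unique(cls)
  comp <- tibble(
    residue_class = classes,
    n_D = vapply(classes, function(cl) sum(cls == cl & x$configuration == "D"),
                 integer(1), USE.NAMES = FALSE),
    n_L = vapply(classes, function(cl) sum(cls == cl & x$configuration == "L"),
                 integer(1), USE.NAMES = FALSE)
  )
  if (swap_error) {
    set.seed(split_seed(seed, "marfeys-error"))
    i <- sample.int(nrow(comp), 1L)
    if (comp$n_D[i] > 0L) {
      comp$n_D[i] <- comp$n_D[i] - 1L
      comp$n_L[i] <- comp$n_L[i] + 1L
    } else {
      comp$n_D[i] <- comp$n_D[i] + 1L
      comp$n_L[i] <- comp$n_L[i] - 1L
    }
  }
  comp
}

#' Simulate a CH-alpha HSQC peak list
#'
#' Base shifts are drawn reproducibly from coarse class-typical CH-alpha
#' ranges (1H 3.8-5.3 ppm, 13C 45-65 ppm): each residue class gets a centre
#' keyed to the class name, plus a per-position jitter, so peaks are
#' separable and two products of one system share identical base
#' fingerprints. When `reference` differs from `assignment` at one or more
#' positions, peaks near each switch are displaced by
#' `switch_perturbation_h` (1H; 10x for 13C), attenuated linearly with
#' residue distance and vanishing at `decay_span`. Independent Gaussian
#' measurement noise is then added per peak under `noise_seed`, which is the
#' only stream that differs between replicate measurements.
#'
#' @param assignment A [stereo_assignment()].
#' @param cfg A [sim_config()]; supplies ranges, perturbation and noise.
#' @param reference Optional second [stereo_assignment()] over the same
#'   residue sequence; positions where the two differ are perturbed.
#' @param noise_seed Seed of the measurement-noise stream (defaults to a
#'   stream derived from `cfg$seed`).
#' @return A [peak_list()] with labels `<residue><position>`.
#' @export
simulate_hsqc <- function(assignment, cfg, reference = NULL,
                          noise_seed = NULL) {
  stopifnot(inherits(assignment, "stereo_assignment"),
            inherits(cfg, "sim_config"))
  n <- nrow(assignment)

  # class centre within the CH-alpha region plus a broad per-position
  # spread: same-class peaks cluster loosely but stay separable on the
  # scale of a D/L-switch displacement
  centre_h <- vapply(assignment$residue, function(cl) {
    set.seed(split_seed(cfg$seed, paste0("class-h-", cl)))
    runif(1, 4.05, 5.05)
  }, numeric(1), USE.NAMES = FALSE)
  centre_c <- vapply(assignment$residue, function(cl) {
    set.seed(split_seed(cfg$seed, paste0("class-c-", cl)))
    runif(1, 47.5, 62.5)
  }, numeric(1), USE.NAMES = FALSE)
  set.seed(split_seed(cfg$seed, "hsqc-jitter"))
  delta_h <- centre_h + runif(n, -0.25, 0.25)
  delta_c <- centre_c + runif(n, -2.5, 2.5)

  if (!is.null(reference)) {
    stopifnot(inherits(reference, "stereo_assignment"))
    if (!identical(reference$residue, assignment$residue)) {
      abort("assignment and reference must share a residue sequence")
    }
    switched <- which(reference$configuration != assignment$configuration)
    for (k in switched) {
      w <- pmax(0, 1 - abs(seq_len(n) - k) / cfg$decay_span)
      delta_h <- delta_h + cfg$switch_perturbation_h * w
      delta_c <- delta_c + 10 * cfg$switch_perturbation_h * w
    }
  }

  set.seed(noise_seed %||% split_seed(cfg$seed, "hsqc-noise"))
  delta_h <- delta_h + rnorm(n, 0, cfg$noise_sigma_h)
  delta_c <- delta_c + rnorm(n, 0, cfg$noise_sigma_c)

  peak_list(tibble(label = paste0(assignment$residue, assignment$position),
                   delta_h = delta_h, delta_c = delta_c),
            solvent = "simulated")
}

#' Simulate C-domain sequences with planted histidine motifs
#'
#' Generates random-background protein sequences carrying a planted primary
#' motif (final G for LCL; H, A or N for E/C, histidine most often) and, for
#' E/C domains, a planted secondary motif inside the N-terminal window with
#' a typical leucine - or, on request, the atypical extra-histidine - flank
#' and an optional single His/Pro insertion in the wildcard block
#' (probability `insertion_prob`). Point mutations hit positions outside the
#' pattern-constrained motif positions (and outside the planted insertion)
#' at `mutation_rate`, so wildcard positions can drift.
#'
#' So that planted truth is uniquely decodable at mutation rate 0, the
#' background alphabet excludes histidine and the secondary wildcard block
#' additionally excludes P, D and G (see the methods vignette).
#'
#' @param cfg A [sim_config()].
#' @param n Number of domains.
#' @param class `"EC"` or `"LCL"`.
#' @param atypical_flank Plant an H instead of the conserved L in front of
#'   the secondary motif?
#' @return A tibble with one row per domain: `id`, `sequence`, `class`, and
#'   truth columns `primary_start`, `secondary_start`, `insertion`,
#'   `insertion_offset` (position within the matched span), `flank_residue`.
#' @export
simulate_domains <- function(cfg, n = 1L, class = c("EC", "LCL"),
                             atypical_flank = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  class <- match.arg(class)
  set.seed(split_seed(cfg$seed, paste0("domains-", class, "-", atypical_flank)))
  background <- setdiff(aa_alphabet(), "H")
  xblock_letters <- setdiff(background, c("P", "D", "G"))
  len <- cfg$domain_length
  win <- cfg$nterm_window

  one <- function(i) {
    s <- sample(background, len, replace = TRUE)
    constrained <- logical(len)

    primary_start <- sample(seq(win + 11L, len - 7L), 1L)
    final <- if (class == "LCL") "G" else {
      sample(c("H", "A", "N"), 1L, prob = c(0.8, 0.1, 0.1))
    }
    s[primary_start:(primary_start + 6L)] <-
      c("H", "H", sample(background, 3L, replace = TRUE), "D", final)
    constrained[c(primary_start, primary_start + 1L,
                  primary_start + 5L, primary_start + 6L)] <- TRUE

    secondary_start <- NA_integer_
    insertion <- NA
    insertion_offset <- NA_integer_
    flank <- NA_character_
    if (class == "EC") {
      insertion <- runif(1) < cfg$insertion_prob
      span <- if (insertion) 10L else 9L
      secondary_start <- sample(seq(2L, win - span + 1L), 1L)
      flank <- if (atypical_flank) "H" else "L"
      block <- sample(xblock_letters, span - 5L, replace = TRUE)
      if (insertion) {
        insertion_offset <- sample(4:8, 1L)
        block[insertion_offset - 3L] <- sample(c("H", "P"), 1L)
      }
      motif <- c("H", "H", sample(c("I", "L"), 1L), block, "G", "D")
      idx <- secondary_start:(secondary_start + span - 1L)
      s[idx] <- motif
      s[secondary_start - 1L] <- flank
      # protect the pattern-constrained positions, the flank and the planted
      # insertion; wildcard positions stay mutable
      keep <- c(secondary_start + c(0L, 1L, 2L, span - 2L, span - 1L),
                secondary_start - 1L,
                if (insertion) secondary_start + insertion_offset - 1L)
      constrained[keep] <- TRUE
    }

    if (cfg$mutation_rate > 0) {
      mut <- which(!constrained & runif(len) < cfg$mutation_rate)
      if (length(mut)) s[mut] <- sample(aa_alphabet(), length(mut), replace = TRUE)
    }

    tibble(id = sprintf("%s_dom%03d", tolower(class), i),
           sequence = paste(s, collapse = ""),
           class = class,
           primary_start = primary_start,
           secondary_start = secondary_start,
           insertion = insertion,
           insertion_offset = insertion_offset,
           flank_residue = flank)
  }
  purrr::map_dfr(seq_len(n), one)
}

#' Draw product identities at the configured abundance ratio
#'
#' Samples which product each observed molecule is, at the ground truth's
#' major:minor abundance (3:2 by default), e.g. to emulate relative
#' chromatographic peak areas.
#'
#' @param gt A `clip_ground_truth`.
#' @param n Number of draws.
#' @param seed Seed of the draw stream.
#' @return Character vector of product names.
#' @export
sample_products <- function(gt, n, seed = 1L) {
  stopifnot(inherits(gt, "clip_ground_truth"))
  set.seed(split_seed(seed, "product-draws"))
  sample(gt$products$product, n, replace = TRUE, prob = gt$products$abundance)
}
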