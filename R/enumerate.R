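# Constraint-based enumeration of diastereomer candidates.
#
# A Marfey's analysis reports, per residue class, how many copies are D- and
# how many are L-configured, but not *where* they sit. Combined with hard
# positional constraints from the NRPS architecture (residues preceding an
# LCL domain stay L; the terminal residue is L; E/C domains with a confident
# activity label pin their position), the set of full-sequence D/L
# assignments compatible with both families is a product of per-class
# combinatorial choices. These functions enumerate, count and prune that set.

#' Hard positional constraints from NRPS architecture
#'
#' Position `i` is restricted to `L` when module `i + 1` carries an LCL
#' (condensation-only) domain, because such a domain cannot epimerize the
#' residue it condenses onto. The terminal position is always `L`. A position
#' followed by an E/C domain is unconstrained (`DL`) unless that domain
#' carries a confident activity label: `ACTIVE` pins `D`, `INACTIVE` pins
#' `L`; `INTERMITTENT` and `UNKNOWN` leave both possibilities open.
#'
#' @param system An [nrps_system()].
#' @param use_priors If `FALSE`, activity labels are ignored and only the
#'   architectural (LCL/terminal) constraints are kept.
#' @return A tibble with columns `position` and `allowed` (one of `"D"`,
#'   `"L"`, `"DL"`).
#' @export
#' @examples
#' sys <- read_nrps(clipstereo_example("entolysin_nrps.tsv"))
#' derive_hard_constraints(sys)
derive_hard_constraints <- function(system, use_priors = TRUE) {
  stopifnot(inherits(system, "nrps_system"))
  n <- nrow(system)
  allowed <- rep("DL", n)
  for (i in seq_len(n - 1L)) {
    if (system$cdomain[i + 1L] == "LCL") {
      allowed[i] <- "L"
    } else {
      lab <- if (use_priors) system$epi_label[i + 1L] else "UNKNOWN"
      allowed[i] <- switch(lab, ACTIVE = "D", INACTIVE = "L", "DL")
    }
  }
  allowed[n] <- "L"  # no downstream C-domain before TE release
  tibble(position = seq_len(n), allowed = allowed)
}

normalize_allowed <- function(x) {
  vapply(strsplit(toupper(as.character(x)), ""), function(ch) {
    paste(sort(unique(ch)), collapse = "")
  }, character(1))
}

# Fill a partial constraint table out to all n positions (default "DL").
as_position_constraint <- function(constraints, n) {
  if (is.null(constraints)) {
    return(tibble(position = seq_len(n), allowed = rep("DL", n)))
  }
  constraints <- tibble::as_tibble(constraints)
  if (!all(c("position", "allowed") %in% names(constraints))) {
    abort("position constraints need columns 'position' and 'allowed'")
  }
  pos <- as.integer(constraints$position)
  if (anyNA(pos) || any(pos < 1L | pos > n)) {
    abort(sprintf("constraint positions must lie in 1..%d", n))
  }
  if (anyDuplicated(pos)) abort("duplicate constraint for a position")
  allowed <- normalize_allowed(constraints$allowed)
  bad <- which(!allowed %in% c("D", "L", "DL"))
  if (length(bad)) {
    abort(sprintf("position %d: allowed set must be a nonempty subset of {D, L}",
                  pos[bad[1]]))
  }
  full <- tibble(position = seq_len(n), allowed = rep("DL", n))
  full$allowed[pos] <- allowed
  full
}

check_composition <- function(sequence, composition) {
  composition <- tibble::as_tibble(composition)
  if (!all(c("residue_class", "n_D", "n_L") %in% names(composition))) {
    abort("composition needs columns 'residue_class', 'n_D' and 'n_L'")
  }
  composition$n_D <- as.integer(composition$n_D)
  composition$n_L <- as.integer(composition$n_L)
  if (anyNA(composition$n_D) || anyNA(composition$n_L) ||
      any(composition$n_D < 0L) || any(composition$n_L < 0L)) {
    abort("composition counts must be nonnegative integers")
  }
  if (anyDuplicated(composition$residue_class)) {
    abort("composition lists a residue class twice")
  }
  counts <- table(sequence)
  for (cl in names(counts)) {
    row <- match(cl, composition$residue_class)
    if (is.na(row)) {
      abort(sprintf("composition is missing residue class '%s'", cl))
    }
    total <- composition$n_D[row] + composition$n_L[row]
    if (total != counts[[cl]]) {
      abort(sprintf(
        "composition for class '%s' totals %d residues but the sequence has %d",
        cl, total, counts[[cl]]))
    }
  }
  extra <- setdiff(composition$residue_class[composition$n_D + composition$n_L > 0L],
                   names(counts))
  if (length(extra)) {
    abort(sprintf("composition lists class '%s' absent from the sequence", extra[1]))
  }
  composition
}

# Per-class placement plan: which positions are pinned by constraints, which
# are free, and how many D's remain to place. Returns the first infeasible
# class (if any) instead of a plan.
class_plan <- function(sequence, composition, pc) {
  plans <- list()
  for (cl in unique(sequence)) {
    pos <- which(sequence == cl)
    al <- pc$allowed[pos]
    fixed_D <- pos[al == "D"]
    free <- pos[al == "DL"]
    n_D <- composition$n_D[match(cl, composition$residue_class)]
    need <- n_D - length(fixed_D)
    if (need < 0L || need > length(free)) {
      return(list(plans = NULL, infeasible = cl))
    }
    plans[[cl]] <- list(class = cl, free = free, need = need)
  }
  list(plans = plans, infeasible = NULL)
}

# combn() treats a length-1 integer first argument as seq_len(); guard it
combn_positions <- function(x, m) {
  if (length(x) == 1L) {
    if (m == 0L) list(integer(0)) else list(x)
  } else {
    combn(x, m, simplify = FALSE)
  }
}

infeasible_message <- function(cl) {
  sprintf(paste0("residue class '%s': no D/L placement satisfies both the ",
                 "composition counts and the position constraints"), cl)
}

new_candidate_set <- function(config, sequence, provenance = character(),
                              infeasible = NULL) {
  config <- unique(config)
  config <- config[order(config, method = "radix")]
  structure(tibble(config = config),
            class = c("candidate_set", class(tibble::tibble())),
            sequence = sequence,
            provenance = provenance,
            infeasible_class = infeasible)
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> %d assignment(s) over %d positions\n",
              nrow(x), length(attr(x, "sequence"))))
  prov <- attr(x, "provenance")
  if (length(prov)) cat("constraints applied:", paste(prov, collapse = "; "), "\n")
  inf <- attr(x, "infeasible_class")
  if (!is.null(inf)) cat("infeasible at class:", inf, "\n")
  print(tibble::new_tibble(as.list(x), nrow = nrow(x)), ...)
  invisible(x)
}

#' Enumerate D/L assignments consistent with composition and position data
#'
#' Returns every full-sequence D/L assignment that simultaneously reproduces
#' the per-class Marfey's counts and respects the per-position allowed sets.
#' The result is deterministic: candidates are listed in lexicographic order
#' of their configuration string (`D` before `L`).
#'
#' An infeasible combination (the constraints pin more D's or L's of a class
#' than the composition provides) yields an empty set plus a warning naming
#' the first violated class, so that inconsistent Marfey's inputs surface
#' rather than vanish.
#'
#' @param sequence Character vector of residue classes, one per position, in
#'   the vocabulary of `composition` (apply [pool_residues()] first when the
#'   composition uses pooled classes such as `Glx`).
#' @param composition Data frame with columns `residue_class`, `n_D`, `n_L`;
#'   totals must match the class multiplicities of `sequence`.
#' @param constraints Optional data frame with columns `position` and
#'   `allowed` (`"D"`, `"L"` or `"DL"`), e.g. from
#'   [derive_hard_constraints()]. Missing positions default to `"DL"`.
#' @return A `candidate_set`: a tibble with a `config` column of D/L strings
#'   (e.g. `"LDDDDDDDDDLLLL"`), carrying the residue sequence and the applied
#'   constraints as attributes.
#' @seealso [count_assignments()], [brute_force_enumerate()],
#'   [prioritize_candidates()]
#' @export
#' @examples
#' seq14 <- pool_residues(c("Leu", "Glu", "Gln", "Val", "Leu", "Gln", "Val",
#'                          "Leu", "Gln", "Ser", "Val", "Leu", "Ser", "Ile"))
#' comp_b <- read_composition(clipstereo_example("entolysin_marfeys_B.tsv"))
#' nrow(enumerate_assignments(seq14, comp_b))  # 18
enumerate_assignments <- function(sequence, composition, constraints = NULL) {
  sequence <- as.character(sequence)
  n <- length(sequence)
  pc <- as_position_constraint(constraints, n)
  composition <- check_composition(sequence, composition)
  provenance <- c("composition",
                  constraint_provenance(pc))

  plan <- class_plan(sequence, composition, pc)
  if (!is.null(plan$infeasible)) {
    warn(infeasible_message(plan$infeasible))
    return(new_candidate_set(character(0), sequence, provenance,
                             infeasible = plan$infeasible))
  }

  template <- rep(NA_character_, n)
  template[pc$allowed == "D"] <- "D"
  template[pc$allowed == "L"] <- "L"

  plans <- plan$plans
  choices <- lapply(plans, function(p) {
    if (length(p$free)) combn_positions(p$free, p$need)
    else list(integer(0))
  })
  if (length(plans) == 0L) {
    return(new_candidate_set(paste(template, collapse = ""), sequence, provenance))
  }
  grid <- expand.grid(lapply(choices, seq_along), KEEP.OUT.ATTRS = FALSE)
  configs <- character(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    cfg <- template
    for (ci in seq_along(plans)) {
      p <- plans[[ci]]
      cfg[p$free] <- "L"
      cfg[choices[[ci]][[grid[r, ci]]]] <- "D"
    }
    configs[r] <- paste(cfg, collapse = "")
  }
  new_candidate_set(configs, sequence, provenance)
}

constraint_provenance <- function(pc) {
  pinned <- pc[pc$allowed != "DL", ]
  if (!nrow(pinned)) return(character(0))
  sprintf("positions %s", paste0(pinned$position, "=", pinned$allowed,
                                 collapse = ","))
}

#' Closed-form count of consistent D/L assignments
#'
#' The candidate count factorizes over residue classes: each class
#' contributes `choose(n_free, n_D_remaining)` ways of placing its remaining
#' D residues among its unconstrained positions. Always equals
#' `nrow(enumerate_assignments(...))`.
#'
#' @inheritParams enumerate_assignments
#' @return An integer count (0, with a warning, when infeasible).
#' @export
count_assignments <- function(sequence, composition, constraints = NULL) {
  sequence <- as.character(sequence)
  pc <- as_position_constraint(constraints, length(sequence))
  composition <- check_composition(sequence, composition)
  plan <- class_plan(sequence, composition, pc)
  if (!is.null(plan$infeasible)) {
    warn(infeasible_message(plan$infeasible))
    return(0L)
  }
  as.integer(round(prod(vapply(plan$plans, function(p) {
    choose(length(p$free), p$need)
  }, numeric(1)))))
}

#' Arrangements of one residue class's D/L pool
#'
#' Restricts the count to a single named class: the number of ways its
#' remaining D residues can be distributed over its unconstrained positions
#' (e.g. three ways to place two D-Leu and one L-Leu once Leu12 is pinned L).
#'
#' @inheritParams enumerate_assignments
#' @param residue_class Class to count arrangements for.
#' @return An integer count.
#' @export
class_arrangements <- function(sequence, composition, constraints = NULL,
                               residue_class) {
  sequence <- as.character(sequence)
  if (!residue_class %in% sequence) {
    abort(sprintf("residue class '%s' does not occur in the sequence",
                  residue_class))
  }
  pc <- as_position_constraint(constraints, length(sequence))
  composition <- check_composition(sequence, composition)
  plan <- class_plan(sequence, composition, pc)
  if (!is.null(plan$infeasible)) {
    warn(infeasible_message(plan$infeasible))
    return(0L)
  }
  p <- plan$plans[[residue_class]]
  as.integer(choose(length(p$free), p$need))
}

#' Brute-force reference enumeration
#'
#' Filters all `2^n` configuration vectors against both constraint families.
#' Exponential by construction; it exists as an independent oracle for the
#' combinatorial enumeration and refuses sequences longer than 24 positions.
#'
#' @inheritParams enumerate_assignments
#' @return A `candidate_set`, identical to the one from
#'   [enumerate_assignments()].
#' @export
brute_force_enumerate <- function(sequence, composition, constraints = NULL) {
  sequence <- as.character(sequence)
  n <- length(sequence)
  if (n > 24L) abort("brute-force enumeration is limited to 24 positions")
  pc <- as_position_constraint(constraints, n)
  composition <- check_composition(sequence, composition)
  provenance <- c("composition (brute force)", constraint_provenance(pc))

  total <- as.integer(2^n)
  if (n == 0L) return(new_candidate_set("", sequence, provenance))
  is_d <- matrix(FALSE, nrow = total, ncol = n)
  for (j in seq_len(n)) {
    is_d[, j] <- bitwAnd(seq_len(total) - 1L, bitwShiftL(1L, j - 1L)) > 0L
  }
  keep <- rep(TRUE, total)
  for (j in which(pc$allowed == "D")) keep <- keep & is_d[, j]
  for (j in which(pc$allowed == "L")) keep <- keep & !is_d[, j]
  for (cl in unique(sequence)) {
    pos <- which(sequence == cl)
    n_D <- composition$n_D[match(cl, composition$residue_class)]
    keep <- keep & rowSums(is_d[, pos, drop = FALSE]) == n_D
  }
  rows <- which(keep)
  configs <- vapply(rows, function(r) {
    paste(ifelse(is_d[r, ], "D", "L"), collapse = "")
  }, character(1))
  new_candidate_set(configs, sequence, provenance)
}

#' Merge candidate sets from alternative compositions
#'
#' Two diastereomeric products of one assembly line share a residue sequence
#' but differ in composition; their candidate sets are merged into one
#' deduplicated synthesis shortlist, each member annotated with the
#' composition(s) it satisfies.
#'
#' @param set_a,set_b `candidate_set`s over sequences of the same length.
#' @param labels Length-2 character vector naming the two sets in the
#'   provenance column.
#' @return A `candidate_set` with an extra `source` column.
#' @export
prioritize_candidates <- function(set_a, set_b, labels = c("A", "B")) {
  stopifnot(inherits(set_a, "candidate_set"), inherits(set_b, "candidate_set"))
  if (length(attr(set_a, "sequence")) != length(attr(set_b, "sequence"))) {
    abort("candidate sets describe sequences of different lengths")
  }
  configs <- union(set_a$config, set_b$config)
  source <- vapply(configs, function(cf) {
    paste(labels[c(cf %in% set_a$config, cf %in% set_b$config)], collapse = "+")
  }, character(1), USE.NAMES = FALSE)
  out <- new_candidate_set(configs, attr(set_a, "sequence"),
                           provenance = c(attr(set_a, "provenance"),
                                          attr(set_b, "provenance"),
                                          sprintf("union(%s,%s)", labels[1], labels[2])))
  out$source <- source[match(out$config, configs)]
  out
}

#' Map residues to pooled Marfey's classes
#'
#' Marfey's analysis (and mass spectrometry) cannot always resolve related
#' residues: Glu and Gln derivatives co-report as `Glx`, and isobaric
#' Leu/Ile are indistinguishable by mass (`Xle`). Pooling replaces member
#' residues by their pooled class name so that sequence and composition share
#' one vocabulary.
#'
#' @param residues Character vector of residue names.
#' @param pooling Named list mapping a pooled class to its members; see
#'   [marfeys_pooling()].
#' @return Character vector with pooled class names substituted.
#' @export
#' @examples
#' pool_residues(c("Leu", "Glu", "Gln", "Ser"))
pool_residues <- function(residues, pooling = marfeys_pooling()) {
  residues <- as.character(residues)
  for (cl in names(pooling)) {
    residues[residues %in% pooling[[cl]]] <- cl
  }
  residues
}

#' @param xle Also pool Leu/Ile as `Xle`? Off by default: Marfey's
#'   chromatography resolves them, the pooling is only needed for
#'   mass-spectrometric compositions.
#' @rdname pool_residues
#' @export
marfeys_pooling <- function(xle = FALSE) {
  p <- list(Glx = c("Glu", "Gln"))
  if (xle) p$Xle <- c("Leu", "Ile")
  p
}

#' Read a Marfey's composition table
#'
#' @param path TSV with columns `residue_class`, `n_D`, `n_L`.
#' @return A validated composition tibble.
#' @export
read_composition <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such composition file: '%s'", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           residue_class = readr::col_character(),
                           n_D = readr::col_integer(),
                           n_L = readr::col_integer()))
  if (!all(c("residue_class", "n_D", "n_L") %in% names(tbl))) {
    abort(sprintf("'%s' must have columns residue_class, n_D, n_L", path))
  }
  if (anyNA(tbl$n_D) || anyNA(tbl$n_L)) {
    abort(sprintf("'%s': non-integer counts", path))
  }
  tbl
}

#' @export
tidy.candidate_set <- function(x, ...) {
  sequence <- attr(x, "sequence")
  n <- length(sequence)
  if (!nrow(x)) {
    return(tibble(candidate = integer(0), position = integer(0),
                  residue = character(0), configuration = character(0)))
  }
  letters_by_cand <- strsplit(x$config, "")
  tibble(
    candidate = rep(seq_len(nrow(x)), each = n),
    position = rep(seq_len(n), times = nrow(x)),
    residue = rep(sequence, times = nrow(x)),
    configuration = unlist(letters_by_cand)
  )
}

#' @export
glance.candidate_set <- function(x, ...) {
  tibble(n_candidates = nrow(x),
         n_positions = length(attr(x, "sequence")),
         infeasible_class = attr(x, "infeasible_class") %||% NA_character_)
}
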