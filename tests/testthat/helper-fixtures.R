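# Shared fixtures. The entolysin inputs come from the packaged descriptor
# and composition tables; everything else is generated in code.

ent_system <- function() {
  read_nrps(clipstereo_example("entolysin_nrps.tsv"))
}

ent_sequence <- function() {
  pool_residues(ent_system()$residue)
}

ent_composition <- function(which = c("A", "B")) {
  which <- match.arg(which)
  read_composition(clipstereo_example(sprintf("entolysin_marfeys_%s.tsv", which)))
}

# published configuration strings (positions 1..14)
ENT_A_CONFIG <- "LDDDDDDDDDLLLL"  # L-Ser13
ENT_B_CONFIG <- "LDDDDDDDDDLLDL"  # D-Ser10 / D-Ser13
ENT_SER10_CONFIG <- "LDDDDDDDDLLLDL"  # L-Ser10 variant

# random enumeration instance built from a known satisfying truth, so the
# instance is always feasible and the truth must appear in the answer
random_stereo_instance <- function(seed, n_range = 4:16) {
  set.seed(seed)
  n <- sample(n_range, 1)
  k <- sample(2:5, 1)
  sequence <- sample(LETTERS[seq_len(k)], n, replace = TRUE)
  truth <- sample(c("D", "L"), n, replace = TRUE)
  classes <- unique(sequence)
  composition <- data.frame(
    residue_class = classes,
    n_D = vapply(classes, function(cl) sum(sequence == cl & truth == "D"),
                 integer(1)),
    n_L = vapply(classes, function(cl) sum(sequence == cl & truth == "L"),
                 integer(1))
  )
  n_fix <- sample(0:3, 1)
  fix <- sample(n, min(n_fix, n))
  constraints <- if (length(fix)) {
    data.frame(position = fix, allowed = truth[fix])
  }
  list(sequence = sequence, composition = composition,
       constraints = constraints, truth = paste(truth, collapse = ""))
}

# all permutations of 1..n, for exhaustive pairing checks (n small)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (i in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
    }
  }
  out
}

# minimal total pairing cost over all one-to-one pairings (square cost)
exhaustive_pairing_cost <- function(cost) {
  n <- nrow(cost)
  min(vapply(all_perms(n), function(p) {
    sum(cost[cbind(seq_len(n), p)])
  }, numeric(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
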