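test_that("hard constraints reflect LCL domains, the terminus, and priors", {
  sys <- ent_system()
  hc <- derive_hard_constraints(sys)
  expect_equal(hc$allowed[c(11, 12, 14)], rep("L", 3))  # LCL at 12, 13; terminus
  expect_equal(hc$allowed[c(1:10, 13)], rep("DL", 11))
  # homology prior: epi-inactive module-2 E/C pins the N-terminal residue L
  sys2 <- apply_epi_labels(sys, data.frame(index = 2, epi_label = "INACTIVE"))
  hc2 <- derive_hard_constraints(sys2)
  expect_equal(hc2$allowed[1], "L")
  expect_equal(hc2$allowed[-1], hc$allowed[-1])
  # an ACTIVE label pins D; use_priors = FALSE ignores labels
  sys3 <- apply_epi_labels(sys, data.frame(index = 3, epi_label = "ACTIVE"))
  expect_equal(derive_hard_constraints(sys3)$allowed[2], "D")
  expect_equal(derive_hard_constraints(sys3, use_priors = FALSE)$allowed[2], "DL")
  # a chain of condensation-only domains leaves everything L
  all_lcl <- nrps_system(data.frame(index = 1:4, residue = "Ala",
                                    cdomain = c("CSTART", rep("LCL", 3))))
  expect_equal(derive_hard_constraints(all_lcl)$allowed, rep("L", 4))
})

test_that("composition-only enumeration reproduces the 18/36 candidate counts", {
  seq14 <- ent_sequence()
  expect_equal(count_assignments(seq14, ent_composition("B")), 18L)
  expect_equal(count_assignments(seq14, ent_composition("A")), 36L)
  expect_equal(nrow(enumerate_assignments(seq14, ent_composition("B"))), 18L)
  expect_equal(nrow(enumerate_assignments(seq14, ent_composition("A"))), 36L)
})

test_that("pinning the valine before the first LCL domain cuts counts threefold", {
  seq14 <- ent_sequence()
  base <- count_assignments(seq14, ent_composition("A"),
                            data.frame(position = 14, allowed = "L"))
  pinned <- count_assignments(seq14, ent_composition("A"),
                              data.frame(position = c(14, 11), allowed = "L"))
  expect_equal(base / pinned, 3)
})

test_that("architecture constraints leave 6 candidates and 3 leucine arrangements", {
  seq14 <- ent_sequence()
  hc <- derive_hard_constraints(ent_system())
  expect_equal(count_assignments(seq14, ent_composition("A"), hc), 6L)
  expect_equal(class_arrangements(seq14, ent_composition("A"), hc,
                                  residue_class = "Leu"), 3L)
  # a fully pinned class admits exactly one arrangement
  all_fixed <- data.frame(position = c(1, 5, 8, 12), allowed = c("D", "D", "L", "L"))
  expect_equal(class_arrangements(seq14, ent_composition("A"), all_fixed,
                                  residue_class = "Leu"), 1L)
  # 2 D + 2 L over 4 free positions: choose(4, 2)
  expect_equal(class_arrangements(seq14, ent_composition("A"),
                                  residue_class = "Leu"), 6L)
  expect_error(class_arrangements(seq14, ent_composition("A"),
                                  residue_class = "Trp"), "does not occur")
})

test_that("an all-D composition admits a single assignment", {
  seqx <- c("Ala", "Ala", "Ser")
  comp <- data.frame(residue_class = c("Ala", "Ser"), n_D = c(2, 1), n_L = c(0, 0))
  cs <- enumerate_assignments(seqx, comp)
  expect_equal(cs$config, "DDD")
  expect_equal(count_assignments(seqx, comp), 1L)
})

test_that("the empty sequence has exactly the empty assignment", {
  empty_comp <- data.frame(residue_class = character(0),
                           n_D = integer(0), n_L = integer(0))
  expect_equal(count_assignments(character(0), empty_comp), 1L)
  expect_equal(enumerate_assignments(character(0), empty_comp)$config, "")
})

test_that("the epi-inactivity prior prioritizes exactly the three synthesis targets", {
  seq14 <- ent_sequence()
  sys <- apply_epi_labels(ent_system(), data.frame(index = 2, epi_label = "INACTIVE"))
  hc <- derive_hard_constraints(sys)
  set_a <- enumerate_assignments(seq14, ent_composition("A"), hc)
  set_b <- enumerate_assignments(seq14, ent_composition("B"), hc)
  expect_equal(set_a$config, sort(c(ENT_A_CONFIG, ENT_SER10_CONFIG)))
  expect_equal(set_b$config, ENT_B_CONFIG)
  merged <- prioritize_candidates(set_a, set_b)
  expect_equal(nrow(merged), 3L)
  expect_setequal(merged$config, c(ENT_A_CONFIG, ENT_SER10_CONFIG, ENT_B_CONFIG))
  expect_equal(merged$source[merged$config == ENT_B_CONFIG], "B")
  expect_equal(merged$source[merged$config == ENT_A_CONFIG], "A")
})

test_that("candidate-set union is idempotent and validates lengths", {
  seq14 <- ent_sequence()
  cs <- enumerate_assignments(seq14, ent_composition("B"),
                              derive_hard_constraints(ent_system()))
  again <- prioritize_candidates(cs, cs)
  expect_equal(again$config, cs$config)
  # disjoint singletons merge to two members
  s1 <- enumerate_assignments("Ala", data.frame(residue_class = "Ala", n_D = 1, n_L = 0))
  s2 <- enumerate_assignments("Ala", data.frame(residue_class = "Ala", n_D = 0, n_L = 1))
  expect_equal(nrow(prioritize_candidates(s1, s2)), 2L)
  expect_error(prioritize_candidates(cs, s1), "different lengths")
})

test_that("enumeration, closed-form count and brute force agree on random instances", {
  for (s in 1:120) {
    inst <- random_stereo_instance(s, n_range = 4:12)
    cs <- enumerate_assignments(inst$sequence, inst$composition, inst$constraints)
    expect_equal(count_assignments(inst$sequence, inst$composition, inst$constraints),
                 nrow(cs))
    bf <- brute_force_enumerate(inst$sequence, inst$composition, inst$constraints)
    expect_identical(cs$config, bf$config)
    expect_true(inst$truth %in% cs$config)
  }
})

test_that("tightening a position constraint never increases the count", {
  for (s in 1:60) {
    inst <- random_stereo_instance(s, n_range = 4:12)
    base <- count_assignments(inst$sequence, inst$composition, inst$constraints)
    free_pos <- setdiff(seq_along(inst$sequence),
                        inst$constraints$position %||% integer(0))
    if (!length(free_pos)) next
    set.seed(s + 7000)
    extra <- data.frame(position = free_pos[sample.int(length(free_pos), 1)],
                        allowed = sample(c("D", "L"), 1))
    tightened <- suppressWarnings(
      count_assignments(inst$sequence, inst$composition,
                        rbind(inst$constraints %||% extra[0, ], extra)))
    expect_lte(tightened, base)
  }
})

test_that("infeasible inputs are surfaced, not silently emptied", {
  seqx <- c("Ser", "Ser", "Ala")
  # composition totals that contradict the sequence are an input error
  bad_total <- data.frame(residue_class = c("Ser", "Ala"), n_D = c(3, 0), n_L = c(0, 1))
  expect_error(enumerate_assignments(seqx, bad_total), "totals")
  expect_error(brute_force_enumerate(seqx, bad_total), "totals")
  # constraints clashing with a feasible composition warn and name the class
  comp <- data.frame(residue_class = c("Ser", "Ala"), n_D = c(2, 0), n_L = c(0, 1))
  cons <- data.frame(position = 1, allowed = "L")
  expect_warning(out <- enumerate_assignments(seqx, comp, cons), "Ser")
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "infeasible_class"), "Ser")
  expect_warning(expect_equal(count_assignments(seqx, comp, cons), 0L), "Ser")
  # the brute-force oracle agrees that nothing satisfies both families
  expect_equal(nrow(brute_force_enumerate(seqx, comp, cons)), 0L)
})

test_that("candidate listings are deterministic and lexicographically ordered", {
  seq14 <- ent_sequence()
  a <- enumerate_assignments(seq14, ent_composition("A"))
  b <- enumerate_assignments(seq14, ent_composition("A"))
  expect_identical(a$config, b$config)
  expect_identical(a$config, a$config[order(a$config, method = "radix")])
})

test_that("brute force refuses sequences beyond its guard", {
  n <- 25
  comp <- data.frame(residue_class = "Ala", n_D = n, n_L = 0)
  expect_error(brute_force_enumerate(rep("Ala", n), comp), "24")
})

test_that("pooling maps members onto Marfey's classes", {
  expect_equal(pool_residues(c("Leu", "Glu", "Gln", "Ser")),
               c("Leu", "Glx", "Glx", "Ser"))
  expect_equal(pool_residues(c("Leu", "Ile"), marfeys_pooling(xle = TRUE)),
               c("Xle", "Xle"))
})

test_that("candidate sets tidy into per-position tables", {
  cs <- enumerate_assignments(c("Ala", "Ser"),
                              data.frame(residue_class = c("Ala", "Ser"),
                                         n_D = c(1, 0), n_L = c(0, 1)))
  td <- tidy(cs)
  expect_equal(nrow(td), 2L)
  expect_equal(td$configuration, c("D", "L"))
  gl <- glance(cs)
  expect_equal(gl$n_candidates, 1L)
  expect_equal(gl$n_positions, 2L)
})
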