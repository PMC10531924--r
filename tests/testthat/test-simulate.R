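test_that("simulation is reproducible from the master seed", {
  cfg <- sim_config(seed = 42)
  gt1 <- simulate_system(cfg)
  gt2 <- simulate_system(cfg)
  expect_equal(gt1$products, gt2$products)
  expect_equal(as.data.frame(gt1$system), as.data.frame(gt2$system))
  p1 <- simulate_hsqc(product_assignment(gt1, "major"), cfg)
  p2 <- simulate_hsqc(product_assignment(gt2, "major"), cfg)
  expect_equal(as.data.frame(p1), as.data.frame(p2))
  d1 <- simulate_domains(cfg, n = 2, class = "EC")
  d2 <- simulate_domains(cfg, n = 2, class = "EC")
  expect_equal(d1, d2)
})

test_that("sim_config validates its parameters", {
  expect_error(sim_config(p_ec = 1.2), "probabilities")
  expect_error(sim_config(major_minor_ratio = c(3, 0)), "positive")
  expect_error(sim_config(noise_sigma_h = -1), "sigmas")
  expect_error(sim_config(domain_length = 100, nterm_window = 120), "exceed")
})

test_that("an intermittent E/C domain yields two products differing at one position", {
  # without intermittency: a single product
  gt0 <- simulate_system(sim_config(seed = 5, p_intermittent = 0))
  expect_equal(nrow(gt0$products), 1L)
  expect_true(is.na(gt0$switch_position))

  for (s in 1:50) {
    gt <- simulate_system(sim_config(seed = s, p_ec = 1, p_intermittent = 1))
    expect_equal(nrow(gt$products), 2L)
    a <- strsplit(gt$products$config[1], "")[[1]]
    b <- strsplit(gt$products$config[2], "")[[1]]
    diffs <- which(a != b)
    expect_equal(diffs, gt$switch_position)
    # major carries the unepimerized L form at the switch
    expect_equal(a[gt$switch_position], "L")
    expect_equal(b[gt$switch_position], "D")
    # the switch sits right before the INTERMITTENT module
    inter <- gt$true_labels$index[gt$true_labels$epi_label == "INTERMITTENT"]
    expect_length(inter, 1L)
    expect_equal(gt$switch_position, inter - 1L)
    # products obey the architecture rules under the true labels
    expect_equal(gt$products$abundance, c(0.6, 0.4))
  }
})

test_that("simulated Marfey's counts reproduce the entolysin composition", {
  # the published entolysin A assignment tallied per pooled class
  ent_a <- stereo_assignment(ent_system()$residue, ENT_A_CONFIG)
  comp <- simulate_marfeys(ent_a)
  get <- function(cl) unlist(comp[comp$residue_class == cl, c("n_D", "n_L")])
  expect_equal(get("Leu"), c(n_D = 2L, n_L = 2L))
  expect_equal(get("Glx"), c(n_D = 4L, n_L = 0L))
  expect_equal(get("Val"), c(n_D = 2L, n_L = 1L))
  expect_equal(get("Ser"), c(n_D = 1L, n_L = 1L))
  expect_equal(get("Ile"), c(n_D = 0L, n_L = 1L))
  # entolysin B moves one Ser count from L to D
  comp_b <- simulate_marfeys(stereo_assignment(ent_system()$residue, ENT_B_CONFIG))
  expect_equal(unlist(comp_b[comp_b$residue_class == "Ser", c("n_D", "n_L")]),
               c(n_D = 2L, n_L = 0L))

  # an all-L product reports everything on the L side
  all_l <- stereo_assignment(c("Ala", "Ala", "Ser"), "LLL")
  call <- simulate_marfeys(all_l)
  expect_true(all(call$n_D == 0L))
  expect_equal(sum(call$n_L), 3L)

  # the count-swap error mode perturbs exactly one class total
  err <- simulate_marfeys(ent_a, swap_error = TRUE, seed = 3)
  expect_equal(sum(abs(err$n_D - comp$n_D)), 1L)
})

test_that("marfeys counts of a ground truth come per product", {
  gt <- simulate_system(sim_config(seed = 8, p_ec = 1, p_intermittent = 1))
  mar <- simulate_marfeys(gt)
  expect_named(mar, c("major", "minor"))
  swl <- pool_residues(gt$system$residue)[gt$switch_position]
  i <- match(swl, mar$major$residue_class)
  expect_equal(mar$major$n_D[i] + 1L, mar$minor$n_D[i])
})

test_that("the product mixture draws at the configured 3:2 ratio", {
  gt <- simulate_system(sim_config(seed = 13, p_ec = 1, p_intermittent = 1))
  draws <- sample_products(gt, 10000, seed = 99)
  p_hat <- mean(draws == "major")
  se <- sqrt(0.6 * 0.4 / 10000)
  expect_lt(abs(p_hat - 0.6), 3 * se)
})

test_that("noise-free fingerprints of one assignment are identical", {
  cfg <- sim_config(seed = 4, noise_sigma_h = 0, noise_sigma_c = 0)
  gt <- simulate_system(cfg)
  a <- product_assignment(gt, "major")
  p1 <- simulate_hsqc(a, cfg, noise_seed = 1)
  p2 <- simulate_hsqc(a, cfg, noise_seed = 2)
  expect_equal(as.data.frame(p1), as.data.frame(p2))
  expect_equal(match_peaklists(p1, p2)$total_distance, 0)
})

test_that("a D/L switch displaces peaks locally with linear decay", {
  cfg <- sim_config(seed = 4, noise_sigma_h = 0, noise_sigma_c = 0,
                    p_ec = 1, p_intermittent = 0)
  gt <- simulate_system(cfg)
  residues <- gt$system$residue
  base <- simulate_hsqc(stereo_assignment(residues, gt$products$config), cfg)
  # switch position 13 of 14: positions 12-14 move, position 1 does not
  switched <- gt$products$config
  substr(switched, 13, 13) <- if (substr(switched, 13, 13) == "D") "L" else "D"
  ref <- stereo_assignment(residues, gt$products$config)
  pert <- simulate_hsqc(stereo_assignment(residues, switched), cfg, reference = ref)
  dh <- pert$delta_h - base$delta_h
  expect_equal(dh[13], 0.12)
  expect_equal(dh[12], 0.06)
  expect_equal(dh[14], 0.06)
  expect_equal(dh[c(1:10, 11)], rep(0, 11))
  # carbon moves 10x the proton displacement
  expect_equal(pert$delta_c[13] - base$delta_c[13], 1.2)
  # the matcher ranks the switched residue first
  m <- match_peaklists(base, pert)
  expect_equal(m$verdict, "MISMATCH")
  expect_equal(rank_residue_differences(m)$label[1], paste0(residues[13], 13))
})

test_that("planted domain truths are recovered by the scanners", {
  for (s in 1:50) {
    cfg <- sim_config(seed = s)
    atyp <- s %% 2 == 0
    d <- simulate_domains(cfg, n = 1, class = "EC", atypical_flank = atyp)
    pr <- classify_primary_motif(d$sequence)
    expect_equal(pr$classification, "EC")
    expect_equal(pr$start, d$primary_start)
    hit <- scan_secondary_motif(d$sequence, cfg$nterm_window)
    expect_equal(hit$start, d$secondary_start)
    expect_equal(hit$insertion, d$insertion)
    if (d$insertion) expect_equal(hit$insertion_offset, d$insertion_offset)
    expect_equal(flag_atypical_flank(hit)$atypical, atyp)

    dl <- simulate_domains(cfg, n = 1, class = "LCL")
    prl <- classify_primary_motif(dl$sequence)
    expect_equal(prl$classification, "LCL")
    expect_equal(prl$start, dl$primary_start)
  }
})

test_that("full motif-truth recovery degrades as the mutation rate rises", {
  # full truth = exact offset + insertion flag + apparent inserted residue;
  # wildcard drift can disguise an insertion, so recovery falls with rate
  hit_rate <- function(rate) {
    mean(vapply(1:120, function(s) {
      cfg <- sim_config(seed = s, mutation_rate = rate)
      d <- simulate_domains(cfg, n = 1, class = "EC")
      hit <- scan_secondary_motif(d$sequence, cfg$nterm_window)
      nrow(hit) == 1L && hit$start == d$secondary_start &&
        identical(hit$insertion, d$insertion) &&
        (!d$insertion || identical(hit$insertion_offset, d$insertion_offset))
    }, logical(1)))
  }
  r0 <- hit_rate(0)
  r_mid <- hit_rate(0.25)
  r_hi <- hit_rate(0.5)
  expect_equal(r0, 1)
  expect_gte(r0, r_mid)
  expect_gte(r_mid, r_hi - 0.05)  # monotone within sampling noise
  expect_lt(r_hi, 1)
})
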