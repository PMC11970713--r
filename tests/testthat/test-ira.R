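test_that("P_F kernel matches direct evaluation", {
  # exact match in every dimension
  expect_equal(score_pf(c(8.2, 120), c(8.2, 120), c(0.01, 0.1), c(0.02, 0.2)), 1)
  # one dimension off by one combined standard deviation
  s <- sqrt(0.01^2 + 0.02^2)
  expect_equal(score_pf(8.2 + s, 8.2, 0.01, 0.02), exp(-0.5), tolerance = 1e-12)
  expect_equal(exp(-0.5), 0.6065, tolerance = 1e-4)
  # the 0.07 retention gate corresponds to ~2.3 combined deviations
  expect_equal(score_pf(8.2 + 2.305 * s, 8.2, 0.01, 0.02), 0.070,
               tolerance = 5e-3)
  # strictly decreasing in |mu - a|
  d <- seq(0, 0.2, by = 0.01)
  pf <- vapply(d, function(dd) score_pf(8.2 + dd, 8.2, 0.01, 0.02), numeric(1))
  expect_true(all(diff(pf) < 0))
  # density-normalized variant scales by the normal density prefactor
  expect_equal(score_pf(8.2, 8.2, 0.01, 0.02, normalized = TRUE),
               1 / sqrt(2 * pi * (0.01^2 + 0.02^2)))
})

test_that("P_D uses class priors without a template and Phi with one", {
  cfg <- ira_config()
  expect_equal(score_pd(NULL, "long", 0.15, cfg), 0.1)
  expect_equal(score_pd(NULL, "intra", 0.15, cfg), 1.0)
  expect_equal(score_pd(NULL, "sequential", 0.15, cfg), 0.5)
  # r_0 at the observability threshold: Phi(0) = 1/2
  expect_equal(score_pd(cfg$r_min, "long", 0.15, cfg), 0.5)
  # very short distance saturates at k_D
  expect_equal(score_pd(1.0, "long", 0.15, cfg), 1.0, tolerance = 1e-4)
  # nonincreasing in r_0
  r <- seq(1, 8, by = 0.25)
  pd <- vapply(r, function(rr) score_pd(rr, "long", 0.15, cfg), numeric(1))
  expect_true(all(diff(pd) <= 0))
  # ensemble averaging over template models
  expect_equal(score_pd(c(3, 6), "long", 0.1, cfg),
               mean(c(score_pd(3, "long", 0.1, cfg),
                      score_pd(6, "long", 0.1, cfg))))
})

test_that("P_D formula matches its printed form", {
  cfg <- ira_config()
  r0 <- 5.1
  sD <- 0.1
  z <- 6 * (cfg$r_min - r0) / sqrt(36 * sD^2 + 1.0^2)
  expect_equal(score_pd(r0, "long", sD, cfg), pnorm(z))
})

test_that("stripping keeps the per-peak maximum and applies a strict threshold", {
  cand <- data.frame(list_name = "a", peak_id = "p1",
                     form = "S", res_a = 1, atom_a = "HN",
                     res_b = c(5, 9, 12), atom_b = "HA",
                     sep_class = "long", p_f = 1, p_d = 1,
                     p = c(1.0, 0.05, 0.001), status = "active")
  out <- strip_candidates(cand, 50)
  expect_equal(out$status, c("active", "active", "stripped"))  # 0.05 > 1/50? no: strict <
  # single candidate survives any f
  single <- cand[1, ]
  expect_equal(strip_candidates(single, 1e6)$status, "active")
  # ties at P_max all survive
  tied <- cand
  tied$p <- c(0.5, 0.5, 0.5)
  expect_true(all(strip_candidates(tied, 50)$status == "active"))
  expect_error(strip_candidates(cand, 1), "> 1")
})

test_that("stripping equals brute-force application of P_i < P_max / f", {
  set.seed(11)
  for (rep in 1:10) {
    n_peaks <- sample(5:50, 1)
    rows <- do.call(rbind, lapply(seq_len(n_peaks), function(p) {
      k <- sample(1:6, 1)
      data.frame(list_name = "x", peak_id = sprintf("p%03d", p),
                 form = "S", res_a = 1, atom_a = "HN", res_b = seq_len(k),
                 atom_b = "HA", sep_class = "long", p_f = 1, p_d = 1,
                 p = runif(k), status = "active")
    }))
    f <- sample(c(5, 10, 20, 50), 1)
    got <- strip_candidates(rows, f)$status
    want <- unlist(lapply(split(rows$p, rows$peak_id)[unique(rows$peak_id)],
                          function(p) ifelse(p < max(p) / f, "stripped", "active")))
    expect_equal(got, unname(want))
  }
})

test_that("candidate generation finds exact-match assignments and gates on P_F", {
  sh <- shift_table(data.frame(
    residue_index = c(1, 1, 1, 2, 2, 2),
    residue_type = "A",
    atom = c("HN", "N", "HA", "HN", "N", "HA"),
    shift = c(8.10, 119.0, 4.20, 8.60, 124.0, 4.70),
    form = "S"))
  pk <- peak_list(rbind(c(8.10, 119.0, 4.70),   # HN(1)/N(1) -> HA(2)
                        c(5.00, 100.0, 3.00)),  # matches nothing
                  c("HN", "N", "H"), c(1, 1))
  cand <- generate_candidates(pk, sh)
  c1 <- cand[cand$peak_id == pk$peak_id[1], ]
  expect_true(any(c1$res_a == 1 & c1$res_b == 2 & c1$atom_b == "HA"))
  best <- c1[which.max(c1$p_f), ]
  expect_equal(best$res_a, 1)
  expect_gt(best$p_f, 0.99)
  expect_false(pk$peak_id[2] %in% cand$peak_id)
  expect_equal(attr(cand, "dropped_peaks")$peaks, pk$peak_id[2])
})

test_that("U-form candidates at short range are excluded as medium-range", {
  sh <- shift_table(data.frame(
    residue_index = rep(c(1, 2, 4), each = 3),
    residue_type = "A",
    atom = rep(c("HN", "N", "HA"), 3),
    shift = c(8.10, 119.0, 4.20, 8.12, 119.3, 4.22, 8.11, 119.1, 4.21),
    form = "U"))
  # peak at U-form positions of residue 1 amide and residue 4 HA: |1-4| = 3
  pk <- peak_list(rbind(c(8.10, 119.0, 4.21)), c("HN", "N", "H"), 1)
  cand <- generate_candidates(pk, sh)
  mr <- cand[cand$form == "U" & cand$res_a == 1 & cand$res_b == 4 &
               cand$atom_b == "HA", ]
  expect_true(nrow(mr) >= 1)
  expect_true(all(mr$status == "excluded_medium_range_U"))
  expect_true(all(cand$status[cand$form == "U"] == "excluded_medium_range_U"))
})

test_that("config validation rejects mismatched schedules", {
  expect_error(ira_config(f_schedule = c(50, 20)), "same length")
  expect_error(ira_config(f_schedule = c(1, 1, 1, 1, 1)), "> 1")
  cfg <- ira_config()
  expect_length(cfg$f_schedule, 5)
  expect_equal(cfg$sigma_D_schedule, c(0.15, 0.15, 0.15, 0.1, 0.05))
})

test_that("assignment-derived restraints calibrate against the weakest peak", {
  sh <- shift_table(data.frame(
    residue_index = rep(c(1, 5), each = 3), residue_type = "A",
    atom = rep(c("HN", "N", "HA"), 2),
    shift = c(8.10, 119.0, 4.20, 8.60, 124.0, 4.70), form = "S"))
  pk <- peak_list(rbind(c(8.10, 119.0, 4.70), c(8.60, 124.0, 4.20)),
                  c("HN", "N", "H"), c(64, 1))
  cand <- generate_candidates(pk, sh)
  cand <- irafold:::score_pd_all(cand, NULL, 1, ira_config())
  rs <- assignments_to_restraints(cand, list(peaks = pk))
  targets <- vapply(rs$distance, `[[`, numeric(1), "target")
  expect_equal(sort(targets), c(2.125, 4.25), tolerance = 1e-6)
  peak_of <- vapply(rs$distance, `[[`, character(1), "peak_id")
  expect_equal(targets[peak_of == pk$peak_id[2]], 4.25)
})
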