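mk_table <- function(shifts, atoms = "HN", res = seq_along(shifts),
                     types = "A", form = "S") {
  shift_table(data.frame(residue_index = res, residue_type = types,
                         atom = atoms, shift = shifts, form = form))
}

test_that("delta_rms matches hand evaluation of the truncated formula", {
  # single H atom, |ddelta| = 0.1, sigma = 1, tau = 0.02620: above 2*tau
  a <- mk_table(4.50, atoms = "HA")
  b <- mk_table(4.60, atoms = "HA")
  prof <- compute_delta_rms(a, b)
  expect_equal(prof$value, 0.01, tolerance = 1e-12)
  expect_equal(prof$n_atoms, 1L)

  # below the truncation threshold: |ddelta| = 0.03 < 2*tau = 0.0524
  b2 <- mk_table(4.53, atoms = "HA")
  expect_equal(compute_delta_rms(a, b2)$value, 0)

  # identical tables give zero everywhere
  big_a <- mk_table(c(8.1, 120.5, 4.3), atoms = c("HN", "N", "HA"),
                    res = c(1, 1, 1))
  expect_equal(compute_delta_rms(big_a, big_a)$value, 0)

  # apply_sqrt takes the root of the mean truncated square
  cfg <- csp_config(apply_sqrt = TRUE)
  expect_equal(compute_delta_rms(a, b, cfg)$value, 0.1)
})

test_that("delta_rms is symmetric, nonnegative and monotone above threshold", {
  set.seed(7)
  for (rep in 1:20) {
    n <- 6
    sa <- mk_table(8 + rnorm(n, sd = 0.3), res = 1:n)
    sb <- mk_table(8 + rnorm(n, sd = 0.3), res = 1:n)
    p1 <- compute_delta_rms(sa, sb)
    p2 <- compute_delta_rms(sb, sa)
    expect_equal(p1$value, p2$value)
    expect_true(all(p1$value >= 0))
    # increase one difference already above threshold: value cannot drop
    d <- abs(sa$shift - sb$shift)
    i <- which(d > 2 * 0.01977)[1]
    if (!is.na(i)) {
      sb2 <- sb
      sb2$shift[i] <- sb$shift[i] + sign(sb$shift[i] - sa$shift[i]) * 0.1
      p3 <- compute_delta_rms(sa, sb2)
      expect_true(all(p3$value >= p1$value - 1e-12))
    }
  }
})

test_that("residues without shared atoms are absent, not zero", {
  a <- mk_table(c(8.1, 8.3), atoms = c("HN", "HN"), res = c(1, 2))
  b <- mk_table(8.1, atoms = "HN", res = 1)
  prof <- compute_delta_rms(a, b)
  expect_equal(prof$residue_index, 1L)
})

test_that("tau estimation is the sample sd over reference residues", {
  a <- mk_table(c(8.10, 8.20), res = 1:2)
  b <- mk_table(c(8.11, 8.19), res = 1:2)  # differences -0.01, +0.01
  tau <- suppressWarnings(estimate_tau(a, b, reference_residues = 1:2))
  expect_equal(unname(tau["HN"]), sd(c(-0.01, 0.01)), tolerance = 1e-10)
  expect_equal(unname(tau["HN"]), 0.01414, tolerance = 1e-3)
  # untouched classes keep their defaults, warning per sparse class
  ws <- capture_warnings(tau2 <- estimate_tau(a, b, reference_residues = 1))
  expect_true(any(grepl("default", ws)))
  expect_equal(unname(tau2["HN"]), 0.01977)
  # zero differences give tau = 0
  tau3 <- suppressWarnings(estimate_tau(a, a, reference_residues = 1:2))
  expect_equal(unname(tau3["HN"]), 0)
})

test_that("titration tracking follows drift and flags dropout/reappearance", {
  mk_pt <- function(ratio, hn, n, ids = NULL) {
    list(ratio = ratio,
         peaks = peak_list(cbind(hn, n), c("HN", "N"), rep(1, length(hn)),
                           ids))
  }
  # peak 1 drifts steadily; peak 2 vanishes mid-series and reappears
  ser <- titration_series(list(
    mk_pt(0.0, c(8.00, 7.50), c(120.0, 115.0)),
    mk_pt(0.3, c(8.01, 7.51), c(120.1, 115.1)),
    mk_pt(0.6, c(8.02), c(120.2)),
    mk_pt(1.0, c(8.03, 7.60), c(120.3, 115.5))))
  tr <- track_titration(ser, c(HN = 0.12, N = 0.8))
  expect_equal(tr[[1]]$status, rep("matched", 4))
  expect_equal(unname(tr[[1]]$drift["HN"]), 0.03, tolerance = 1e-9)
  expect_equal(tr[[2]]$status, c("matched", "matched", "broadened_out",
                                 "reappeared"))
  expect_equal(unname(tr[[2]]$drift["N"]), 0.5, tolerance = 1e-9)
})

test_that("competing matches resolve by smallest displacement", {
  p0 <- list(ratio = 0, peaks = peak_list(cbind(c(8.00, 8.05), c(120, 120)),
                                          c("HN", "N"), c(1, 1)))
  p1 <- list(ratio = 1, peaks = peak_list(cbind(c(8.001, 8.049), c(120, 120)),
                                          c("HN", "N"), c(1, 1)))
  tr <- track_titration(titration_series(list(p0, p1)), c(HN = 0.06, N = 0.6))
  expect_equal(unname(tr[[1]]$drift["HN"]), 0.001, tolerance = 1e-9)
  expect_equal(unname(tr[[2]]$drift["HN"]), -0.001, tolerance = 1e-9)
})

test_that("binding-site ranking drops zeros and warns on oversized k", {
  prof <- structure(data.frame(residue_index = 1:4,
                               value = c(0, 0.4, 0.1, 0.2),
                               n_atoms = 1, atoms = "HN"),
                    class = c("csp_profile", "data.frame"))
  top <- rank_binding_site(prof, 2)
  expect_equal(top$residue_index, c(2L, 4L))
  expect_warning(all4 <- rank_binding_site(prof, 10), "exceeds")
  expect_equal(nrow(all4), 3)  # the zero residue never ranks
  flat <- prof; flat$value <- 0
  expect_message(none <- rank_binding_site(flat, 3), "flat")
  expect_equal(nrow(none), 0)
})
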