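# counting rules: nucleolus gate, adjacent-section exclusion, secondary and
# growing-follicle schemes, and counted-section morphometry

test_that("a nucleolus spanning two serial sections is counted exactly once", {
  # nucleolus centred on the z = 5000 section boundary spans both sections
  ov <- manual_ovary(follicle_at_z(5000))
  obs <- section_ovary(ov, exhaustive_plan(), seed = 1)
  spans <- obs$observations[obs$observations$nucleolus_hit, ]
  expect_equal(nrow(spans), 2)  # visible on both adjacent sections
  for (gate in c("center", "chord")) {
    cr <- count_follicles(obs, mode = "nucleolus_gated", gate = gate)
    expect_equal(cr$counts[["primordial"]], 1L, info = gate)
  }
})

test_that("a follicle whose nucleolus lies in unsampled sections is not counted", {
  # sampled runs are sections 0-4 of each group of 50; park the nucleolus in
  # section 10 (z 50-55 um)
  ov <- manual_ovary(follicle_at_z(52.5))
  obs <- section_ovary(ov, fixed_plan(), seed = 1)
  for (gate in c("center", "chord")) {
    cr <- count_follicles(obs, mode = "nucleolus_gated", gate = gate)
    expect_equal(sum(cr$counts), 0L, info = gate)
  }
})

test_that("exhaustive sampling recovers the brute-force count exactly", {
  for (seed in 4:6) {
    ov <- small_mixed_ovary(seed)
    obs <- section_ovary(ov, exhaustive_plan(), seed = seed)
    oracle <- exhaustive_oracle(ov)
    for (gate in c("center", "chord")) {
      cr <- count_follicles(obs, mode = "nucleolus_gated", gate = gate)
      expect_equal(cr$counts, oracle, info = paste(seed, gate))
    }
  }
})

test_that("profile-presence counts dominate nucleolus-gated counts", {
  for (seed in 1:4) {
    ov <- small_mixed_ovary(seed)
    obs <- section_ovary(ov, sampling_plan(), seed = seed)
    gated <- count_follicles(obs, mode = "nucleolus_gated")
    naive <- count_follicles(obs, mode = "profile_presence")
    expect_true(all(naive$counts >= gated$counts), info = seed)
  }
})

test_that("unknown stage labels and unordered observations are rejected", {
  ov <- small_mixed_ovary(1)
  obs <- section_ovary(ov, fixed_plan(), seed = 1)
  bad <- obs
  bad$observations$stage[1] <- "tertiary"
  expect_error(count_follicles(bad), "unknown follicle stage")
  shuffled <- obs
  shuffled$observations <- shuffled$observations[rev(seq_len(
    nrow(shuffled$observations))), ]
  expect_error(count_follicles(shuffled), "ordered")
})

test_that("the relative secondary scheme demands its 1-of-50 plan", {
  ov <- small_mixed_ovary(1)
  obs_bad <- section_ovary(ov, sampling_plan(), seed = 1)
  expect_error(count_secondary_relative(obs_bad), "run_length = 1")

  plan1 <- sampling_plan(run_length = 1, run_start = 1, slab_start = 1)
  none <- generate_ovary(c(primordial = 50), semi_axes = c(5000, 3000, 2500),
                         seed = 2)
  expect_equal(count_secondary_relative(section_ovary(none, plan1, seed = 1)),
               0L, ignore_attr = TRUE)

  # one secondary follicle whose nucleolus sits in a sampled section (idx 0)
  one <- manual_ovary(follicle_at_z(2.5, stage = "secondary",
                                    d_follicle = 150, d_oocyte = 80,
                                    d_nucleus = 30, d_nucleolus = 5))
  expect_equal(count_secondary_relative(section_ovary(one, plan1, seed = 1)),
               1L, ignore_attr = TRUE)
})

test_that("relative secondary counts preserve known abundance ratios", {
  # two cohorts whose true secondary numbers differ 2:1; the scheme has no
  # scale-up, so only the ratio of mean raw counts is meaningful
  plan1 <- sampling_plan(run_length = 1)
  mean_count <- function(n_sec, seeds) {
    mean(vapply(seeds, function(s) {
      ov <- generate_ovary(c(secondary = n_sec),
                           semi_axes = c(4000, 3000, 2500),
                           cortex_thickness = 1500, seed = s)
      as.numeric(count_secondary_relative(section_ovary(ov, plan1, seed = s)))
    }, numeric(1)))
  }
  rich <- mean_count(800, 1:150)
  poor <- mean_count(400, 151:300)
  expect_gt(rich / poor, 1.5)
  expect_lt(rich / poor, 2.6)
})

test_that("growing-follicle raw counts match a direct geometry oracle", {
  plan1 <- sampling_plan(run_length = 1, run_start = 1, slab_start = 1)
  prim_only <- generate_ovary(c(primordial = 80),
                              semi_axes = c(5000, 3000, 2500), seed = 3)
  raw0 <- count_growing_raw(section_ovary(prim_only, plan1, seed = 1))
  expect_true(all(raw0$n_growing == 0))

  # three growing follicles straddling one sampled section (z 0-5 of slab 3)
  built <- manual_ovary(rbind(
    follicle_at_z(3001, stage = "primary", d_follicle = 60, d_oocyte = 45,
                  d_nucleus = 22, d_nucleolus = 4),
    follicle_at_z(3004, stage = "secondary", d_follicle = 150, d_oocyte = 80,
                  d_nucleus = 30, d_nucleolus = 5),
    follicle_at_z(3020, stage = "antral", d_follicle = 900, d_oocyte = 110,
                  d_nucleus = 35, d_nucleolus = 6),
    follicle_at_z(3002, stage = "primordial", d_follicle = 35, d_oocyte = 30,
                  d_nucleus = 18, d_nucleolus = 3)))
  raw3 <- count_growing_raw(section_ovary(built, plan1, seed = 1))
  expect_equal(raw3$n_growing[raw3$slab_index == 3 & raw3$section_index == 0],
               3L)

  # randomized ovary against brute-force per-section intersection counting
  ov <- small_mixed_ovary(9)
  obs <- section_ovary(ov, plan1, seed = 9)
  raw <- count_growing_raw(obs)
  f <- ov$follicles
  z0 <- f$cz + ov$semi_axes[1]
  fr <- obs$frames[obs$frames$sampled, ]
  oracle <- vapply(seq_len(nrow(fr)), function(i) {
    sum(f$stage %in% c("primary", "secondary", "antral") &
          z0 - f$d_oocyte / 2 < fr$z_hi[i] & z0 + f$d_oocyte / 2 > fr$z_lo[i])
  }, numeric(1))
  expect_equal(raw$n_growing[order(raw$z_lo)], as.integer(oracle[order(fr$z_lo)]))
})

test_that("morphometry reads diameters in the counted section", {
  # follicle counted at its equatorial section: profile equals true diameter
  ov <- manual_ovary(follicle_at_z(5002.5))
  cr <- count_follicles(section_ovary(ov, exhaustive_plan(), seed = 1))
  m <- measure_primordial_diameters(cr)
  expect_equal(m$n, 1)
  expect_equal(m$mean_oocyte_diameter, 30)
  expect_equal(m$mean_nucleus_diameter, 18)

  none <- generate_ovary(c(primary = 5), semi_axes = c(5000, 3000, 2500),
                         seed = 1)
  m0 <- measure_primordial_diameters(
    count_follicles(section_ovary(none, exhaustive_plan(), seed = 1)))
  expect_equal(m0$n, 0)
  expect_false(m0$defined)
  expect_true(is.na(m0$mean_oocyte_diameter))
})
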