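# slabs, systematic slab selection, serial runs, and intersection geometry

test_that("slab cutting tiles the long-axis extent with a ceiling rule", {
  plan <- sampling_plan()
  ten <- cut_slabs(list(semi_axes = c(5000, 3000, 2500)), plan)
  expect_equal(nrow(ten), 10)
  expect_equal(ten$z_hi - ten$z_lo, rep(1000, 10))

  eleven <- cut_slabs(list(semi_axes = c(5250, 3000, 2500)), plan)
  expect_equal(nrow(eleven), 11)
  expect_equal(eleven$z_hi[11] - eleven$z_lo[11], 500)
  expect_equal(eleven$z_lo[-1], eleven$z_hi[-11])  # contiguous

  degenerate <- cut_slabs(list(semi_axes = c(0, 0, 0)), plan)
  expect_equal(nrow(degenerate), 0)
})

test_that("systematic slab selection enumerates start, start+interval, ...", {
  plan3 <- sampling_plan(slab_start = 2)
  nine <- cut_slabs(list(semi_axes = c(4500, 3000, 2500)), plan3)
  sel <- select_slabs(nine, plan3)
  expect_equal(sel$indices, c(1L, 4L, 7L))
  expect_equal(sel$realized_f2, 1 / 3)

  plan1 <- sampling_plan(slab_start = 1)
  ten <- cut_slabs(list(semi_axes = c(5000, 3000, 2500)), plan1)
  sel10 <- select_slabs(ten, plan1)
  expect_equal(sel10$indices, c(0L, 3L, 6L, 9L))
  expect_equal(sel10$realized_f2, 0.4)  # realized, not the nominal 1/3

  all_plan <- sampling_plan(slab_interval = 1, slab_start = 1)
  expect_equal(select_slabs(ten, all_plan)$realized_f2, 1)

  wide <- sampling_plan(slab_interval = 20, slab_start = 1)
  expect_warning(sel_w <- select_slabs(ten, wide), "exceeds")
  expect_lte(length(sel_w$indices), 1)
})

test_that("random slab starts are seed-deterministic", {
  plan <- sampling_plan()
  slabs <- cut_slabs(list(semi_axes = c(5000, 3000, 2500)), plan)
  expect_identical(select_slabs(slabs, plan, seed = 3),
                   select_slabs(slabs, plan, seed = 3))
})

test_that("serial-run flagging matches direct enumeration", {
  plan <- fixed_plan()
  full <- select_serial_runs(list(slab_index = 0L, z_lo = 0, z_hi = 1000),
                             plan)
  expect_equal(nrow(full), 200)
  expect_equal(which(full$sampled) - 1L,
               c(0:4, 50:54, 100:104, 150:154))
  expect_equal(attr(full, "realized_f3"), 0.1)

  all_plan <- sampling_plan(run_length = 50, run_start = 1, slab_start = 1)
  expect_equal(attr(select_serial_runs(list(slab_index = 0L, z_lo = 0,
                                            z_hi = 1000), all_plan),
                    "realized_f3"), 1)

  # partial slab of 30 sections against an explicit enumeration oracle
  partial <- select_serial_runs(list(slab_index = 3L, z_lo = 3000,
                                     z_hi = 3150), plan)
  oracle <- vapply(0:29, function(i) (i %% 50) < 5, logical(1))
  expect_equal(partial$sampled, oracle)
  expect_equal(which(partial$sampled) - 1L, 0:4)
  expect_equal(attr(partial, "realized_f3"), 5 / 30)
})

test_that("run offsets are reused across groups, or re-drawn per slab on request", {
  ov <- small_mixed_ovary(1)
  obs <- section_ovary(ov, sampling_plan(), seed = 2)
  expect_length(obs$run_start, 1)
  pos <- obs$frames$section_index[obs$frames$sampled] %% 50
  expect_true(all(pos >= obs$run_start - 1 & pos <= obs$run_start + 3))

  obs2 <- section_ovary(ov, sampling_plan(run_start_per_slab = TRUE), seed = 2)
  expect_length(obs2$run_start, length(unique(obs2$frames$slab_index)))
})

test_that("section frames tile each slab exactly, half-open", {
  plan <- sampling_plan()
  for (width in c(1000, 150, 997)) {  # exact, partial-group, remainder cases
    fr <- select_serial_runs(list(slab_index = 0L, z_lo = 200, z_hi = 200 + width),
                             plan, run_start = 1)
    expect_equal(fr$z_lo[1], 200)
    expect_equal(fr$z_hi[nrow(fr)], 200 + width)
    expect_equal(fr$z_lo[-1], fr$z_hi[-nrow(fr)])
    expect_true(all(fr$z_hi > fr$z_lo))
  }
})

test_that("profile diameter follows the chord formula and peaks at the equator", {
  ov <- manual_ovary(follicle_at_z(5002.5))  # oocyte centred mid-section
  eq <- observe_section(ov, list(z_lo = 5000, z_hi = 5005))
  expect_equal(eq$oocyte_profile, 30)
  expect_equal(eq$nucleus_profile, 18)

  # centre 2.5 um above the mid-plane of the section below
  off <- observe_section(manual_ovary(follicle_at_z(5000)),
                         list(z_lo = 4995, z_hi = 5000))
  expect_equal(off$oocyte_profile, 2 * sqrt(15^2 - 2.5^2))  # 29.5804
  expect_equal(off$nucleus_profile, 2 * sqrt(9^2 - 2.5^2))

  # moving the centre away from the mid-plane shrinks the profile monotonically
  mids <- seq(0, 20, by = 2.5)
  profs <- vapply(mids, function(dz) {
    o <- observe_section(manual_ovary(follicle_at_z(5000 + dz)),
                         list(z_lo = 4997.5, z_hi = 5002.5))
    if (nrow(o)) o$oocyte_profile else 0
  }, numeric(1))
  expect_true(all(diff(profs) <= 1e-12))
  expect_true(all(profs <= 30 + 1e-12))
})

test_that("half-open frames assign a boundary nucleolus to exactly one section", {
  # nucleolus z-extent [97, 100) against frames [95, 100) and [100, 105)
  ov <- manual_ovary(follicle_at_z(98.5), semi_axes = c(5000, 3000, 2500))
  lower <- observe_section(ov, list(z_lo = 95, z_hi = 100))
  upper <- observe_section(ov, list(z_lo = 100, z_hi = 105))
  expect_true(lower$nucleolus_hit)
  expect_false(upper$nucleolus_hit)
  expect_true(lower$nucleolus_center_in)
  expect_false(upper$nucleolus_center_in)
})

test_that("vectorized frame observation agrees with per-section observation", {
  ov <- small_mixed_ovary(3)
  obs <- section_ovary(ov, fixed_plan(), seed = 1)
  fr <- obs$frames[obs$frames$sampled, ]
  direct <- do.call(rbind, lapply(seq_len(nrow(fr)), function(i) {
    p <- observe_section(ov, fr[i, ])
    if (nrow(p)) cbind(z_lo = fr$z_lo[i], p) else NULL
  }))
  direct <- direct[order(direct$z_lo, direct$follicle_id), ]
  got <- obs$observations
  expect_equal(nrow(got), nrow(direct))
  for (col in c("follicle_id", "oocyte_profile", "nucleus_profile",
                "nucleolus_hit", "nucleolus_chord", "nucleolus_center_in")) {
    expect_equal(got[[col]], direct[[col]], info = col)
  }
})

test_that("a sphere of diameter d hits (d + t)/t sections on average", {
  # d chosen off the section-thickness lattice so the hit count is random
  sizes <- stage_size_defaults()
  sizes$primordial <- list(follicle = 32, oocyte = 32, nucleus = 12,
                           nucleolus = 3, cv = 0)
  ov <- generate_ovary(c(primordial = 2000), semi_axes = c(4000, 3000, 2500),
                       placement = "whole", sizes = sizes, seed = 21)
  obs <- section_ovary(ov, exhaustive_plan(), seed = 1)
  hits <- table(obs$observations$follicle_id)
  expect_equal(length(hits), 2000)  # every sphere hits at least one section
  se <- sd(hits) / sqrt(length(hits))
  expect_lt(abs(mean(hits) - (32 + 5) / 5), 3 * se)
})

test_that("every positive-diameter nucleolus intersects a section of its slab", {
  for (seed in c(11, 12)) {
    ov <- small_mixed_ovary(seed)
    obs <- section_ovary(ov, exhaustive_plan(), seed = seed)
    hit_ids <- unique(obs$observations$follicle_id[obs$observations$nucleolus_hit])
    expect_setequal(hit_ids, ov$follicles$id)
  }
})
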