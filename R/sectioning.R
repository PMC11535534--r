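# Virtual microtome: slabs, systematic slab selection, serial-run section
# subsampling, and sphere-section intersection geometry.
#
# Coordinates: z runs along the ovary's long axis with the origin at the
# lower pole, so the organ occupies [0, 2 * semi_axes[1]). All slab and
# section intervals are half-open [z_lo, z_hi); a z exactly on a boundary
# belongs to the upper interval, which removes any double-counting ambiguity.

pole_z <- function(model) model$follicles$cz + model$semi_axes[1]

#' Cut an ovary into slabs perpendicular to its long axis
#'
#' Partitions the organ's long-axis extent into contiguous half-open slabs of
#' the plan's slab thickness; a final partial slab (width < slab thickness)
#' is kept so the slabs tile the whole extent.
#'
#' @param model an `ovary_model` (only its long semi-axis is used).
#' @param plan a [sampling_plan()].
#' @return data frame with columns `slab_index` (0-based), `z_lo`, `z_hi`
#'   (micrometre, pole-based); zero rows if the extent is zero.
#' @export
cut_slabs <- function(model, plan) {
  extent <- 2 * model$semi_axes[1]
  if (extent <= 0) {
    return(data.frame(slab_index = integer(0), z_lo = numeric(0),
                      z_hi = numeric(0)))
  }
  n <- ceiling(extent / plan$slab_thickness - 1e-9)
  z_lo <- (seq_len(n) - 1) * plan$slab_thickness
  data.frame(slab_index = seq_len(n) - 1L, z_lo = z_lo,
             z_hi = pmin(z_lo + plan$slab_thickness, extent))
}

#' Systematic uniform random slab selection
#'
#' Implements systematic random sampling of slabs: a start slab is drawn
#' uniformly within the first sampling interval (or fixed by the plan) and
#' every `slab_interval`-th slab from there is kept. The realized slab
#' fraction f2 = kept/total is returned; it is this realized value, not the
#' nominal 1/interval, that enters the estimator.
#'
#' @param slabs output of [cut_slabs()].
#' @param plan a [sampling_plan()].
#' @param seed integer seed, used only when the plan's `slab_start` is
#'   `"random"`.
#' @return list with `indices` (0-based kept slab indices), `slab_start`
#'   (the realized 1-based start) and `realized_f2`.
#' @export
select_slabs <- function(slabs, plan, seed = 1L) {
  n <- nrow(slabs)
  if (n == 0L) {
    return(list(indices = integer(0), slab_start = NA_integer_,
                realized_f2 = NA_real_))
  }
  start <- if (identical(plan$slab_start, "random")) {
    withr::with_seed(as.integer(seed), sample.int(plan$slab_interval, 1L))
  } else {
    plan$slab_start
  }
  if (plan$slab_interval > n) {
    warning("slab interval (", plan$slab_interval, ") exceeds the number of ",
            "slabs (", n, "); at most one slab is selected", call. = FALSE)
  }
  idx <- seq.int(start - 1L, n - 1L, by = plan$slab_interval)
  idx <- idx[idx >= 0L & idx < n]
  list(indices = as.integer(idx), slab_start = as.integer(start),
       realized_f2 = length(idx) / n)
}

# enumerate the section frames of one slab; a remainder narrower than one
# section becomes a final partial frame so the frames tile the slab exactly
section_frames <- function(slab_index, z_lo, z_hi, plan) {
  width <- z_hi - z_lo
  t <- plan$section_thickness
  n_full <- floor(width / t + 1e-9)
  lo <- z_lo + t * seq_len(n_full) - t
  hi <- lo + t
  if (n_full == 0L || z_hi - hi[n_full] > 1e-9) {
    lo <- c(lo, z_lo + t * n_full)
    hi <- c(hi, z_hi)
  } else {
    hi[n_full] <- z_hi  # absorb float dust so tiling is exact
  }
  data.frame(slab_index = slab_index, section_index = seq_along(lo) - 1L,
             z_lo = lo, z_hi = hi)
}

#' Flag the serial runs of sections collected from one slab
#'
#' Enumerates a slab's sections and flags as sampled, within every
#' consecutive group of `group_size` sections, the serial run of
#' `run_length` sections beginning at `run_start`. A run truncated by the end
#' of a partial group keeps its available sections; the realized section
#' fraction f3 (sampled/total in the slab) reflects the truncation.
#'
#' @param slab one-row data frame (or list) with `slab_index`, `z_lo`, `z_hi`.
#' @param plan a [sampling_plan()].
#' @param seed integer seed, used only when the plan's `run_start` is
#'   `"random"`.
#' @param run_start optional fixed 1-based run offset overriding the plan
#'   (used to reuse one ovary-level offset across slabs).
#' @return data frame of frames with a logical `sampled` column and an
#'   attribute `realized_f3`.
#' @export
select_serial_runs <- function(slab, plan, seed = 1L, run_start = NULL) {
  if (is.null(run_start)) {
    run_start <- if (identical(plan$run_start, "random")) {
      withr::with_seed(as.integer(seed),
                       sample.int(plan$group_size - plan$run_length + 1L, 1L))
    } else {
      plan$run_start
    }
  }
  fr <- section_frames(slab$slab_index, slab$z_lo, slab$z_hi, plan)
  pos <- fr$section_index %% plan$group_size
  fr$sampled <- pos >= run_start - 1L & pos <= run_start + plan$run_length - 2L
  attr(fr, "realized_f3") <- mean(fr$sampled)
  attr(fr, "run_start") <- as.integer(run_start)
  fr
}

# shared profile geometry: one section frame against a follicle table
# (z coordinates pole-based)
profiles_in_frame <- function(fol, z0, z_lo, z_hi, threshold = 0) {
  r_oo <- fol$d_oocyte / 2
  hit <- z0 - r_oo < z_hi & z0 + r_oo > z_lo
  idx <- which(hit)
  build_profiles(fol, z0, idx, rep(z_lo, length(idx)), rep(z_hi, length(idx)),
                 threshold)
}

build_profiles <- function(fol, z0, idx, z_lo, z_hi, threshold) {
  z0 <- z0[idx]
  mid <- (z_lo + z_hi) / 2
  zn <- z0 + fol$off_z[idx]
  dn <- fol$d_nucleolus[idx]
  nucleolus_hit <- zn - dn / 2 < z_hi & zn + dn / 2 > z_lo
  # chord read at the in-section plane closest to the nucleolus center
  plane <- pmin(pmax(zn, z_lo), z_hi)
  chord <- ifelse(nucleolus_hit, sphere_chord(dn, zn - plane), 0)
  data.frame(
    follicle_id = fol$id[idx],
    stage = as.character(fol$stage[idx]),
    oocyte_profile = sphere_chord(fol$d_oocyte[idx], z0 - mid),
    nucleus_profile = sphere_chord(fol$d_nucleus[idx], z0 - mid),
    nucleolus_hit = nucleolus_hit,
    nucleolus_chord = chord,
    nucleolus_center_in = zn >= z_lo & zn < z_hi,
    nucleolus_visible = nucleolus_hit & chord >= threshold,
    stringsAsFactors = FALSE
  )
}

#' Observe one section of an ovary
#'
#' Emits the profile a histologist would see on a single section: every
#' follicle whose oocyte sphere intersects the half-open section slab
#' `[z_lo, z_hi)` contributes a profile. Oocyte and nucleus profile diameters
#' are the chord diameters at the section mid-plane; the nucleolus is tested
#' for intersection against the full section thickness and its chord is read
#' at the in-section plane closest to the nucleolus center (the plane where
#' it is sharpest). `nucleolus_center_in` marks the unique section containing
#' the nucleolus midpoint.
#'
#' @param model an `ovary_model`.
#' @param frame list or one-row data frame with `z_lo`, `z_hi` (pole-based
#'   micrometre).
#' @param threshold minimum nucleolus chord (micrometre) for
#'   `nucleolus_visible`; 0 means any intersection is visible.
#' @return data frame of profiles (possibly zero rows).
#' @export
observe_section <- function(model, frame, threshold = 0) {
  stopifnot(frame$z_hi > frame$z_lo)
  profiles_in_frame(model$follicles, pole_z(model), frame$z_lo, frame$z_hi,
                    threshold)
}

#' Apply a sampling plan to an ovary
#'
#' Runs the whole physical sampling chain on a synthetic ovary: slab cutting,
#' systematic random slab selection, section enumeration and serial-run
#' flagging, and per-section observation of every sampled section. Random
#' design offsets (slab start, run start) are drawn from `seed` in a fixed
#' order: slab start first, then the run start (or one per slab when the plan
#' says so).
#'
#' Serial runs are identified as maximal stretches of physically contiguous
#' sampled sections (merged across slab boundaries when adjacent slabs are
#' both kept, as in exhaustive plans); the run id drives the
#' adjacent-section exclusion at counting time.
#'
#' @param model an `ovary_model` (already thinned by [thin_available()] if
#'   `f1 < 1`).
#' @param plan a [sampling_plan()].
#' @param seed integer seed for the design's random offsets.
#' @param threshold nucleolus visibility threshold, micrometre.
#' @param ovary_id identifier carried into downstream tables.
#' @return an object of class `section_obs`: list with `frames` (all frames
#'   of the selected slabs, with `sampled` and `run_id`), `observations`
#'   (one row per follicle profile on a sampled section, ordered by section
#'   then follicle), the realized fractions `f1`, `realized_f2`,
#'   `realized_f3`, the realized `slab_start`/`run_start`, `plan` and
#'   `ovary_id`.
#' @export
section_ovary <- function(model, plan = sampling_plan(), seed = 1L,
                          threshold = 0, ovary_id = "ovary1") {
  stopifnot(inherits(model, "ovary_model"), inherits(plan, "sampling_plan"))
  slabs <- cut_slabs(model, plan)
  seed <- as.integer(seed)
  sel <- select_slabs(slabs, plan, seed = seed)
  kept <- slabs[slabs$slab_index %in% sel$indices, , drop = FALSE]

  # design offsets drawn in documented order from one derived stream
  n_starts <- if (plan$run_start_per_slab) nrow(kept) else 1L
  run_starts <- if (identical(plan$run_start, "random")) {
    withr::with_seed(seed + 1L,
                     sample.int(plan$group_size - plan$run_length + 1L,
                                n_starts, replace = TRUE))
  } else {
    rep(plan$run_start, n_starts)
  }

  frames <- do.call(rbind, lapply(seq_len(nrow(kept)), function(i) {
    rs <- if (plan$run_start_per_slab) run_starts[i] else run_starts[1L]
    select_serial_runs(kept[i, ], plan, run_start = rs)
  }))
  if (is.null(frames)) {
    stop("no slabs selected; extent or slab interval is degenerate",
         call. = FALSE)
  }
  frames <- frames[order(frames$z_lo), , drop = FALSE]
  rownames(frames) <- NULL
  n <- nrow(frames)
  contiguous <- c(FALSE, abs(frames$z_lo[-1] - frames$z_hi[-n]) < 1e-6)
  starts <- frames$sampled & !(contiguous & c(FALSE, frames$sampled[-n]))
  frames$run_id <- cumsum(starts)
  frames$run_id[!frames$sampled] <- NA_integer_

  obs <- observe_frames(model, frames[frames$sampled, , drop = FALSE],
                        threshold)
  structure(list(frames = frames, observations = obs,
                 f1 = model$f1,
                 realized_f2 = sel$realized_f2,
                 realized_f3 = mean(frames$sampled),
                 slab_start = sel$slab_start,
                 run_start = run_starts,
                 plan = plan, threshold = threshold,
                 ovary_id = ovary_id, seed = seed),
            class = "section_obs")
}

# vectorized sphere-frame intersection over sorted, non-overlapping frames:
# for each follicle the intersecting frames form a contiguous index range
observe_frames <- function(model, fr, threshold = 0) {
  fol <- model$follicles
  empty <- data.frame(slab_index = integer(0), section_index = integer(0),
                      z_lo = numeric(0), z_hi = numeric(0),
                      sampled = logical(0), run_id = integer(0),
                      follicle_id = integer(0), stage = character(0),
                      oocyte_profile = numeric(0), nucleus_profile = numeric(0),
                      nucleolus_hit = logical(0), nucleolus_chord = numeric(0),
                      nucleolus_center_in = logical(0),
                      nucleolus_visible = logical(0))
  if (nrow(fol) == 0L || nrow(fr) == 0L) return(empty)
  z0 <- pole_z(model)
  zl <- z0 - fol$d_oocyte / 2
  zu <- z0 + fol$d_oocyte / 2
  first <- findInterval(zl, fr$z_hi) + 1L             # first frame with z_hi > zl
  last <- findInterval(zu, fr$z_lo, left.open = TRUE) # last frame with z_lo < zu
  n_i <- pmax(0L, last - first + 1L)
  if (sum(n_i) == 0L) return(empty)
  fol_idx <- rep.int(seq_len(nrow(fol)), n_i)
  frame_idx <- sequence(n_i, from = first)
  prof <- build_profiles(fol, z0, fol_idx, fr$z_lo[frame_idx],
                         fr$z_hi[frame_idx], threshold)
  out <- cbind(fr[frame_idx, c("slab_index", "section_index", "z_lo", "z_hi",
                               "sampled", "run_id")], prof)
  out <- out[order(out$z_lo, out$follicle_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.section_obs <- function(x, ...) {
  cat("Virtual sectioning of", x$ovary_id, "\n")
  cat(sprintf("  %d frames in %d selected slabs; %d sampled sections in runs\n",
              nrow(x$frames), length(unique(x$frames$slab_index)),
              sum(x$frames$sampled)))
  cat(sprintf("  realized fractions: f1 = %.4g, f2 = %.4g, f3 = %.4g\n",
              x$f1, x$realized_f2, x$realized_f3))
  cat(sprintf("  %d follicle profiles observed on sampled sections\n",
              nrow(x$observations)))
  invisible(x)
}

#' Write / read a section observation table
#'
#' Tab-separated serialization of the sampled-section observations, with the
#' realized sampling fractions and the plan's run geometry stored as
#' `# key=value` header comments so counting can run from the file alone.
#'
#' @param obs a `section_obs`.
#' @param path file path.
#' @return `write_sections()` returns the path invisibly; `read_sections()`
#'   returns a `section_obs` (without the frame list).
#' @export
write_sections <- function(obs, path) {
  stopifnot(inherits(obs, "section_obs"))
  write_tsv(obs$observations, path, comments = c(
    sprintf("ovary_id=%s", obs$ovary_id),
    sprintf("f1=%s", format(obs$f1, digits = 15)),
    sprintf("f2=%s", format(obs$realized_f2, digits = 15)),
    sprintf("f3=%s", format(obs$realized_f3, digits = 15)),
    sprintf("group_size=%d", obs$plan$group_size),
    sprintf("run_length=%d", obs$plan$run_length)
  ))
  invisible(path)
}

#' @rdname write_sections
#' @export
read_sections <- function(path) {
  meta <- read_tsv_comments(path)
  df <- read_tsv(path)
  check_stage(df$stage)
  plan_stub <- sampling_plan(group_size = as.integer(meta$group_size %||% 50L),
                             run_length = as.integer(meta$run_length %||% 5L))
  structure(list(frames = NULL, observations = df,
                 f1 = meta$f1 %||% 1,
                 realized_f2 = meta$f2 %||% 1,
                 realized_f3 = meta$f3 %||% 1,
                 plan = plan_stub,
                 ovary_id = as.character(meta$ovary_id %||% "ovary1")),
            class = "section_obs")
}
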