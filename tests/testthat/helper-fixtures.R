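# fixtures are built in code: hand-assembled ovary models for geometric edge
# cases, plus a default small ovary for pipeline tests

# hand-build an ovary_model from an explicit follicle table; defaults give a
# primordial-sized follicle at the ovary centroid with a centred nucleolus
manual_ovary <- function(follicles, semi_axes = c(5000, 3000, 2500),
                         cortex_thickness = min(semi_axes), f1 = 1,
                         overlap_allowed = TRUE) {
  defaults <- data.frame(stage = "primordial", cx = 0, cy = 0, cz = 0,
                         d_follicle = 35, d_oocyte = 30, d_nucleus = 18,
                         d_nucleolus = 3, off_x = 0, off_y = 0, off_z = 0)
  for (col in names(defaults)) {
    if (is.null(follicles[[col]])) follicles[[col]] <- defaults[[col]]
  }
  follicles$id <- seq_len(nrow(follicles))
  structure(list(semi_axes = semi_axes, cortex_thickness = cortex_thickness,
                 f1 = f1, seed = 0L, placement = "whole",
                 overlap_allowed = overlap_allowed,
                 follicles = follicles[, c("id", "stage", "cx", "cy", "cz",
                                           "d_follicle", "d_oocyte",
                                           "d_nucleus", "d_nucleolus",
                                           "off_x", "off_y", "off_z")]),
            class = "ovary_model")
}

# follicle whose nucleolus z-centre sits at pole coordinate z (cz = z - a)
follicle_at_z <- function(z, semi_axes = c(5000, 3000, 2500), ...) {
  data.frame(cz = z - semi_axes[1], ...)
}

small_mixed_ovary <- function(seed, n = c(primordial = 30, primary = 10,
                                          secondary = 5, antral = 2)) {
  generate_ovary(n, semi_axes = c(5000, 3000, 2500), cortex_thickness = 1500,
                 seed = seed)
}

# fully deterministic plan variants (no random design offsets)
fixed_plan <- function(...) sampling_plan(slab_start = 1L, run_start = 1L, ...)
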