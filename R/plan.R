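#' Define the physical sampling design
#'
#' The three-level fractionator design applied to an ovary: the organ is cut
#' into slabs of `slab_thickness` perpendicular to its long axis; every
#' `slab_interval`-th slab is kept, starting from a (systematic uniform
#' random) start slab; each kept slab is cut into sections of
#' `section_thickness`; and within every consecutive group of `group_size`
#' sections a serial run of `run_length` sections, beginning at `run_start`,
#' is collected. The defaults encode the design used for primordial/primary
#' follicles in the human study this package simulates: 1-mm slabs, one slab
#' in three, 5-um sections, 5 serial sections of every 50.
#'
#' `slab_start` and `run_start` may be `"random"` (drawn once per ovary from
#' the sectioning seed) or fixed integers; fixed values make the whole design
#' deterministic. `run_start_per_slab = TRUE` re-draws the serial-run offset
#' for every slab instead of reusing one offset across the ovary.
#'
#' @param slab_thickness slab thickness, micrometre (default 1000).
#' @param slab_interval keep every `slab_interval`-th slab (default 3).
#' @param slab_start `"random"` or integer in `1:slab_interval`.
#' @param section_thickness section thickness, micrometre (default 5).
#' @param group_size sections per sampling group (default 50).
#' @param run_length serial sections collected per group (default 5).
#' @param run_start `"random"` or integer in `1:(group_size - run_length + 1)`.
#' @param run_start_per_slab re-randomize the run offset per slab?
#' @return an object of class `sampling_plan`.
#' @seealso [exhaustive_plan()], [section_ovary()]
#' @examples
#' sampling_plan()                      # the primordial/primary design
#' sampling_plan(run_length = 1)        # the relative secondary design
#' @export
sampling_plan <- function(slab_thickness = 1000,
                          slab_interval = 3L,
                          slab_start = "random",
                          section_thickness = 5,
                          group_size = 50L,
                          run_length = 5L,
                          run_start = "random",
                          run_start_per_slab = FALSE) {
  if (slab_thickness <= 0 || section_thickness <= 0) {
    stop("slab and section thickness must be > 0", call. = FALSE)
  }
  if (section_thickness > slab_thickness) {
    stop("`section_thickness` must not exceed `slab_thickness`", call. = FALSE)
  }
  slab_interval <- as.integer(slab_interval)
  group_size <- as.integer(group_size)
  run_length <- as.integer(run_length)
  if (slab_interval < 1L) stop("`slab_interval` must be >= 1", call. = FALSE)
  if (run_length < 1L || run_length > group_size) {
    stop("need 1 <= run_length <= group_size", call. = FALSE)
  }
  if (!identical(slab_start, "random")) {
    slab_start <- as.integer(slab_start)
    if (slab_start < 1L || slab_start > slab_interval) {
      stop("`slab_start` must be 'random' or in 1:slab_interval", call. = FALSE)
    }
  }
  if (!identical(run_start, "random")) {
    run_start <- as.integer(run_start)
    if (run_start < 1L || run_start > group_size - run_length + 1L) {
      stop("`run_start` must be 'random' or in 1:(group_size - run_length + 1)",
           call. = FALSE)
    }
  }
  structure(list(slab_thickness = slab_thickness,
                 slab_interval = slab_interval,
                 slab_start = slab_start,
                 section_thickness = section_thickness,
                 group_size = group_size,
                 run_length = run_length,
                 run_start = run_start,
                 run_start_per_slab = isTRUE(run_start_per_slab)),
            class = "sampling_plan")
}

#' Exhaustive sampling plan
#'
#' A degenerate design that keeps every slab and every section
#' (f2 = f3 = 1); under it the nucleolus-gated pipeline must recover the true
#' follicle count exactly, which anchors the simulator's correctness tests.
#'
#' @inheritParams sampling_plan
#' @return a `sampling_plan` with `slab_interval = 1` and
#'   `run_length = group_size`.
#' @export
exhaustive_plan <- function(slab_thickness = 1000, section_thickness = 5,
                            group_size = 50L) {
  sampling_plan(slab_thickness = slab_thickness, slab_interval = 1L,
                slab_start = 1L, section_thickness = section_thickness,
                group_size = group_size, run_length = group_size,
                run_start = 1L)
}

#' @export
print.sampling_plan <- function(x, ...) {
  cat("Fractionator sampling plan\n")
  cat(sprintf("  slabs:    %g um thick, every %d%s (start: %s)\n",
              x$slab_thickness, x$slab_interval,
              if (x$slab_interval == 1L) " (all kept)" else "",
              if (identical(x$slab_start, "random")) "random" else x$slab_start))
  cat(sprintf("  sections: %g um thick, runs of %d per %d (start: %s%s)\n",
              x$section_thickness, x$run_length, x$group_size,
              if (identical(x$run_start, "random")) "random" else x$run_start,
              if (x$run_start_per_slab) ", per slab" else ""))
  cat(sprintf("  nominal fractions: f2 = 1/%d, f3 = %d/%d\n",
              x$slab_interval, x$run_length, x$group_size))
  invisible(x)
}
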