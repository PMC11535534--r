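# Counting rules applied to section observations: the nucleolus-gated rule
# with adjacent-section exclusion (raw counts Q for the fractionator), the
# relative secondary-follicle scheme, raw growing-follicle counts, and
# profile morphometry of counted primordial follicles.

#' Count follicles on the sampled sections
#'
#' Applies a counting rule to the observations of [section_ovary()] and
#' returns per-stage raw counts Q together with the realized sampling
#' fractions, ready for the fractionator scale-up.
#'
#' Two modes are available:
#' \describe{
#'   \item{`nucleolus_gated`}{the production rule: a follicle is counted only
#'     in a section where its oocyte nucleolus qualifies, once per serial
#'     run; having been counted, it is excluded from all subsequent adjacent
#'     sections of the run. The `gate` argument selects what "a clearly
#'     defined nucleolus" means: `"center"` (default) counts the follicle in
#'     the unique section containing the nucleolus midpoint -- the section
#'     where the nucleolus is in sharpest focus -- which gives every follicle
#'     an inclusion probability exactly equal to the section sampling
#'     fraction; `"chord"` counts it in the first sampled section where the
#'     nucleolus chord reaches `threshold` micrometre (0 = any visible
#'     trace), the permissive reading whose size-dependent overcounting
#'     [overcount_experiment()] quantifies.}
#'   \item{`profile_presence`}{a deliberately naive rule used for bias
#'     studies only: the follicle is counted in every sampled section where
#'     any oocyte profile appears, with no gate and no exclusion.}
#' }
#'
#' @param obs a `section_obs`.
#' @param mode `"nucleolus_gated"` or `"profile_presence"`.
#' @param gate nucleolus criterion for the gated mode: `"center"` or
#'   `"chord"`.
#' @param threshold minimum nucleolus chord (micrometre) under
#'   `gate = "chord"`.
#' @return an object of class `count_result`: list with `counts` (named
#'   integer vector over the four stages), `counted` (one row per counting
#'   event with the profile diameters read in the counted section), the
#'   fractions `f1`, `f2`, `f3`, `mode`, `gate` and `ovary_id`.
#' @export
count_follicles <- function(obs, mode = c("nucleolus_gated", "profile_presence"),
                            gate = c("center", "chord"), threshold = 0) {
  mode <- match.arg(mode)
  gate <- match.arg(gate)
  stopifnot(inherits(obs, "section_obs"))
  rows <- obs$observations
  if (nrow(rows) && is.unsorted(rows$z_lo)) {
    stop("observations must be ordered by section (slab_index, section_index)",
         call. = FALSE)
  }
  stage <- check_stage(rows$stage)

  if (mode == "profile_presence") {
    counted <- rows
  } else if (gate == "center") {
    counted <- rows[rows$nucleolus_center_in &
                      rows$nucleolus_chord >= threshold, , drop = FALSE]
    # the nucleolus midpoint lies in exactly one section, but dedupe per run
    # anyway so hand-built tables cannot double count
    counted <- counted[!duplicated(counted[, c("follicle_id", "run_id")]), ,
                       drop = FALSE]
  } else {
    vis <- rows[rows$nucleolus_hit & rows$nucleolus_chord >= threshold, ,
                drop = FALSE]
    # first qualifying section per (follicle, serial run); later adjacent
    # sections of the run are excluded
    counted <- vis[!duplicated(vis[, c("follicle_id", "run_id")]), ,
                   drop = FALSE]
  }
  rownames(counted) <- NULL
  counts <- table(factor(counted$stage, levels = STAGES))
  structure(list(counts = stats::setNames(as.integer(counts), STAGES),
                 counted = counted,
                 f1 = obs$f1, f2 = obs$realized_f2, f3 = obs$realized_f3,
                 mode = mode, gate = if (mode == "nucleolus_gated") gate else NA,
                 threshold = threshold,
                 ovary_id = obs$ovary_id),
            class = "count_result")
}

#' @export
print.count_result <- function(x, ...) {
  cat(sprintf("Raw follicle counts (Q) for %s [%s%s]\n", x$ovary_id, x$mode,
              if (!is.na(x$gate)) paste0(", ", x$gate, " gate") else ""))
  for (st in STAGES) cat(sprintf("  %-10s %d\n", st, x$counts[[st]]))
  cat(sprintf("  fractions: f1 = %.4g, f2 = %.4g, f3 = %.4g\n",
              x$f1, x$f2, x$f3))
  invisible(x)
}

#' Relative secondary-follicle count
#'
#' The separate scheme used for secondary follicles: because they span far
#' more sections than primordial/primary follicles, they are not pushed
#' through the fractionator; instead one section in every 50 is read on 1/3
#' of the slabs and the raw nucleolus-gated count is reported with no
#' scale-up, for between-ovary comparison only.
#'
#' @param obs a `section_obs` generated under a plan with `run_length = 1`
#'   and `group_size = 50` (anything else is an error).
#' @inheritParams count_follicles
#' @return integer raw count of secondary follicles, with the realized
#'   fractions attached as attributes.
#' @export
count_secondary_relative <- function(obs, gate = c("center", "chord"),
                                     threshold = 0) {
  stopifnot(inherits(obs, "section_obs"))
  if (obs$plan$run_length != 1L || obs$plan$group_size != 50L) {
    stop("the relative secondary scheme requires a plan with run_length = 1 ",
         "and group_size = 50 (one section of every 50)", call. = FALSE)
  }
  cr <- count_follicles(obs, mode = "nucleolus_gated", gate = gate,
                        threshold = threshold)
  structure(cr$counts[["secondary"]], f1 = cr$f1, f2 = cr$f2, f3 = cr$f3,
            ovary_id = cr$ovary_id)
}

#' Raw growing-follicle counts per section
#'
#' The raw scheme used for the monkey ovaries: on each selected section the
#' whole section is read and every growing follicle (primary, secondary or
#' antral) presenting any oocyte profile is counted; no nucleolus gate and no
#' scale-up. Intended for plans selecting single sections at fixed intervals
#' (e.g. 3 sections, 50 sections apart).
#'
#' @param obs a `section_obs`.
#' @return data frame with one row per sampled section: `slab_index`,
#'   `section_index`, `z_lo` and `n_growing`.
#' @export
count_growing_raw <- function(obs) {
  stopifnot(inherits(obs, "section_obs"))
  rows <- obs$observations
  check_stage(rows$stage)
  growing <- rows[rows$stage %in% GROWING_STAGES, , drop = FALSE]
  fr <- obs$frames
  if (is.null(fr)) {
    fr <- unique(rows[, c("slab_index", "section_index", "z_lo")])
    fr$sampled <- TRUE
  }
  fr <- fr[fr$sampled, c("slab_index", "section_index", "z_lo"), drop = FALSE]
  key <- paste(fr$slab_index, fr$section_index)
  n <- table(factor(paste(growing$slab_index, growing$section_index),
                    levels = key))
  out <- data.frame(fr, n_growing = as.integer(n), row.names = NULL)
  out[order(out$z_lo), , drop = FALSE]
}

#' Profile morphometry of counted primordial follicles
#'
#' Average oocyte and nucleus profile diameters of primordial follicles,
#' measured in the section in which each follicle was counted under the
#' nucleolus-gated rule. Because the gate selects near-equatorial sections,
#' these means sit close below the true diameters.
#'
#' @param counts a `count_result` from the `nucleolus_gated` mode.
#' @return list with `mean_oocyte_diameter`, `mean_nucleus_diameter`
#'   (micrometre; `NA` when nothing was counted), `n` and `defined`
#'   (FALSE when `n = 0`).
#' @export
measure_primordial_diameters <- function(counts) {
  stopifnot(inherits(counts, "count_result"))
  if (counts$mode != "nucleolus_gated") {
    stop("morphometry is defined on nucleolus-gated counts", call. = FALSE)
  }
  rows <- counts$counted[counts$counted$stage == "primordial", , drop = FALSE]
  n <- nrow(rows)
  list(mean_oocyte_diameter = if (n) mean(rows$oocyte_profile) else NA_real_,
       mean_nucleus_diameter = if (n) mean(rows$nucleus_profile) else NA_real_,
       n = n, defined = n > 0L)
}

#' Write a counts table
#'
#' Per-stage raw counts and fractions as delimited text: one row per
#' (ovary, stage) with columns `ovary_id`, `stage`, `mode`, `sum_Q`, `f1`,
#' `f2`, `f3`.
#'
#' @param counts a `count_result` or list of them.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_counts <- function(counts, path) {
  if (inherits(counts, "count_result")) counts <- list(counts)
  df <- do.call(rbind, lapply(counts, function(cr) {
    data.frame(ovary_id = cr$ovary_id, stage = STAGES, mode = cr$mode,
               sum_Q = as.integer(cr$counts[STAGES]),
               f1 = cr$f1, f2 = cr$f2, f3 = cr$f3, stringsAsFactors = FALSE)
  }))
  write_tsv(df, path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- read_tsv(path)
  need <- c("ovary_id", "stage", "sum_Q", "f1", "f2", "f3")
  if (!all(need %in% names(df))) {
    stop("counts table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  check_stage(df$stage)
  df
}
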