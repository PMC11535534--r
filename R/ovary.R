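#' Default follicle size parameters per stage
#'
#' Mean diameters (micrometre) of the nested spheres making up a follicle at
#' each developmental stage, plus a coefficient of variation `cv` applied to
#' every diameter as a positive-truncated normal dispersion. These are
#' literature-informed simulator defaults, not measured values: a primordial
#' follicle is a ~30-um oocyte (nucleus ~18 um, nucleolus ~3 um) wrapped in a
#' single flattened granulosa layer (~35 um overall); primary, secondary and
#' antral stages grow to ~60, ~150 and ~1000 um overall. Every value can be
#' overridden through the `sizes` argument of [generate_ovary()].
#'
#' @return named list (one element per stage) of lists with elements
#'   `follicle`, `oocyte`, `nucleus`, `nucleolus` (mean diameters, um) and
#'   `cv` (dimensionless dispersion).
#' @export
stage_size_defaults <- function() {
  list(
    primordial = list(follicle = 35,   oocyte = 30,  nucleus = 18, nucleolus = 3, cv = 0.08),
    primary    = list(follicle = 60,   oocyte = 45,  nucleus = 22, nucleolus = 4, cv = 0.08),
    secondary  = list(follicle = 150,  oocyte = 80,  nucleus = 30, nucleolus = 5, cv = 0.08),
    antral     = list(follicle = 1000, oocyte = 110, nucleus = 35, nucleolus = 6, cv = 0.08)
  )
}

check_sizes <- function(sizes) {
  for (st in names(sizes)) {
    s <- sizes[[st]]
    need <- c("follicle", "oocyte", "nucleus", "nucleolus", "cv")
    if (!all(need %in% names(s))) {
      stop("size spec for stage '", st, "' must name: ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    m <- unlist(s[c("nucleolus", "nucleus", "oocyte", "follicle")])
    if (any(m <= 0) || is.unsorted(m)) {
      stop("size means for stage '", st,
           "' must be positive and nested: nucleolus <= nucleus <= oocyte <= follicle",
           call. = FALSE)
    }
    if (s$cv < 0) stop("cv for stage '", st, "' must be >= 0", call. = FALSE)
  }
  invisible(sizes)
}

# nested-diameter draw with rejection to keep the nesting order
draw_stage_sizes <- function(k, s) {
  draw <- function(n) cbind(
    d_follicle  = rtrunc_norm(n, s$follicle,  s$cv * s$follicle),
    d_oocyte    = rtrunc_norm(n, s$oocyte,    s$cv * s$oocyte),
    d_nucleus   = rtrunc_norm(n, s$nucleus,   s$cv * s$nucleus),
    d_nucleolus = rtrunc_norm(n, s$nucleolus, s$cv * s$nucleolus)
  )
  d <- draw(k)
  ok <- function(m) m[, "d_nucleolus"] <= m[, "d_nucleus"] &
    m[, "d_nucleus"] <= m[, "d_oocyte"] &
    m[, "d_oocyte"] <= m[, "d_follicle"]
  bad <- which(!ok(d))
  guard <- 0L
  while (length(bad)) {
    d[bad, ] <- draw(length(bad))
    bad <- bad[!ok(d[bad, , drop = FALSE])]
    guard <- guard + 1L
    if (guard > 10000L) {
      stop("could not draw nested diameters for a stage; ",
           "check size means/cv", call. = FALSE)
    }
  }
  d
}

# quadratic form of the ellipsoid with the sectioning (long) axis on cz:
# cz pairs with semi[1], cx with semi[2], cy with semi[3]
ellipsoid_q <- function(cx, cy, cz, semi) {
  (cz / semi[1])^2 + (cx / semi[2])^2 + (cy / semi[3])^2
}

# uniform placement in the cortical shell by rejection against the analytic
# boundaries; each follicle's own radius erodes the outer boundary
place_centers <- function(radii, semi_axes, cortex_thickness, placement,
                          max_attempts, stage) {
  k <- length(radii)
  if (k == 0L) return(matrix(numeric(0), 0, 3))
  if (any(radii >= min(semi_axes))) {
    stop("a ", stage, " follicle is larger than the ovary", call. = FALSE)
  }
  whole <- placement == "whole" || cortex_thickness >= min(semi_axes)
  core <- semi_axes - cortex_thickness
  centers <- matrix(NA_real_, k, 3)
  left <- seq_len(k)
  attempts <- integer(k)
  while (length(left)) {
    m <- length(left)
    p <- cbind(stats::runif(m, -semi_axes[2], semi_axes[2]),   # cx
               stats::runif(m, -semi_axes[3], semi_axes[3]),   # cy
               stats::runif(m, -semi_axes[1], semi_axes[1]))   # cz, long axis
    r <- radii[left]
    acc <- (p[, 3] / (semi_axes[1] - r))^2 +
           (p[, 1] / (semi_axes[2] - r))^2 +
           (p[, 2] / (semi_axes[3] - r))^2 <= 1
    if (!whole) acc <- acc & ellipsoid_q(p[, 1], p[, 2], p[, 3], core) > 1
    centers[left[acc], ] <- p[acc, , drop = FALSE]
    attempts[left] <- attempts[left] + 1L
    left <- left[!acc]
    if (length(left) && min(attempts[left]) > max_attempts) {
      stop("failed to place a ", stage, " follicle within ", max_attempts,
           " attempts; enlarge the ovary or the cortical shell", call. = FALSE)
    }
  }
  centers
}

#' Generate a synthetic three-dimensional ovary
#'
#' Builds a ground-truth ovary for virtual sectioning: a prolate ellipsoid
#' whose first (longest) semi-axis is the sectioning axis, carrying follicles
#' of the four developmental stages. Each follicle is a nest of concentric
#' spheres (follicle > oocyte > nucleus) plus a nucleolus sphere placed
#' uniformly at random strictly inside the nucleus. Follicle centers are
#' placed uniformly at random in the cortical shell (or the whole ovary),
#' with the whole follicle sphere required to lie inside the ovary.
#'
#' All randomness is drawn from a single seeded generator in a fixed,
#' documented order (per stage in primordial, primary, secondary, antral
#' order: diameters, then centers, then nucleolus offsets), so a given seed
#' reproduces the model field-for-field.
#'
#' @param n named integer vector: follicles to generate per stage
#'   (names among `primordial`, `primary`, `secondary`, `antral`).
#' @param semi_axes length-3 positive numeric, micrometre; the first entry
#'   must be the largest (the long/sectioning axis).
#' @param cortex_thickness depth of the placement shell below the surface,
#'   micrometre; a value `>= min(semi_axes)` means whole-ovary placement.
#' @param f1 available tissue fraction in (0, 1]; the fraction of the ovary
#'   left for counting after a wedge is removed for pathology. Applied as
#'   independent thinning by [thin_available()].
#' @param sizes stage size parameters, see [stage_size_defaults()].
#' @param placement `"cortex"` (default) or `"whole"`.
#' @param overlap_allowed if `FALSE`, follicles are placed sequentially and
#'   re-drawn until they do not overlap any earlier follicle.
#' @param max_attempts placement attempts per follicle before failing.
#' @param seed integer seed.
#' @return an object of class `ovary_model`: a list with `semi_axes`,
#'   `cortex_thickness`, `f1`, `seed`, `placement`, `overlap_allowed` and
#'   `follicles`, a data frame with one row per follicle and columns `id`,
#'   `stage`, `cx`, `cy`, `cz` (center relative to the ovary centroid, um;
#'   `cz` runs along the long/sectioning axis),
#'   `d_follicle`, `d_oocyte`, `d_nucleus`, `d_nucleolus` (um) and
#'   `off_x`, `off_y`, `off_z` (nucleolus center relative to the oocyte
#'   center, um).
#' @seealso [validate_ovary()], [section_ovary()], [thin_available()]
#' @examples
#' ov <- generate_ovary(c(primordial = 50), seed = 1)
#' ov
#' @export
generate_ovary <- function(n = c(primordial = 1000, primary = 100,
                                 secondary = 10, antral = 2),
                           semi_axes = c(15000, 7500, 5000),
                           cortex_thickness = 1500,
                           f1 = 1,
                           sizes = stage_size_defaults(),
                           placement = c("cortex", "whole"),
                           overlap_allowed = TRUE,
                           max_attempts = 1000L,
                           seed = 1L) {
  placement <- match.arg(placement)
  if (length(semi_axes) != 3L || any(semi_axes <= 0)) {
    stop("`semi_axes` must be 3 positive numbers", call. = FALSE)
  }
  if (semi_axes[1] < max(semi_axes)) {
    stop("the first semi-axis is the sectioning (long) axis and must be the largest",
         call. = FALSE)
  }
  if (cortex_thickness <= 0) stop("`cortex_thickness` must be > 0", call. = FALSE)
  if (cortex_thickness > min(semi_axes)) {
    stop("`cortex_thickness` must not exceed the smallest semi-axis", call. = FALSE)
  }
  check_fraction(f1, "f1")
  if (is.null(names(n)) || !all(names(n) %in% STAGES)) {
    stop("`n` must be a named vector with names among: ",
         paste(STAGES, collapse = ", "), call. = FALSE)
  }
  if (any(n < 0) || any(n != round(n))) {
    stop("stage counts must be non-negative integers", call. = FALSE)
  }
  check_sizes(sizes[names(n)[n > 0]])

  follicles <- withr::with_seed(as.integer(seed), {
    per_stage <- lapply(STAGES, function(st) {
      k <- if (st %in% names(n)) as.integer(n[[st]]) else 0L
      if (k == 0L) return(NULL)
      d <- draw_stage_sizes(k, sizes[[st]])
      centers <- place_centers(d[, "d_follicle"] / 2, semi_axes,
                               cortex_thickness, placement, max_attempts, st)
      # nucleolus strictly inside the nucleus: uniform in the allowed ball
      rmax <- (d[, "d_nucleus"] - d[, "d_nucleolus"]) / 2
      dir <- matrix(stats::rnorm(3L * k), k, 3)
      dir <- dir / sqrt(rowSums(dir^2))
      rad <- rmax * stats::runif(k)^(1 / 3)
      off <- dir * rad
      data.frame(stage = st,
                 cx = centers[, 1], cy = centers[, 2], cz = centers[, 3],
                 d_follicle = d[, "d_follicle"], d_oocyte = d[, "d_oocyte"],
                 d_nucleus = d[, "d_nucleus"], d_nucleolus = d[, "d_nucleolus"],
                 off_x = off[, 1], off_y = off[, 2], off_z = off[, 3])
    })
    out <- do.call(rbind, per_stage)
    if (is.null(out)) {
      out <- data.frame(stage = character(0), cx = numeric(0), cy = numeric(0),
                        cz = numeric(0), d_follicle = numeric(0),
                        d_oocyte = numeric(0), d_nucleus = numeric(0),
                        d_nucleolus = numeric(0), off_x = numeric(0),
                        off_y = numeric(0), off_z = numeric(0))
    }
    if (!overlap_allowed && nrow(out) > 1L) {
      out <- resolve_overlaps(out, semi_axes, cortex_thickness, placement,
                              max_attempts)
    }
    out
  })
  follicles <- cbind(id = seq_len(nrow(follicles)), follicles)
  rownames(follicles) <- NULL
  structure(list(semi_axes = as.numeric(semi_axes),
                 cortex_thickness = cortex_thickness,
                 f1 = f1, seed = as.integer(seed),
                 placement = placement, overlap_allowed = overlap_allowed,
                 follicles = follicles),
            class = "ovary_model")
}

# sequential re-placement until pairwise non-overlap (centers at least the
# sum of follicle radii apart); only used when overlap_allowed = FALSE
resolve_overlaps <- function(fol, semi_axes, cortex_thickness, placement,
                             max_attempts) {
  r <- fol$d_follicle / 2
  pos <- as.matrix(fol[, c("cx", "cy", "cz")])
  for (i in seq_len(nrow(fol))[-1]) {
    prev <- seq_len(i - 1L)
    attempts <- 0L
    repeat {
      dist2 <- rowSums((pos[prev, , drop = FALSE] -
                          matrix(pos[i, ], length(prev), 3, byrow = TRUE))^2)
      if (all(dist2 >= (r[prev] + r[i])^2)) break
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("failed to place a ", fol$stage[i], " follicle without overlap ",
             "within ", max_attempts, " attempts", call. = FALSE)
      }
      pos[i, ] <- place_centers(r[i], semi_axes, cortex_thickness, placement,
                                max_attempts, fol$stage[i])
    }
  }
  fol[, c("cx", "cy", "cz")] <- pos
  fol
}

#' Remove the tissue fraction unavailable for counting
#'
#' Mimics the removal of an ovarian wedge for pathology review: each follicle
#' is deleted independently with probability `1 - f1`, where `f1` is the
#' model's available tissue fraction. The nominal `f1` is carried forward as
#' the first sampling fraction of the fractionator (in practice `f1` is known
#' from tissue weights, not from follicle bookkeeping).
#'
#' @param model an `ovary_model`.
#' @param seed integer seed for the thinning draws.
#' @return the model with the retained follicles; `model$f1` is unchanged and
#'   an attribute `thinned = TRUE` is set.
#' @export
thin_available <- function(model, seed = model$seed + 1L) {
  stopifnot(inherits(model, "ovary_model"))
  if (model$f1 >= 1) return(model)
  keep <- withr::with_seed(as.integer(seed),
                           stats::runif(nrow(model$follicles)) <= model$f1)
  model$follicles <- model$follicles[keep, , drop = FALSE]
  rownames(model$follicles) <- NULL
  attr(model, "thinned") <- TRUE
  model
}

#' Validate the geometric invariants of a synthetic ovary
#'
#' Checks, per follicle: positive and nested diameters
#' (nucleolus <= nucleus <= oocyte <= follicle), the nucleolus strictly
#' inside the nucleus (|offset| + r_nucleolus <= r_nucleus), and the follicle
#' sphere inside the ovary boundary (center within the ellipsoid eroded by
#' the follicle radius). When the model was generated with
#' `overlap_allowed = FALSE`, pairwise non-overlap is checked as well.
#'
#' @param model an `ovary_model`.
#' @param tol numeric slack for boundary comparisons.
#' @return a data frame of class `ovary_validation` with columns `check`,
#'   `pass`, `n_fail` and `fail_ids` (comma-separated ids, truncated).
#' @export
validate_ovary <- function(model, tol = 1e-9) {
  stopifnot(inherits(model, "ovary_model"))
  f <- model$follicles
  semi <- model$semi_axes
  checks <- list()
  report <- function(name, bad) {
    ids <- f$id[bad]
    data.frame(check = name, pass = !length(ids), n_fail = length(ids),
               fail_ids = paste(utils::head(ids, 10L), collapse = ","),
               stringsAsFactors = FALSE)
  }
  pos_ok <- f$d_nucleolus > 0 & f$d_nucleus > 0 & f$d_oocyte > 0 & f$d_follicle > 0
  nest_ok <- f$d_nucleolus <= f$d_nucleus + tol &
    f$d_nucleus <= f$d_oocyte + tol & f$d_oocyte <= f$d_follicle + tol
  checks$sizes <- report("diameters positive and nested", which(!(pos_ok & nest_ok)))
  off <- sqrt(f$off_x^2 + f$off_y^2 + f$off_z^2)
  checks$nucleolus <- report("nucleolus inside nucleus",
                             which(off + f$d_nucleolus / 2 > f$d_nucleus / 2 + tol))
  r <- f$d_follicle / 2
  inside <- (f$cz / (semi[1] - r))^2 + (f$cx / (semi[2] - r))^2 +
    (f$cy / (semi[3] - r))^2 <= 1 + tol
  inside[r >= min(semi)] <- FALSE
  checks$boundary <- report("follicle inside ovary", which(!inside))
  if (!model$overlap_allowed && nrow(f) > 1L) {
    pos <- as.matrix(f[, c("cx", "cy", "cz")])
    d2 <- as.matrix(stats::dist(pos))^2
    lim <- outer(r, r, `+`)^2
    diag(d2) <- Inf
    checks$overlap <- report("no follicle overlap",
                             which(apply(d2 < lim - tol, 1, any)))
  }
  out <- do.call(rbind, checks)
  rownames(out) <- NULL
  class(out) <- c("ovary_validation", "data.frame")
  out
}

#' @export
print.ovary_model <- function(x, ...) {
  cat("Synthetic ovary (prolate ellipsoid)\n")
  cat(sprintf("  semi-axes: %s um (sectioning along the first axis)\n",
              paste(format(x$semi_axes), collapse = " x ")))
  cat(sprintf("  cortical shell: %g um (%s placement); f1 = %g; seed = %d\n",
              x$cortex_thickness, x$placement, x$f1, x$seed))
  tab <- table(factor(x$follicles$stage, levels = STAGES))
  cat("  follicles:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                            collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.ovary_validation <- function(x, ...) {
  cat("Ovary validation report\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  [%s] %s%s\n", if (x$pass[i]) "ok" else "FAIL", x$check[i],
                if (x$pass[i]) "" else sprintf(" (%d failing: %s)",
                                               x$n_fail[i], x$fail_ids[i])))
  }
  invisible(x)
}

#' Write / read a follicle table
#'
#' Delimited-text serialization of the follicle list of an `ovary_model`
#' (tab-separated, header row mandatory, units micrometre). Ovary geometry is
#' stored in `# key=value` comment lines so the table round-trips into a
#' model usable for sectioning.
#'
#' @param model an `ovary_model`.
#' @param path file path.
#' @return `write_follicles()` returns the path invisibly;
#'   `read_follicles()` returns an `ovary_model`.
#' @export
write_follicles <- function(model, path) {
  stopifnot(inherits(model, "ovary_model"))
  write_tsv(model$follicles, path, comments = c(
    sprintf("semi_axes=%s", paste(format(model$semi_axes, digits = 15), collapse = ",")),
    sprintf("cortex_thickness=%s", format(model$cortex_thickness, digits = 15)),
    sprintf("f1=%s", format(model$f1, digits = 15)),
    sprintf("seed=%d", model$seed)
  ))
  invisible(path)
}

#' @rdname write_follicles
#' @export
read_follicles <- function(path) {
  meta <- read_tsv_comments(path)
  f <- read_tsv(path)
  need <- c("id", "stage", "cx", "cy", "cz", "d_follicle", "d_oocyte",
            "d_nucleus", "d_nucleolus", "off_x", "off_y", "off_z")
  if (!all(need %in% names(f))) {
    stop("follicle table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  check_stage(f$stage)
  semi <- as.numeric(strsplit(as.character(meta$semi_axes %||% ""), ",")[[1]])
  if (length(semi) != 3L) {
    stop("follicle table is missing its '# semi_axes=a,b,c' header", call. = FALSE)
  }
  structure(list(semi_axes = semi,
                 cortex_thickness = meta$cortex_thickness %||% min(semi),
                 f1 = meta$f1 %||% 1,
                 seed = as.integer(meta$seed %||% NA),
                 placement = "cortex", overlap_allowed = TRUE,
                 follicles = f[, need]),
            class = "ovary_model")
}

#' Read a generation/sampling configuration file
#'
#' YAML configuration with blocks `ovary` (`semi_axes`, `cortex_thickness`,
#' `f1`), `stages` (per stage: `count` and optional `sizes` overriding
#' [stage_size_defaults()]), optional `plan` (fields of [sampling_plan()])
#' and `seed`.
#'
#' @param path YAML file path.
#' @return list with elements `gen` (arguments for [generate_ovary()]),
#'   `plan` (a [sampling_plan()]) and `seed`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  sizes <- stage_size_defaults()
  n <- integer(0)
  for (st in names(cfg$stages %||% list())) {
    if (!st %in% STAGES) stop("unknown stage in config: ", st, call. = FALSE)
    n[st] <- as.integer(cfg$stages[[st]]$count %||% 0L)
    for (key in names(cfg$stages[[st]]$sizes %||% list())) {
      sizes[[st]][[key]] <- cfg$stages[[st]]$sizes[[key]]
    }
  }
  gen <- list(
    n = n,
    semi_axes = as.numeric(cfg$ovary$semi_axes %||% c(15000, 7500, 5000)),
    cortex_thickness = cfg$ovary$cortex_thickness %||% 1500,
    f1 = cfg$ovary$f1 %||% 1,
    sizes = sizes,
    placement = cfg$ovary$placement %||% "cortex",
    overlap_allowed = cfg$ovary$overlap_allowed %||% TRUE
  )
  plan <- do.call(sampling_plan, cfg$plan %||% list())
  list(gen = gen, plan = plan, seed = as.integer(cfg$seed %||% 1L))
}
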