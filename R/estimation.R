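# The fractionator scale-up N = sum(Q) / (f1 * f2 * f3) and the derived
# study summaries (bilateral averaging, age-group means, stage ratios).

#' Fractionator scale-up of a raw count
#'
#' Converts a raw sampled count into an estimate of the total number of
#' follicles in the ovary by dividing by the product of the sampling
#' fractions: `N_hat = sum_Q / (f1 * f2 * f3)`, where `f1` is the available
#' tissue fraction, `f2` the slab sampling fraction and `f3` the section
#' sampling fraction. Realized fractions should be supplied, not nominal
#' design values. Vectorized; exact arithmetic, no rounding.
#'
#' @param sum_Q non-negative raw count(s).
#' @param f1,f2,f3 sampling fractions in (0, 1].
#' @return estimated total count(s), `>= sum_Q`.
#' @examples
#' estimate_total(10, 1, 1 / 3, 0.1)  # 300
#' @export
estimate_total <- function(sum_Q, f1, f2, f3) {
  if (any(sum_Q < 0)) stop("`sum_Q` must be >= 0", call. = FALSE)
  check_fraction(f1, "f1")
  check_fraction(f2, "f2")
  check_fraction(f3, "f3")
  sum_Q / (f1 * f2 * f3)
}

#' Fit the fractionator estimator
#'
#' The estimation surface of the package: takes raw per-stage counts with
#' their sampling fractions -- a [count_follicles()] result, a list of them,
#' or a data frame of real count tables -- and returns per-ovary, per-stage
#' total-count estimates as a classed object with the usual accessor
#' methods.
#'
#' For data-frame input each row is one (ovary, stage) with columns
#' `ovary_id`, `stage`, `sum_Q` (or per-section `Q` values that are summed
#' within ovary and stage) and either `f1`, `f2`, `f3` columns or the
#' equally named scalar arguments.
#'
#' @param x counts: a `count_result`, list of `count_result`s, or data frame.
#' @param ... passed to methods.
#' @param f1,f2,f3 sampling fractions used when `x` carries none.
#' @return an object of class `fractionator`: list with `estimates` (data
#'   frame `ovary_id`, `stage`, `sum_Q`, `f1`, `f2`, `f3`, `N_hat`) and
#'   `call`. `coef()` returns the named `N_hat` vector; `summary()` adds the
#'   primary:primordial ratio per ovary.
#' @examples
#' tab <- data.frame(ovary_id = "ov1", stage = c("primordial", "primary"),
#'                   sum_Q = c(33, 3))
#' fit <- fractionator(tab, f1 = 1, f2 = 1 / 3, f3 = 0.1)
#' coef(fit)
#' @export
fractionator <- function(x, ...) UseMethod("fractionator")

#' @rdname fractionator
#' @export
fractionator.count_result <- function(x, ...) {
  fractionator(list(x), ...)
}

#' @rdname fractionator
#' @export
fractionator.list <- function(x, ...) {
  stopifnot(all(vapply(x, inherits, TRUE, "count_result")))
  df <- do.call(rbind, lapply(x, function(cr) {
    data.frame(ovary_id = cr$ovary_id, stage = STAGES,
               sum_Q = as.numeric(cr$counts[STAGES]),
               f1 = cr$f1, f2 = cr$f2, f3 = cr$f3, stringsAsFactors = FALSE)
  }))
  build_fractionator(df, match.call())
}

#' @rdname fractionator
#' @export
fractionator.data.frame <- function(x, f1 = NULL, f2 = NULL, f3 = NULL, ...) {
  df <- x
  if (!all(c("ovary_id", "stage") %in% names(df))) {
    stop("count table needs `ovary_id` and `stage` columns", call. = FALSE)
  }
  if (!"sum_Q" %in% names(df)) {
    if (!"Q" %in% names(df)) {
      stop("count table needs a `sum_Q` (or per-section `Q`) column",
           call. = FALSE)
    }
    df <- stats::aggregate(list(sum_Q = df$Q),
                           by = df[, c("ovary_id", "stage")], FUN = sum)
  }
  for (fr in c("f1", "f2", "f3")) {
    if (!fr %in% names(df)) {
      val <- switch(fr, f1 = f1, f2 = f2, f3 = f3)
      if (is.null(val)) {
        stop("supply `", fr, "` as a column or argument", call. = FALSE)
      }
      df[[fr]] <- val
    }
  }
  build_fractionator(df[, c("ovary_id", "stage", "sum_Q", "f1", "f2", "f3")],
                     match.call())
}

build_fractionator <- function(df, call) {
  check_stage(df$stage)
  df$N_hat <- estimate_total(df$sum_Q, df$f1, df$f2, df$f3)
  df <- df[order(df$ovary_id, factor(df$stage, levels = STAGES)), ,
           drop = FALSE]
  rownames(df) <- NULL
  structure(list(estimates = df, call = call), class = "fractionator")
}

#' @export
print.fractionator <- function(x, digits = 1, ...) {
  cat("Fractionator estimates: N = sum(Q) / (f1 * f2 * f3)\n\n")
  df <- x$estimates
  df$N_hat <- round(df$N_hat, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.fractionator <- function(object, ...) {
  df <- object$estimates
  stats::setNames(df$N_hat, paste(df$ovary_id, df$stage, sep = ":"))
}

#' @export
summary.fractionator <- function(object, ...) {
  out <- list(estimates = object$estimates,
              ratio = ratio_primary_to_primordial(object))
  class(out) <- "summary.fractionator"
  out
}

#' @export
print.summary.fractionator <- function(x, ...) {
  cat("Fractionator estimates by ovary and stage\n\n")
  df <- x$estimates
  df$N_hat <- round(df$N_hat, 1)
  print(df, row.names = FALSE)
  cat("\nPrimary : primordial ratio per ovary\n")
  print(round(x$ratio, 4))
  invisible(x)
}

#' Ratio of primary to primordial follicle estimates
#'
#' `N_hat(primary) / N_hat(primordial)` per ovary; a rising ratio with age
#' signals that the primordial pool shrinks faster than the primary pool.
#' When the primordial estimate is zero the ratio is undefined and reported
#' as `NA` (no error).
#'
#' @param x a `fractionator` fit or its `estimates` data frame.
#' @return named numeric vector (one element per ovary), `NA` where
#'   undefined.
#' @examples
#' ratio_primary_to_primordial(data.frame(
#'   ovary_id = "g1", stage = c("primary", "primordial"),
#'   N_hat = c(978, 11098)))
#' @export
ratio_primary_to_primordial <- function(x) {
  df <- if (inherits(x, "fractionator")) x$estimates else x
  ov <- unique(df$ovary_id)
  vapply(ov, function(id) {
    num <- df$N_hat[df$ovary_id == id & df$stage == "primary"]
    den <- df$N_hat[df$ovary_id == id & df$stage == "primordial"]
    if (!length(num) || !length(den)) {
      stop("ovary ", id, " is missing a primary or primordial estimate",
           call. = FALSE)
    }
    if (den == 0) NA_real_ else num / den
  }, numeric(1))
}

#' Summarize estimates by subject and age group
#'
#' Study-level bookkeeping: bilateral ovaries of one subject are averaged
#' first (at the `N_hat` level, after scale-up), then arithmetic group means
#' per stage are taken over subjects within each age bin.
#'
#' @param x a `fractionator` fit or its `estimates` data frame.
#' @param subjects data frame mapping `ovary_id` to `subject_id` and `age`
#'   (years).
#' @param breaks increasing numeric age-bin edges as in [cut()]; bins are
#'   `[b1, b2), [b2, b3), ...` and must cover every subject's age (an age
#'   outside all bins is an error naming the ovary).
#' @return an object of class `study_summary`: data frame with `age_group`,
#'   `stage`, `n_subjects`, `mean_N_hat`, plus the per-group
#'   primary:primordial ratio of the group means.
#' @export
summarize_groups <- function(x, subjects, breaks = c(35, 40, 45, 50, 53)) {
  df <- if (inherits(x, "fractionator")) x$estimates else x
  need <- c("ovary_id", "subject_id", "age")
  if (!all(need %in% names(subjects))) {
    stop("`subjects` needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  m <- merge(df, subjects, by = "ovary_id")
  if (nrow(m) < nrow(df)) {
    missing <- setdiff(df$ovary_id, subjects$ovary_id)
    stop("no subject/age for ovary: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m$age_group <- cut(m$age, breaks = breaks, right = FALSE, dig.lab = 4)
  if (anyNA(m$age_group)) {
    bad <- unique(m$ovary_id[is.na(m$age_group)])
    stop("age outside all bins for ovary: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  # bilateral mean first, then group means over subjects
  per_subject <- stats::aggregate(
    list(N_hat = m$N_hat),
    by = list(subject_id = m$subject_id, stage = m$stage,
              age_group = m$age_group),
    FUN = mean)
  grp <- stats::aggregate(list(mean_N_hat = per_subject$N_hat),
                          by = list(age_group = per_subject$age_group,
                                    stage = per_subject$stage),
                          FUN = mean)
  nsub <- stats::aggregate(
    list(n_subjects = per_subject$subject_id),
    by = list(age_group = per_subject$age_group, stage = per_subject$stage),
    FUN = function(s) length(unique(s)))
  out <- merge(grp, nsub, by = c("age_group", "stage"))
  out <- out[order(out$age_group, factor(out$stage, levels = STAGES)), ,
             drop = FALSE]
  rownames(out) <- NULL
  ratio <- vapply(split(out, out$age_group), function(g) {
    num <- g$mean_N_hat[g$stage == "primary"]
    den <- g$mean_N_hat[g$stage == "primordial"]
    if (!length(num) || !length(den) || den == 0) NA_real_ else num / den
  }, numeric(1))
  structure(out, ratio_primary_to_primordial = ratio,
            class = c("study_summary", "data.frame"))
}

#' @export
print.study_summary <- function(x, ...) {
  cat("Group means of fractionator estimates (bilateral ovaries averaged)\n")
  df <- as.data.frame(x)
  df$mean_N_hat <- round(df$mean_N_hat, 1)
  print(df, row.names = FALSE)
  r <- attr(x, "ratio_primary_to_primordial")
  if (length(r)) {
    cat("\nPrimary : primordial ratio of group means\n")
    print(round(r, 4))
  }
  invisible(x)
}

#' One-call pipeline: thin, section, count, estimate
#'
#' Convenience driver running the full fractionator procedure on a synthetic
#' ovary: f1 thinning (when `f1 < 1`), virtual sectioning under the plan,
#' nucleolus-gated counting, and the scale-up with realized fractions.
#' Child seeds for the thinning and sectioning stages are derived
#' deterministically from `seed`.
#'
#' @param model an `ovary_model`.
#' @param plan a [sampling_plan()].
#' @param seed integer seed.
#' @param mode,gate,threshold forwarded to [count_follicles()].
#' @param nominal_fractions if `TRUE` use the plan's nominal f2 = 1/interval
#'   and f3 = run/group instead of the realized fractions (to measure the
#'   error the "approximately one-third" wording would introduce).
#' @param ovary_id identifier for the output tables.
#' @return list with `model`, `obs` (`section_obs`), `counts`
#'   (`count_result`) and `fit` (`fractionator`).
#' @export
fractionate_ovary <- function(model, plan = sampling_plan(), seed = 1L,
                              mode = "nucleolus_gated", gate = "center",
                              threshold = 0, nominal_fractions = FALSE,
                              ovary_id = "ovary1") {
  seeds <- derive_child_seeds(seed, 2L)
  model <- thin_available(model, seed = seeds[1])
  obs <- section_ovary(model, plan, seed = seeds[2], threshold = threshold,
                       ovary_id = ovary_id)
  counts <- count_follicles(obs, mode = mode, gate = gate,
                            threshold = threshold)
  if (nominal_fractions) {
    counts$f2 <- 1 / plan$slab_interval
    counts$f3 <- plan$run_length / plan$group_size
  }
  list(model = model, obs = obs, counts = counts,
       fit = fractionator(counts))
}

#' Write a fractionator estimates table
#'
#' @param fit a `fractionator` object.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_estimates <- function(fit, path) {
  stopifnot(inherits(fit, "fractionator"))
  write_tsv(fit$estimates, path)
}
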