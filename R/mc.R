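# Monte-Carlo harness: brute-force ground-truth oracle, replicate studies of
# estimator bias and precision, and the diameter sweep quantifying the
# overcounting of large follicles under naive profile counting.

#' Ground-truth follicle counts by direct enumeration
#'
#' The brute-force oracle: counts every follicle whose nucleolus has positive
#' diameter, per stage, straight off the model's follicle table -- completely
#' independent of the sectioning and counting code paths. Under exhaustive
#' sampling the nucleolus-gated pipeline must reproduce these counts exactly.
#'
#' @param model an `ovary_model`.
#' @return named integer vector over the four stages.
#' @export
exhaustive_oracle <- function(model) {
  stopifnot(inherits(model, "ovary_model"))
  f <- model$follicles
  tab <- table(factor(f$stage[f$d_nucleolus > 0], levels = STAGES))
  stats::setNames(as.integer(tab), STAGES)
}

#' Replicate study of fractionator bias and precision
#'
#' Generates `reps` independent synthetic ovaries (child seeds derived
#' deterministically from `master_seed`), runs the full pipeline on each
#' under `plan`, and aggregates, per stage and counting mode, the mean
#' estimate, the relative bias `E[N_hat]/N_true - 1`, the coefficient of
#' variation `SD/mean`, and the standard error of the relative bias (from
#' the replicate SD).
#'
#' @param reps number of replicate ovaries (>= 1).
#' @param master_seed integer master seed; the summary is a deterministic
#'   function of it.
#' @param plan a [sampling_plan()].
#' @param gen list of arguments for [generate_ovary()] (the study
#'   conditions); the per-stage `n` gives the true counts.
#' @param modes counting modes to evaluate, subset of
#'   `c("nucleolus_gated", "profile_presence")`.
#' @param gate,threshold forwarded to [count_follicles()].
#' @return an object of class `mc_summary`: list with `summary` (data frame
#'   per stage x mode: `mean_N_hat`, `rel_bias`, `cv`, `se_rel_bias`,
#'   `N_true`), `replicates` (per-replicate estimates with child seeds and
#'   realized fractions), `reps`, `master_seed` and `fingerprint`.
#' @export
run_replicates <- function(reps, master_seed, plan = sampling_plan(),
                           gen = list(n = c(primordial = 1000)),
                           modes = "nucleolus_gated",
                           gate = "center", threshold = 0) {
  stopifnot(reps >= 1L)
  modes <- match.arg(modes, c("nucleolus_gated", "profile_presence"),
                     several.ok = TRUE)
  n_true <- gen$n
  seeds <- derive_child_seeds(master_seed, 2L * reps)
  per_rep <- vector("list", reps)
  for (r in seq_len(reps)) {
    seed_gen <- seeds[2L * r - 1L]
    seed_pipe <- seeds[2L * r]
    model <- tryCatch(
      do.call(generate_ovary, c(gen, list(seed = seed_gen))),
      error = function(e) stop("replicate ", r, " (child seed ", seed_gen,
                               ") failed: ", conditionMessage(e),
                               call. = FALSE))
    model <- thin_available(model, seed = seed_gen + 1L)
    obs <- section_ovary(model, plan, seed = seed_pipe, threshold = threshold)
    rows <- lapply(modes, function(m) {
      cr <- count_follicles(obs, mode = m, gate = gate, threshold = threshold)
      data.frame(rep = r, seed = seed_gen, mode = m, stage = STAGES,
                 sum_Q = as.numeric(cr$counts[STAGES]),
                 f1 = cr$f1, f2 = cr$f2, f3 = cr$f3,
                 N_hat = estimate_total(cr$counts[STAGES], cr$f1, cr$f2, cr$f3),
                 stringsAsFactors = FALSE)
    })
    per_rep[[r]] <- do.call(rbind, rows)
  }
  repl <- do.call(rbind, per_rep)
  rownames(repl) <- NULL
  keep <- names(n_true)[n_true > 0]
  repl <- repl[repl$stage %in% keep, , drop = FALSE]
  summ <- do.call(rbind, lapply(split(repl, list(repl$mode, repl$stage),
                                      drop = TRUE), function(g) {
    nt <- as.numeric(n_true[[g$stage[1]]])
    mu <- mean(g$N_hat)
    data.frame(mode = g$mode[1], stage = g$stage[1], N_true = nt,
               mean_N_hat = mu,
               rel_bias = mu / nt - 1,
               cv = if (mu > 0) stats::sd(g$N_hat) / mu else NA_real_,
               se_rel_bias = stats::sd(g$N_hat / nt) / sqrt(nrow(g)),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, replicates = repl, reps = reps,
                 master_seed = as.integer(master_seed),
                 fingerprint = config_fingerprint(list(plan = unclass(plan),
                                                       gen = gen,
                                                       gate = gate,
                                                       threshold = threshold))),
            class = "mc_summary")
}

# compact, reproducible identifier of the generating configuration
config_fingerprint <- function(cfg) {
  txt <- paste(deparse(cfg, control = "all"), collapse = "")
  txt <- gsub("[[:space:]]+", "", txt)
  sum(utf8ToInt(txt) * (seq_len(nchar(txt)) %% 97 + 1)) %% 1e9
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf("Monte-Carlo study: %d replicates, master seed %d, config %09d\n\n",
              x$reps, x$master_seed, x$fingerprint))
  df <- x$summary
  df$mean_N_hat <- round(df$mean_N_hat, 1)
  df$rel_bias <- round(df$rel_bias, 4)
  df$cv <- round(df$cv, 4)
  df$se_rel_bias <- round(df$se_rel_bias, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Size-dependent overcounting experiment
#'
#' Quantifies why large follicles need their own counting scheme: spheres of
#' diameter d span about (d + t)/t sections of thickness t, so counting a
#' follicle in every section where a profile appears inflates the raw count
#' roughly (d + t)/t-fold, while the nucleolus-gated rule counts each
#' follicle once regardless of its size.
#'
#' For each diameter in `diameters`, `reps` single-stage ovaries of
#' `n_objects` follicles with oocyte diameter d are generated and counted
#' under both modes. Under an exhaustive plan the profile-presence
#' sections-per-object converges to (d + t)/t and the gated estimate equals
#' the true count.
#'
#' @param diameters numeric vector (>= 2 values) of oocyte diameters, um.
#' @param reps replicates per diameter.
#' @param master_seed integer master seed.
#' @param n_objects follicles per replicate ovary.
#' @param plan a [sampling_plan()]; defaults to [exhaustive_plan()].
#' @param semi_axes ovary semi-axes for the sweep ovaries, um.
#' @param gate,threshold forwarded to [count_follicles()].
#' @return an object of class `overcount_table`: list with `results`
#'   (per diameter x rep x mode: `N_hat`, `sections_per_object`), `summary`
#'   (means and SEs per diameter x mode with the analytic `(d + t)/t`
#'   expectation), `plan` and `master_seed`.
#' @export
overcount_experiment <- function(diameters, reps = 30L, master_seed = 1L,
                                 n_objects = 100L, plan = exhaustive_plan(),
                                 semi_axes = c(3000, 2500, 2000),
                                 gate = "center", threshold = 0) {
  if (length(diameters) < 1L) stop("need at least one diameter", call. = FALSE)
  t <- plan$section_thickness
  seeds <- derive_child_seeds(master_seed, 2L * reps * length(diameters))
  k <- 0L
  res <- list()
  for (d in diameters) {
    sizes <- stage_size_defaults()
    # abstract test object: follicle = oocyte sphere of diameter d with a
    # standard 3-um nucleolus inside a 0.4 d nucleus; no size dispersion
    sizes$primordial <- list(follicle = d, oocyte = d, nucleus = 0.4 * d,
                             nucleolus = min(3, 0.2 * d), cv = 0)
    for (r in seq_len(reps)) {
      k <- k + 1L
      model <- generate_ovary(n = c(primordial = as.integer(n_objects)),
                              semi_axes = semi_axes,
                              cortex_thickness = min(semi_axes),
                              placement = "whole", sizes = sizes,
                              seed = seeds[2L * k - 1L])
      obs <- section_ovary(model, plan, seed = seeds[2L * k],
                           threshold = threshold)
      for (m in c("profile_presence", "nucleolus_gated")) {
        cr <- count_follicles(obs, mode = m, gate = gate,
                              threshold = threshold)
        q <- cr$counts[["primordial"]]
        res[[length(res) + 1L]] <- data.frame(
          diameter = d, rep = r, mode = m,
          sum_Q = q,
          N_hat = estimate_total(q, cr$f1, cr$f2, cr$f3),
          sections_per_object = q / n_objects,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, res)
  summ <- do.call(rbind, lapply(split(res, list(res$mode, res$diameter),
                                      drop = TRUE), function(g) {
    data.frame(diameter = g$diameter[1], mode = g$mode[1],
               mean_N_hat = mean(g$N_hat),
               mean_sections_per_object = mean(g$sections_per_object),
               se_sections_per_object =
                 stats::sd(g$sections_per_object) / sqrt(nrow(g)),
               analytic_sections = (g$diameter[1] + t) / t,
               N_true = n_objects,
               stringsAsFactors = FALSE)
  }))
  summ <- summ[order(summ$diameter, summ$mode), , drop = FALSE]
  rownames(summ) <- NULL
  structure(list(results = res, summary = summ, plan = plan,
                 master_seed = as.integer(master_seed)),
            class = "overcount_table")
}

#' @export
print.overcount_table <- function(x, ...) {
  cat("Overcounting sweep: sections hit per object vs (d + t)/t\n\n")
  df <- x$summary
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
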