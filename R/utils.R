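# internal helpers shared across modules

# canonical stage order; factors everywhere use this ordering
STAGES <- c("primordial", "primary", "secondary", "antral")
GROWING_STAGES <- c("primary", "secondary", "antral")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Chord diameter of a sphere cut by a plane
#'
#' For a sphere of diameter `diameter` whose center lies at signed distance
#' `dz` from the cutting plane, the circular profile has diameter
#' `2 * sqrt((diameter/2)^2 - dz^2)`, clamped to zero when the plane misses
#' the sphere. This is the profile diameter a histologist would measure on a
#' section through the sphere.
#'
#' @param diameter true sphere diameter (micrometre), vectorized.
#' @param dz signed distance from sphere center to the plane (micrometre).
#' @return chord diameter(s), micrometre; 0 where the plane misses the sphere.
#' @examples
#' sphere_chord(30, 0)    # equatorial cut: full diameter
#' sphere_chord(30, 2.5)  # off-equator: 29.58
#' @export
sphere_chord <- function(diameter, dz) {
  2 * sqrt(pmax(0, (diameter / 2)^2 - dz^2))
}

# deterministic per-replicate seeds: one draw stream keyed by the master seed
derive_child_seeds <- function(master_seed, n) {
  withr::with_seed(as.integer(master_seed),
                   sample.int(2147483646L, n, replace = FALSE))
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x <= 0) || any(x > 1)) {
    stop(sprintf("`%s` must lie in (0, 1], got: %s",
                 name, paste(format(x), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

check_stage <- function(stage) {
  bad <- setdiff(unique(as.character(stage)), STAGES)
  if (length(bad)) {
    stop("unknown follicle stage label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factor(as.character(stage), levels = STAGES)
}

# positive-truncated normal by rejection; sd = 0 collapses to the mean
rtrunc_norm <- function(n, mean, sd, lower = 0) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower)
  guard <- 0L
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
    guard <- guard + 1L
    if (guard > 10000L) {
      stop("truncated-normal sampler did not converge; check mean/sd",
           call. = FALSE)
    }
  }
  x
}

# stable table writer used by all external interfaces (byte-identical reruns)
write_tsv <- function(df, path, comments = character(0)) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(comments)) {
    writeLines(paste0("# ", comments), con, sep = "\n")
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# fractions etc. stashed as "# key=value" comment lines at the top of a table
read_tsv_comments <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- lines[startsWith(lines, "# ")]
  kv <- strsplit(sub("^# ", "", lines), "=", fixed = TRUE)
  kv <- kv[lengths(kv) == 2L]
  out <- lapply(kv, function(p) {
    v <- suppressWarnings(as.numeric(p[[2]]))
    if (is.na(v)) p[[2]] else v
  })
  names(out) <- vapply(kv, `[[`, "", 1L)
  out
}
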