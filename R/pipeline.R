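#' Group comparison with the design-appropriate standard test
#'
#' Two groups are compared with a Student's t-test — paired when the design
#' says so (samples aligned by position, e.g. injured limb vs contralateral
#' control of the same animal), unpaired with pooled variance otherwise.
#' More than two groups dispatch to one-way ANOVA. Exact degeneracies
#' (zero-variance difference vectors) are flagged rather than producing an
#' infinite statistic: an all-zero difference vector reports `p = 1`, a
#' zero-variance nonzero difference reports `NA` with the flag set.
#'
#' @param values named list of numeric vectors, one per group (>= 2 values
#'   each).
#' @param paired logical; with two groups, use a paired t-test (group
#'   vectors must be equally long and aligned). Ignored (with a warning)
#'   for more than two groups.
#' @param alpha significance level (default 0.05).
#' @return A `comparison_report`: `test` (`"paired t"`, `"unpaired t"`, or
#'   `"one-way ANOVA"`), `statistic`, `df`, `p_value`, `alpha`,
#'   `significant`, `degenerate`, and `group_summary` (mean, SD, n per
#'   group).
#' @export
compare_groups <- function(values, paired = FALSE, alpha = 0.05) {
  stopifnot(is.list(values), length(values) >= 2, !is.null(names(values)),
            alpha > 0, alpha < 1)
  for (g in names(values))
    if (length(values[[g]]) < 2)
      stop(sprintf("group '%s' needs >= 2 values", g))
  summ <- data.frame(group = names(values),
                     n = vapply(values, length, integer(1)),
                     mean = vapply(values, mean, numeric(1)),
                     sd = vapply(values, sd, numeric(1)),
                     row.names = NULL)
  degenerate <- FALSE
  if (length(values) > 2) {
    if (paired) warning("`paired` ignored with more than two groups (ANOVA)")
    v <- unlist(values, use.names = FALSE)
    g <- factor(rep(names(values), lengths(values)))
    fit <- stats::aov(v ~ g)
    tab <- summary(fit)[[1]]
    test <- "one-way ANOVA"
    statistic <- tab[["F value"]][1]
    df <- c(tab[["Df"]][1], tab[["Df"]][2])
    p <- tab[["Pr(>F)"]][1]
  } else if (paired) {
    x <- values[[1]]; y <- values[[2]]
    if (length(x) != length(y))
      stop("paired design requires equal group sizes with aligned pairs")
    d <- x - y
    test <- "paired t"
    df <- length(d) - 1
    if (stats::sd(d) == 0) {
      degenerate <- TRUE
      if (all(d == 0)) { statistic <- 0; p <- 1 }
      else { statistic <- NA_real_; p <- NA_real_ }
    } else {
      tt <- stats::t.test(x, y, paired = TRUE)
      statistic <- unname(tt$statistic); df <- unname(tt$parameter)
      p <- tt$p.value
    }
  } else {
    x <- values[[1]]; y <- values[[2]]
    test <- "unpaired t"
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      degenerate <- TRUE
      df <- length(x) + length(y) - 2
      if (mean(x) == mean(y)) { statistic <- 0; p <- 1 }
      else { statistic <- NA_real_; p <- NA_real_ }
    } else {
      tt <- stats::t.test(x, y, var.equal = TRUE)
      statistic <- unname(tt$statistic); df <- unname(tt$parameter)
      p <- tt$p.value
    }
  }
  structure(list(test = test, statistic = statistic, df = df, p_value = p,
                 alpha = alpha,
                 significant = if (is.na(p)) NA else p < alpha,
                 degenerate = degenerate, group_summary = summ),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s: statistic %.4g, df %s, p = %.4g%s\n",
              x$test, x$statistic, paste(signif(x$df, 4), collapse = "/"),
              x$p_value,
              if (isTRUE(x$degenerate)) " [degenerate]"
              else if (isTRUE(x$significant)) " *" else ""))
  print(x$group_summary, row.names = FALSE)
  invisible(x)
}

#' Configuration of a simulated group-comparison experiment
#'
#' Binds generator spec templates into named groups, a pairing structure,
#' and a master seed. Sample `i` of group `g` is generated from the group
#' template with its seed replaced by `seed + 7919 * g + 17 * i` (the group
#' and sample indices keep streams disjoint); with a paired design, sample
#' `i` of every group shares the placement stream so pairs are generated
#' from matched fields (same animal, different treatment), which mirrors a
#' contralateral-control design.
#'
#' @param kind `"viability"`, `"calcium"` or `"if"`.
#' @param group_specs named list of spec templates ([impact_spec()],
#'   [trace_sim_spec()] or [if_field_spec()], matching `kind`), one per
#'   group.
#' @param n_per_group samples (specimens) per group.
#' @param paired logical; paired design (equal group sizes by
#'   construction).
#' @param alpha significance level.
#' @param seed master integer seed.
#' @param params extra analysis parameters passed to the per-sample
#'   analysis (e.g. `k` for calcium, `n_target` for IF).
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(kind = c("viability", "calcium", "if"),
                              group_specs, n_per_group = 5, paired = TRUE,
                              alpha = 0.05, seed = 1, params = list()) {
  kind <- match.arg(kind)
  stopifnot(is.list(group_specs), length(group_specs) >= 2,
            !is.null(names(group_specs)), n_per_group >= 2)
  expected <- switch(kind, viability = "impact_spec",
                     calcium = "trace_sim_spec", `if` = "if_field_spec")
  for (g in names(group_specs))
    if (!inherits(group_specs[[g]], expected))
      stop(sprintf("group '%s': expected a %s for kind '%s'", g, expected, kind))
  structure(list(kind = kind, group_specs = group_specs,
                 n_per_group = as.integer(n_per_group), paired = paired,
                 alpha = alpha, seed = as.integer(seed), params = params),
            class = "experiment_config")
}

# Per-sample seed schedule; paired designs share the placement stream
# across groups within a sample (matched fields), unpaired do not.
sample_seed <- function(config, g, i) {
  if (config$paired) config$seed + 17L * i
  else config$seed + 7919L * g + 17L * i
}

# Headline per-sample metric for each experiment kind.
analyze_sample <- function(kind, spec, params) {
  if (kind == "viability") {
    pair <- generate_impact_pair(spec)
    args <- c(list(pre = pair$pre, post = pair$post),
              params[intersect(names(params),
                               c("min_cell_area", "min_separation",
                                 "max_shift", "tie_break"))])
    do.call(analyze_viability_pair, args)$result$death_area_um2
  } else if (kind == "calcium") {
    tr <- generate_traces(spec)
    k <- if (!is.null(params$k)) params$k else 3
    analyze_traces(tr$traces, k = k)$delta_ca
  } else {
    fld <- generate_if_field(spec)
    args <- c(list(stack = fld$image,
                   compartment_masks = fld$compartment_masks),
              params[intersect(names(params),
                               c("circularity_min", "n_target",
                                 "min_cell_area", "min_separation"))])
    do.call(analyze_if_field, args)$joint_score
  }
}

#' Run a simulated experiment end to end
#'
#' Generates every sample of every group from the seeded spec templates,
#' analyzes each with identical parameters, and compares the groups with
#' the design-appropriate test. The report carries full provenance (config
#' hash, master seed, per-sample seeds, package version), and identical
#' configs reproduce byte-identical reports.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory; when given, the report is written
#'   there via [write_report()].
#' @return An `experiment_report`: `kind`, `samples` (data frame: group,
#'   sample, seed, value), `summary` (per-group mean/SD/n), `comparison`
#'   (a `comparison_report`), `provenance`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  groups <- names(config$group_specs)
  rows <- list()
  for (g in seq_along(groups)) {
    for (i in seq_len(config$n_per_group)) {
      spec <- config$group_specs[[g]]
      s <- sample_seed(config, g, i)
      if (config$kind == "viability") spec$field$seed <- s else spec$seed <- s
      rows[[length(rows) + 1L]] <- data.frame(
        group = groups[g], sample = i, seed = s,
        value = analyze_sample(config$kind, spec, config$params))
    }
  }
  samples <- do.call(rbind, rows)
  values <- split(samples$value, factor(samples$group, levels = groups))
  comparison <- compare_groups(values, paired = config$paired,
                               alpha = config$alpha)
  report <- structure(
    list(kind = config$kind, samples = samples,
         summary = comparison$group_summary, comparison = comparison,
         provenance = list(
           config_hash = config_hash(config),
           seed = config$seed,
           package = "chondroquant",
           version = as.character(utils::packageVersion("chondroquant")))),
    class = "experiment_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> kind '%s', %d sample(s)\n",
              x$kind, nrow(x$samples)))
  print(x$comparison)
  invisible(x)
}

#' Write an experiment report to disk
#'
#' `report.json` (summary, test result, provenance) plus `samples.csv`.
#' Output is deterministic: identical reports produce byte-identical files.
#'
#' @param report an [run_experiment()] report.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cmp <- report$comparison
  jsonlite::write_json(
    list(kind = report$kind,
         summary = report$summary,
         test = list(test = cmp$test, statistic = cmp$statistic,
                     df = cmp$df, p_value = cmp$p_value, alpha = cmp$alpha,
                     significant = cmp$significant,
                     degenerate = cmp$degenerate),
         provenance = report$provenance),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$samples, file.path(dir, "samples.csv"),
                   row.names = FALSE)
  invisible(dir)
}

# FNV-1a hash of the canonical JSON serialization of a config; enough to
# make every report traceable to the exact configuration that produced it.
config_hash <- function(config) {
  strip <- function(x) {
    if (inherits(x, "field_spec") || is.list(x)) {
      x <- unclass(x)
      x$cap_mask <- if (!is.null(x$cap_mask)) sum(x$cap_mask)
      lapply(x, strip)
    } else x
  }
  js <- jsonlite::toJSON(strip(unclass(config)), auto_unbox = TRUE,
                         digits = 10, null = "null")
  bytes <- utf8ToInt(as.character(js))
  h <- 2166136261
  for (b in bytes) {
    low <- bitwXor(as.integer(h %% 256), as.integer(b %% 256))
    h <- ((h - h %% 256 + low) * 16777619) %% 4294967296
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}
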