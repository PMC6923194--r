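#' Region-level differential enrichment statistic (M')
#'
#' M' compares a region's methylation enrichment between the two groups:
#' the unweighted arithmetic mean of `log2(MeDIP/Input)` over the region's
#' member probes and the treatment group's samples, minus the same mean for
#' the control group. Positive M' means hypermethylation in the treatment
#' group.
#'
#' @param peaks A `peak_set` (or any data.frame with a `probes` list-column).
#' @param r Enrichment matrix from [log_ratio()].
#' @param groups Two group labels, `c(treatment, control)`.
#' @param samples Sample sheet (defaults to `attr(r, "samples")`).
#' @return Numeric vector of M' values, one per peak.
#' @export
region_mprime <- function(peaks, r, groups = c("HF-CON", "CON-CON"),
                          samples = attr(r, "samples")) {
  stopifnot(length(groups) == 2L)
  cols1 <- which(samples$group == groups[1L])
  cols2 <- which(samples$group == groups[2L])
  if (length(cols1) == 0L || length(cols2) == 0L)
    stop("both groups must have at least one sample")
  vapply(peaks$probes, function(p) {
    rows <- match(p, rownames(r))
    if (anyNA(rows)) stop("peak references probes absent from enrichment")
    mean(r[rows, cols1, drop = FALSE]) - mean(r[rows, cols2, drop = FALSE])
  }, numeric(1))
}

#' Per-probe replicate coefficient of variability
#'
#' CV = sample standard deviation / mean of the linear-scale MeDIP/Input
#' ratio across a group's replicates, per probe.
#'
#' @param m An [intensity_matrix()].
#' @param group Group label.
#' @param probes Optional probe ids (default: all probes).
#' @return Named numeric vector of CVs.
#' @export
probe_cv <- function(m, group, probes = NULL) {
  stopifnot(inherits(m, "intensity_matrix"))
  cols <- which(m$samples$group == group)
  if (length(cols) < 2L)
    stop("group '", group, "' has fewer than 2 replicates; CV undefined")
  ratio <- ratio_linear(m)[, cols, drop = FALSE]
  if (!is.null(probes)) {
    rows <- match(probes, rownames(ratio))
    if (anyNA(rows)) stop("unknown probe id(s)")
    ratio <- ratio[rows, , drop = FALSE]
  }
  apply(ratio, 1L, function(v) stats::sd(v) / mean(v))
}

#' Filter candidate peaks into differential enrichment peaks (DEPs)
#'
#' Applies the two-criterion filter to candidate regions:
#' \enumerate{
#'   \item at least one of the two groups has a median member-probe
#'     `log2(MeDIP/Input)` of at least `median_min` (0.3), and M' is nonzero
#'     (direction = sign of M': hyper if positive, hypo if negative);
#'   \item in each group separately, at least a fraction `cv_frac` (half) of
#'     the member probes have a replicate CV of at most `cv_max` (0.8).
#' }
#' The group medians are taken over all member-probe x within-group-sample
#' enrichment values (even counts: midpoint of the central pair, the usual
#' sample median).
#'
#' @param peaks Candidate `peak_set`, e.g. from [call_candidate_regions()].
#' @param r Enrichment matrix from [log_ratio()].
#' @param m The [intensity_matrix()] (for replicate CVs).
#' @param median_min Criterion-1 median threshold (default 0.3, log2 units).
#' @param cv_max Criterion-2 CV ceiling (default 0.8).
#' @param cv_frac Criterion-2 minimum fraction of member probes meeting
#'   `cv_max`, per group (default 0.5).
#' @param groups Two group labels, `c(treatment, control)`.
#' @return A `dep_set` data.frame: the passing peaks with `mprime`,
#'   `median_treatment`, `median_control`, `cv_frac_treatment`,
#'   `cv_frac_control` and `direction` (`"hyper"`/`"hypo"`) columns, sorted
#'   by `|M'|` descending. Empty output allowed.
#' @export
filter_deps <- function(peaks, r, m, median_min = 0.3, cv_max = 0.8,
                        cv_frac = 0.5, groups = c("HF-CON", "CON-CON")) {
  stats_df <- region_stats(peaks, r, m, groups, cv_max = cv_max)
  pass <- pmax(stats_df$median_treatment, stats_df$median_control) >= median_min &
    stats_df$mprime != 0 &
    stats_df$cv_frac_treatment >= cv_frac &
    stats_df$cv_frac_control >= cv_frac
  deps <- cbind(as.data.frame(peaks), stats_df)[pass, , drop = FALSE]
  deps$direction <- ifelse(deps$mprime > 0, "hyper", "hypo")
  deps <- deps[order(-abs(deps$mprime)), , drop = FALSE]
  rownames(deps) <- NULL
  structure(deps, class = c("dep_set", "data.frame"))
}

#' Region-level summary statistics for candidate peaks
#'
#' Computes, per peak, M', the per-group median member enrichment and the
#' per-group fraction of member probes with replicate CV at or below
#' `cv_max`.
#'
#' @inheritParams filter_deps
#' @return A data.frame aligned with `peaks`.
#' @export
region_stats <- function(peaks, r, m, groups = c("HF-CON", "CON-CON"),
                         cv_max = 0.8) {
  samples <- m$samples
  cols1 <- which(samples$group == groups[1L])
  cols2 <- which(samples$group == groups[2L])
  if (length(cols1) == 0L || length(cols2) == 0L)
    stop("both groups must have at least one sample")
  cv1 <- probe_cv(m, groups[1L])
  cv2 <- probe_cv(m, groups[2L])
  rows_of <- function(p) {
    rows <- match(p, rownames(r))
    if (anyNA(rows)) stop("peak references probes absent from enrichment")
    rows
  }
  do.call(rbind, lapply(peaks$probes, function(p) {
    rows <- rows_of(p)
    data.frame(
      mprime = mean(r[rows, cols1, drop = FALSE]) -
               mean(r[rows, cols2, drop = FALSE]),
      median_treatment = stats::median(r[rows, cols1]),
      median_control = stats::median(r[rows, cols2]),
      cv_frac_treatment = mean(cv1[rows] <= cv_max),
      cv_frac_control = mean(cv2[rows] <= cv_max))
  }))
}

#' Attach promoter and gene annotations to DEPs
#'
#' Each DEP inherits the promoter(s) of its member probes; a DEP spanning
#' probes of several promoters carries all their gene ids (so the count of
#' unique annotated genes can be below the DEP count). The CpG class of a
#' multi-promoter DEP is that of the promoter contributing the most member
#' probes.
#'
#' @param deps A `dep_set` from [filter_deps()].
#' @param design The [probe_design()] (maps probes to promoters).
#' @param promoters Optional promoter table with columns `promoter_id`,
#'   `gene_id`; defaults to gene id = promoter id.
#' @param classes Optional named character vector of promoter CpG classes
#'   (names = promoter ids), e.g. from [classify_promoters()].
#' @return The `dep_set` with `promoter_ids`, `gene_ids` (comma-separated)
#'   and, when `classes` is given, `cpg_class` columns.
#' @export
assign_promoter <- function(deps, design, promoters = NULL, classes = NULL) {
  prom_of <- stats::setNames(design$promoter_id, design$probe_id)
  gene_of <- if (is.null(promoters)) identity else {
    map <- stats::setNames(promoters$gene_id, promoters$promoter_id)
    function(p) unname(map[p])
  }
  per_dep <- lapply(deps$probes, function(p) {
    proms <- prom_of[p]
    if (anyNA(proms)) stop("DEP member probe missing from design")
    tab <- table(proms)
    list(proms = unique(unname(proms)),
         main = names(tab)[which.max(tab)])
  })
  deps$promoter_ids <- vapply(per_dep, function(x)
    paste(x$proms, collapse = ","), character(1))
  deps$gene_ids <- vapply(per_dep, function(x)
    paste(gene_of(x$proms), collapse = ","), character(1))
  if (!is.null(classes)) {
    deps$cpg_class <- vapply(per_dep, function(x) {
      cls <- classes[[x$main]]
      if (is.null(cls)) stop("no CpG class for promoter ", x$main)
      cls
    }, character(1))
  }
  deps
}

#' Tally DEPs by direction, CpG class and chromosome
#'
#' @param deps A `dep_set` with `direction` and (optionally) `cpg_class` and
#'   `chrom` columns. An empty set yields an all-zero tally.
#' @return A `dep_tally` list: `by_direction` (named counts), `by_class`
#'   (direction x class count matrix with `pct` percentages of the direction
#'   total, rounded to 2 decimals), `by_chrom`, `total`.
#' @export
tally_deps <- function(deps) {
  dirs <- c("hyper", "hypo")
  classes <- c("HCP", "ICP", "LCP")
  by_dir <- stats::setNames(
    vapply(dirs, function(d) sum(deps$direction == d), integer(1)), dirs)
  counts <- matrix(0L, 2L, 3L, dimnames = list(dirs, classes))
  if (nrow(deps) > 0L && "cpg_class" %in% names(deps)) {
    tab <- table(factor(deps$direction, dirs), factor(deps$cpg_class, classes))
    counts[] <- as.integer(tab)
  }
  pct <- counts
  for (d in dirs)
    pct[d, ] <- if (by_dir[[d]] > 0) round(counts[d, ] / by_dir[[d]] * 100, 2)
                else 0
  by_chrom <- if (nrow(deps) > 0L)
    table(chrom = deps$chrom, direction = factor(deps$direction, dirs))
  else table(chrom = character(), direction = factor(character(), dirs))
  res <- list(by_direction = by_dir, by_class = counts, pct_by_class = pct,
              by_chrom = by_chrom, total = sum(by_dir))
  stopifnot(sum(res$by_class) == 0L || all(rowSums(res$by_class) == by_dir),
            res$total == sum(by_dir))
  structure(res, class = "dep_tally")
}

#' @export
print.dep_tally <- function(x, ...) {
  cat(format_tally(x), sep = "\n")
  invisible(x)
}

#' Human-readable tally report
#'
#' @param tally A `dep_tally` from [tally_deps()].
#' @return Character vector of report lines.
#' @export
format_tally <- function(tally) {
  lines <- c(sprintf("Differential enrichment peaks: %d total (%d hyper, %d hypo)",
                     tally$total, tally$by_direction[["hyper"]],
                     tally$by_direction[["hypo"]]))
  for (d in rownames(tally$by_class)) {
    lines <- c(lines, sprintf(
      "  %s by CpG class: %s", d,
      paste(sprintf("%s %d (%.2f%%)", colnames(tally$by_class),
                    tally$by_class[d, ], tally$pct_by_class[d, ]),
            collapse = ", ")))
  }
  lines
}

#' Write a tally as TSV
#'
#' @param tally A `dep_tally`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tally <- function(tally, path) {
  df <- data.frame(direction = rep(rownames(tally$by_class), each = 3L),
                   cpg_class = rep(colnames(tally$by_class), 2L),
                   count = as.vector(t(tally$by_class)),
                   pct_of_direction = as.vector(t(tally$pct_by_class)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write DEPs as BED6+ (extra columns: M', direction, gene ids, CpG class)
#'
#' @param deps An annotated `dep_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deps_bed <- function(deps, path) {
  bed <- data.frame(deps$chrom, deps$start, deps$end,
                    sprintf("dep_%04d", seq_len(nrow(deps))),
                    pmin(pmax(round(10 * deps$score), 0), 1000), ".",
                    signif(deps$mprime, 6), deps$direction,
                    if ("gene_ids" %in% names(deps)) deps$gene_ids else ".",
                    if ("cpg_class" %in% names(deps)) deps$cpg_class else ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
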