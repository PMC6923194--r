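#' Sliding-window enrichment scores
#'
#' For every probe, collects the probes whose interval midpoints lie within
#' `window_bp / 2` of its own midpoint on the same chromosome and scores the
#' window against the array-wide enrichment distribution with a one-sided
#' two-sample Kolmogorov-Smirnov test (alternative: window stochastically
#' greater). The score is `-log10` of the classic one-sided asymptotic
#' p-value `exp(-2 D^2 nm / (n + m))`, where `D` is the one-sided KS
#' statistic, `n` the window size and `m` the number of probes on the array.
#' Windows holding fewer than two probes score 0.
#'
#' The per-window statistic is deliberately isolated here so an alternative
#' scorer (e.g. a one-sided Wilcoxon) can be swapped in without touching peak
#' assembly.
#'
#' @param track Per-probe group-mean enrichment (named numeric vector aligned
#'   with `design` rows), e.g. from [group_mean_track()].
#' @param design A [probe_design()].
#' @param window_bp Window width in bp centred on each probe midpoint
#'   (default 750).
#' @return Numeric vector of scores (`-log10 p`), one per design row.
#' @export
window_score <- function(track, design, window_bp = 750) {
  stopifnot(inherits(design, "probe_design"))
  if (length(track) != nrow(design))
    stop("track length does not match design")
  if (length(track) == 0L) stop("empty track")
  if (any(!is.finite(track))) stop("track must be finite")

  m <- length(track)
  # number of array-wide values strictly below each track value
  n_less <- rank(track, ties.method = "min") - 1L
  half <- window_bp / 2
  scores <- numeric(m)

  for (chrom in unique(design$chrom)) {
    idx <- which(design$chrom == chrom)
    mid <- (design$start[idx] + design$end[idx]) / 2  # sorted within chrom
    lo <- findInterval(mid - half, mid, left.open = TRUE) + 1L
    hi <- findInterval(mid + half, mid)
    for (k in seq_along(idx)) {
      n <- hi[k] - lo[k] + 1L
      if (n < 2L) next
      win <- idx[lo[k]:hi[k]]
      w_less <- sort(n_less[win]) / m
      d <- max(w_less - (seq_len(n) - 1L) / n)
      if (d > 0)
        scores[idx[k]] <- 2 * d^2 * n * m / (n + m) / log(10)
    }
  }
  names(scores) <- design$probe_id
  scores
}

#' Detect peaks from window scores
#'
#' A peak is a maximal run of consecutive design-order probes (same
#' chromosome) whose scores reach `cutoff`, with at least `min_probes`
#' members. Ties at exactly the cutoff are included.
#'
#' @param scores Per-probe scores from [window_score()], aligned with
#'   `design`.
#' @param design A [probe_design()].
#' @param cutoff Minimum `-log10 p` score (default 2).
#' @param min_probes Minimum run length (default 2).
#' @param group Optional group label recorded on the peaks.
#' @return A `peak_set` data.frame: `chrom`, `start`, `end`, `n_probes`,
#'   `score` (max member score), `group`, and a list-column `probes` of member
#'   probe ids. Empty result allowed.
#' @export
find_peaks <- function(scores, design, cutoff = 2, min_probes = 2,
                       group = NA_character_) {
  stopifnot(inherits(design, "probe_design"),
            length(scores) == nrow(design))
  qual <- scores >= cutoff
  # break runs at chromosome boundaries
  run_id <- cumsum(c(TRUE, design$chrom[-1L] != design$chrom[-nrow(design)] |
                             qual[-1L] != qual[-length(qual)]))
  rows <- lapply(split(seq_along(qual)[qual], run_id[qual]), function(ii) {
    if (length(ii) < min_probes) return(NULL)
    data.frame(chrom = design$chrom[ii[1L]],
               start = min(design$start[ii]),
               end = max(design$end[ii]),
               n_probes = length(ii),
               score = max(scores[ii]),
               group = group)
  })
  members <- lapply(split(seq_along(qual)[qual], run_id[qual]), function(ii)
    if (length(ii) >= min_probes) design$probe_id[ii] else NULL)
  keep <- !vapply(rows, is.null, logical(1))
  peaks <- do.call(rbind, rows[keep])
  if (is.null(peaks))
    peaks <- data.frame(chrom = character(), start = integer(),
                        end = integer(), n_probes = integer(),
                        score = numeric(), group = character())
  peaks$probes <- I(unname(members[keep]))
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(peaks, class = c("peak_set", "data.frame"))
}

#' Merge nearby peaks
#'
#' Same-chromosome peaks whose genomic gap (`next start - previous end`) is at
#' most `gap_bp` are replaced by their union (member probes concatenated,
#' score = max), repeated to a fixed point. With peaks sorted by
#' (chrom, start) a single left-to-right pass reaches the fixed point, so the
#' operation is idempotent.
#'
#' @param peaks A `peak_set` from [find_peaks()].
#' @param gap_bp Maximum gap for merging, in bp (default 500). Overlapping
#'   peaks (negative gap) always merge.
#' @return A merged `peak_set`.
#' @export
merge_peaks <- function(peaks, gap_bp = 500) {
  if (nrow(peaks) <= 1L) return(peaks)
  peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  out <- list()
  cur <- peaks[1L, , drop = FALSE]
  for (i in seq_len(nrow(peaks))[-1L]) {
    nxt <- peaks[i, , drop = FALSE]
    if (nxt$chrom == cur$chrom && nxt$start - cur$end <= gap_bp) {
      cur$end <- max(cur$end, nxt$end)
      cur$score <- max(cur$score, nxt$score)
      probes <- unique(c(cur$probes[[1L]], nxt$probes[[1L]]))
      cur$probes <- I(list(probes))
      cur$n_probes <- length(probes)
      gg <- unique(stats::na.omit(c(strsplit(cur$group, ",")[[1L]],
                                    strsplit(nxt$group, ",")[[1L]])))
      cur$group <- if (length(gg)) paste(gg, collapse = ",") else NA_character_
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- nxt
    }
  }
  out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("peak_set", "data.frame"))
}

#' Call candidate differential regions from both group tracks
#'
#' Runs the sliding-window scorer and peak detector on each group's mean
#' enrichment track separately (peaks in the treatment track are
#' hypermethylation candidates, peaks in the control track hypomethylation
#' candidates), merges within each track at `gap_bp`, then unions the two
#' peak lists, fusing overlapping or abutting candidates. Direction is
#' assigned downstream from the sign of M' ([filter_deps()]).
#'
#' @param r Enrichment matrix from [log_ratio()].
#' @param design A [probe_design()].
#' @param groups Character vector of the two group labels,
#'   `c(treatment, control)`.
#' @param window_bp,cutoff,min_probes,gap_bp Peak-calling parameters; see
#'   [window_score()], [find_peaks()], [merge_peaks()].
#' @param samples Sample sheet (defaults to `attr(r, "samples")`).
#' @return A `peak_set` of candidate regions with the originating group(s)
#'   recorded.
#' @export
call_candidate_regions <- function(r, design,
                                   groups = c("HF-CON", "CON-CON"),
                                   window_bp = 750, cutoff = 2,
                                   min_probes = 2, gap_bp = 500,
                                   samples = attr(r, "samples")) {
  per_group <- lapply(groups, function(g) {
    track <- group_mean_track(r, g, samples)
    merge_peaks(find_peaks(window_score(track, design, window_bp),
                           design, cutoff, min_probes, group = g),
                gap_bp)
  })
  all_peaks <- do.call(rbind, per_group)
  all_peaks <- all_peaks[order(all_peaks$chrom, all_peaks$start), ,
                         drop = FALSE]
  rownames(all_peaks) <- NULL
  merge_peaks(structure(all_peaks, class = c("peak_set", "data.frame")),
              gap_bp = 0)
}

#' Write peaks as BED6
#'
#' BED score column = `10 * max(-log10 p)` clamped to `[0, 1000]`.
#'
#' @param peaks A `peak_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  bed <- data.frame(peaks$chrom, peaks$start, peaks$end,
                    sprintf("peak_%04d", seq_len(nrow(peaks))),
                    pmin(pmax(round(10 * peaks$score), 0), 1000), ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
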