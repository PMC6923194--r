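#' CpG observed/expected ratio and GC fraction of a DNA window
#'
#' Computes the classic CpG-island dinucleotide statistics for a single
#' sequence window: the observed/expected CpG ratio
#' `(#CG dinucleotides * L) / (#C * #G)` and the GC fraction `(#C + #G) / L`,
#' where `L` is the number of unambiguous (non-N) bases. CG dinucleotides are
#' counted at every position `i` with `seq[i..i+1] == "CG"`. When the sequence
#' contains no C or no G the ratio is defined as 0.
#'
#' @param seq A single DNA sequence: a character string or a
#'   [Biostrings::DNAString]. Alphabet ACGTN; N bases are excluded from all
#'   counts (a CG pair spanning an N does not count).
#' @return A list with elements `ratio` (CpG observed/expected) and `gc`
#'   (GC fraction in `[0, 1]`).
#' @examples
#' cpg_obs_exp(strrep("CG", 250))  # ratio 2, gc 1
#' cpg_obs_exp("AAAA")             # ratio 0, gc 0
#' @export
cpg_obs_exp <- function(seq) {
  x <- .as_dna_chars(seq)
  if (length(x) == 0L)
    stop("empty sequence window")
  n_c <- sum(x == "C")
  n_g <- sum(x == "G")
  l_eff <- sum(x != "N")
  if (l_eff == 0L)
    stop("window contains only N bases")
  n_cg <- if (length(x) >= 2L) sum(x[-length(x)] == "C" & x[-1L] == "G") else 0L
  ratio <- if (n_c == 0L || n_g == 0L) 0 else n_cg * l_eff / (n_c * n_g)
  list(ratio = ratio, gc = (n_c + n_g) / l_eff)
}

#' Windowed CpG statistics along a sequence
#'
#' Slides a window of `window_bp` bases at `step_bp` increments (always
#' including a final window flush with the sequence end) and returns the CpG
#' observed/expected ratio and GC fraction per window. Windows with more than
#' `max_n_frac` ambiguous bases are dropped.
#'
#' @inheritParams cpg_obs_exp
#' @param window_bp Window width in bp (default 500).
#' @param step_bp Step between window starts in bp (default 5).
#' @param max_n_frac Maximum tolerated fraction of N per window (default 0.1).
#' @return A data.frame with columns `start` (1-based window start), `ratio`,
#'   `gc`.
#' @export
cpg_window_stats <- function(seq, window_bp = 500L, step_bp = 5L,
                             max_n_frac = 0.1) {
  x <- .as_dna_chars(seq)
  len <- length(x)
  if (len == 0L) stop("empty sequence")
  window_bp <- min(as.integer(window_bp), len)
  stopifnot(window_bp >= 2L, step_bp >= 1L)

  is_c <- x == "C"
  is_g <- x == "G"
  is_n <- x == "N"
  # cg[i] = 1 if a CG dinucleotide starts at i (length len - 1)
  cg <- is_c[-len] & is_g[-1L]
  cum_c <- c(0L, cumsum(is_c))
  cum_g <- c(0L, cumsum(is_g))
  cum_n <- c(0L, cumsum(is_n))
  cum_cg <- c(0L, cumsum(cg))

  starts <- unique(c(seq.int(1L, len - window_bp + 1L, by = step_bp),
                     len - window_bp + 1L))
  ends <- starts + window_bp - 1L
  n_c <- cum_c[ends + 1L] - cum_c[starts]
  n_g <- cum_g[ends + 1L] - cum_g[starts]
  n_n <- cum_n[ends + 1L] - cum_n[starts]
  # CG starts within [start, end - 1]
  n_cg <- cum_cg[ends] - cum_cg[starts]
  l_eff <- window_bp - n_n
  ratio <- ifelse(n_c > 0L & n_g > 0L, n_cg * l_eff / (n_c * n_g), 0)
  gc <- ifelse(l_eff > 0L, (n_c + n_g) / l_eff, 0)
  keep <- n_n / window_bp <= max_n_frac & l_eff > 0L
  data.frame(start = starts, ratio = ratio, gc = gc)[keep, , drop = FALSE]
}

#' Classify a promoter sequence by CpG density (HCP/ICP/LCP)
#'
#' Assigns the high/intermediate/low CpG-density promoter class from windowed
#' CpG statistics: HCP if any window has observed/expected ratio strictly above
#' `hcp_ratio` *and* GC fraction strictly above `hcp_gc`; LCP if no window
#' reaches `lcp_ratio`; ICP otherwise. Thresholds follow the widely used
#' Weber-style scheme (0.75/0.55 for HCP, 0.48 for LCP, 500-bp windows at
#' 5-bp steps) and are all adjustable.
#'
#' @inheritParams cpg_window_stats
#' @param hcp_ratio,hcp_gc HCP thresholds: some window must exceed both
#'   (strictly) for an HCP call. Defaults 0.75 and 0.55.
#' @param lcp_ratio LCP threshold: LCP iff no window has ratio >= this value.
#'   Default 0.48. Must be below `hcp_ratio` so HCP and LCP are exclusive.
#' @return A single character: `"HCP"`, `"ICP"` or `"LCP"`.
#' @seealso [classify_promoters()] for a vector of sequences.
#' @export
classify_promoter <- function(seq, window_bp = 500L, step_bp = 5L,
                              hcp_ratio = 0.75, hcp_gc = 0.55,
                              lcp_ratio = 0.48, max_n_frac = 0.1) {
  stopifnot(lcp_ratio < hcp_ratio)
  x <- .as_dna_chars(seq)
  if (length(x) < window_bp) {
    warning("sequence shorter than window (", length(x), " < ", window_bp,
            " bp); classifying on the whole sequence")
    window_bp <- length(x)
  }
  w <- cpg_window_stats(x, window_bp = window_bp, step_bp = step_bp,
                        max_n_frac = max_n_frac)
  if (nrow(w) == 0L) stop("no scorable window (too many N bases)")
  if (any(w$ratio > hcp_ratio & w$gc > hcp_gc)) return("HCP")
  if (all(w$ratio < lcp_ratio)) return("LCP")
  "ICP"
}

#' Classify many promoter sequences
#'
#' @param seqs A character vector or [Biostrings::DNAStringSet] of promoter
#'   sequences; names are preserved.
#' @inheritParams classify_promoter
#' @return A named character vector of classes in `{"HCP","ICP","LCP"}`.
#' @export
classify_promoters <- function(seqs, window_bp = 500L, step_bp = 5L,
                               hcp_ratio = 0.75, hcp_gc = 0.55,
                               lcp_ratio = 0.48, max_n_frac = 0.1) {
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  vapply(seqs, classify_promoter, character(1),
         window_bp = window_bp, step_bp = step_bp, hcp_ratio = hcp_ratio,
         hcp_gc = hcp_gc, lcp_ratio = lcp_ratio, max_n_frac = max_n_frac)
}

#' Write a per-promoter CpG class table
#'
#' @param classes Named character vector as returned by [classify_promoters()].
#' @param path Output TSV path (columns `promoter_id`, `cpg_class`).
#' @return `path`, invisibly.
#' @export
write_cpg_classes <- function(classes, path) {
  df <- data.frame(promoter_id = names(classes), cpg_class = unname(classes))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Coerce a single sequence to an uppercase character vector of bases.
.as_dna_chars <- function(seq) {
  if (methods::is(seq, "XString")) seq <- as.character(seq)
  if (is.character(seq) && length(seq) == 1L)
    seq <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  else if (is.character(seq))
    seq <- toupper(seq)
  else stop("sequence must be a character string or DNAString")
  bad <- setdiff(unique(seq), c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("unexpected characters in sequence: ", paste(bad, collapse = ", "))
  seq
}
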