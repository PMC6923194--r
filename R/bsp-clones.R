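#' Generate synthetic bisulfite-sequencing PCR clones
#'
#' Emulates cloned Sanger reads of a bisulfite-converted amplicon: in each
#' clone every CpG cytosine of the reference stays `C` (methylated) with its
#' site probability and reads `T` otherwise, while every non-CpG cytosine
#' converts to `T` with probability `conversion_rate` (independent Bernoulli
#' conversion failures, the standard BSP QC assumption). All other bases are
#' copied unchanged; clones are emitted pre-aligned to the reference.
#'
#' @param reference Reference amplicon sequence (character or
#'   [Biostrings::DNAString]); must contain at least one CpG.
#' @param meth_profile Per-CpG methylation probabilities in `[0, 1]`
#'   (length 1 recycled across sites).
#' @param n_subjects Number of subjects (mice); default 10 per group design.
#' @param clones_per_subject Clones sequenced per subject (default 10;
#'   values below 10 are allowed but warned about, as fewer clones give a
#'   coarse per-subject ratio).
#' @param conversion_rate Bisulfite conversion probability for non-CpG
#'   cytosines, in `(0, 1]` (default 0.99).
#' @param groups Optional data.frame with one row per subject
#'   (`maternal_diet`, `offspring_diet`); recycled labels otherwise `NULL`.
#' @param seed Integer seed.
#' @return A `clone_set` list: `reference`, `cpg_positions` (1-based
#'   positions of the CpG cytosines), `clones` (named character vector,
#'   `subjectXX_cloneYY`), `subjects` (data.frame), `meth_profile`.
#' @export
gen_bsp_clones <- function(reference, meth_profile, n_subjects = 10L,
                           clones_per_subject = 10L, conversion_rate = 0.99,
                           groups = NULL, seed = 1L) {
  ref <- .as_dna_chars(reference)
  cpg <- which(ref[-length(ref)] == "C" & ref[-1L] == "G")
  if (length(cpg) == 0L)
    stop("reference amplicon contains no CpG site")
  stopifnot(all(meth_profile >= 0), all(meth_profile <= 1),
            conversion_rate > 0, conversion_rate <= 1,
            n_subjects >= 1L, clones_per_subject >= 1L)
  meth_profile <- rep_len(meth_profile, length(cpg))
  if (clones_per_subject < 10L)
    warning("fewer than 10 clones per subject")
  non_cpg_c <- setdiff(which(ref == "C"), cpg)
  withr::with_seed(as.integer(seed), {
    clones <- character(0)
    for (s in seq_len(n_subjects)) {
      for (k in seq_len(clones_per_subject)) {
        x <- ref
        meth <- stats::runif(length(cpg)) < meth_profile
        x[cpg[!meth]] <- "T"
        conv <- stats::runif(length(non_cpg_c)) < conversion_rate
        x[non_cpg_c[conv]] <- "T"
        clones[sprintf("subject%02d_clone%02d", s, k)] <-
          paste(x, collapse = "")
      }
    }
    subjects <- data.frame(subject_id = sprintf("subject%02d",
                                                seq_len(n_subjects)))
    if (!is.null(groups)) subjects <- cbind(subjects, groups)
    structure(list(reference = paste(ref, collapse = ""),
                   cpg_positions = cpg, clones = clones,
                   subjects = subjects, meth_profile = meth_profile),
              class = "clone_set")
  })
}

#' Write / read a clone set as FASTA (+ subject sidecar CSV)
#'
#' The reference is written as the first record (`reference`); clone ids
#' encode the subject (`subjectXX_cloneYY`), and the sidecar CSV maps
#' subjects to group labels.
#'
#' @param cs A `clone_set`.
#' @param path FASTA path.
#' @param subjects_csv Sidecar CSV path (default `path` + `.subjects.csv`).
#' @return `path`, invisibly.
#' @export
write_clones <- function(cs, path, subjects_csv = paste0(path, ".subjects.csv")) {
  seqs <- Biostrings::DNAStringSet(c(reference = cs$reference, cs$clones))
  Biostrings::writeXStringSet(seqs, path)
  utils::write.csv(cs$subjects, subjects_csv, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clones
#' @export
read_clones <- function(path, subjects_csv = paste0(path, ".subjects.csv")) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (!"reference" %in% names(seqs))
    stop("FASTA must contain a record named 'reference'")
  ref <- as.character(seqs[["reference"]])
  clones <- as.character(seqs[names(seqs) != "reference"])
  refc <- .as_dna_chars(ref)
  cpg <- which(refc[-length(refc)] == "C" & refc[-1L] == "G")
  if (length(cpg) == 0L) stop("reference amplicon contains no CpG site")
  subjects <- if (file.exists(subjects_csv))
    utils::read.csv(subjects_csv, colClasses = "character")
  else data.frame(subject_id = unique(sub("_clone.*$", "", names(clones))))
  structure(list(reference = ref, cpg_positions = cpg, clones = clones,
                 subjects = subjects, meth_profile = NULL),
            class = "clone_set")
}

#' Call per-CpG methylation on one clone
#'
#' At each CpG position a `C` is called methylated, a `T` unmethylated, and
#' any other base ambiguous. Conversion efficiency is the fraction of
#' non-CpG reference cytosines read as `T` — the standard bisulfite QC
#' metric.
#'
#' @param reference Reference amplicon (character).
#' @param cpg_positions 1-based positions of CpG cytosines on the reference.
#' @param clone Clone sequence, same length as the reference.
#' @param primer_mask Optional integer positions to exclude from both CpG
#'   calling and conversion scoring (e.g. degenerate bisulfite primer
#'   regions).
#' @return A list: `calls` (integer vector per CpG site: 1 methylated,
#'   0 unmethylated, NA ambiguous) and `conversion` (efficiency in `[0,1]`,
#'   NaN when the reference has no scorable non-CpG C).
#' @export
call_clone <- function(reference, cpg_positions, clone, primer_mask = NULL) {
  ref <- .as_dna_chars(reference)
  cl <- .as_dna_chars(clone)
  if (length(ref) != length(cl))
    stop("clone length (", length(cl), ") differs from reference (",
         length(ref), ")")
  score_cpg <- setdiff(cpg_positions, primer_mask)
  base <- cl[score_cpg]
  calls <- rep(NA_integer_, length(cpg_positions))
  names(calls) <- paste0("cpg_", cpg_positions)
  keep <- match(score_cpg, cpg_positions)
  calls[keep] <- ifelse(base == "C", 1L, ifelse(base == "T", 0L, NA_integer_))
  non_cpg_c <- setdiff(which(ref == "C"), union(cpg_positions, primer_mask))
  conversion <- if (length(non_cpg_c)) mean(cl[non_cpg_c] == "T") else NaN
  list(calls = calls, conversion = conversion)
}

#' Call methylation for every clone in a set
#'
#' @param cs A `clone_set`.
#' @param primer_mask Optional positions excluded from scoring; see
#'   [call_clone()].
#' @return A `meth_calls` object: `calls` (clones x CpG-sites integer matrix,
#'   1/0/NA), `conversion` (per-clone efficiency), `subject` (per-clone
#'   subject id), `subjects` (subject table).
#' @export
call_clones <- function(cs, primer_mask = NULL) {
  stopifnot(inherits(cs, "clone_set"))
  per <- lapply(cs$clones, call_clone, reference = cs$reference,
                cpg_positions = cs$cpg_positions, primer_mask = primer_mask)
  calls <- do.call(rbind, lapply(per, `[[`, "calls"))
  rownames(calls) <- names(cs$clones)
  structure(list(calls = calls,
                 conversion = vapply(per, `[[`, numeric(1), "conversion"),
                 subject = sub("_clone.*$", "", names(cs$clones)),
                 subjects = cs$subjects),
            class = "meth_calls")
}

#' Methylation ratios at site, region or subject level
#'
#' Ratio = methylated / (methylated + unmethylated), ambiguous calls
#' excluded from the denominator. Subject-level ratios pool all of a
#' subject's clones and sites (the mouse, not the clone, is the statistical
#' unit for group comparisons). Strata with no unambiguous call are reported
#' as `NA` (missing), never 0.
#'
#' @param mc A `meth_calls` object from [call_clones()].
#' @param level `"site"` (per CpG), `"region"` (one pooled ratio) or
#'   `"subject"` (per subject, pooled over clones and sites).
#' @return Named numeric vector (`site`, `subject`) or a single number
#'   (`region`).
#' @export
methylation_ratio <- function(mc, level = c("region", "site", "subject")) {
  stopifnot(inherits(mc, "meth_calls"))
  level <- match.arg(level)
  pool <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) NA_real_ else mean(x)
  }
  switch(level,
         region = pool(mc$calls),
         site = apply(mc$calls, 2L, pool),
         subject = vapply(split(seq_len(nrow(mc$calls)), mc$subject),
                          function(ii) pool(mc$calls[ii, , drop = FALSE]),
                          numeric(1)))
}

#' Remove clones with poor bisulfite conversion
#'
#' Clones whose conversion efficiency falls below `min_conversion` are
#' dropped (idempotent). If all of a subject's clones are removed the
#' subject disappears from subject-level statistics, with a warning.
#'
#' @param mc A `meth_calls` object.
#' @param min_conversion Minimum conversion efficiency (default 0.95).
#' @return The filtered `meth_calls`.
#' @export
qc_filter <- function(mc, min_conversion = 0.95) {
  stopifnot(inherits(mc, "meth_calls"))
  keep <- is.na(mc$conversion) | mc$conversion >= min_conversion
  dropped <- sum(!keep)
  if (dropped > 0L)
    message(dropped, " clone(s) removed at conversion < ", min_conversion)
  lost <- setdiff(unique(mc$subject), unique(mc$subject[keep]))
  if (length(lost))
    warning("all clones removed for subject(s): ",
            paste(lost, collapse = ", "))
  structure(list(calls = mc$calls[keep, , drop = FALSE],
                 conversion = mc$conversion[keep],
                 subject = mc$subject[keep],
                 subjects = mc$subjects),
            class = "meth_calls")
}

#' Text lollipop grid of clone methylation calls
#'
#' One row per clone, one column per CpG site; filled circles are methylated
#' calls, open circles unmethylated, `?` ambiguous. Rows are ordered by
#' (subject, clone id), deterministically.
#'
#' @param mc A `meth_calls` object.
#' @param symbols Length-3 character vector for (methylated, unmethylated,
#'   ambiguous); defaults to filled/open circles and `?`.
#' @return Character vector of report lines (clone id + grid), printed as a
#'   side effect of `print`.
#' @export
lollipop_report <- function(mc, symbols = c("\u25cf", "\u25cb", "?")) {
  stopifnot(inherits(mc, "meth_calls"), length(symbols) == 3L)
  ord <- order(mc$subject, rownames(mc$calls))
  rows <- apply(mc$calls[ord, , drop = FALSE], 1L, function(v)
    paste(ifelse(is.na(v), symbols[3L],
                 ifelse(v == 1L, symbols[1L], symbols[2L])), collapse = ""))
  sprintf("%-22s %s", rownames(mc$calls)[ord], rows)
}

#' Write the methylation call matrix as TSV
#'
#' @param mc A `meth_calls` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(mc, path) {
  df <- data.frame(clone_id = rownames(mc$calls), subject = mc$subject,
                   conversion = mc$conversion, mc$calls, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' A synthetic CpG-rich amplicon for demonstrations
#'
#' Builds a deterministic amplicon of the requested length containing
#' exactly `n_cpg` CpG sites (default geometry mirrors a typical bisulfite
#' amplicon of ~300 bp with 30 CpGs). Purely synthetic plumbing for examples
#' and simulations.
#'
#' @param length_bp Amplicon length (default 301).
#' @param n_cpg Number of CpG sites (default 30).
#' @param seed Integer seed.
#' @return A character string.
#' @export
synthetic_amplicon <- function(length_bp = 301L, n_cpg = 30L, seed = 7L) {
  stopifnot(length_bp >= 2L * n_cpg, n_cpg >= 1L)
  withr::with_seed(as.integer(seed), {
    repeat {
      x <- sample(c("A", "T", "C", "G"), length_bp, replace = TRUE,
                  prob = c(0.35, 0.35, 0.15, 0.15))
      # break accidental CpGs, then plant exactly n_cpg of them
      cg <- which(x[-length(x)] == "C" & x[-1L] == "G")
      x[cg + 1L] <- "A"
      pos <- sort(sample(seq(2L, length_bp - 2L, by = 2L), n_cpg))
      ok <- all(diff(pos) >= 2L)
      x[pos] <- "C"; x[pos + 1L] <- "G"
      x[pos - 1L][x[pos - 1L] == "C"] <- "A"  # no upstream C creating extra CpG
      x[pos + 2L][x[pos + 2L] == "G"] <- "A"
      cg_final <- which(x[-length(x)] == "C" & x[-1L] == "G")
      if (ok && length(cg_final) == n_cpg) break
    }
    paste(x, collapse = "")
  })
}
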