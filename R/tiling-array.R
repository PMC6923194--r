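#' Construct and validate a probe design
#'
#' A probe design is the array geometry: an ordered table of probes tiling
#' strand-aware promoter windows. Coordinates are 0-based half-open
#' internally (BED convention on disk).
#'
#' @param df A data.frame with columns `probe_id`, `chrom`, `start`, `end`,
#'   `promoter_id`.
#' @return The validated design, sorted by (chrom, start), with class
#'   `"probe_design"`.
#' @export
probe_design <- function(df) {
  need <- c("probe_id", "chrom", "start", "end", "promoter_id")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("design is missing columns: ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[need]
  dup <- unique(df$probe_id[duplicated(df$probe_id)])
  if (length(dup))
    stop("duplicated probe_id in design: ", paste(utils::head(dup, 5), collapse = ", "))
  if (any(df$end <= df$start))
    stop("degenerate probe intervals (end <= start)")
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("probe_design", "data.frame"))
}

#' Construct a two-channel intensity set
#'
#' Holds strictly positive linear-scale MeDIP and Input intensities for each
#' probe and sample, plus the sample sheet (group and replicate labels).
#'
#' @param medip,input Numeric matrices, probes x samples, strictly positive,
#'   with matching dimnames (`rownames` = probe ids, `colnames` = sample ids).
#' @param samples A data.frame with columns `sample_id`, `group`, `replicate`;
#'   one row per column of the matrices, in order.
#' @return An object of class `"intensity_matrix"`: a list with elements
#'   `medip`, `input`, `samples`.
#' @export
intensity_matrix <- function(medip, input, samples) {
  stopifnot(is.matrix(medip), is.matrix(input),
            identical(dim(medip), dim(input)),
            identical(dimnames(medip), dimnames(input)))
  if (is.null(rownames(medip)) || is.null(colnames(medip)))
    stop("intensity matrices need probe rownames and sample colnames")
  samples <- as.data.frame(samples)
  stopifnot(all(c("sample_id", "group", "replicate") %in% names(samples)))
  if (!identical(as.character(samples$sample_id), colnames(medip)))
    stop("sample sheet does not match intensity columns")
  if (any(!is.finite(medip)) || any(!is.finite(input)) ||
      any(medip <= 0) || any(input <= 0))
    stop("intensities must be finite and strictly positive")
  tab <- table(samples$group)
  if (any(tab < 2))
    warning("groups with < 2 replicates: ",
            paste(names(tab)[tab < 2], collapse = ", "),
            " (CV is undefined there)")
  structure(list(medip = medip, input = input, samples = samples),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat("intensity_matrix:", nrow(x$medip), "probes x", ncol(x$medip),
      "samples\n")
  cat("groups:", paste(sprintf("%s (n=%d)", names(table(x$samples$group)),
                               table(x$samples$group)), collapse = ", "), "\n")
  invisible(x)
}

#' Linear MeDIP/Input ratio per probe and sample
#'
#' @param m An [intensity_matrix()].
#' @return Numeric matrix of `medip / input`, probes x samples.
#' @export
ratio_linear <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  m$medip / m$input
}

#' Per-probe, per-sample log2(MeDIP/Input) enrichment
#'
#' The core enrichment transform: `r = log2(MeDIP) - log2(Input)`,
#' elementwise. Positivity of the inputs (enforced at construction/read time)
#' guarantees a finite result. No between-array normalisation is applied by
#' default; `center_medians = TRUE` subtracts each sample's median enrichment
#' (optional, off by default).
#'
#' @param m An [intensity_matrix()].
#' @param center_medians Median-centre each sample's enrichment column?
#'   Default `FALSE`.
#' @return Numeric matrix of log2 enrichment values, probes x samples, with a
#'   `"samples"` attribute carrying the sample sheet.
#' @export
log_ratio <- function(m, center_medians = FALSE) {
  r <- log2(ratio_linear(m))
  if (center_medians)
    r <- sweep(r, 2L, apply(r, 2L, stats::median), "-")
  attr(r, "samples") <- m$samples
  r
}

#' Group-mean enrichment track
#'
#' Averages the enrichment matrix over the samples of one group, giving the
#' per-probe track on which peaks are called.
#'
#' @param r Enrichment matrix from [log_ratio()].
#' @param samples Sample sheet (defaults to the matrix's `"samples"`
#'   attribute).
#' @param group Group label to average over.
#' @return Named numeric vector, one value per probe.
#' @export
group_mean_track <- function(r, group, samples = attr(r, "samples")) {
  if (is.null(samples)) stop("no sample sheet available")
  idx <- which(samples$group == group)
  if (length(idx) == 0L) stop("no samples in group '", group, "'")
  rowMeans(r[, idx, drop = FALSE])
}

# ---- I/O ------------------------------------------------------------------

#' Write / read a probe design
#'
#' The authoritative on-disk format is a TSV probe table (`probe_id`, `chrom`,
#' `start`, `end`, `promoter_id`; 0-based half-open coordinates). A BED6
#' companion (name = probe id, score 0, strand ".") can be written alongside.
#'
#' @param design A [probe_design()].
#' @param path TSV path.
#' @param bed Optional path for a BED6 rendering of the probes.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path, bed = NULL) {
  stopifnot(inherits(design, "probe_design"))
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bed)) {
    bed6 <- data.frame(design$chrom, design$start, design$end,
                       design$probe_id, 0L, ".")
    utils::write.table(bed6, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(probe_id = "character",
                                         chrom = "character",
                                         promoter_id = "character"),
                          stringsAsFactors = FALSE)
  probe_design(df)
}

#' Write / read two-channel intensities
#'
#' Long TSV with columns `probe_id`, `sample_id`, `channel` (`MeDIP` or
#' `Input`) and `value`. The sample sheet travels in a YAML sidecar mapping
#' each sample id to its group and replicate.
#'
#' @param m An [intensity_matrix()].
#' @param path TSV path for the intensities.
#' @param samples_yaml Path for the YAML sample sheet (default:
#'   `path` with a `.samples.yaml` suffix).
#' @return `path`, invisibly.
#' @export
write_intensities <- function(m, path,
                              samples_yaml = paste0(path, ".samples.yaml")) {
  stopifnot(inherits(m, "intensity_matrix"))
  long <- rbind(
    data.frame(probe_id = rep(rownames(m$medip), ncol(m$medip)),
               sample_id = rep(colnames(m$medip), each = nrow(m$medip)),
               channel = "MeDIP", value = as.vector(m$medip)),
    data.frame(probe_id = rep(rownames(m$input), ncol(m$input)),
               sample_id = rep(colnames(m$input), each = nrow(m$input)),
               channel = "Input", value = as.vector(m$input)))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sheet <- lapply(seq_len(nrow(m$samples)), function(i)
    list(group = as.character(m$samples$group[i]),
         replicate = as.integer(m$samples$replicate[i])))
  names(sheet) <- as.character(m$samples$sample_id)
  yaml::write_yaml(sheet, samples_yaml)
  invisible(path)
}

#' @rdname write_intensities
#' @param design The [probe_design()] the intensities belong to; rows naming
#'   unknown probes are rejected.
#' @export
read_intensities <- function(path, design,
                             samples_yaml = paste0(path, ".samples.yaml")) {
  stopifnot(inherits(design, "probe_design"))
  long <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = c(probe_id = "character",
                                           sample_id = "character",
                                           channel = "character"),
                            stringsAsFactors = FALSE)
  unknown <- setdiff(unique(long$probe_id), design$probe_id)
  if (length(unknown))
    stop("intensity rows reference probes absent from the design: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  sheet <- yaml::read_yaml(samples_yaml)
  samples <- data.frame(
    sample_id = names(sheet),
    group = vapply(sheet, function(s) as.character(s$group), character(1)),
    replicate = vapply(sheet, function(s) as.integer(s$replicate), integer(1)),
    row.names = NULL)
  sample_ids <- samples$sample_id
  for (ch in c("MeDIP", "Input")) {
    have <- unique(long$sample_id[long$channel == ch])
    miss <- setdiff(sample_ids, have)
    if (length(miss))
      stop("samples missing the ", ch, " channel: ",
           paste(miss, collapse = ", "))
  }
  shape <- function(ch) {
    sub <- long[long$channel == ch, ]
    mat <- matrix(NA_real_, nrow(design), length(sample_ids),
                  dimnames = list(design$probe_id, sample_ids))
    mat[cbind(match(sub$probe_id, design$probe_id),
              match(sub$sample_id, sample_ids))] <- sub$value
    if (any(is.na(mat)))
      stop("missing ", ch, " values for some probe/sample pairs")
    mat
  }
  intensity_matrix(shape("MeDIP"), shape("Input"), samples)
}
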