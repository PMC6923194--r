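#' HOMA-IR insulin-resistance index
#'
#' The standard homeostatic model assessment:
#' `fasting glucose (mmol/L) x fasting insulin (uIU/mL) / 22.5`.
#' Vectorised; both inputs must be strictly positive.
#'
#' @param glucose Fasting glucose, mmol/L.
#' @param insulin Fasting insulin, uIU/mL.
#' @return HOMA-IR score(s).
#' @examples
#' homa_ir(22.5, 1)  # 1
#' homa_ir(5, 4.5)   # 1
#' @export
homa_ir <- function(glucose, insulin) {
  if (any(!is.finite(glucose)) || any(!is.finite(insulin)) ||
      any(glucose <= 0) || any(insulin <= 0))
    stop("glucose and insulin must be finite and > 0")
  glucose * insulin / 22.5
}

#' Area under the OGTT glucose curve
#'
#' Trapezoidal integral of glucose versus time over the full sampled span
#' (total AUC); `incremental = TRUE` subtracts the baseline rectangle
#' `glucose[1] * (t_max - t_min)` to give incremental AUC above baseline.
#'
#' @param glucose Glucose series, mmol/L (vector, or matrix with one row per
#'   animal and one column per time point).
#' @param times Sampling times in minutes, strictly increasing
#'   (default `c(0, 30, 60, 120)`).
#' @param incremental Subtract the baseline rectangle? Default `FALSE`.
#' @return AUC in mmol/L*min (scalar or per-row vector).
#' @examples
#' ogtt_auc(rep(5, 4))            # 600
#' ogtt_auc(c(0, 10), c(0, 120))  # 600
#' @export
ogtt_auc <- function(glucose, times = c(0, 30, 60, 120),
                     incremental = FALSE) {
  if (is.matrix(glucose))
    return(apply(glucose, 1L, ogtt_auc, times = times,
                 incremental = incremental))
  if (length(glucose) != length(times))
    stop("glucose series and times differ in length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  auc <- sum(diff(times) * (glucose[-1L] + glucose[-length(glucose)]) / 2)
  if (incremental) auc <- auc - glucose[1L] * (max(times) - min(times))
  auc
}

#' Relative expression by the comparative Ct method (2^-ddCt)
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; `ddCt` subtracts the mean
#' `dCt` of the calibrator group; fold change is `2^-ddCt`. By construction
#' the calibrator group's folds have geometric mean exactly 1.
#'
#' @param ct A data.frame with columns `sample_id`, `group`, `ct_target`,
#'   `ct_reference`.
#' @param calibrator Calibrator group label (default `"CON-CON"`).
#' @return The input with `dct`, `ddct` and `fold` columns appended.
#' @export
ddct <- function(ct, calibrator = "CON-CON") {
  stopifnot(all(c("sample_id", "group", "ct_target", "ct_reference") %in%
                  names(ct)))
  bad <- !is.finite(ct$ct_reference)
  if (any(bad))
    stop("missing reference Ct for sample(s): ",
         paste(ct$sample_id[bad], collapse = ", "))
  if (any(!is.finite(ct$ct_target)))
    stop("missing target Ct")
  if (!any(ct$group == calibrator))
    stop("calibrator group '", calibrator, "' is empty")
  ct$dct <- ct$ct_target - ct$ct_reference
  ct$ddct <- ct$dct - mean(ct$dct[ct$group == calibrator])
  ct$fold <- 2^(-ct$ddct)
  ct
}

#' Two-way factorial ANOVA (maternal diet x offspring diet)
#'
#' Fits `values ~ A * B`. Balanced designs give the textbook orthogonal
#' sum-of-squares partition (sequential and marginal SS coincide);
#' unbalanced designs use Type-II sums of squares via [car::Anova()].
#' A response with zero total variance yields `NA` F and p (reported as
#' not-applicable rather than an error).
#'
#' @param values Numeric response.
#' @param a,b Factor labels (factor A: e.g. maternal diet; factor B: e.g.
#'   offspring diet).
#' @return An object of class `"anova2"`: data.frame with rows `A`, `B`,
#'   `A:B`, `Residuals` and columns `ss`, `df`, `f`, `p`, plus attributes
#'   `ss_total` and `balanced`.
#' @export
twoway_anova <- function(values, a, b) {
  a <- factor(a); b <- factor(b)
  stopifnot(length(values) == length(a), length(a) == length(b))
  cells <- table(a, b)
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)
    stop("empty design cell(s): ",
         paste(rownames(cells)[empty[, 1L]], colnames(cells)[empty[, 2L]],
               sep = ":", collapse = ", "))
  }
  if (any(cells < 2L))
    stop("interaction term needs >= 2 observations per cell")
  ss_total <- sum((values - mean(values))^2)
  fit <- stats::lm(values ~ a * b)
  balanced <- length(unique(as.vector(cells))) == 1L
  if (ss_total == 0) {
    tab <- data.frame(ss = c(0, 0, 0, 0),
                      df = c(nlevels(a) - 1L, nlevels(b) - 1L,
                             (nlevels(a) - 1L) * (nlevels(b) - 1L),
                             stats::df.residual(fit)),
                      f = NA_real_, p = NA_real_)
  } else if (balanced) {
    at <- stats::anova(fit)
    tab <- data.frame(ss = at$`Sum Sq`, df = at$Df,
                      f = at$`F value`, p = at$`Pr(>F)`)
  } else {
    at <- car::Anova(fit, type = 2)
    resid_row <- which(rownames(at) == "Residuals")
    at <- at[c(setdiff(seq_len(nrow(at)), resid_row), resid_row), ]
    tab <- data.frame(ss = at$`Sum Sq`, df = at$Df,
                      f = at$`F value`, p = at$`Pr(>F)`)
  }
  rownames(tab) <- c("A", "B", "A:B", "Residuals")
  structure(tab, class = c("anova2", "data.frame"),
            ss_total = ss_total, balanced = balanced)
}

#' @export
print.anova2 <- function(x, ...) {
  cat("Two-way factorial ANOVA",
      if (attr(x, "balanced")) "(balanced)" else "(unbalanced, Type II SS)",
      "\n")
  print.data.frame(x, digits = 5)
  invisible(x)
}

#' Welch t test from summary statistics
#'
#' Computes the Welch t statistic and Satterthwaite degrees of freedom from
#' group means, dispersions and sizes. Dispersions may be SDs or SEMs
#' (SEMs are converted internally: `SD = SEM * sqrt(n)`).
#'
#' @param mean1,mean2 Group means.
#' @param disp1,disp2 Group dispersions (SD or SEM; both > 0).
#' @param n1,n2 Group sizes (each >= 2).
#' @param kind `"sd"` or `"sem"`.
#' @return A list: `t`, `df`, `p` (two-sided).
#' @export
t_from_summary <- function(mean1, disp1, n1, mean2, disp2, n2,
                           kind = c("sd", "sem")) {
  kind <- match.arg(kind)
  if (disp1 <= 0 || disp2 <= 0) stop("dispersions must be > 0")
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in each group")
  sd1 <- if (kind == "sem") disp1 * sqrt(n1) else disp1
  sd2 <- if (kind == "sem") disp2 * sqrt(n2) else disp2
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# ---- synthetic phenotypes -------------------------------------------------

#' Default cell means for the synthetic phenotype generator
#'
#' A 2x2 (maternal diet x offspring diet) mean table per trait, with
#' realistic 8-week C57BL/6 magnitudes and the qualitative pattern of a
#' maternal/offspring high-fat diet study: offspring-diet effect on body
#' weight, both-diet effects on fasting glucose and OGTT excursion, and a
#' maternal-by-offspring interaction on insulin. Units: g, mmol/L, uIU/mL.
#'
#' @return A named list; scalar traits are 2x2 matrices
#'   (rows maternal CON/HF, columns offspring CON/HF), `ogtt` is a list of
#'   2x2 matrices per time point.
#' @export
default_phenotype_means <- function() {
  cell <- function(cc, ch, hc, hh)
    matrix(c(cc, hc, ch, hh), 2L, 2L,
           dimnames = list(maternal = c("CON", "HF"),
                           offspring = c("CON", "HF")))
  list(body_weight = cell(22, 27, 22.5, 27.5),
       fasting_glucose = cell(6.0, 7.5, 7.0, 8.0),
       fasting_insulin = cell(10, 14, 12, 20),
       ogtt = list(`0` = cell(6.0, 7.5, 7.0, 8.0),
                   `30` = cell(14, 17, 16.5, 18),
                   `60` = cell(11, 14.5, 14, 15.5),
                   `120` = cell(7.5, 10, 9.5, 11)))
}

#' Generate a balanced factorial phenotype table
#'
#' Draws `n_per_group` animals per design cell (CON-CON, CON-HF, HF-CON,
#' HF-HF) with normal within-cell noise around the supplied 2x2 cell means.
#' OGTT glucose is sampled at 0, 30, 60 and 120 minutes.
#'
#' @param group_means Named list of traits as in
#'   [default_phenotype_means()].
#' @param sd Named list (or single number, recycled) of within-cell SDs per
#'   trait; for `ogtt` one SD shared across time points. Defaults:
#'   body_weight 2 g, fasting_glucose 0.8 mmol/L, fasting_insulin
#'   2.5 uIU/mL, ogtt 1.2 mmol/L.
#' @param n_per_group Animals per cell (default 10; must be >= 2 for the
#'   factorial ANOVA to be defined).
#' @param seed Integer seed.
#' @return A data.frame: `animal_id`, `maternal_diet`, `offspring_diet`,
#'   `group`, the scalar traits, and `ogtt_0`, `ogtt_30`, `ogtt_60`,
#'   `ogtt_120`.
#' @export
gen_phenotypes <- function(group_means = default_phenotype_means(),
                           sd = list(body_weight = 2, fasting_glucose = 0.8,
                                     fasting_insulin = 2.5, ogtt = 1.2),
                           n_per_group = 10L, seed = 1L) {
  if (n_per_group < 2L)
    stop("n_per_group must be >= 2 (ANOVA undefined otherwise)")
  if (!is.list(sd))
    sd <- stats::setNames(as.list(rep(sd, length(group_means))),
                          names(group_means))
  stopifnot(all(names(group_means) %in% c(names(sd), "ogtt")),
            all(vapply(sd, function(x) all(x >= 0), logical(1))))
  withr::with_seed(as.integer(seed), {
    grid <- expand.grid(maternal_diet = c("CON", "HF"),
                        offspring_diet = c("CON", "HF"),
                        stringsAsFactors = FALSE)
    rows <- grid[rep(seq_len(4L), each = n_per_group), ]
    out <- data.frame(
      animal_id = sprintf("m%03d", seq_len(nrow(rows))),
      rows, row.names = NULL)
    out$group <- paste(out$maternal_diet, out$offspring_diet, sep = "-")
    draw <- function(means2x2, s)
      stats::rnorm(nrow(out),
                   means2x2[cbind(match(out$maternal_diet, c("CON", "HF")),
                                  match(out$offspring_diet, c("CON", "HF")))],
                   s)
    for (trait in setdiff(names(group_means), "ogtt"))
      out[[trait]] <- pmax(draw(group_means[[trait]], sd[[trait]]), 1e-3)
    if ("ogtt" %in% names(group_means)) {
      for (tp in names(group_means$ogtt))
        out[[paste0("ogtt_", tp)]] <-
          pmax(draw(group_means$ogtt[[tp]], sd$ogtt), 1e-3)
    }
    out
  })
}

#' Write / read a phenotype table as CSV
#'
#' @param pheno Phenotype data.frame from [gen_phenotypes()].
#' @param path CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
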