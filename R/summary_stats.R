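#' One-way ANOVA with Dunnett comparisons against a reference group
#'
#' Fits a one-way ANOVA over the groups and tests each non-reference group
#' against the reference with Dunnett's multiple-comparison procedure
#' (single-step adjustment via \pkg{multcomp}). Groups with zero pooled
#' variance (all observations identical across all groups) are degenerate:
#' the comparison is reported with `p = 1` and `degenerate = TRUE` rather
#' than an undefined F statistic.
#'
#' @param groups named list of numeric vectors, one per group (each n >= 2).
#' @param reference name of the reference (sham/baseline) group.
#' @param method only `"Dunnett"` is implemented.
#' @return a `group_comparison`: list with `F`, `df` (between, within),
#'   `p_values` (adjusted, named by comparison), `p_unadjusted`, `method`,
#'   `degenerate`.
#' @export
anova_vs_reference <- function(groups, reference, method = "Dunnett") {
  method <- match.arg(method)
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (!reference %in% names(groups))
    stop("`reference` must name one of the groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("insufficient n: every group needs at least 2 observations",
         call. = FALSE)
  lv <- c(reference, setdiff(names(groups), reference))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1))),
                   levels = lv))
  if (all(df$value == df$value[1])) {
    cmp <- paste(lv[-1], "-", reference)
    return(structure(list(F = NA_real_,
                          df = c(between = length(groups) - 1L,
                                 within = nrow(df) - length(groups)),
                          p_values = setNames(rep(1, length(cmp)), cmp),
                          p_unadjusted = setNames(rep(1, length(cmp)), cmp),
                          method = method, degenerate = TRUE),
                     class = "group_comparison"))
  }
  fit <- aov(value ~ group, data = df)
  an <- anova(fit)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
  sm <- summary(gl)
  sm_un <- summary(gl, test = multcomp::adjusted("none"))
  nm <- names(sm$test$coefficients)
  structure(list(F = an$`F value`[1],
                 df = c(between = an$Df[1], within = an$Df[2]),
                 p_values = setNames(as.numeric(sm$test$pvalues), nm),
                 p_unadjusted = setNames(as.numeric(sm_un$test$pvalues), nm),
                 method = method, degenerate = FALSE),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison %s: F(%d, %d) = %s%s>\n", x$method,
              x$df[["between"]], x$df[["within"]],
              if (is.na(x$F)) "NA" else sprintf("%.3f", x$F),
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  print(round(x$p_values, 4))
  invisible(x)
}

#' Repeated-measures ANOVA over timepoints with sphericity correction
#'
#' One-within-factor (time) repeated-measures ANOVA on a subjects-by-
#' timepoints matrix, with the Greenhouse-Geisser epsilon and corrected
#' p-value (applied whenever epsilon < 0.75; both raw and corrected values
#' are returned), followed by Tukey-style pairwise comparisons of
#' timepoints (paired t tests, single-step-free Bonferroni-Holm would
#' over-correct, so TukeyHSD on the subject-centred long layout is used).
#'
#' @param values numeric matrix, rows = subjects, columns = timepoints
#'   (column names label the timepoints).
#' @return list with `F`, `df`, `p_uncorrected`, `gg_epsilon`,
#'   `p_gg`, `p_reported` (GG-corrected when epsilon < 0.75), and
#'   `tukey` (data.frame of pairwise comparisons).
#' @export
repeated_anova <- function(values) {
  if (!is.matrix(values) || ncol(values) < 2L || nrow(values) < 2L)
    stop("`values` must be a subjects x timepoints matrix", call. = FALSE)
  k <- ncol(values); n <- nrow(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("t", seq_len(k))
  mlm <- lm(values ~ 1)
  idata <- data.frame(time = factor(colnames(values),
                                    levels = colnames(values)))
  av <- car::Anova(mlm, idata = idata, idesign = ~time, type = "III")
  # car warns when the Huynh-Feldt epsilon exceeds 1; HF is not used here
  sm <- suppressWarnings(summary(av, multivariate = FALSE))
  uni <- sm$univariate.tests
  row <- grep("time", rownames(uni))[1]
  Fv <- uni[row, "F value"]
  df1 <- uni[row, "num Df"]; df2 <- uni[row, "den Df"]
  p_un <- uni[row, "Pr(>F)"]
  eps <- sm$pval.adjustments[grep("time", rownames(sm$pval.adjustments))[1],
                             "GG eps"]
  p_gg <- sm$pval.adjustments[grep("time",
                                   rownames(sm$pval.adjustments))[1],
                              "Pr(>F[GG])"]
  # subject-centred Tukey over timepoints
  long <- data.frame(
    value = as.vector(values - rowMeans(values)),
    time = factor(rep(colnames(values), each = n),
                  levels = colnames(values)))
  tk <- stats::TukeyHSD(aov(value ~ time, data = long))$time
  structure(list(F = unname(Fv), df = c(num = unname(df1),
                                        den = unname(df2)),
                 p_uncorrected = unname(p_un),
                 gg_epsilon = unname(eps), p_gg = unname(p_gg),
                 p_reported = unname(if (!is.na(eps) && eps < 0.75)
                   p_gg else p_un),
                 tukey = as.data.frame(tk)),
            class = "rm_anova")
}

timepoint_levels <- c("BL/sham", "4h", "24h", "48h", "72h", "1wk", "2wk",
                      "3wk")

#' Build a summary row for the timecourse grid
#'
#' @param timepoint one of `"BL/sham"`, `"4h"`, `"24h"`, `"48h"`, `"72h"`,
#'   `"1wk"`, `"2wk"`, `"3wk"`.
#' @param modality e.g. `"utricle"`, `"crista"`, `"avor-0.2Hz"`.
#' @param metric metric name, e.g. `"intact_synapses_pct"`.
#' @param values numeric per-subject/field values (percent of baseline).
#' @return a one-row `timepoint_summary` data.frame with mean, sem, n.
#' @export
timepoint_summary <- function(timepoint, modality, metric, values) {
  if (!timepoint %in% timepoint_levels)
    stop(sprintf("vocabulary error: unknown timepoint '%s' (expected %s)",
                 timepoint, paste(timepoint_levels, collapse = ", ")),
         call. = FALSE)
  if (length(values) < 1L) stop("need n >= 1 values", call. = FALSE)
  data.frame(timepoint = timepoint, modality = modality, metric = metric,
             mean = mean(values),
             sem = if (length(values) > 1L)
               sd(values) / sqrt(length(values)) else 0,
             n = length(values), stringsAsFactors = FALSE)
}

#' Assemble the timecourse correlation grid
#'
#' Reshapes per-timepoint summaries of the different modalities --
#' intact-synapse percentage (presynaptic-ribbon expression as a proxy),
#' normalised aVOR/MOR gains, and optional externally scored
#' posturo-locomotor percentages -- into one wide table with a fixed row
#' per timepoint and a column per `modality.metric` trajectory. Cells with
#' no summary are explicit `NA`.
#'
#' @param summaries data.frame of rows built by [timepoint_summary()]
#'   (stackable with `rbind`).
#' @return data.frame with 8 timepoint rows and one column per trajectory
#'   (mean values), plus the `timepoint` column.
#' @export
build_correlation_grid <- function(summaries) {
  need <- c("timepoint", "modality", "metric", "mean")
  if (!all(need %in% names(summaries)))
    stop("summaries need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(summaries$timepoint), timepoint_levels)
  if (length(bad))
    stop("vocabulary error: unknown timepoint label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  traj <- unique(paste(summaries$modality, summaries$metric, sep = "."))
  grid <- data.frame(timepoint = timepoint_levels,
                     stringsAsFactors = FALSE)
  for (tr in traj) grid[[tr]] <- NA_real_
  for (i in seq_len(nrow(summaries))) {
    tr <- paste(summaries$modality[i], summaries$metric[i], sep = ".")
    r <- match(summaries$timepoint[i], timepoint_levels)
    grid[r, tr] <- summaries$mean[i]
  }
  grid
}
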