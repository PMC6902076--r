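## Demographic/clinical group statistics: 2x2 chi-square, two-sample t from
## summary statistics (pooled and Welch), and a demographics report table.

#' Pearson chi-square test for a 2x2 table
#'
#' No continuity correction by default.
#'
#' @param counts 2x2 matrix of non-negative counts, or a length-4 vector
#'   `c(a, b, c, d)` filling the table by row.
#' @param continuity apply the Yates correction.
#' @return List with `chisq`, `df` (= 1), `p` and `expected`.
#' @examples
#' chiSquare2x2(matrix(c(13, 9, 4, 11), 2)) # chi-square 3.776
#' @export
chiSquare2x2 <- function(counts, continuity = FALSE) {
  if (!is.matrix(counts)) counts <- matrix(counts, 2, 2, byrow = TRUE)
  if (!all(dim(counts) == 2L)) stop("a 2x2 table is required")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal in the table")
  ct <- suppressWarnings(chisq.test(counts, correct = continuity))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}

#' Two-sample t test from summary statistics or raw data
#'
#' Works from `mean`, `sd` and `n` alone (no raw data needed), in either
#' the classical pooled-variance form (df = n1 + n2 - 2) or the Welch
#' unequal-variance form with Satterthwaite degrees of freedom. Raw vectors
#' may be passed instead via `x` and `y`; their summaries are used, so the
#' two modes agree exactly.
#'
#' @param mean1,sd1,n1 summary of the first sample.
#' @param mean2,sd2,n2 summary of the second sample.
#' @param variant `"pooled"` or `"welch"`.
#' @param x,y optional raw samples overriding the summaries.
#' @return List with `t`, `df`, `p` (two-sided), `variant`.
#' @examples
#' twoSampleT(19.06, 4.81, 17, 29.05, 0.89, 20, variant = "welch")
#' @export
twoSampleT <- function(mean1, sd1, n1, mean2, sd2, n2,
                       variant = c("pooled", "welch"), x = NULL, y = NULL) {
  variant <- match.arg(variant)
  if (!is.null(x)) { mean1 <- mean(x); sd1 <- sd(x); n1 <- length(x) }
  if (!is.null(y)) { mean2 <- mean(y); sd2 <- sd(y); n2 <- length(y) }
  if (n1 < 2 || n2 < 2) stop("each sample needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0")
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) stop("t undefined: zero variance and equal means")
  }
  if (variant == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df), variant = variant)
}

#' Demographics and clinical report table
#'
#' Builds the standard demographics table for a two-group manifest: sex as
#' a male/female 2x2 chi-square, and every continuous variable (age plus
#' any numeric columns of `clinical`) as "mean (SD)" per group with both
#' pooled and Welch t statistics (reported side by side, since either
#' convention may be the one a variance-homogeneity gate would have
#' chosen).
#'
#' @param manifest data.frame with `subject_id`, `group`, `age`, `sex`.
#' @param clinical optional data.frame with `subject_id` plus numeric
#'   columns; non-missing values are summarized per group and tested when
#'   both groups are observed.
#' @return data.frame with one row per variable.
#' @export
table1Report <- function(manifest, clinical = NULL) {
  required <- c("subject_id", "group", "age", "sex")
  missing <- setdiff(required, names(manifest))
  if (length(missing))
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  grp <- factor(manifest$group)
  if (nlevels(grp) != 2L) stop("two groups required")
  if ("control" %in% levels(grp)) grp <- stats::relevel(grp, "control")
  gref <- levels(grp)[1]; gtest <- levels(grp)[2]

  df <- manifest
  if (!is.null(clinical)) df <- merge(df, clinical, by = "subject_id",
                                      sort = FALSE)
  grp <- factor(df$group)
  if ("control" %in% levels(grp)) grp <- stats::relevel(grp, "control")

  sexTab <- table(factor(df$sex, levels = c("M", "F")), grp)[, c(gtest, gref)]
  sexTest <- chiSquare2x2(t(sexTab))
  rows <- list(data.frame(
    variable = "sex (male/female)",
    summary_test = sprintf("%d/%d", sexTab["M", gtest], sexTab["F", gtest]),
    summary_ref = sprintf("%d/%d", sexTab["M", gref], sexTab["F", gref]),
    statistic = sexTest$chisq, test = "chi-square", p = sexTest$p,
    stringsAsFactors = FALSE))

  contVars <- c("age", setdiff(names(clinical), "subject_id"))
  contVars <- contVars[vapply(contVars, function(v)
    is.numeric(df[[v]]), logical(1))]
  for (v in contVars) {
    x <- df[[v]][grp == gtest & !is.na(df[[v]])]
    y <- df[[v]][grp == gref & !is.na(df[[v]])]
    sumX <- if (length(x)) sprintf("%.2f (%.2f)", mean(x), sd(x)) else "-"
    sumY <- if (length(y)) sprintf("%.2f (%.2f)", mean(y), sd(y)) else "-"
    if (length(x) >= 2 && length(y) >= 2) {
      tp <- twoSampleT(x = x, y = y, variant = "pooled")
      tw <- twoSampleT(x = x, y = y, variant = "welch")
      rows[[length(rows) + 1L]] <- data.frame(
        variable = paste0(v, " [pooled]"), summary_test = sumX,
        summary_ref = sumY, statistic = tp$t, test = "t (pooled)", p = tp$p,
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = paste0(v, " [welch]"), summary_test = sumX,
        summary_ref = sumY, statistic = tw$t, test = "t (welch)", p = tw$p,
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, summary_test = sumX, summary_ref = sumY,
        statistic = NA_real_, test = "-", p = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[2:3] <- c(paste0(gtest, "_summary"), paste0(gref, "_summary"))
  out
}
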