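#' AUC of a risk score with a DeLong confidence interval
#'
#' Area under the ROC curve by the rank statistic (tied score pairs counted
#' one half), with the asymptotic structural-components (DeLong) 95%
#' confidence interval.
#'
#' @param scores numeric risk scores (higher = more likely positive).
#' @param labels 0/1 or logical event indicators.
#' @return list of class `roc_result`: `auc`, `lower`, `upper`, `n_pos`,
#'   `n_neg`, and the underlying `pROC::roc` object as `roc`.
#' @export
compute_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores and labels lengths differ")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to compute an AUC")
  }
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- tryCatch(
    suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong"))),
    error = function(e) rep(NA_real_, 3))
  structure(list(auc = as.numeric(pROC::auc(r)),
                 lower = max(ci[1], 0), upper = min(ci[3], 1),
                 n_pos = n_pos, n_neg = n_neg, roc = r),
            class = "roc_result")
}

#' Paired comparison of two AUCs (DeLong test)
#'
#' Both score vectors must refer to the same subjects. Identical score
#' vectors trivially give a zero difference with p = 1.
#'
#' @param scores_a,scores_b two risk scores on the same subjects.
#' @param labels shared 0/1 event indicators.
#' @return list: `auc_a`, `auc_b`, `delta`, `p`.
#' @export
compare_auc <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("scores_a, scores_b and labels must be aligned (equal lengths)")
  }
  a <- compute_auc(scores_a, labels)
  b <- compute_auc(scores_b, labels)
  delta <- a$auc - b$auc
  if (isTRUE(all.equal(scores_a, scores_b))) {
    return(list(auc_a = a$auc, auc_b = b$auc, delta = 0, p = 1))
  }
  tst <- pROC::roc.test(a$roc, b$roc, method = "delong", paired = TRUE)
  p <- as.numeric(tst$p.value)
  if (is.nan(p)) p <- 1  # zero-variance difference
  list(auc_a = a$auc, auc_b = b$auc, delta = delta, p = p)
}

#' Risk score of the fully adjusted prediction model
#'
#' Linear predictor of the fully adjusted Cox model (model-3 covariates
#' plus baseline systolic/diastolic blood pressure) including the diet-index
#' term; labels are the event indicator over the whole follow-up.
#'
#' @param sample an `analysis_sample`.
#' @param index `"pdi"`, `"hpdi"`, or `"none"` for the covariate-only model.
#' @return list: `scores` (linear predictor), `labels`, `fit`.
#' @export
model_score_for_roc <- function(sample, index = c("pdi", "hpdi", "none")) {
  index <- match.arg(index)
  spec <- if (index == "none") {
    cox_model_spec(exposure = "none", model = 3L, include_bp = TRUE)
  } else {
    cox_model_spec(index = index, exposure = "per_sd", model = 3L,
                   include_bp = TRUE)
  }
  fit <- fit_cox(sample, spec)
  list(scores = unname(stats::predict(fit$fit, type = "lp")),
       labels = as.integer(sample$event), fit = fit)
}

#' Spearman rank correlation
#'
#' Midranks for ties; errors on constant input, where the coefficient is
#' undefined.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return the rank correlation coefficient.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector: Spearman correlation undefined")
  }
  stats::cor(x, y, method = "spearman")
}

#' Baseline descriptive table with between-group tests
#'
#' Continuous variables are summarized as mean (SD) and compared by one-way
#' ANOVA, or by the Kruskal-Wallis test when listed in `nonnormal`;
#' categorical variables as n (%) with an (uncorrected) chi-square test.
#' Variables constant across the sample are reported without a test.
#'
#' @param sample data frame.
#' @param group name of the binary grouping column (e.g. `"event"`).
#' @param variables columns to summarize; defaults to the standard covariate
#'   set present in the sample.
#' @param nonnormal character vector of variables to test by Kruskal-Wallis.
#' @return data frame: `variable`, `type`, `test`, one summary column per
#'   group level, `p`.
#' @export
descriptive_table <- function(sample, group = "event", variables = NULL,
                              nonnormal = character(0)) {
  g <- sample[[group]]
  if (is.null(g)) stop("grouping column not found: ", group)
  g <- factor(g)
  if (any(table(g) == 0L) || nlevels(g) < 2L) {
    stop("each group must be non-empty")
  }
  if (is.null(variables)) {
    variables <- intersect(
      c("age", "male", "rural", "total_energy", "education", "met",
        "smoking", "alcohol", "bmi", "sbp", "dbp",
        "pdi_total", "hpdi_total"),
      names(sample))
  }
  rows <- lapply(variables, function(v) {
    x <- sample[[v]]
    categorical <- is.logical(x) || is.factor(x) || is.character(x) ||
      (is.numeric(x) && length(unique(x)) <= 5L && v == "education")
    if (categorical) {
      x <- factor(x)
      summaries <- vapply(levels(g), function(lv) {
        xs <- x[g == lv]
        paste(sprintf("%s: %d (%.1f%%)", levels(x), tabulate(xs, nlevels(x)),
                      100 * tabulate(xs, nlevels(x)) / length(xs)),
              collapse = "; ")
      }, character(1))
      if (nlevels(x) < 2L) {
        return(data.frame(variable = v, type = "categorical",
                          test = "none (constant)",
                          t(summaries), p = NA_real_))
      }
      p <- suppressWarnings(
        stats::chisq.test(table(x, g), correct = FALSE)$p.value)
      data.frame(variable = v, type = "categorical", test = "chi-square",
                 t(summaries), p = p)
    } else {
      summaries <- vapply(levels(g), function(lv) {
        sprintf("%.2f (%.2f)", mean(x[g == lv]), stats::sd(x[g == lv]))
      }, character(1))
      if (length(unique(x)) < 2L) {
        return(data.frame(variable = v, type = "continuous",
                          test = "none (constant)",
                          t(summaries), p = NA_real_))
      }
      if (v %in% nonnormal) {
        p <- stats::kruskal.test(x, g)$p.value
        test <- "kruskal-wallis"
      } else {
        p <- summary(stats::aov(x ~ g))[[1]][["Pr(>F)"]][1]
        test <- "anova"
      }
      data.frame(variable = v, type = "continuous", test = test,
                 t(summaries), p = p)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
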