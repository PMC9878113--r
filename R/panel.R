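#' Area under the ROC curve from scores and binary labels
#'
#' The rank (Mann-Whitney) form: the probability that a random positive
#' scores above a random negative, with ties counted half.
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (0/1, logical, or a two-level factor) of the
#'   same length; the higher level / TRUE / 1 is the positive class.
#' @return AUC in \[0, 1\].
#' @export
auc_from_scores <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)  # mid-ranks handle ties with the half-count convention
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Fit a logistic-regression biomarker panel
#'
#' Maximum-likelihood logistic fit of the class labels on the panel
#' variables; the fitted linear predictor is the panel score whose ranking
#' yields the in-sample AUC. Samples with missing values in any panel
#' variable are dropped and logged. Complete separation (infinite MLE) is
#' detected and the fit retried with a small ridge penalty so scores remain
#' usable; the AUC is a rank statistic and is unaffected.
#'
#' @param features Data.frame or matrix of panel variables, rows = samples.
#' @param labels Binary class vector aligned with the rows.
#' @param regularization Ridge penalty on the coefficients (default 0, pure
#'   ML; used automatically on separation).
#' @return A list with `scores` (linear predictor per retained sample),
#'   `coefficients`, `labels` (retained), `kept` (logical row filter),
#'   `auc`, `deviance`, `null_deviance`, `n_params`, `separated`.
#' @export
fit_logistic_panel <- function(features, labels, regularization = 0) {
  features <- as.data.frame(features)
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels))
  if (nrow(features) != length(labels))
    stop("features and labels must align", call. = FALSE)
  kept <- stats::complete.cases(features)
  if (any(!kept))
    message(sum(!kept), " sample(s) dropped for missing panel values")
  features <- features[kept, , drop = FALSE]
  labels <- labels[kept]
  if (sum(labels == 1L) < 3 || sum(labels == 0L) < 3)
    stop("need at least 3 samples per class", call. = FALSE)

  ridge_fit <- function(lambda) {
    X <- cbind(`(Intercept)` = 1, as.matrix(features))
    beta <- rep(0, ncol(X))
    for (it in seq_len(200)) {            # IRLS with an L2 penalty
      eta <- drop(X %*% beta)
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      z <- eta + (labels - mu) / w
      pen <- diag(c(0, rep(lambda, ncol(X) - 1)), ncol(X))
      beta_new <- solve(crossprod(X, w * X) + pen, crossprod(X, w * z))
      if (max(abs(beta_new - beta)) < 1e-10) { beta <- beta_new; break }
      beta <- beta_new
    }
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    dev <- -2 * sum(labels * log(pmax(mu, 1e-300)) +
                      (1 - labels) * log(pmax(1 - mu, 1e-300)))
    list(beta = drop(beta), eta = eta, dev = dev)
  }

  separated <- FALSE
  if (regularization == 0) {
    fit <- suppressWarnings(
      stats::glm(labels ~ ., data = cbind(features, labels = labels),
                 family = stats::binomial()))
    mu <- stats::fitted(fit)
    separated <- !fit$converged || fit$deviance < 1e-6 ||
      all(mu > 1 - 1e-8 | mu < 1e-8)
    if (separated) {
      rf <- ridge_fit(1e-3)
      scores <- rf$eta; coefs <- rf$beta; dev <- rf$dev
    } else {
      scores <- unname(fit$linear.predictors)
      coefs <- stats::coef(fit)
      dev <- fit$deviance
    }
  } else {
    rf <- ridge_fit(regularization)
    scores <- rf$eta; coefs <- rf$beta; dev <- rf$dev
  }
  p0 <- mean(labels)
  null_dev <- -2 * sum(labels * log(p0) + (1 - labels) * log(1 - p0))
  list(scores = scores, coefficients = coefs, labels = labels, kept = kept,
       auc = auc_from_scores(scores, labels), deviance = dev,
       null_deviance = null_dev, n_params = length(coefs),
       separated = separated)
}

#' Significance of a panel against a nested null model
#'
#' Default mode `"lr"` is the likelihood-ratio chi-square test on the
#' deviance difference with the difference in parameter counts as degrees of
#' freedom. Mode `"deviance_f"` divides the per-parameter deviance drop by
#' the full model's residual deviance scale and refers it to an F
#' distribution, mirroring an F-test phrasing sometimes used for logistic
#' panels. Both models must be fitted on identical samples.
#'
#' @param fit_full,fit_null Fits from [fit_logistic_panel()]; `fit_null` may
#'   be `NULL` to test against the intercept-only model recorded in
#'   `fit_full`.
#' @param mode `"lr"` (default) or `"deviance_f"`.
#' @return P-value.
#' @export
panel_significance <- function(fit_full, fit_null = NULL,
                               mode = c("lr", "deviance_f")) {
  mode <- match.arg(mode)
  n <- length(fit_full$labels)
  if (is.null(fit_null)) {
    dev_null <- fit_full$null_deviance
    df_delta <- fit_full$n_params - 1L
  } else {
    if (length(fit_null$labels) != n || !all(fit_null$labels == fit_full$labels))
      stop("models must be fitted on identical samples", call. = FALSE)
    if (fit_null$n_params > fit_full$n_params)
      stop("models are not nested (null has more parameters)", call. = FALSE)
    dev_null <- fit_null$deviance
    df_delta <- fit_full$n_params - fit_null$n_params
  }
  delta <- max(dev_null - fit_full$deviance, 0)
  if (df_delta == 0) return(1)
  if (mode == "lr")
    return(stats::pchisq(delta, df = df_delta, lower.tail = FALSE))
  df2 <- n - fit_full$n_params
  scale <- max(fit_full$deviance / max(df2, 1), 1e-12)
  fstat <- (delta / df_delta) / scale
  stats::pf(fstat, df1 = df_delta, df2 = max(df2, 1), lower.tail = FALSE)
}

#' Evaluate marker-plus-miRNA diagnostic panels
#'
#' For one clinical marker, evaluates the marker alone and the marker
#' combined with each candidate miRNA for discriminating two groups
#' (by design TGA-RV vs TGA-LV: controls lack the marker labs and drop out of
#' complete cases). Reports the in-sample AUC of each fitted logistic score
#' and a model-vs-null p-value (full panel against intercept-only), with
#' Benjamini-Hochberg adjustment across the miRNA rows of the marker's
#' panel family.
#'
#' @param x An [expr_matrix()] on the log2 scale (miRNA platform).
#' @param annotation Sample annotation with the marker column.
#' @param marker Name of the marker column (e.g. `"ntprobnp"`).
#' @param mirnas Character vector of miRNA feature ids to combine.
#' @param group_pos,group_neg Group labels defining the classes (defaults
#'   `"TGA_RV"` vs `"TGA_LV"`).
#' @param mode Passed to [panel_significance()].
#' @return Data.frame with columns `panel`, `auc`, `p_raw`, `p_adj`,
#'   `n_pos`, `n_neg`.
#' @export
evaluate_marker_panels <- function(x, annotation, marker, mirnas,
                                   group_pos = "TGA_RV", group_neg = "TGA_LV",
                                   mode = c("lr", "deviance_f")) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "expr_matrix"))
  annotation <- validate_annotation(annotation)
  if (!marker %in% colnames(annotation))
    stop("marker column not found: ", marker, call. = FALSE)
  ann <- annotation[annotation$group %in% c(group_pos, group_neg), ]
  ann <- ann[ann$sample_id %in% colnames(x$values), ]
  labels <- as.integer(ann$group == group_pos)
  base <- data.frame(marker = ann[[marker]])
  colnames(base) <- marker

  one_row <- function(vars, panel_name) {
    fit <- suppressMessages(fit_logistic_panel(vars, labels))
    data.frame(panel = panel_name, auc = fit$auc,
               p_raw = panel_significance(fit, mode = mode),
               p_adj = NA_real_,
               n_pos = sum(fit$labels == 1L), n_neg = sum(fit$labels == 0L),
               stringsAsFactors = FALSE)
  }
  rows <- list(one_row(base, marker))
  for (m in mirnas) {
    if (!m %in% rownames(x$values))
      stop("miRNA not in matrix: ", m, call. = FALSE)
    vars <- cbind(base, mir = x$values[m, ann$sample_id])
    colnames(vars)[2] <- m
    rows[[length(rows) + 1L]] <- one_row(vars, paste(marker, m, sep = " + "))
  }
  out <- do.call(rbind, rows)
  if (nrow(out) > 1)
    out$p_adj[-1] <- benjamini_hochberg(out$p_raw[-1])
  out$p_adj[1] <- out$p_raw[1]
  out
}

#' Single-feature screens within a clinical stratum
#'
#' Differential expression between the two classes of a clinical stratum
#' (overt heart failure, or death) using the same t-test / fold-change
#' machinery as the group screens. miRNA platforms report raw p-values (the
#' convention for the small single-feature panels of this design); mRNA
#' platforms report BH-adjusted p-values with the dual fold-change threshold.
#' A warning is issued when a class holds fewer than 3 samples, as is the
#' case for the emulated cohort's strata (n = 4).
#'
#' @param x An [expr_matrix()] on the log2 scale.
#' @param annotation Sample annotation with the stratum flag column.
#' @param stratum `"overt_hf"` or `"death"`.
#' @param fc_threshold,alpha Screening thresholds.
#' @return Data.frame of [call_differential()] records restricted to the
#'   stratum comparison, with a `stratum` column; for miRNA platforms the
#'   `direction` call uses the raw p.
#' @export
stratum_screen <- function(x, annotation, stratum = c("overt_hf", "death"),
                           fc_threshold = 1.5, alpha = 0.05) {
  stratum <- match.arg(stratum)
  stopifnot(inherits(x, "expr_matrix"))
  annotation <- validate_annotation(annotation)
  if (!stratum %in% colnames(annotation))
    stop("annotation lacks a ", stratum, " column", call. = FALSE)
  ann <- annotation[!is.na(annotation[[stratum]]) &
                      annotation$sample_id %in% colnames(x$values), ]
  pos <- ann$sample_id[ann[[stratum]]]
  neg <- ann$sample_id[!ann[[stratum]]]
  if (length(pos) == 0 || length(neg) == 0)
    stop("empty stratum class", call. = FALSE)
  if (length(pos) < 3 || length(neg) < 3)
    warning("a stratum class has fewer than 3 samples; interpret with care")
  rec <- call_differential(x, pos, neg, fc_threshold = fc_threshold,
                           alpha = alpha)
  if (x$platform == "miRNA") {
    # single-feature screens on the miRNA side are reported on the raw p
    rec$direction <- "NotSignificant"
    rec$direction[rec$p_raw < alpha & rec$fold_change >= fc_threshold] <- "Higher"
    rec$direction[rec$p_raw < alpha &
                    rec$fold_change <= 1 / fc_threshold] <- "Lower"
  }
  rec$stratum <- stratum
  rec
}
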