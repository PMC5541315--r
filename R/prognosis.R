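# Gene-age-filtered prognostic signatures --------------------------------------

#' Construct a survival dataset
#'
#' @param expression Numeric matrix, genes in rows, samples in columns
#'   (rownames = gene symbols, colnames = sample ids).
#' @param time Positive follow-up times, one per sample.
#' @param event Event indicator per sample: 1 = metastasis/death observed,
#'   0 = censored.
#' @return A list of class `endo_survival` with elements `expression`, `time`,
#'   `event`.
#' @export
survival_dataset <- function(expression, time, event) {
  expression <- as.matrix(expression)
  if (is.null(rownames(expression))) {
    stop("expression matrix needs gene symbols as rownames")
  }
  ns <- ncol(expression)
  stopifnot(length(time) == ns, length(event) == ns)
  if (any(time <= 0)) stop("follow-up times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0 (censored) or 1 (event)")
  structure(list(expression = expression, time = as.numeric(time),
                 event = as.integer(event)),
            class = "endo_survival")
}

#' Read a survival dataset from TSV files
#'
#' @param expression_table Headered TSV, first column `gene`, remaining columns
#'   one per sample.
#' @param clinical_table Headered TSV with columns `sample`, `time`, `event`.
#' @return A [survival_dataset()]; samples are aligned by id and must match.
#' @export
read_survival_dataset <- function(expression_table, clinical_table) {
  expr <- utils::read.delim(expression_table, stringsAsFactors = FALSE,
                            check.names = FALSE)
  if (names(expr)[1] != "gene") stop("first expression column must be 'gene'")
  mat <- as.matrix(expr[, -1, drop = FALSE])
  rownames(mat) <- expr$gene
  clin <- utils::read.delim(clinical_table, stringsAsFactors = FALSE)
  if (!all(c("sample", "time", "event") %in% names(clin))) {
    stop("clinical table must have columns sample, time, event")
  }
  if (!setequal(clin$sample, colnames(mat))) {
    stop("expression and clinical tables cover different samples")
  }
  clin <- clin[match(colnames(mat), clin$sample), ]
  survival_dataset(mat, clin$time, clin$event)
}

#' Write a survival dataset to TSV files
#'
#' @param ds A [survival_dataset()].
#' @param expression_table,clinical_table Output paths.
#' @return `ds`, invisibly.
#' @export
write_survival_dataset <- function(ds, expression_table, clinical_table) {
  stopifnot(inherits(ds, "endo_survival"))
  expr <- data.frame(gene = rownames(ds$expression), ds$expression,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(expr, expression_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  clin <- data.frame(sample = colnames(ds$expression), time = ds$time,
                     event = ds$event, stringsAsFactors = FALSE)
  utils::write.table(clin, clinical_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(ds)
}

# z-score each gene (row) within the dataset; constant genes become all zero.
.standardize_rows <- function(mat) {
  mu <- rowMeans(mat)
  sd <- apply(mat, 1, stats::sd)
  sd[sd == 0 | is.na(sd)] <- Inf
  (mat - mu) / sd
}

#' Univariate Cox screen over all genes
#'
#' Fits one univariate Cox proportional-hazards model per gene (single
#' covariate = that gene's expression) and reports the regression coefficient
#' (log hazard per expression unit) and Wald p-value. Genes with constant
#' expression or non-convergent fits are skipped with a warning. Expression is
#' z-scored per gene within the dataset by default so coefficients are
#' comparable across genes and platforms.
#'
#' @param ds A [survival_dataset()] with at least two observed events.
#' @param standardize z-score expression per gene before fitting.
#' @param p_threshold Significance cutoff (strict `<`) flagging candidate
#'   genes.
#' @return Data frame with one row per screened gene: `gene`, `coef`, `se`,
#'   `p_value`, `candidate`.
#' @export
cox_screen <- function(ds, standardize = TRUE, p_threshold = 0.001) {
  stopifnot(inherits(ds, "endo_survival"))
  if (sum(ds$event) < 2) stop("need at least two observed events to screen")
  mat <- ds$expression
  if (standardize) mat <- .standardize_rows(mat)
  surv <- survival::Surv(ds$time, ds$event)
  skipped <- character(0)
  rows <- lapply(rownames(mat), function(g) {
    x <- mat[g, ]
    if (stats::sd(x) == 0 || anyNA(x)) {
      skipped <<- c(skipped, g)
      return(NULL)
    }
    fit <- tryCatch(
      suppressWarnings(survival::coxph(surv ~ x)),
      error = function(e) NULL
    )
    if (is.null(fit) || is.na(stats::coef(fit))) {
      skipped <<- c(skipped, g)
      return(NULL)
    }
    s <- summary(fit)$coefficients
    data.frame(gene = g, coef = s[1, "coef"], se = s[1, "se(coef)"],
               p_value = s[1, "Pr(>|z|)"], stringsAsFactors = FALSE)
  })
  if (length(skipped)) {
    warning("skipped gene(s) with constant expression or non-convergent fit: ",
            paste(skipped, collapse = ", "))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene could be screened")
  out$candidate <- out$p_value < p_threshold
  rownames(out) <- NULL
  attr(out, "p_threshold") <- p_threshold
  out
}

#' Select gene-age-based and control signatures
#'
#' From the candidate genes of a training-cohort Cox screen (p below the screen
#' threshold), the gene-age-based signature keeps the candidates whose age
#' stratum lies in `strata`; each kept gene carries the sign of its screening
#' coefficient. The control signature consists of the most significant
#' candidates by p-value from any stratum, matched in size to the age-based
#' signature. Candidates with coefficient exactly zero are excluded from both
#' with a warning (their sign is undefined).
#'
#' @param screen Result of [cox_screen()] on the training cohort.
#' @param ages Named character vector (gene -> stratum).
#' @param strata Age strata admitted to the age-based signature.
#' @return A list of class `endo_signature_pair`: `age_based` and `control`,
#'   each a data frame (`gene`, `sign`, `coef`, `p_value`, `stratum`) with a
#'   `provenance` attribute, plus `strata`.
#' @export
select_signature <- function(screen, ages,
                             strata = c("eukaryota", "opisthokonta",
                                        "eumetazoa")) {
  stopifnot(is.data.frame(screen),
            all(c("gene", "coef", "p_value", "candidate") %in% names(screen)))
  strata <- as.character(as_age_class(strata))
  cand <- screen[screen$candidate, , drop = FALSE]
  zero <- cand$coef == 0
  if (any(zero)) {
    warning("candidate(s) with zero coefficient excluded: ",
            paste(cand$gene[zero], collapse = ", "))
    cand <- cand[!zero, , drop = FALSE]
  }
  cand$stratum <- unname(ages[match(cand$gene, names(ages))])
  age_based <- cand[!is.na(cand$stratum) & cand$stratum %in% strata, ,
                    drop = FALSE]
  if (!nrow(age_based)) {
    stop("no candidate gene falls in the requested strata; relax the screen ",
         "p-value threshold or check the age map")
  }
  control <- cand[order(cand$p_value), , drop = FALSE][seq_len(nrow(age_based)), ]
  shape <- function(d, provenance) {
    out <- data.frame(gene = d$gene,
                      sign = ifelse(d$coef > 0, "positive", "negative"),
                      coef = d$coef, p_value = d$p_value, stratum = d$stratum,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "provenance") <- provenance
    out
  }
  structure(list(age_based = shape(age_based, "age_based"),
                 control = shape(control, "control"),
                 strata = strata),
            class = "endo_signature_pair")
}

#' Per-sample risk score of a signature
#'
#' The risk score is the unweighted sum of expression over genes with a
#' positive screening coefficient minus the sum over genes with a negative
#' coefficient (a Gene-expression-Grade-Index-style score).
#'
#' @param expression Numeric matrix (genes x samples) or a named numeric vector
#'   for a single sample.
#' @param signature A signature data frame (`gene`, `sign`) as produced by
#'   [select_signature()].
#' @return Numeric vector of scores, one per sample.
#' @export
#' @examples
#' sig <- data.frame(gene = c("g1", "g2", "g3"),
#'                   sign = c("positive", "positive", "negative"))
#' risk_score(c(g1 = 2, g2 = 3, g3 = 1), sig)  # 4
risk_score <- function(expression, signature) {
  stopifnot(all(c("gene", "sign") %in% names(signature)))
  if (is.null(dim(expression))) {
    expression <- matrix(expression, ncol = 1,
                         dimnames = list(names(expression), NULL))
  }
  missing <- setdiff(signature$gene, rownames(expression))
  if (length(missing)) {
    stop("signature gene(s) absent from expression: ",
         paste(missing, collapse = ", "))
  }
  pos <- signature$gene[signature$sign == "positive"]
  neg <- signature$gene[signature$sign == "negative"]
  score <- colSums(expression[pos, , drop = FALSE]) -
    colSums(expression[neg, , drop = FALSE])
  stats::setNames(as.numeric(score), colnames(expression))
}

#' Stratify a cohort by risk score and evaluate survival separation
#'
#' Computes the signature risk score per sample, splits the cohort into
#' high-risk and low-risk groups at the within-dataset median score (ties go to
#' the low-risk group), and evaluates the separation by the log-rank test and
#' by the hazard ratio of a Cox proportional-hazards fit on the binary group
#' indicator (high vs low, Efron tie handling).
#'
#' @param ds A [survival_dataset()].
#' @param signature Signature data frame (`gene`, `sign`).
#' @param standardize z-score expression per gene within the dataset before
#'   scoring (matching the screening scale).
#' @return A list of class `endo_risk`: `score` and `group` per sample,
#'   `hazard_ratio`, `hr_ci` (95% Wald interval), `logrank_stat`, `logrank_p`,
#'   `n_high`, `n_low`.
#' @export
stratify_and_evaluate <- function(ds, signature, standardize = TRUE) {
  stopifnot(inherits(ds, "endo_survival"))
  mat <- ds$expression
  if (standardize) mat <- .standardize_rows(mat)
  score <- risk_score(mat, signature)
  group <- factor(ifelse(score > stats::median(score), "high", "low"),
                  levels = c("low", "high"))
  if (any(table(group) == 0)) {
    stop("risk split produced an empty group (degenerate score distribution)")
  }
  surv <- survival::Surv(ds$time, ds$event)
  sd_fit <- survival::survdiff(surv ~ group)
  logrank_p <- stats::pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE)
  cox <- survival::coxph(surv ~ group)
  beta <- unname(stats::coef(cox)[1])
  se <- sqrt(stats::vcov(cox)[1, 1])
  structure(list(score = score, group = group,
                 hazard_ratio = exp(beta),
                 hr_ci = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
                 logrank_stat = unname(sd_fit$chisq),
                 logrank_p = logrank_p,
                 n_high = sum(group == "high"),
                 n_low = sum(group == "low")),
            class = "endo_risk")
}

#' @export
print.endo_risk <- function(x, ...) {
  cat(sprintf(
    "<endo_risk> HR %.3f [%.3f, %.3f], log-rank p %.3g (high n=%d, low n=%d)\n",
    x$hazard_ratio, x$hr_ci[1], x$hr_ci[2], x$logrank_p, x$n_high, x$n_low))
  invisible(x)
}
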