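#' Construct a survival data set
#'
#' @param clinical data.frame with columns \code{sample_id}, \code{time}
#'   (follow-up, days, > 0), \code{event} (1 = death, 0 = censored) and
#'   \code{subtype} (e.g. the gastric-cancer molecular classes CIN, GS, EBV,
#'   MSI).
#' @param expression numeric matrix, genes x samples; columns must cover all
#'   \code{sample_id}s.
#' @return list with class \code{"survival_data"}.
#' @export
survival_data <- function(clinical, expression) {
  stopifnot(all(c("sample_id", "time", "event", "subtype") %in%
                  names(clinical)),
            is.matrix(expression))
  if (any(clinical$time <= 0)) stop("follow-up times must be positive")
  if (!all(clinical$event %in% c(0, 1))) stop("event must be 0 or 1")
  if (!all(clinical$sample_id %in% colnames(expression)))
    stop("expression matrix missing samples")
  structure(list(clinical = clinical,
                 expression = expression[, clinical$sample_id,
                                         drop = FALSE]),
            class = "survival_data")
}

subset_subtype <- function(sd, subtype) {
  if (identical(subtype, "ALL")) return(sd)
  keep <- sd$clinical$subtype == subtype
  survival_data(sd$clinical[keep, , drop = FALSE],
                sd$expression[, keep, drop = FALSE])
}

#' Univariate Cox regression for one gene
#'
#' Fits a single-covariate Cox proportional-hazards model of survival on the
#' gene's expression (partial likelihood, Breslow tie handling, convergence
#' tolerance 1e-8, at most 50 iterations) and returns the coefficient, its
#' standard error and the Wald p-value. Degenerate inputs (fewer than two
#' events, zero expression variance) or non-convergence return a flagged
#' failure instead of an estimate.
#'
#' @param sd \code{survival_data}.
#' @param gene gene id (row of the expression matrix).
#' @return list with \code{beta}, \code{se}, \code{wald_p}, \code{ok} and a
#'   \code{reason} when \code{ok} is FALSE.
#' @export
univariate_cox <- function(sd, gene) {
  fail <- function(reason) list(beta = NA_real_, se = NA_real_,
                                wald_p = NA_real_, ok = FALSE,
                                reason = reason)
  if (!gene %in% rownames(sd$expression))
    stop("gene not in expression matrix: ", gene)
  x <- sd$expression[gene, ]
  if (sum(sd$clinical$event) < 2L) return(fail("fewer than 2 events"))
  if (var(x) == 0) return(fail("zero expression variance"))
  fit <- tryCatch(
    survival::coxph(
      survival::Surv(sd$clinical$time, sd$clinical$event) ~ x,
      ties = "breslow",
      control = survival::coxph.control(eps = 1e-8, iter.max = 50)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit) || anyNA(coef(fit))) return(fail("non-convergence"))
  s <- summary(fit)
  list(beta = unname(coef(fit)), se = unname(s$coefficients[1L, "se(coef)"]),
       wald_p = unname(s$coefficients[1L, "Pr(>|z|)"]), ok = TRUE,
       reason = NA_character_)
}

#' Build a risk-score signature by univariate Cox screening
#'
#' Runs \code{\link{univariate_cox}} per candidate gene and keeps the genes
#' whose Wald p-value is below \code{p_threshold}; their Cox coefficients
#' become the signature weights. Gene order follows the input order. Genes
#' with flagged fit failures are skipped.
#'
#' @param sd \code{survival_data}.
#' @param candidate_genes character vector of candidate gene ids.
#' @param p_threshold screening p cutoff (default 0.05).
#' @return a \code{risk_model}: list with \code{genes}, \code{beta},
#'   \code{n}, and the full \code{screen} table (gene, beta, se, wald_p,
#'   ok).
#' @export
build_signature <- function(sd, candidate_genes, p_threshold = 0.05) {
  stopifnot(length(candidate_genes) >= 1L)
  rows <- lapply(candidate_genes, function(g) {
    r <- univariate_cox(sd, g)
    data.frame(gene = g, beta = r$beta, se = r$se, wald_p = r$wald_p,
               ok = r$ok, stringsAsFactors = FALSE)
  })
  screen <- do.call(rbind, rows)
  keep <- screen$ok & !is.na(screen$wald_p) & screen$wald_p < p_threshold
  if (!any(keep)) warning("no gene passed the survival screen; empty model")
  structure(list(genes = screen$gene[keep], beta = screen$beta[keep],
                 n = sum(keep), screen = screen),
            class = "risk_model")
}

#' Risk score of one sample
#'
#' The signature risk score is the linear combination
#' \code{sum(beta_i * Exp_i)} of the signature genes' expression values
#' weighted by their univariate Cox coefficients. An empty model scores 0.
#'
#' @param model \code{risk_model}.
#' @param expression named numeric vector (gene -> expression value).
#' @return numeric score.
#' @export
risk_score <- function(model, expression) {
  if (model$n == 0L) return(0)
  miss <- setdiff(model$genes, names(expression))
  if (length(miss))
    stop("expression missing signature gene(s): ",
         paste(miss, collapse = ", "))
  sum(model$beta * expression[model$genes])
}

#' Risk scores of all samples in a survival data set
#' @param model \code{risk_model}.
#' @param sd \code{survival_data}.
#' @return named numeric vector of scores, one per sample.
#' @export
risk_scores <- function(model, sd) {
  g <- rownames(sd$expression)
  vapply(seq_len(ncol(sd$expression)), function(j)
    risk_score(model, setNames(sd$expression[, j], g)), 0) |>
    setNames(colnames(sd$expression))
}

#' Median split into high- and low-risk groups
#'
#' The cutoff is the median risk score; samples strictly above it are
#' high-risk, the rest (ties included) low-risk.
#'
#' @param sd \code{survival_data} (>= 2 samples).
#' @param model \code{risk_model}.
#' @return list with \code{high_risk}, \code{low_risk} (sample ids),
#'   \code{cutoff} and the \code{scores} vector.
#' @export
dichotomize <- function(sd, model) {
  stopifnot(nrow(sd$clinical) >= 2L)
  scores <- risk_scores(model, sd)
  if (length(unique(scores)) == 1L) stop("non-informative score")
  cutoff <- median(scores)
  list(high_risk = names(scores)[scores > cutoff],
       low_risk = names(scores)[scores <= cutoff],
       cutoff = cutoff, scores = scores)
}

#' Kaplan-Meier estimate of the survival function
#'
#' Product-limit estimator: S(0) = 1, with a step at every event time;
#' censoring reduces the risk set without a step.
#'
#' @param clinical data.frame with \code{time} and \code{event} columns.
#' @return data.frame (time, n_risk, n_event, n_censor, surv) ordered by
#'   time.
#' @export
km_estimate <- function(clinical) {
  stopifnot(nrow(clinical) >= 1L)
  fit <- survival::survfit(
    survival::Surv(clinical$time, clinical$event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Evaluate a Kaplan-Meier curve at given times
#' @param km output of \code{\link{km_estimate}}.
#' @param t numeric times.
#' @return S(t), right-continuous.
#' @export
km_surv_at <- function(km, t) {
  vapply(t, function(tt) {
    i <- which(km$time <= tt)
    if (length(i)) km$surv[max(i)] else 1
  }, 0)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square with 1 df over the pooled event times.
#'
#' @param a,b clinical data.frames (\code{time}, \code{event}).
#' @return list with \code{statistic}, \code{p}.
#' @export
logrank <- function(a, b) {
  if (sum(a$event) + sum(b$event) == 0L) stop("no events in either group")
  df <- rbind(data.frame(time = a$time, event = a$event, grp = "A"),
              data.frame(time = b$time, event = b$event, grp = "B"))
  ht <- survival::survdiff(survival::Surv(time, event) ~ grp, data = df)
  list(statistic = unname(ht$chisq),
       p = pchisq(unname(ht$chisq), df = 1, lower.tail = FALSE))
}

#' Subtype-stratified prognostic marker classification
#'
#' For each subtype (\code{"ALL"} applies no filter), screens each candidate
#' gene with a univariate Cox fit on the subtype's samples and keeps genes
#' with Wald p below \code{p_threshold}. A retained gene is classed
#' \code{"Risky"} when higher expression associates with worse survival
#' (beta > 0) and \code{"Protective"} otherwise. Subtypes with fewer than
#' two events are skipped with a warning.
#'
#' @param sd \code{survival_data}.
#' @param candidate_genes character vector.
#' @param subtypes subtype labels to screen (default ALL plus the four
#'   molecular subtypes).
#' @param p_threshold p cutoff (default 0.05).
#' @return data.frame (gene, subtype, beta, p, class).
#' @export
subtype_markers <- function(sd, candidate_genes,
                            subtypes = c("ALL", "CIN", "GS", "EBV", "MSI"),
                            p_threshold = 0.05) {
  out <- list()
  for (st in subtypes) {
    ssd <- subset_subtype(sd, st)
    if (sum(ssd$clinical$event) < 2L) {
      warning("subtype ", st, " skipped: fewer than 2 events")
      next
    }
    for (g in candidate_genes) {
      r <- univariate_cox(ssd, g)
      if (!r$ok || is.na(r$wald_p) || r$wald_p >= p_threshold) next
      out[[length(out) + 1L]] <- data.frame(
        gene = g, subtype = st, beta = r$beta, p = r$wald_p,
        class = if (r$beta > 0) "Risky" else "Protective",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene = character(), subtype = character(),
                      beta = numeric(), p = numeric(), class = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
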