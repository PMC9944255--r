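# Cox proportional-hazards association of signature scores with overall
# survival, reported as hazard ratios scaled to the score IQR. Single
# continuous covariate, Breslow (default) or Efron tie handling, Newton
# iterations on the partial log-likelihood.

#' Build a survival record table
#'
#' @param sample_id Unique sample identifiers.
#' @param time Follow-up durations, strictly positive (units opaque).
#' @param event 1 = death observed, 0 = censored.
#' @return data.frame of class \code{SurvivalRecords}.
#' @export
survival_records <- function(sample_id, time, event) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids")
  stopifnot(length(time) == length(sample_id),
            length(event) == length(sample_id))
  if (any(!is.finite(time)) || any(time <= 0)) stop("time must be > 0")
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1")
  structure(data.frame(sample_id = sample_id, time = as.numeric(time),
                       event = as.integer(event), stringsAsFactors = FALSE),
            class = c("SurvivalRecords", "data.frame"))
}

#' Read a clinical table
#'
#' Delimited text with columns sample_id, os_time, os_event and optionally
#' group.
#'
#' @param path File path.
#' @return A [survival_records()] table with a \code{group} attribute when
#'   present.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "os_time", "os_event")
  if (!all(need %in% names(df))) {
    stop("clinical table needs columns: ", paste(need, collapse = ", "))
  }
  out <- survival_records(df$sample_id, df$os_time, df$os_event)
  if ("group" %in% names(df)) {
    attr(out, "group") <- stats::setNames(df$group, df$sample_id)
  }
  out
}

# Partial log-likelihood, score and information for a single covariate at
# beta; Breslow or Efron handling of tied event times.
.cox_derivs <- function(beta, time, event, x, ties = "breslow") {
  ord <- order(time, -event)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  n <- length(time)
  eta <- beta * x
  w <- exp(eta)
  # risk-set sums from the tail
  s0 <- rev(cumsum(rev(w)))
  s1 <- rev(cumsum(rev(w * x)))
  s2 <- rev(cumsum(rev(w * x^2)))
  ll <- 0; sc <- 0; info <- 0
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && time[j + 1L] == time[i]) j <- j + 1L
    d_idx <- i:j
    d_idx <- d_idx[event[d_idx] == 1L]
    d <- length(d_idx)
    if (d > 0L) {
      if (ties == "breslow") {
        ll <- ll + sum(eta[d_idx]) - d * log(s0[i])
        sc <- sc + sum(x[d_idx]) - d * s1[i] / s0[i]
        info <- info + d * (s2[i] / s0[i] - (s1[i] / s0[i])^2)
      } else {  # efron
        wd <- sum(w[d_idx]); wx <- sum(w[d_idx] * x[d_idx])
        wx2 <- sum(w[d_idx] * x[d_idx]^2)
        for (l in seq_len(d) - 1L) {
          f <- l / d
          a0 <- s0[i] - f * wd
          a1 <- s1[i] - f * wx
          a2 <- s2[i] - f * wx2
          ll <- ll - log(a0)
          sc <- sc - a1 / a0
          info <- info + a2 / a0 - (a1 / a0)^2
        }
        ll <- ll + sum(eta[d_idx])
        sc <- sc + sum(x[d_idx])
      }
    }
    i <- j + 1L
  }
  list(loglik = ll, score = sc, info = info)
}

#' Fit a univariate Cox proportional-hazards model
#'
#' Maximizes the partial likelihood for a single continuous covariate
#' (the signature score) by Newton-Raphson, stopping when the change in
#' log-likelihood falls below \code{tol}. Standard error comes from the
#' observed information at the maximum.
#'
#' @param scores Numeric score vector, or a named vector matched to
#'   \code{surv$sample_id}.
#' @param surv A [survival_records()] table.
#' @param ties \code{"breslow"} (default) or \code{"efron"}.
#' @param tol Convergence tolerance on |change in loglik| (default 1e-9).
#' @param max_iter Maximum Newton iterations (default 50).
#' @return List: beta, se, loglik, loglik_null, n, n_events, iter, ties.
#' @export
fit_cox <- function(scores, surv, ties = c("breslow", "efron"),
                    tol = 1e-9, max_iter = 50L) {
  ties <- match.arg(ties)
  stopifnot(inherits(surv, "SurvivalRecords"))
  if (!is.null(names(scores))) {
    scores <- scores[surv$sample_id]
    if (anyNA(scores)) stop("scores missing for some samples")
  }
  stopifnot(length(scores) == nrow(surv))
  x <- as.numeric(scores)
  time <- surv$time; event <- surv$event
  if (sum(event) < 2L) stop("need >= 2 events to fit a Cox model")
  if (stats::sd(x) == 0) stop("scores are constant: no information")
  beta <- 0
  d0 <- .cox_derivs(beta, time, event, x, ties)
  ll_null <- d0$loglik
  ll_old <- d0$loglik
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (d0$info <= 0) stop("non-positive information; model degenerate")
    step <- d0$score / d0$info
    beta_new <- beta + step
    d1 <- .cox_derivs(beta_new, time, event, x, ties)
    # step-halving if the likelihood worsens
    halves <- 0L
    while (d1$loglik < ll_old && halves < 20L) {
      step <- step / 2
      beta_new <- beta + step
      d1 <- .cox_derivs(beta_new, time, event, x, ties)
      halves <- halves + 1L
    }
    beta <- beta_new
    conv <- abs(d1$loglik - ll_old) < tol
    ll_old <- d1$loglik
    d0 <- d1
    if (conv) break
    if (iter >= max_iter) {
      stop(sprintf(paste0("Cox fit did not converge in %d iterations ",
                          "(beta = %.4g, score = %.4g, loglik = %.6g)"),
                   max_iter, beta, d0$score, d0$loglik))
    }
  }
  list(beta = beta, se = 1 / sqrt(d0$info), loglik = d0$loglik,
       loglik_null = ll_null, n = length(x), n_events = sum(event),
       iter = iter, ties = ties)
}

#' IQR-scaled hazard ratio
#'
#' HRs for a continuous score are rescaled to compare two subjects whose
#' scores differ by the interquartile range of the observed scores:
#' \code{hr_iqr = exp(beta * IQR)}, with a Wald 95\% CI. Quantiles use
#' linear interpolation between order statistics (type 7).
#'
#' @param beta,se Log-hazard per score unit and its standard error.
#' @param scores The score vector whose IQR sets the scale (>= 4 values).
#' @return A \code{HazardEstimate} list: beta, se, hr_iqr, ci95_iqr
#'   (length-2), iqr_used.
#' @export
iqr_scaled_hr <- function(beta, se, scores) {
  if (!is.finite(beta) || !is.finite(se)) stop("beta and se must be finite")
  scores <- scores[is.finite(scores)]
  if (length(scores) < 4L) stop("need >= 4 score values for an IQR")
  qs <- stats::quantile(scores, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- qs[2] - qs[1]
  if (iqr == 0) stop("zero IQR: hazard ratio scale undefined")
  ci <- exp((beta + c(-1, 1) * 1.96 * se) * iqr)
  structure(list(beta = beta, se = se, hr_iqr = exp(beta * iqr),
                 ci95_iqr = ci, iqr_used = iqr),
            class = "HazardEstimate")
}

#' @export
print.HazardEstimate <- function(x, ...) {
  cat(sprintf("HR per IQR (%.3g): %.3f [%.3f, %.3f]\n", x$iqr_used,
              x$hr_iqr, x$ci95_iqr[1], x$ci95_iqr[2]))
  invisible(x)
}

#' Survival association panel over groups and signatures
#'
#' One Cox fit and IQR-scaled hazard ratio per (group x signature) on the
#' samples shared by the score table and the survival records. Groups or
#' signatures failing fit preconditions (too few events, constant scores,
#' zero IQR) are reported in the \code{note} column rather than raised.
#'
#' @param scoretable A [score_table()] with group labels (or none: one
#'   group \code{"all"}).
#' @param surv A [survival_records()] table.
#' @param ties Passed to [fit_cox()].
#' @return data.frame (group, signature, n, n_events, beta, se, hr_iqr,
#'   ci_lo, ci_hi, iqr, note).
#' @export
survival_panel <- function(scoretable, surv, ties = "breslow") {
  stopifnot(inherits(scoretable, "ScoreTable"),
            inherits(surv, "SurvivalRecords"))
  shared <- intersect(scoretable$sample_ids, surv$sample_id)
  if (length(shared) == 0L) stop("no shared samples")
  group <- scoretable$group
  if (is.null(group)) {
    group <- stats::setNames(rep("all", length(scoretable$sample_ids)),
                             scoretable$sample_ids)
  }
  group <- group[shared]
  rows <- list()
  for (g in unique(group)) {
    ids <- shared[group == g]
    sub <- surv[match(ids, surv$sample_id), ]
    class(sub) <- class(surv)
    for (sig in scoretable$signature_names) {
      sc <- scoretable$scores[ids, sig]
      res <- tryCatch({
        fit <- fit_cox(stats::setNames(sc, ids), sub, ties = ties)
        hr <- iqr_scaled_hr(fit$beta, fit$se, sc)
        data.frame(group = g, signature = sig, n = fit$n,
                   n_events = fit$n_events, beta = fit$beta, se = fit$se,
                   hr_iqr = hr$hr_iqr, ci_lo = hr$ci95_iqr[1],
                   ci_hi = hr$ci95_iqr[2], iqr = hr$iqr_used, note = "",
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(group = g, signature = sig, n = length(ids),
                   n_events = sum(sub$event), beta = NA_real_,
                   se = NA_real_, hr_iqr = NA_real_, ci_lo = NA_real_,
                   ci_hi = NA_real_, iqr = NA_real_,
                   note = conditionMessage(e), stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
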