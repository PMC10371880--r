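#' Two-sided Mann-Whitney rank-sum p-value
#'
#' Exact by enumeration of all labelings when both samples have at most 8
#' values (ties handled through the permutation distribution of the
#' rank-sum statistic); otherwise the tie-corrected normal approximation
#' with continuity correction. With every value tied across both samples
#' the test is uninformative and p = 1.
#'
#' @param a,b numeric samples (each length >= 1).
#' @return two-sided p-value in `(0, 1]`.
#' @export
rank_sum_p <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  if (length(unique(c(a, b))) == 1L) return(1)
  u_of <- function(rsum, n1) rsum - n1 * (n1 + 1) / 2
  u_obs <- u_of(sum(r[seq_len(n1)]), n1)
  mu <- n1 * n2 / 2
  if (n1 <= 8L && n2 <= 8L) {
    labs <- utils::combn(n1 + n2, n1)
    us <- apply(labs, 2L, function(ix) u_of(sum(r[ix]), n1))
    return(min(1, mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)))
  }
  n <- n1 + n2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-max(z, 0)))
}

#' Rank-based AUC of a score against a binary label
#'
#' Probability that a randomly chosen positive outranks a randomly chosen
#' negative, with ties counting one half -- the Mann-Whitney statistic
#' normalized by `n1 * n0`. For a univariate monotone score this equals
#' the AUC of a univariate logistic regression on that score.
#'
#' @param scores numeric vector.
#' @param labels binary vector (0/1 or logical), positives = 1.
#' @return AUC in `[0, 1]`, or `NA` when only one class is present.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Run a simulated cohort through both algorithm variants
#'
#' For each virtual-patient spec, simulates the recording once and runs
#' both the fine-tuned (`config_new`) and previous (`config_prev`)
#' configurations on the identical input, collecting a [trend_report()]
#' per patient and variant, cohort summaries (median and IQR of stability
#' index and yield per variant) and Mann-Whitney p-values comparing the
#' variants. A synthetic binary outcome ("died") is drawn per patient
#' with probability `plogis(outcome_beta[1] + outcome_beta[2] *
#' (-delta_cppopt))`, so running CPP below the estimated optimum raises
#' mortality risk; set `outcome_beta[2] = 0` for a null cohort.
#'
#' @param specs list of [virtual_patient_spec()].
#' @param config_new,config_prev the two [cppopt_config()] arms.
#' @param outcome_beta length-2 numeric `c(intercept, slope)` on the
#'   `-delta` scale (default `c(-1.5, 0.4)`).
#' @param seed seed for the outcome draws.
#' @return A `cohort_result`: `per_patient` data frame (one row per
#'   patient x variant), `summary` data frame, `stability_p`, `yield_p`.
#' @export
run_cohort <- function(specs, config_new = cppopt_config("new"),
                       config_prev = cppopt_config("previous"),
                       outcome_beta = c(-1.5, 0.4), seed = 1L) {
  stopifnot(length(specs) >= 1L)
  arms <- list(new = config_new, previous = config_prev)
  rows <- list()
  deltas <- numeric(length(specs))
  for (p in seq_along(specs)) {
    rec <- simulate_patient(specs[[p]])
    for (arm in names(arms)) {
      tr <- compute_cppopt(rec$abp10, rec$icp10, arms[[arm]])
      rep_ <- trend_report(tr)
      rows[[length(rows) + 1L]] <- data.frame(
        patient = p, variant = arm,
        stability_index = rep_$stability_index,
        yield_pct = rep_$yield_pct,
        delta_cppopt = rep_$delta_cppopt,
        n_jumps = rep_$n_jumps,
        plausible_frac = rep_$plausible_frac,
        first_value_time = rep_$first_value_time,
        warmed_up = tr$warmed_up)
      if (arm == "new")
        deltas[p] <- if (is.na(rep_$delta_cppopt)) 0 else rep_$delta_cppopt
    }
  }
  per_patient <- do.call(rbind, rows)
  p_death <- stats::plogis(outcome_beta[1] + outcome_beta[2] * (-deltas))
  died <- with_seed(seed, stats::rbinom(length(specs), 1L, p_death))
  per_patient$died <- died[per_patient$patient]
  summ <- do.call(rbind, lapply(split(per_patient, per_patient$variant),
                                function(d) data.frame(
    variant = d$variant[1],
    stability_median = stats::median(d$stability_index, na.rm = TRUE),
    stability_iqr_lo = stats::quantile(d$stability_index, 0.25, na.rm = TRUE,
                                       names = FALSE),
    stability_iqr_hi = stats::quantile(d$stability_index, 0.75, na.rm = TRUE,
                                       names = FALSE),
    yield_median = stats::median(d$yield_pct, na.rm = TRUE),
    yield_iqr_lo = stats::quantile(d$yield_pct, 0.25, na.rm = TRUE,
                                   names = FALSE),
    yield_iqr_hi = stats::quantile(d$yield_pct, 0.75, na.rm = TRUE,
                                   names = FALSE))))
  rownames(summ) <- NULL
  sn <- per_patient[per_patient$variant == "new", ]
  sp <- per_patient[per_patient$variant == "previous", ]
  structure(
    list(per_patient = per_patient, summary = summ,
         stability_p = safe_ranksum(sn$stability_index, sp$stability_index),
         yield_p = safe_ranksum(sn$yield_pct, sp$yield_pct)),
    class = "cohort_result"
  )
}

safe_ranksum <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) return(NA_real_)
  rank_sum_p(a, b)
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d patients x 2 variants\n",
              length(unique(x$per_patient$patient))))
  print(x$summary, row.names = FALSE)
  cat(sprintf("  stability p = %.3g, yield p = %.3g\n",
              x$stability_p, x$yield_p))
  invisible(x)
}
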