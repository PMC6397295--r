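# Survival association of module activities: extreme-percentile
# stratification + log-rank test (survival::survdiff), and a small
# product-limit estimator for Kaplan-Meier curves.

#' Read survival records from TSV
#'
#' Header `sample<TAB>time<TAB>event`; `time >= 0`, `event` 1 = event
#' (death), 0 = censored.
#'
#' @param path path to a tab-delimited file.
#' @return data.frame with columns `sample`, `time`, `event`.
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) stop(sprintf("survival file '%s' does not exist", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  names(df)[1:3] <- c("sample", "time", "event")
  validate_survival(df)
}

validate_survival <- function(df) {
  df$sample <- as.character(df$sample)
  df$time <- as.numeric(df$time)
  df$event <- as.integer(df$event)
  if (anyDuplicated(df$sample))
    stop(sprintf("duplicate sample '%s' in survival data",
                 df$sample[duplicated(df$sample)][1]))
  if (any(is.na(df$time)) || any(df$time < 0))
    stop("survival times must be non-negative numbers")
  if (!all(df$event %in% c(0L, 1L)))
    stop("event must be 0 (censored) or 1 (event)")
  df[c("sample", "time", "event")]
}

#' Kaplan-Meier product-limit curve
#'
#' @param records data.frame with columns `time` and `event` (1 = event,
#'   0 = censored); at least one record.
#' @return data.frame with one row per distinct event time: `time`,
#'   `n_risk`, `n_event`, `survival` (the estimate just after that time).
#'   The curve starts at 1 and is non-increasing; with no events it is
#'   identically 1.
#' @export
km_curve <- function(records) {
  stopifnot(nrow(records) >= 1L)
  time <- records$time
  event <- records$event
  ts <- sort(unique(time[event == 1]))
  surv <- 1
  out <- lapply(ts, function(tt) {
    n_risk <- sum(time >= tt)
    n_event <- sum(time == tt & event == 1)
    surv <<- surv * (1 - n_event / n_risk)
    data.frame(time = tt, n_risk = n_risk, n_event = n_event,
               survival = surv)
  })
  if (length(out) == 0L)
    return(data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), survival = numeric(0)))
  do.call(rbind, out)
}

# two-group log-rank via survival::survdiff; returns chi-square and p
logrank_test <- function(time, event, group) {
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chisq <- unname(sd$chisq)
  list(chisq = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Associate module activities with patient survival
#'
#' For each module, samples are ranked by activity and the upper and lower
#' `percentile` extremes (group sizes `ceiling(percentile * n)`) are
#' compared with the two-group log-rank test; boundary ties are broken by
#' sample-id order. P-values are FDR-adjusted across modules.
#'
#' @param act modules x samples activity matrix.
#' @param surv data.frame with columns `sample`, `time`, `event` (see
#'   [read_survival()]). Samples without survival data are dropped per
#'   module.
#' @param percentile extreme fraction in (0, 0.5\] (default 0.20).
#' @return data.frame sorted by `fdr_p` with columns `module_id`,
#'   `chi_square`, `p_value`, `fdr_p`, `n_high`, `n_low`.
#' @export
module_survival_association <- function(act, surv, percentile = 0.20) {
  stopifnot(is.matrix(act))
  surv <- validate_survival(surv)
  if (percentile <= 0 || percentile > 0.5)
    stop("percentile must lie in (0, 0.5]")
  common <- intersect(colnames(act), surv$sample)
  n <- length(common)
  g <- ceiling(percentile * n)
  if (n < 2L * g || g < 1L)
    stop(sprintf("need at least 2*ceiling(percentile*n) samples with both activity and survival data (have %d)", n))
  surv <- surv[match(common, surv$sample), ]

  rows <- lapply(rownames(act), function(m) {
    a <- act[m, common]
    ord <- order(-a, common)          # high first; ties by sample id
    high <- common[ord[seq_len(g)]]
    low <- common[rev(ord)[seq_len(g)]]
    if (length(intersect(high, low)))
      stop(sprintf("module '%s': high and low percentile groups overlap; reduce percentile", m))
    sel <- c(high, low)
    grp <- rep(c("high", "low"), each = g)
    ss <- surv[match(sel, surv$sample), ]
    lr <- logrank_test(ss$time, ss$event, grp)
    data.frame(module_id = m, chi_square = lr$chisq, p_value = lr$p,
               n_high = g, n_low = g, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_p <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$fdr_p, out$p_value, out$module_id),
             c("module_id", "chi_square", "p_value", "fdr_p",
               "n_high", "n_low")]
  rownames(out) <- NULL
  out
}
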