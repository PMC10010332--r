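#' Mixed-response classification and survival comparison
#'
#' Patients on PD-1 blockade monotherapy are classified from their
#' per-lesion diameter trajectories during the first six months of therapy:
#' nonmixed responders (every lesion regressing, no new lesions), mixed
#' responders (regressing and progressing lesions simultaneously, or a
#' regressing lesion plus a new lesion), and nonmixed nonresponders
#' (progression without regression at any site). Progression-free and
#' overall survival are then compared across groups with the Kaplan-Meier
#' estimator and a log-rank test.
#'
#' @name response_survival
NULL

#' Per-lesion change classification within the assessment window
#'
#' Percent change from baseline is evaluated at every scan inside the
#' window. A lesion is regressing when any scan reaches -30% or below,
#' progressing when any scan reaches +20% or above or when the lesion is new
#' (first detected after baseline). A lesion that both regresses and
#' progresses within the window contributes to both flags — responses are
#' dynamic and can evolve — and is categorised `progressing`.
#'
#' @param lesions data.frame for one patient with columns `lesion`,
#'   `time_days`, `diameter_mm`, `is_new`.
#' @param window_days assessment window (inclusive).
#' @param regress_pct,progress_pct per-lesion thresholds (percent change).
#' @return data.frame with one row per lesion: `lesion`, `best_change_pct`
#'   (most negative change observed), `worst_change_pct`, `regressing`,
#'   `progressing`, `is_new`, `category` (`regressing`/`progressing`/
#'   `stable`), `evaluable`.
#' @export
lesion_change <- function(lesions, window_days = 183,
                          regress_pct = -30, progress_pct = 20) {
  stopifnot(is.data.frame(lesions),
            all(c("lesion", "time_days", "diameter_mm", "is_new")
                %in% names(lesions)),
            all(lesions$diameter_mm >= 0))
  out <- lapply(split(lesions, lesions$lesion), function(tr) {
    new_lesion <- any(tr$is_new)
    base <- tr[tr$time_days == 0, , drop = FALSE]
    scans <- tr[tr$time_days > 0 & tr$time_days <= window_days, , drop = FALSE]
    if (new_lesion) {
      # a lesion absent at baseline: its appearance is progression
      return(data.frame(lesion = tr$lesion[1], best_change_pct = NA_real_,
                        worst_change_pct = NA_real_, regressing = FALSE,
                        progressing = TRUE, is_new = TRUE,
                        category = "progressing", evaluable = TRUE))
    }
    if (nrow(base) == 0 || base$diameter_mm[1] <= 0 || nrow(scans) == 0) {
      return(data.frame(lesion = tr$lesion[1], best_change_pct = NA_real_,
                        worst_change_pct = NA_real_, regressing = FALSE,
                        progressing = FALSE, is_new = FALSE,
                        category = NA_character_, evaluable = FALSE))
    }
    change <- 100 * (scans$diameter_mm - base$diameter_mm[1]) / base$diameter_mm[1]
    reg <- any(change <= regress_pct)
    pro <- any(change >= progress_pct)
    data.frame(lesion = tr$lesion[1],
               best_change_pct = min(change), worst_change_pct = max(change),
               regressing = reg, progressing = pro, is_new = FALSE,
               category = if (pro) "progressing" else if (reg) "regressing" else "stable",
               evaluable = TRUE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Classify a patient's response as mixed or nonmixed
#'
#' @param lesions one patient's lesion observations (see [lesion_change()]).
#' @param window_days assessment window in days.
#' @param regress_pct,progress_pct per-lesion thresholds.
#' @return one of `"nonmixed_responder"`, `"mixed_responder"`,
#'   `"nonmixed_nonresponder"`, `"stable_unclassified"` (all evaluable
#'   lesions stable — outside the three-group taxonomy, excluded from group
#'   comparisons) or `NA` when no lesion is evaluable.
#' @examples
#' les <- data.frame(lesion = rep(c("a", "b"), each = 2),
#'                   time_days = c(0, 90, 0, 90),
#'                   diameter_mm = c(20, 12, 20, 26), is_new = FALSE)
#' classify_response(les)  # mixed_responder
#' @export
classify_response <- function(lesions, window_days = 183,
                              regress_pct = -30, progress_pct = 20) {
  lc <- lesion_change(lesions, window_days, regress_pct, progress_pct)
  lc <- lc[lc$evaluable, , drop = FALSE]
  if (nrow(lc) == 0) return(NA_character_)
  any_reg <- any(lc$regressing)
  any_pro <- any(lc$progressing)  # includes new lesions
  if (any_reg && any_pro) return("mixed_responder")
  if (any_reg && !any_pro) {
    # responder only if nothing is left behind: all lesions regressing
    if (all(lc$regressing)) return("nonmixed_responder")
    return("stable_unclassified")
  }
  if (any_pro) return("nonmixed_nonresponder")
  "stable_unclassified"
}

#' Total tumor burden at a scan
#'
#' Burden is the sum of the diameters of all measured lesions at the queried
#' time.
#'
#' @param lesions one patient's lesion observations.
#' @param time scan time in days.
#' @return burden in mm (0 when no lesion is measured at that time).
#' @export
tumor_burden <- function(lesions, time) {
  sum(lesions$diameter_mm[lesions$time_days == time])
}

#' Simplified RECIST category over the assessment window
#'
#' Target-lesion response on total burden: CR when the burden reaches 0, PR
#' when it falls to -30% or below of baseline, PD when it rises +20% or more
#' above the nadir (baseline included) or a new lesion appears, SD
#' otherwise. Node-size rules, target-lesion selection and confirmation
#' scans are not modelled.
#'
#' @param lesions one patient's lesion observations.
#' @param window_days assessment window.
#' @return `"CR"`, `"PR"`, `"SD"`, `"PD"`, or `NA` when inevaluable.
#' @export
recist_category <- function(lesions, window_days = 183) {
  times <- sort(unique(lesions$time_days[lesions$time_days <= window_days]))
  if (!(0 %in% times) || length(times) < 2) return(NA_character_)
  burden <- vapply(times, function(t) tumor_burden(lesions, t), numeric(1))
  b0 <- burden[1]
  if (b0 <= 0) return(NA_character_)
  new_lesion <- any(lesions$is_new & lesions$time_days <= window_days)
  post <- burden[-1]
  nadir <- cummin(burden)[-length(burden)]  # nadir before each post scan
  pd <- new_lesion || any(100 * (post - nadir) / nadir >= 20)
  if (pd) return("PD")
  if (any(post == 0)) return("CR")
  if (any(100 * (post - b0) / b0 <= -30)) return("PR")
  "SD"
}

#' Kaplan-Meier product-limit estimator
#'
#' S(t) = prod over event times t_j <= t of (1 - d_j / n_j), with d_j events
#' and n_j subjects at risk at t_j. Under zero censoring S(t) equals the
#' empirical fraction surviving past t. The median survival is the earliest
#' time at which S(t) drops to 0.5 or below (`NA` if never reached).
#'
#' @param times non-negative follow-up times.
#' @param events event indicators (1/TRUE = event, 0/FALSE = censored).
#' @return list of class `"km_fit"`: `time` (distinct event times),
#'   `n_risk`, `n_event`, `survival`, `median`.
#' @examples
#' km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
#' km$survival  # 2/3, 1/3, 0
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) > 0, length(times) == length(events),
            all(times >= 0))
  events <- as.logical(events)
  tt <- sort(unique(times[events]))
  n_risk <- vapply(tt, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(tt, function(t) sum(times == t & events), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  med <- if (any(surv <= 0.5)) tt[which(surv <= 0.5)[1]] else NA_real_
  structure(list(time = tt, n_risk = n_risk, n_event = n_event,
                 survival = surv, median = med),
            class = "km_fit")
}

#' Evaluate a Kaplan-Meier fit at arbitrary times
#'
#' @param fit a `"km_fit"`.
#' @param t times at which to evaluate S(t).
#' @return survival probabilities (1 before the first event).
#' @export
km_survival_at <- function(fit, t) {
  stopifnot(inherits(fit, "km_fit"))
  vapply(t, function(x) {
    j <- sum(fit$time <= x)
    if (j == 0) 1 else fit$survival[j]
  }, numeric(1))
}

#' @export
print.km_fit <- function(x, ...) {
  cat("Kaplan-Meier fit:", length(x$time), "event times; median =",
      ifelse(is.na(x$median), "not reached", x$median), "\n")
  invisible(x)
}

#' Log-rank test across groups
#'
#' The standard observed-minus-expected log-rank statistic: at each pooled
#' event time, each group's expected events are d * n_g / n; the chi-square
#' statistic is (O - E)' V^-1 (O - E) over the first k-1 groups, with the
#' hypergeometric covariance of event counts, on k - 1 degrees of freedom.
#'
#' @param group group labels (>= 2 non-empty groups).
#' @param times follow-up times.
#' @param events event indicators.
#' @return list with `statistic`, `df`, `p_value`, and per-group `observed`
#'   and `expected`.
#' @export
logrank_test <- function(group, times, events) {
  stopifnot(length(group) == length(times), length(times) == length(events))
  group <- factor(group)
  if (nlevels(group) < 2) stop("log-rank needs at least two groups")
  if (any(table(group) == 0)) stop("a group has no subjects")
  events <- as.logical(events)
  k <- nlevels(group)
  tt <- sort(unique(times[events]))
  O <- E <- stats::setNames(numeric(k), levels(group))
  V <- matrix(0, k, k)
  for (t in tt) {
    at_risk <- times >= t
    n <- sum(at_risk)
    d <- sum(times == t & events)
    ng <- vapply(levels(group), function(g) sum(at_risk & group == g),
                 numeric(1))
    dg <- vapply(levels(group), function(g) {
      sum(times == t & events & group == g)
    }, numeric(1))
    O <- O + dg
    E <- E + d * ng / n
    if (n > 1) {
      # multivariate hypergeometric covariance of the event-count vector
      Vt <- (d * (n - d) / (n - 1)) *
        (diag(ng / n, k) - (ng %o% ng) / n^2)
      V <- V + Vt
    }
  }
  i <- seq_len(k - 1)
  diff <- (O - E)[i]
  Vi <- V[i, i, drop = FALSE]
  stat <- if (all(abs(diff) < 1e-12)) 0 else {
    as.numeric(diff %*% solve(Vi, diff))
  }
  list(statistic = stat, df = k - 1,
       p_value = stats::pchisq(stat, df = k - 1, lower.tail = FALSE),
       observed = O, expected = E)
}

round_half_up <- function(x, digits = 1) {
  # printed percentages use arithmetic (half-up) rounding, not banker's
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Cohort summary of response groups
#'
#' Classifies every patient and tabulates response-group frequencies per
#' cancer type and per simplified RECIST category, with a pooled row.
#' Percentages are rounded half-up to one decimal.
#'
#' @param lesions cohort lesion observations (`patient, lesion, time_days,
#'   diameter_mm, is_new`).
#' @param patients cohort patient table (`patient, cancer_type, pfs_days,
#'   pfs_event, os_days, os_event, local_therapy`).
#' @param window_days assessment window.
#' @return list with `classified` (patient table plus `response_group` and
#'   `recist`), `by_cancer_type` and `by_recist` frequency data.frames
#'   (counts, `mixed_pct`), and `pooled` (n, mixed count/percentage, local
#'   therapy count/percentage among mixed responders).
#' @export
cohort_summary <- function(lesions, patients, window_days = 183) {
  stopifnot(all(c("patient", "cancer_type") %in% names(patients)))
  split_lesions <- split(lesions, lesions$patient)
  patients$response_group <- vapply(patients$patient, function(p) {
    pl <- split_lesions[[as.character(p)]]
    if (is.null(pl)) return(NA_character_)
    classify_response(pl, window_days)
  }, character(1))
  patients$recist <- vapply(patients$patient, function(p) {
    pl <- split_lesions[[as.character(p)]]
    if (is.null(pl)) return(NA_character_)
    recist_category(pl, window_days)
  }, character(1))

  freq_by <- function(key) {
    groups <- split(patients, patients[[key]])
    rows <- lapply(names(groups), function(g) {
      gp <- groups[[g]]
      n_mixed <- sum(gp$response_group == "mixed_responder", na.rm = TRUE)
      data.frame(level = g, n = nrow(gp), mixed = n_mixed,
                 mixed_pct = round_half_up(100 * n_mixed / nrow(gp)))
    })
    out <- do.call(rbind, rows)
    names(out)[1] <- key
    out
  }
  n_mixed <- sum(patients$response_group == "mixed_responder", na.rm = TRUE)
  mixed <- patients[!is.na(patients$response_group) &
                      patients$response_group == "mixed_responder", ]
  n_local <- if (!is.null(mixed$local_therapy)) {
    sum(as.logical(mixed$local_therapy))
  } else NA_integer_
  list(classified = patients,
       by_cancer_type = freq_by("cancer_type"),
       by_recist = freq_by("recist"),
       pooled = list(
         n = nrow(patients),
         mixed = n_mixed,
         mixed_pct = round_half_up(100 * n_mixed / nrow(patients)),
         mixed_local_therapy = n_local,
         mixed_local_therapy_pct = if (n_mixed > 0 && !is.na(n_local)) {
           round_half_up(100 * n_local / n_mixed)
         } else NA_real_))
}

#' Compare survival across response groups
#'
#' Kaplan-Meier fits per response group plus a log-rank test, for PFS or OS.
#' `stable_unclassified` and unclassifiable patients are excluded.
#'
#' @param patients classified patient table (from [cohort_summary()]).
#' @param endpoint `"pfs"` or `"os"`.
#' @return list with per-group `"km_fit"`s, the log-rank result, and group
#'   sizes.
#' @export
compare_survival <- function(patients, endpoint = c("pfs", "os")) {
  endpoint <- match.arg(endpoint)
  tcol <- paste0(endpoint, "_days"); ecol <- paste0(endpoint, "_event")
  keep <- !is.na(patients$response_group) &
    patients$response_group %in% c("nonmixed_responder", "mixed_responder",
                                   "nonmixed_nonresponder")
  p <- patients[keep, , drop = FALSE]
  fits <- lapply(split(p, p$response_group), function(gp) {
    km_estimate(gp[[tcol]], gp[[ecol]])
  })
  list(fits = fits,
       logrank = logrank_test(p$response_group, p[[tcol]], p[[ecol]]),
       n = table(p$response_group))
}

#' Read cohort lesion / patient CSV tables
#'
#' Lesion CSV columns: `patient, lesion, time_days, diameter_mm, is_new`.
#' Patient CSV columns: `patient, cancer_type, pfs_days, pfs_event, os_days,
#' os_event, local_therapy`.
#'
#' @param path file path.
#' @export
read_lesions_csv <- function(path) {
  lesions <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient", "lesion", "time_days", "diameter_mm", "is_new")
  missing <- setdiff(need, names(lesions))
  if (length(missing) > 0) {
    stop("lesion table lacks columns: ", paste(missing, collapse = ", "))
  }
  lesions$is_new <- as.logical(lesions$is_new)
  lesions
}

#' @rdname read_lesions_csv
#' @export
read_patients_csv <- function(path) {
  patients <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient", "cancer_type", "pfs_days", "pfs_event",
            "os_days", "os_event")
  missing <- setdiff(need, names(patients))
  if (length(missing) > 0) {
    stop("patient table lacks columns: ", paste(missing, collapse = ", "))
  }
  patients
}
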