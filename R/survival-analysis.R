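#' Kaplan-Meier product-limit curve
#'
#' @param samples Tibble with `time` (months > 0), `event` (logical) and
#'   optionally `group` for stratified curves.
#' @return An `hgp_km` tibble: `group` (if present), `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`; right-continuous steps with an
#'   implicit S(0) = 1 anchor row per stratum.
#' @export
km_curve <- function(samples) {
  s <- validate_survival(samples)
  has_group <- "group" %in% names(s)
  fit <- if (has_group) {
    survival::survfit(survival::Surv(time, event) ~ group, data = s)
  } else {
    survival::survfit(survival::Surv(time, event) ~ 1, data = s)
  }
  sm <- summary(fit, censored = TRUE)
  grp <- if (!has_group) "all"
         else if (is.null(sm$strata)) as.character(s$group[1])  # one level
         else sub("^group=", "", as.character(sm$strata))
  out <- tibble(
    group = grp,
    time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event,
    n_censor = sm$n.censor, survival = sm$surv)
  anchor <- out |> distinct(.data$group) |>
    mutate(time = 0, n_risk = NA_integer_, n_event = 0L, n_censor = 0L,
           survival = 1)
  anchor$n_risk <- vapply(anchor$group, function(g) {
    if (has_group) sum(s$group == g) else nrow(s)
  }, numeric(1))
  out <- bind_rows(anchor, out) |> arrange(.data$group, .data$time)
  structure(out, class = c("hgp_km", class(out)))
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected chi-square with hypergeometric
#' variance at each distinct event time, 1 degree of freedom.
#'
#' @param samples Tibble with `time`, `event`, and a two-level `group`.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
log_rank <- function(samples) {
  s <- validate_survival(samples, need_group = TRUE)
  if (length(unique(s$group)) != 2) abort("log-rank needs exactly 2 groups")
  if (sum(s$event) == 0) abort("no events in either group")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = s)
  tibble(statistic = sd$chisq, df = 1,
         p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards model for a binary group
#'
#' Partial likelihood with Breslow tie handling, Newton-Raphson to a
#' tolerance of 1e-9. The hazard ratio is for the second group level
#' relative to the first (alphabetical when `group` is character).
#'
#' @param samples Tibble with `time`, `event`, binary `group`.
#' @return An `hgp_cox` one-row tibble: `term`, `hr`, `ci_low`, `ci_high`,
#'   `beta`, `se`, `p_value`, `n`, `n_event`.
#' @export
cox_univariate <- function(samples) {
  s <- validate_survival(samples, need_group = TRUE)
  levels_ <- sort(unique(as.character(s$group)))
  if (length(levels_) != 2) abort("Cox covariate must have exactly 2 levels")
  ev <- tapply(s$event, s$group, sum)
  if (any(ev == 0)) {
    abort(paste0("no events in level '", names(ev)[ev == 0][1],
                 "': monotone likelihood"))
  }
  s$group <- factor(s$group, levels = levels_)
  fit <- survival::coxph(survival::Surv(time, event) ~ group, data = s,
                         ties = "breslow",
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 100))
  beta <- unname(coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  out <- tibble(term = paste0("group", levels_[2]),
                hr = exp(beta),
                ci_low = exp(beta - 1.959964 * se),
                ci_high = exp(beta + 1.959964 * se),
                beta = beta, se = se,
                p_value = 2 * pnorm(-abs(beta / se)),
                n = nrow(s), n_event = sum(s$event))
  structure(out, class = c("hgp_cox", class(out)), fit = fit)
}

#' Administrative censoring at a horizon
#'
#' Times are truncated at the horizon and events after the horizon become
#' censorings. An event at exactly the horizon still counts as an event.
#'
#' @param samples Survival tibble.
#' @param horizon Censoring horizon (months).
#' @return The censored tibble.
#' @export
censor_at <- function(samples, horizon) {
  s <- validate_survival(samples)
  s$event <- s$event & s$time <= horizon
  s$time <- pmin(s$time, horizon)
  s
}

#' Six-month early-relapse endpoint
#'
#' Censors administratively at `horizon` months and cross-tabulates
#' early relapse (event within the horizon, boundary inclusive) against
#' the group, with a Pearson chi-square test when the table is
#' non-degenerate.
#'
#' @param samples Survival tibble with `group`.
#' @param horizon Months (6 for the RFS6M endpoint).
#' @return List: `samples` (censored), `table` (early-relapse by group),
#'   `test` (chi-square tibble; `NA` p-value on a degenerate table).
#' @export
rfs6m <- function(samples, horizon = 6) {
  s <- validate_survival(samples, need_group = TRUE)
  cens <- censor_at(s, horizon)
  early <- factor(ifelse(cens$event, "yes", "no"), levels = c("yes", "no"))
  tab <- table(early_relapse = early, group = cens$group)
  test <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0) &&
              nrow(tab) >= 2 && ncol(tab) >= 2) {
    chi_square_test(tab)
  } else {
    inform("early-relapse table degenerate; chi-square not computed")
    tibble(statistic = NA_real_, df = NA_real_, p_value = NA_real_)
  }
  list(samples = cens, table = tab, test = test)
}

validate_survival <- function(samples, need_group = FALSE) {
  need <- c("time", "event", if (need_group) "group")
  if (!all(need %in% names(samples))) {
    abort(paste0("survival table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  if (nrow(samples) == 0) abort("empty survival table")
  if (any(!is.finite(samples$time)) || any(samples$time <= 0)) {
    abort("times must be finite and > 0")
  }
  samples$event <- as.logical(samples$event)
  if (any(is.na(samples$event))) abort("event must be logical or 0/1")
  as_tibble(samples)
}
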