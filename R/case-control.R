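#' Select cases by the hierarchical outcome definition
#'
#' A subject with an event is labelled by the highest-priority outcome it
#' carries, in the fixed order CVD death > MI/ACS > PCI/CABG > stroke.
#' `event_type` may carry several labels separated by `;` or `,` (multiple
#' records); the highest-priority one wins.
#'
#' @param table Participant table with `event` and `event_type` columns.
#' @return The case rows with `event_type` resolved to a single label;
#'   attribute `label_counts` holds the per-label totals. An empty case set
#'   raises a warning, not an error.
#' @export
select_cases <- function(table) {
  hierarchy <- c("cvd_death", "mi_acs", "pci_cabg", "stroke")
  cases <- table[table$event == 1, , drop = FALSE]
  if (nrow(cases) == 0) {
    warning("no events: empty case set")
    attr(cases, "label_counts") <- setNames(integer(4), hierarchy)
    return(cases)
  }
  resolve <- function(lbl) {
    parts <- trimws(strsplit(lbl, "[;,]")[[1]])
    known <- match(parts, hierarchy)
    if (anyNA(known))
      stop("unknown event label(s): ",
           paste(parts[is.na(known)], collapse = ", "))
    hierarchy[min(known)]
  }
  cases$event_type <- vapply(cases$event_type, resolve, character(1))
  counts <- setNames(integer(4), hierarchy)
  tb <- table(cases$event_type)
  counts[names(tb)] <- as.integer(tb)
  attr(cases, "label_counts") <- counts
  cases
}

#' Fit the propensity model for case status
#'
#' Main-effects logistic regression of case status on the matching
#' covariates (defaults: age, sex, ethnicity, smoking status, body mass
#' index, and the clinical risk score).
#'
#' @param table Participant table with an `event` column and complete
#'   covariates.
#' @param covariates Character vector of covariate column names.
#' @return Numeric propensity scores in (0, 1), one per row.
#' @export
fit_propensity <- function(table, covariates = c("age", "sex", "ethnicity",
                                                 "smoking", "bmi",
                                                 "qrisk2")) {
  miss <- setdiff(covariates, names(table))
  if (length(miss)) stop("missing covariate column(s): ",
                         paste(miss, collapse = ", "))
  dat <- table[, covariates, drop = FALSE]
  if (anyNA(dat)) stop("covariates must be complete; handle missing upstream")
  constant <- vapply(dat, function(x) length(unique(x)) < 2, logical(1))
  if (any(constant)) {
    message("dropping constant covariate(s): ",
            paste(covariates[constant], collapse = ", "))
    dat <- dat[, !constant, drop = FALSE]
  }
  dat$.case <- table$event
  fit <- glm(.case ~ ., data = dat, family = binomial())
  ps <- fitted(fit)
  eps <- 1e-8
  if (!fit$converged || any(ps < eps) || any(ps > 1 - eps) ||
      any(abs(coef(fit)) > 50, na.rm = TRUE))
    stop("propensity model shows separation; coefficients: ",
         paste(sprintf("%s=%.2f", names(coef(fit)), coef(fit)),
               collapse = ", "))
  as.numeric(ps)
}

#' Standardized mean difference between two groups
#'
#' Continuous: `|mean1 - mean2| / sqrt((s1^2 + s2^2) / 2)`. Categorical
#' (factor/character input): each level is scored as a binary indicator
#' with the proportion-based pooled SD, and the per-level SMDs are
#' aggregated as their maximum (so "balanced" means every level is
#' balanced). Zero pooled variance with unequal means yields `Inf` with a
#' warning.
#'
#' @param values Numeric, factor, or character vector.
#' @param group Logical or 0/1 vector: group membership per element.
#' @return A single non-negative SMD.
#' @export
smd <- function(values, group) {
  group <- as.logical(group)
  if (!any(group) || !any(!group)) stop("both groups must be non-empty")
  if (is.numeric(values)) {
    m1 <- mean(values[group]); m2 <- mean(values[!group])
    s2 <- (var(values[group]) + var(values[!group])) / 2
    if (s2 == 0) {
      if (m1 == m2) return(0)
      warning("zero pooled variance with unequal means: SMD infinite")
      return(Inf)
    }
    abs(m1 - m2) / sqrt(s2)
  } else {
    lev <- unique(as.character(values))
    if (length(lev) < 2) return(0)
    max(vapply(lev, function(l) {
      p1 <- mean(values[group] == l); p2 <- mean(values[!group] == l)
      s2 <- (p1 * (1 - p1) + p2 * (1 - p2)) / 2
      if (s2 == 0) {
        if (p1 == p2) return(0)
        warning("zero pooled variance with unequal proportions: SMD infinite")
        return(Inf)
      }
      abs(p1 - p2) / sqrt(s2)
    }, numeric(1)))
  }
}

#' Greedy propensity-score matching without replacement
#'
#' Nearest-neighbour matching on the logit-propensity scale. Cases are
#' processed in a randomised order under `seed`; matching proceeds in
#' passes so every case receives its first control before any case
#' receives its second ("approximate" ratio: a case keeps however many
#' controls, up to `ratio`, fall inside the caliper). Controls are used at
#' most once. The default caliper is 0.2 SD of the logit propensity, a
#' standard choice.
#'
#' @param cases,pool Disjoint participant tables (pool = candidate
#'   controls, event-free at selection).
#' @param ps_cases,ps_pool Propensity scores aligned to the two tables.
#' @param ratio Maximum controls per case (default 2).
#' @param caliper Maximum |logit(ps) difference|; `NULL` for the default
#'   0.2 SD rule.
#' @param covariates Covariates for the balance (SMD) table.
#' @param seed Integer seed for the case processing order.
#' @return A `matched_design` list: `case_ids`, `control_ids`, `matches`
#'   (data frame case_id/control_id/pass), `propensity` (named list),
#'   `caliper`, `ratio`, `achieved_ratio`, `unmatched_cases`, and
#'   `smd_table` (covariate x before/after).
#' @export
match_controls <- function(cases, pool, ps_cases, ps_pool, ratio = 2L,
                           caliper = NULL,
                           covariates = c("age", "sex", "ethnicity",
                                          "smoking", "bmi", "qrisk2"),
                           seed = 1L) {
  if (nrow(pool) == 0) stop("empty control pool")
  if (length(intersect(cases$id, pool$id)) > 0)
    stop("cases and pool must be disjoint")
  lc <- qlogis(ps_cases); lp <- qlogis(ps_pool)
  if (is.null(caliper)) caliper <- 0.2 * sd(c(lc, lp))

  set.seed(seed)
  order_cases <- sample.int(nrow(cases))
  available <- rep(TRUE, nrow(pool))
  matches <- vector("list", ratio)
  for (pass in seq_len(ratio)) {
    got <- data.frame(case_id = character(0), control_id = character(0),
                      pass = integer(0), stringsAsFactors = FALSE)
    for (ci in order_cases) {
      if (!any(available)) break
      d <- abs(lp - lc[ci])
      d[!available] <- Inf
      j <- which.min(d)
      if (d[j] <= caliper) {
        available[j] <- FALSE
        got <- rbind(got, data.frame(case_id = cases$id[ci],
                                     control_id = pool$id[j],
                                     pass = pass,
                                     stringsAsFactors = FALSE))
      }
    }
    matches[[pass]] <- got
  }
  matches <- do.call(rbind, matches)
  if (anyDuplicated(matches$control_id))
    stop("internal error: control matched twice")

  matched_pool <- pool[pool$id %in% matches$control_id, , drop = FALSE]
  n_per_case <- table(factor(matches$case_id, levels = cases$id))
  both <- rbind(cases[, covariates, drop = FALSE],
                pool[, covariates, drop = FALSE])
  grp_before <- c(rep(TRUE, nrow(cases)), rep(FALSE, nrow(pool)))
  both_after <- rbind(cases[, covariates, drop = FALSE],
                      matched_pool[, covariates, drop = FALSE])
  grp_after <- c(rep(TRUE, nrow(cases)), rep(FALSE, nrow(matched_pool)))
  smd_table <- data.frame(
    covariate = covariates,
    smd_before = vapply(covariates, function(v) smd(both[[v]], grp_before),
                        numeric(1)),
    smd_after = vapply(covariates, function(v)
      if (nrow(matched_pool) > 0) smd(both_after[[v]], grp_after)
      else NA_real_, numeric(1)),
    row.names = NULL)

  structure(list(case_ids = cases$id,
                 control_ids = matches$control_id,
                 matches = matches,
                 propensity = list(cases = ps_cases, pool = ps_pool),
                 caliper = caliper, ratio = ratio,
                 achieved_ratio = nrow(matches) / nrow(cases),
                 unmatched_cases = cases$id[n_per_case == 0],
                 smd_table = smd_table),
            class = "matched_design")
}

#' @export
print.matched_design <- function(x, ...) {
  cat(sprintf(paste0("<matched_design> %d cases, %d matched controls ",
                     "(achieved ratio %.2f, caliper %.3f)\n"),
              length(x$case_ids), length(x$control_ids),
              x$achieved_ratio, x$caliper))
  print(x$smd_table)
  invisible(x)
}
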