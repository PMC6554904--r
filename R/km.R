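#' Kaplan-Meier survival by comorbidity stratum
#'
#' Product-limit estimate of survival over the first 365 days after index,
#' per stratum of a comorbidity index (or any grouping). Subjects alive at
#' day 365 are censored there. Wraps [survival::survfit()] and returns the
#' step function in long format suitable for plotting or export.
#'
#' @param time Days from index to death or censoring (capped at 365 by the
#'   caller or via `cap`).
#' @param event 1/TRUE if the subject died at `time`, 0/FALSE if censored.
#' @param group Stratum labels (e.g. banded Charlson index); a single stratum
#'   if omitted.
#' @param cap Administrative censoring horizon in days (default 365).
#' @return Object of class `km_estimate`: data frame with `group`, `time`,
#'   `n_risk`, `n_event`, `survival`. `S(0) = 1` per group; the function is
#'   non-increasing and drops only at event times. Empty groups are skipped
#'   with a warning.
#' @examples
#' km <- km_estimate(c(5, 20, 10, rep(365, 7)),
#'                   c(1, 1, 0, rep(0, 7)))
#' km[km$n_event > 0, ]
#' @export
km_estimate <- function(time, event, group = NULL, cap = 365) {
  stopifnot(all(time >= 0))
  event <- as.integer(as.logical(event))
  over <- time > cap
  event[over] <- 0L
  time[over] <- cap
  if (is.null(group)) group <- rep("all", length(time))
  group <- as.character(group)
  keep <- !is.na(group)
  out <- do.call(rbind, lapply(sort(unique(group[keep])), function(g) {
    i <- keep & group == g
    if (!any(i)) {
      warning("empty group '", g, "' skipped", call. = FALSE)
      return(NULL)
    }
    sf <- survival::survfit(survival::Surv(time[i], event[i]) ~ 1)
    data.frame(group = g,
               time = c(0, sf$time),
               n_risk = c(sum(i), sf$n.risk),
               n_event = c(0, sf$n.event),
               survival = c(1, sf$surv),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, class = c("km_estimate", "data.frame"))
}

#' @export
plot.km_estimate <- function(x, xlab = "Days since index",
                             ylab = "Survival", ...) {
  groups <- unique(x$group)
  graphics::plot(NULL, xlim = c(0, max(x$time)), ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, ...)
  for (i in seq_along(groups)) {
    d <- x[x$group == groups[i], ]
    graphics::lines(stats::stepfun(d$time[-1], d$survival), col = i,
                    do.points = FALSE)
  }
  graphics::legend("bottomleft", legend = groups, col = seq_along(groups),
                   lty = 1, bty = "n")
  invisible(x)
}
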