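#' AUC by the linear-up/log-down trapezoidal rule
#'
#' Per interval: the linear trapezoid when the concentration is rising,
#' flat, or either endpoint is zero; the logarithmic trapezoid
#' `(c1 - c2) / log(c1/c2) * dt` when declining with both endpoints
#' positive.
#'
#' @param t time vector, strictly increasing, h
#' @param c concentration vector, non-negative
#' @return AUC, conc x h
#' @examples
#' aucLinUpLogDown(c(0, 1, 2), c(0, 10, 5)) # 5 + 5/log(2)
#' @export
aucLinUpLogDown <- function(t, c) {
  if (length(t) != length(c) || length(t) < 2) stop("need >= 2 matching points")
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  if (any(c < 0)) stop("concentrations must be non-negative")
  c1 <- c[-length(c)]; c2 <- c[-1]; dt <- diff(t)
  logdown <- c2 < c1 & c2 > 0 & c1 > 0
  area <- ifelse(logdown, (c1 - c2) / log(c1 / c2), (c1 + c2) / 2) * dt
  sum(area)
}

#' Terminal slope by adjusted-R2-maximising log-linear regression
#'
#' Fits log(c) ~ t over suffixes of the points after Cmax (excluding Cmax
#' itself), keeps the suffix with at least `min_points` positive
#' concentrations that maximises the adjusted R2, and returns the negated
#' slope.
#'
#' @param t,c concentration-time data
#' @param min_points minimum number of terminal points (default 3)
#' @return list with `lambda_z` (1/h, NA when not estimable), `r2_adj`,
#'   `n_points`, and `flagged` (TRUE when no acceptable fit was found)
#' @export
terminalSlope <- function(t, c, min_points = 3) {
  i_max <- which.max(c)
  idx <- seq_along(t) > i_max & c > 0
  tt <- t[idx]; cc <- c[idx]
  n <- length(tt)
  if (n < min_points)
    return(list(lambda_z = NA_real_, r2_adj = NA_real_, n_points = 0L, flagged = TRUE))
  best <- NULL
  for (start in seq_len(n - min_points + 1)) {
    ts <- tt[start:n]; cs <- cc[start:n]
    fit <- lm(log(cs) ~ ts)
    sl <- coef(fit)[2]
    # summary.lm warns on numerically perfect fits; those are fine here
    r2 <- suppressWarnings(summary(fit)$adj.r.squared)
    if (!is.finite(sl) || sl >= 0) next
    if (is.null(best) || r2 > best$r2_adj)
      best <- list(lambda_z = -unname(sl), r2_adj = r2,
                   n_points = length(ts), flagged = FALSE)
  }
  if (is.null(best))
    return(list(lambda_z = NA_real_, r2_adj = NA_real_, n_points = 0L, flagged = TRUE))
  best
}

#' Non-compartmental analysis summary
#'
#' Computes Cmax, Tmax, AUC(0-t) by linear-up/log-down, the terminal slope,
#' half-life, AUC(0-inf) (`AUC(0-t) + Clast/lambda_z`), and apparent
#' clearance `CL/F = dose / AUC(0-inf)`. When the terminal slope is not
#' estimable, CL/F falls back to `dose / AUC(0-t)` and the result is
#' flagged.
#'
#' @param t,c concentration-time data
#' @param dose administered dose (same mass unit as c x volume)
#' @param min_points minimum terminal points for the slope
#' @return one-row data.frame with columns auc_0_t, auc_0_inf, cmax, tmax,
#'   lambda_z, t_half, cl_over_f, n_lambda_points, r2_adj, flagged
#' @export
ncaSummary <- function(t, c, dose, min_points = 3) {
  if (dose <= 0) stop("dose must be positive")
  auc_t <- aucLinUpLogDown(t, c)
  sl <- terminalSlope(t, c, min_points)
  clast <- rev(c[c > 0])[1]
  if (!sl$flagged && length(clast)) {
    auc_inf <- auc_t + clast / sl$lambda_z
    clf <- dose / auc_inf
    thalf <- log(2) / sl$lambda_z
  } else {
    auc_inf <- NA_real_
    clf <- if (auc_t > 0) dose / auc_t else NA_real_
    thalf <- NA_real_
  }
  data.frame(auc_0_t = auc_t, auc_0_inf = auc_inf, cmax = max(c),
             tmax = t[which.max(c)], lambda_z = sl$lambda_z, t_half = thalf,
             cl_over_f = clf, n_lambda_points = sl$n_points,
             r2_adj = sl$r2_adj, flagged = sl$flagged)
}

#' NCA over a tidy concentration table
#'
#' @param tab data.frame with columns subject, time_h, conc
#' @param dose dose per subject (scalar or named by subject)
#' @return data.frame, one NCA row per subject
#' @export
ncaBySubject <- function(tab, dose) {
  stopifnot(all(c("subject", "time_h", "conc") %in% names(tab)))
  out <- lapply(split(tab, tab$subject), function(d) {
    d <- d[order(d$time_h), ]
    dsub <- if (length(dose) > 1) dose[[as.character(d$subject[1])]] else dose
    cbind(subject = d$subject[1], ncaSummary(d$time_h, d$conc, dsub))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
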