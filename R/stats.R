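#' Pearson correlation with significance test
#'
#' Sample Pearson correlation and the two-sided t-test p-value (wraps
#' [stats::cor.test()]).
#'
#' @param x,y numeric vectors, `n >= 3`, nonzero variance.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) stop("degenerate input: need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: zero variance")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Multiple regression with standardized coefficients
#'
#' Fits a per-leaf response on leaf order (`lo`), intercepted UV dose
#' (`uvi`) and optionally their interaction. `link = "linear"` uses ordinary
#' least squares; `link = "logistic-saturating"` fits
#' `rmax * plogis(g0 + g1 lo + g2 uvi)` by nonlinear least squares (the form
#' used for radical-scavenging activity, which saturates in young leaves).
#' Standardized coefficients are `b * sd(x) / sd(y)`; for the saturating
#' form they are computed on the linear-predictor scale.
#'
#' @param records data frame with the response column plus `leaf_order` and
#'   `uvi` (e.g. from [synth_assays()]).
#' @param response column name, e.g. `"tfc"`.
#' @param terms predictor set: subset of `c("lo", "uvi", "lo:uvi")`.
#' @param link `"linear"` or `"logistic-saturating"`.
#' @param rmax saturation ceiling for the logistic link (response units).
#' @return Object of class `regression_fit`: `coefficients` (raw),
#'   `std_coefficients`, `r_squared`, `p_values`, `n`, `link`.
#' @export
fit_regression <- function(records, response,
                           terms = c("lo", "uvi"),
                           link = c("linear", "logistic-saturating"),
                           rmax = 100) {
  link <- match.arg(link)
  stopifnot(response %in% names(records))
  d <- data.frame(
    y = records[[response]], lo = records$leaf_order, uvi = records$uvi
  )
  d <- d[stats::complete.cases(d), ]
  terms <- match.arg(terms, c("lo", "uvi", "lo:uvi"), several.ok = TRUE)
  rhs <- paste(sub("lo:uvi", "lo:uvi", terms), collapse = " + ")
  if (nrow(d) <= length(terms) + 1) stop("too few records for the model")
  if (link == "linear") {
    X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), d)
    if (qr(X)$rank < ncol(X)) {
      stop("collinearity error: design matrix is rank deficient")
    }
    fit <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = d)
    # noiseless generator checks produce exact fits; the perfect-fit
    # warning from summary.lm is expected there
    sm <- suppressWarnings(summary(fit))
    co <- stats::coef(fit)
    pv <- sm$coefficients[, 4]
    pred_sd <- apply(X[, -1, drop = FALSE], 2, stats::sd)
    std <- co[-1] * pred_sd / stats::sd(d$y)
    r2 <- sm$r.squared
  } else {
    # saturating logistic on the linear-predictor scale
    start <- list(g0 = 0, g1 = 0.1, g2 = 0.1)
    fit <- minpack.lm::nlsLM(
      y ~ rmax * stats::plogis(g0 + g1 * lo + g2 * uvi),
      data = d, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    sm <- summary(fit)
    co <- stats::coef(fit)
    pv <- sm$coefficients[, 4]
    eta_sd <- stats::sd(co["g0"] + co["g1"] * d$lo + co["g2"] * d$uvi)
    std <- c(
      lo = unname(co["g1"]) * stats::sd(d$lo) / eta_sd,
      uvi = unname(co["g2"]) * stats::sd(d$uvi) / eta_sd
    )
    r2 <- 1 - sum(stats::resid(fit)^2) / sum((d$y - mean(d$y))^2)
    names(co) <- c("(Intercept)", "lo", "uvi")[seq_along(co)]
  }
  std_names <- if (link == "linear") names(co)[-1] else c("lo", "uvi")
  names(std) <- std_names
  structure(
    list(
      response = response, link = link, n = nrow(d),
      coefficients = co, std_coefficients = std,
      r_squared = r2, p_values = pv
    ),
    class = "regression_fit"
  )
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "<regression_fit> %s ~ %s (%s link), n = %d, R^2 = %.3f\n",
    x$response, paste(names(x$std_coefficients), collapse = " + "),
    x$link, x$n, x$r_squared
  ))
  tab <- data.frame(
    raw = x$coefficients[names(x$std_coefficients)],
    standardized = x$std_coefficients
  )
  print(round(tab, 4))
  invisible(x)
}

#' Ratio of standardized effect sizes
#'
#' `|std coefficient of term_a| / |std coefficient of term_b|`: how many
#' times stronger one predictor's standardized effect is than another's
#' (e.g. intercepted UV dose vs leaf developmental age).
#'
#' @param fit a `regression_fit`.
#' @param term_a,term_b term names present in the fit.
#' @return Scalar ratio.
#' @export
effect_ratio <- function(fit, term_a = "uvi", term_b = "lo") {
  stopifnot(inherits(fit, "regression_fit"))
  s <- fit$std_coefficients
  for (tm in c(term_a, term_b)) {
    if (!tm %in% names(s)) stop(sprintf("term '%s' not in fit", tm))
  }
  if (s[[term_b]] == 0) stop("undefined ratio: denominator coefficient is zero")
  abs(s[[term_a]]) / abs(s[[term_b]])
}

#' Distribution summaries per leaf order
#'
#' Median, quartiles (linear-interpolation convention, type 7), central 95%
#' interval and Tukey outliers (beyond 1.5 IQR fences) for values grouped by
#' leaf order — the numbers a violin/box plot of per-leaf interception
#' displays.
#'
#' @param values numeric vector.
#' @param leaf_order grouping vector, same length.
#' @return Data frame with one row per group: `leaf_order`, `n`, `q1`,
#'   `median`, `q3`, `lo95`, `hi95`, `n_outliers`, plus attribute
#'   `outliers` (list of outlying values per group). Empty groups are
#'   skipped with a warning.
#' @export
summarize_distribution <- function(values, leaf_order) {
  stopifnot(length(values) == length(leaf_order))
  groups <- sort(unique(leaf_order))
  rows <- list()
  outliers <- list()
  for (g in groups) {
    v <- values[leaf_order == g & is.finite(values)]
    if (!length(v)) {
      warning(sprintf("leaf order %s has no values; skipped", g))
      next
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75, 0.025, 0.975), type = 7,
                         names = FALSE)
    iqr <- q[3] - q[1]
    out <- v[v < q[1] - 1.5 * iqr | v > q[3] + 1.5 * iqr]
    rows[[length(rows) + 1L]] <- data.frame(
      leaf_order = g, n = length(v), q1 = q[1], median = q[2], q3 = q[3],
      lo95 = q[4], hi95 = q[5], n_outliers = length(out)
    )
    outliers[[as.character(g)]] <- out
  }
  res <- do.call(rbind, rows)
  attr(res, "outliers") <- outliers
  res
}

#' Reference per-leaf NPQ summary table
#'
#' Published per-leaf mean nonphotochemical quenching (NPQ) of kale under
#' control and supplemental UV-B conditions, leaf orders 2-10 (1 = oldest).
#' Shipped as a plain-text reference dataset; used to verify summary
#' arithmetic (treatment means and the youngest-leaf fold change) against
#' printed values.
#'
#' @return Data frame with `leaf_order`, `npq_control`, `npq_uvb`.
#' @export
npq_reference <- function() {
  path <- system.file("extdata", "npq_reference.csv", package = "rosetrace")
  utils::read.csv(path)
}
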