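#' Assign an aromatic ring-count class
#'
#' The default (`"table"`) scheme bins ligands into classes
#' 0, 1, 2, 3, 4, "5+" by aromatic ring count. The `"histogram"` scheme
#' used for distribution plots merges the sparse extremes into "0-1"
#' and "5+".
#'
#' @param nAR Integer vector of aromatic ring counts (>= 0).
#' @param scheme `"table"` (default) or `"histogram"`.
#' @return An ordered factor of class labels.
#' @examples
#' assign_ring_class(c(0, 3, 8))
#' @export
assign_ring_class <- function(nAR, scheme = c("table", "histogram")) {
  scheme <- match.arg(scheme)
  if (any(is.na(nAR)) || any(nAR < 0)) {
    abort("aromatic ring counts must be non-negative and non-missing")
  }
  if (scheme == "table") {
    lev <- c("0", "1", "2", "3", "4", "5+")
    lab <- ifelse(nAR >= 5, "5+", as.character(nAR))
  } else {
    lev <- c("0-1", "2", "3", "4", "5+")
    lab <- ifelse(nAR >= 5, "5+", ifelse(nAR <= 1, "0-1", as.character(nAR)))
  }
  factor(lab, levels = lev, ordered = TRUE)
}

#' Ring-class distribution of a ligand cohort
#'
#' Counts, percentages and the mean +/- SEM of WHBC per aromatic
#' ring-count class. Percentages are 100 x count / cohort size; classes
#' with no members are kept with count 0 and undefined (NA) means.
#'
#' @param cohort A data frame with columns `nAR` and `WHBC` (one ligand
#'   per row), e.g. the output of [profile_ligands()] or
#'   [gen_ligand_cohort()].
#' @param scheme Binning scheme passed to [assign_ring_class()].
#' @return A tibble of class `ring_class_table` with columns
#'   `ring_class`, `n`, `percent`, `mean_whbc`, `sem_whbc`.
#' @export
class_distribution <- function(cohort, scheme = c("table", "histogram")) {
  scheme <- match.arg(scheme)
  need <- setdiff(c("nAR", "WHBC"), names(cohort))
  if (length(need)) {
    abort(paste0("cohort table lacks column(s): ", paste(need, collapse = ", ")))
  }
  if (!nrow(cohort)) abort("cannot tabulate an empty cohort")
  total <- nrow(cohort)
  out <- tibble(
    ring_class = assign_ring_class(cohort$nAR, scheme),
    WHBC = cohort$WHBC
  ) |>
    group_by(.data$ring_class) |>
    summarise(
      n = n(),
      mean_whbc = mean(.data$WHBC),
      sem_whbc = if (n() >= 2) stats::sd(.data$WHBC) / sqrt(n()) else 0,
      .groups = "drop"
    ) |>
    tidyr::complete(
      ring_class = assign_ring_class(
        if (scheme == "table") c(0:4, 5) else c(0, 2:4, 5), scheme
      ),
      fill = list(n = 0L)
    ) |>
    mutate(percent = 100 * .data$n / total) |>
    select("ring_class", "n", "percent", "mean_whbc", "sem_whbc") |>
    arrange(.data$ring_class)
  class(out) <- c("ring_class_table", class(out))
  out
}

#' Fit a normal distribution to WHBC values
#'
#' The per-class WHBC histograms are summarised by normal fits; this
#' returns mu = sample mean and sigma = sample standard deviation
#' (n - 1 denominator).
#'
#' @param values Numeric vector, length >= 2.
#' @return A tibble with columns `mu`, `sigma`, `n`, `degenerate`.
#'   `degenerate` is `TRUE` (with a warning) when the values are
#'   constant, where no meaningful width exists.
#' @export
fit_gaussian <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) abort("need at least two values to fit a normal distribution")
  sigma <- stats::sd(values)
  degenerate <- sigma <= 0
  if (degenerate) warn("constant values: sigma is 0, normal fit is degenerate")
  tibble(mu = mean(values), sigma = sigma, n = length(values),
         degenerate = degenerate)
}

#' Fit the WHBC-versus-ring-count exchange line
#'
#' Ordinary least squares of per-class mean WHBC on the class abscissa.
#' The open-ended top class sits at `x_five_plus` (default 5) and the
#' zero-ring class (a near-empty singleton class in realistic cohorts,
#' which would otherwise dominate an unweighted fit) is excluded by
#' default. A negative slope is the signature of the hydrogen-bond /
#' aromatic-ring exchange rule.
#'
#' @param table A `ring_class_table` from [class_distribution()], or any
#'   data frame with `ring_class` and `mean_whbc` (and `sem_whbc` if
#'   `weighted`).
#' @param x_five_plus Abscissa assigned to the "5+" class (default 5).
#' @param include_zero_class Include the 0-ring class (default `FALSE`).
#' @param weighted If `TRUE`, weight classes by 1/sem^2 (classes with
#'   sem 0 are dropped from a weighted fit).
#' @return An object of class `exchange_fit`; see [tidy.exchange_fit()],
#'   [glance.exchange_fit()] and [autoplot.exchange_fit()].
#' @export
fit_exchange_line <- function(table, x_five_plus = 5,
                              include_zero_class = FALSE, weighted = FALSE) {
  need <- setdiff(c("ring_class", "mean_whbc"), names(table))
  if (length(need)) {
    abort(paste0("ring-class table lacks column(s): ", paste(need, collapse = ", ")))
  }
  dat <- as_tibble(table) |>
    filter(!is.na(.data$mean_whbc))
  if (!include_zero_class) {
    dat <- filter(dat, !(as.character(.data$ring_class) %in% c("0")))
  }
  lab <- as.character(dat$ring_class)
  dat$x <- ifelse(grepl("\\+$", lab), x_five_plus,
                  ifelse(lab == "0-1", 1, suppressWarnings(as.numeric(lab))))
  if (any(is.na(dat$x))) abort("unrecognised ring-class labels")
  w <- NULL
  if (weighted) {
    if (!"sem_whbc" %in% names(dat)) abort("weighted fit needs a sem_whbc column")
    dat <- filter(dat, .data$sem_whbc > 0)
    w <- 1 / dat$sem_whbc^2
  }
  if (nrow(dat) < 2) abort("need at least two classes with defined means to fit a line")
  fit <- stats::lm(mean_whbc ~ x, data = dat, weights = w)
  structure(
    list(
      model = fit,
      data = dat,
      slope = unname(stats::coef(fit)[["x"]]),
      intercept = unname(stats::coef(fit)[["(Intercept)"]]),
      # a perfect fit trips lm's "essentially perfect fit" warning, which
      # is expected on collinear class means
      r_squared = suppressWarnings(summary(fit)$r.squared),
      class_x_values = stats::setNames(dat$x, as.character(dat$ring_class)),
      weighted = weighted
    ),
    class = "exchange_fit"
  )
}

#' @export
print.exchange_fit <- function(x, ...) {
  cat("<exchange_fit> mean WHBC ~ aromatic ring class\n")
  cat(sprintf("  slope     %+.5f WHBC per ring\n", x$slope))
  cat(sprintf("  intercept %8.5f WHBC\n", x$intercept))
  cat(sprintf("  r-squared %8.4f  (%d classes%s)\n", x$r_squared,
              nrow(x$data), if (x$weighted) ", inverse-variance weighted" else ""))
  invisible(x)
}

#' Tidy an exchange-line fit
#'
#' @param x An `exchange_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @method tidy exchange_fit
#' @export
tidy.exchange_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p.value = unname(sm[, "Pr(>|t|)"])
  )
}

#' One-line summary of an exchange-line fit
#'
#' @param x An `exchange_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `slope`, `intercept`, `r.squared`,
#'   `sigma`, `n_classes`.
#' @method glance exchange_fit
#' @export
glance.exchange_fit <- function(x, ...) {
  sm <- summary(x$model)
  tibble(
    slope = x$slope, intercept = x$intercept,
    r.squared = sm$r.squared, sigma = sm$sigma,
    n_classes = nrow(x$data)
  )
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Plot an exchange-line fit
#'
#' Class-mean WHBC (with SEM error bars when available) against the
#' ring-class abscissa, with the fitted line.
#'
#' @param object An `exchange_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot exchange_fit
#' @export
autoplot.exchange_fit <- function(object, ...) {
  dat <- object$data
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$mean_whbc)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(
      slope = object$slope, intercept = object$intercept,
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::labs(
      x = "number of aromatic rings (class)",
      y = "mean WHBC",
      title = sprintf("slope %+.4f WHBC/ring, r² = %.3f",
                      object$slope, object$r_squared)
    ) +
    ggplot2::theme_minimal()
  if ("sem_whbc" %in% names(dat) && any(dat$sem_whbc > 0)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_whbc - .data$sem_whbc,
        ymax = .data$mean_whbc + .data$sem_whbc
      ),
      width = 0.1
    )
  }
  p
}

#' Plot per-class WHBC normal fits
#'
#' Overlaid normal density curves, one per ring-count class, from the
#' per-class [fit_gaussian()] parameters.
#'
#' @param cohort A data frame with `nAR` and `WHBC` columns.
#' @param scheme Binning scheme, see [assign_ring_class()].
#' @return A ggplot object.
#' @export
plot_class_gaussians <- function(cohort, scheme = "histogram") {
  dat <- tibble(
    ring_class = assign_ring_class(cohort$nAR, scheme),
    WHBC = cohort$WHBC
  )
  fits <- dat |>
    group_by(.data$ring_class) |>
    filter(n() >= 2) |>
    summarise(fit_gaussian(.data$WHBC), .groups = "drop") |>
    filter(!.data$degenerate)
  grid <- tidyr::crossing(
    fits,
    whbc = seq(max(0, min(dat$WHBC)), max(dat$WHBC), length.out = 200)
  ) |>
    mutate(density = stats::dnorm(.data$whbc, .data$mu, .data$sigma))
  ggplot2::ggplot(grid, ggplot2::aes(.data$whbc, .data$density,
                                     colour = .data$ring_class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "WHBC", y = "normal density",
                  colour = "aromatic rings") +
    ggplot2::theme_minimal()
}
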