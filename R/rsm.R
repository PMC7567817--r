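rsm_terms <- function() c("(Intercept)", "eCO2", "eT", "eCO2:eT", "eCO2^2", "eT^2")

# internal term labels <-> model-matrix column names
rsm_formula <- function(terms) {
  rhs <- c("eCO2" = "eCO2", "eT" = "eT", "eCO2:eT" = "eCO2:eT",
           "eCO2^2" = "I(eCO2^2)", "eT^2" = "I(eT^2)")
  keep <- rhs[intersect(names(rhs), terms)]
  stats::reformulate(unname(keep), response = ".y")
}

canonical_term <- function(x) {
  x <- sub("^I\\(eCO2\\^2\\)$", "eCO2^2", x)
  sub("^I\\(eT\\^2\\)$", "eT^2", x)
}

#' Fit a per-date second-order response-surface model
#'
#' Ordinary least squares of a response on the full second-order polynomial
#' in the coded treatment levels (`eCO2`, `eT`, their interaction and
#' quadratics) for a single sampling date, as used for the per-date
#' treatment-surface tables. Biomass-specific rates are natural-log
#' transformed by default; CUE is fitted untransformed.
#'
#' @param data A tibble holding the response column and coded `eCO2`, `eT`
#'   columns (e.g. physiology joined to [add_coded_units()] output), or a
#'   physiology table plus `design`.
#' @param response Column name: `"G_m"`, `"R_m"` or `"CUE"` (any numeric
#'   column is accepted).
#' @param date Sampling date label to fit; `NULL` uses all rows as given.
#' @param design Optional plot-level design to join treatment codes from.
#' @param log_transform Log the response? Default `TRUE` for `G_m`/`R_m`,
#'   `FALSE` otherwise.
#' @param terms Model terms to include; default the full second-order set.
#' @param qc_filter Drop qc-flagged rows first (default `TRUE` when a
#'   `qc_flags` column is present).
#' @return An object of class `cue_rsm` with [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
#' @examples
#' study <- generate_study(seed = 7)
#' phys <- compute_physiology(study$raw)
#' fit <- fit_surface_model(phys, "G_m", date = "May", design = study$design)
#' generics::tidy(fit)
fit_surface_model <- function(data, response, date = NULL, design = NULL,
                              log_transform = response %in% c("G_m", "R_m"),
                              terms = setdiff(rsm_terms(), "(Intercept)"),
                              qc_filter = TRUE) {
  if (!is.null(design)) {
    codes <- design |>
      rsm_subset() |>
      add_coded_units() |>
      dplyr::select("plot_id", "eT", "eCO2")
    data <- dplyr::inner_join(data, codes, by = "plot_id")
  }
  if (!all(c("eCO2", "eT") %in% names(data))) {
    stop("data must carry coded 'eCO2' and 'eT' columns (or pass a design)",
         call. = FALSE)
  }
  if (!is.null(date)) data <- dplyr::filter(data, .data$date == !!date)
  if (qc_filter && "qc_flags" %in% names(data)) data <- drop_flagged(data)
  data <- dplyr::filter(data, !is.na(.data[[response]]))
  y <- data[[response]]
  if (log_transform) {
    if (any(y <= 0)) stop("cannot log-transform non-positive responses",
                          call. = FALSE)
    y <- log(y)
  }
  p <- length(terms) + 1L
  if (nrow(data) < p + 1L) {
    stop(sprintf("need at least %d rows to fit %d parameters", p + 1L, p),
         call. = FALSE)
  }
  df_fit <- dplyr::tibble(.y = y, eCO2 = data$eCO2, eT = data$eT)
  fit <- stats::lm(rsm_formula(terms), data = df_fit)
  if (anyNA(stats::coef(fit))) {
    stop("rank-deficient response-surface design", call. = FALSE)
  }
  sm <- summary(fit)
  coefs <- sm$coefficients
  table <- dplyr::tibble(
    term = canonical_term(rownames(coefs)),
    estimate = unname(coefs[, 1]), std.error = unname(coefs[, 2]),
    statistic = unname(coefs[, 3]), p.value = unname(coefs[, 4])
  )
  fstat <- sm$fstatistic
  structure(
    list(
      table = table, lm = fit, data = df_fit, terms = terms,
      response = response, date = if (is.null(date)) NA_character_ else
        as.character(date),
      log_transform = log_transform,
      n = nrow(df_fit), r.squared = sm$r.squared,
      adj.r.squared = sm$adj.r.squared,
      f.statistic = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
      f.p.value = if (is.null(fstat)) NA_real_ else
        unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
      sigma = sm$sigma, df.residual = fit$df.residual,
      eliminated = character(0)
    ),
    class = "cue_rsm"
  )
}

#' Reduce a response-surface fit by the marginality principle
#'
#' Backward elimination in which only the highest-order terms (the
#' interaction and the two quadratics) are candidates for removal: the
#' candidate with the largest p-value above `alpha` is dropped and the model
#' refitted, until all remaining candidates are significant. The linear main
#' effects are never dropped, so a retained interaction or quadratic always
#' has its marginal terms present. Ties are broken deterministically
#' (alphabetically among equal p-values).
#'
#' @param fit A `cue_rsm` fit from [fit_surface_model()].
#' @param alpha Significance threshold, default 0.05.
#' @return A reduced `cue_rsm`; the dropped terms, in order, are recorded in
#'   `$eliminated`.
#' @export
reduce_by_marginality <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "cue_rsm"))
  protected <- c("(Intercept)", "eCO2", "eT")
  terms <- fit$terms
  data <- fit$data
  eliminated <- character(0)
  repeat {
    cur <- refit_rsm(fit, terms, data)
    cand <- cur$table |>
      dplyr::filter(!.data$term %in% protected) |>
      dplyr::arrange(dplyr::desc(.data$p.value), .data$term)
    if (nrow(cand) == 0 || cand$p.value[1] <= alpha) {
      cur$eliminated <- eliminated
      return(cur)
    }
    drop <- cand$term[1]
    eliminated <- c(eliminated, drop)
    terms <- setdiff(terms, drop)
  }
}

refit_rsm <- function(fit, terms, data) {
  fit2 <- stats::lm(rsm_formula(terms), data = data)
  sm <- summary(fit2)
  coefs <- sm$coefficients
  fstat <- sm$fstatistic
  out <- fit
  out$lm <- fit2
  out$terms <- terms
  out$table <- dplyr::tibble(
    term = canonical_term(rownames(coefs)),
    estimate = unname(coefs[, 1]), std.error = unname(coefs[, 2]),
    statistic = unname(coefs[, 3]), p.value = unname(coefs[, 4])
  )
  out$r.squared <- sm$r.squared
  out$adj.r.squared <- sm$adj.r.squared
  out$f.statistic <- if (is.null(fstat)) NA_real_ else unname(fstat[1])
  out$f.p.value <- if (is.null(fstat)) NA_real_ else
    unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  out$sigma <- sm$sigma
  out$df.residual <- fit2$df.residual
  out
}

#' @export
print.cue_rsm <- function(x, ...) {
  cat(sprintf("Response-surface fit: %s%s%s (n = %d, R2 = %.3f)\n",
              if (x$log_transform) "log " else "", x$response,
              if (is.na(x$date)) "" else paste0(", ", x$date),
              x$n, x$r.squared))
  print(x$table)
  if (length(x$eliminated) > 0) {
    cat("Eliminated (marginality):", paste(x$eliminated, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a response-surface fit
#'
#' @param x A `cue_rsm` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @exportS3Method generics::tidy
tidy.cue_rsm <- function(x, ...) x$table

#' One-row model summary of a response-surface fit
#'
#' @param x A `cue_rsm` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.cue_rsm <- function(x, ...) {
  dplyr::tibble(
    r.squared = x$r.squared, adj.r.squared = x$adj.r.squared,
    sigma = x$sigma, statistic = x$f.statistic, p.value = x$f.p.value,
    df.residual = x$df.residual, nobs = x$n, AIC = stats::AIC(x$lm)
  )
}
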