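#' Iterative feasible generalised least squares
#'
#' The workhorse estimator behind [fit_seasonal_gls()]: alternates between
#' (1) generalised least squares for the fixed effects given the current
#' covariance, (2) per-stratum residual variances, and (3) a moment estimate
#' of the within-subject correlation for the selected structure, until the
#' parameter vector is stationary. Strata are the sampling dates; subjects
#' are plots measured repeatedly across dates.
#'
#' @param y Numeric response vector.
#' @param x Model matrix (n x p, full column rank).
#' @param group Stratum factor (one residual variance per level), or a
#'   single-level factor for homoscedastic fits.
#' @param subject Optional subject factor linking repeated measures; required
#'   for `structure` other than `"none"`.
#' @param structure Correlation structure within subject: `"none"`,
#'   `"CS"` (compound symmetry) or `"AR1"` (first-order autoregressive over
#'   the stratum order).
#' @param heteroscedastic Estimate one variance per stratum (`TRUE`,
#'   default) or a single pooled variance (`FALSE`, in which case the fit
#'   with `structure = "none"` is exactly OLS).
#' @param max_iter,tol Iteration control: stop when the maximum relative
#'   change of all parameters falls below `tol` (default 1e-8) or after
#'   `max_iter` iterations (default 100, then flagged non-converged).
#' @return A list with elements `coefficients`, `vcov`, `sigma` (per-stratum
#'   residual SDs), `rho`, `structure`, `logLik`, `AIC`, `n`, `p`,
#'   `iterations`, `converged`, `fitted`, `residuals`, and `trace` (per
#'   iteration maximum relative change).
#' @export
fgls <- function(y, x, group, subject = NULL,
                 structure = c("none", "CS", "AR1"),
                 heteroscedastic = TRUE, max_iter = 100L, tol = 1e-8) {
  structure <- match.arg(structure)
  n <- length(y)
  stopifnot(nrow(x) == n, length(group) == n)
  group <- droplevels(as.factor(group))
  levels_g <- levels(group)
  p <- ncol(x)
  if (qr(x)$rank < p) stop("singular (rank-deficient) design matrix",
                           call. = FALSE)
  if (structure != "none") {
    if (is.null(subject)) stop("a subject factor is required for correlated ",
                               "structures", call. = FALSE)
    subject <- as.factor(subject)
  }

  # stratum order defines the AR1 lag metric
  g_idx <- as.integer(group)
  beta <- qr.coef(qr(x), y)
  sigma2 <- rep(stats::var(y), length(levels_g))
  rho <- 0
  converged <- FALSE
  trace <- numeric(0)

  blocks <- if (structure == "none") NULL else split(seq_len(n), subject)

  for (iter in seq_len(max_iter)) {
    r <- y - drop(x %*% beta)
    if (heteroscedastic) {
      sigma2_new <- vapply(seq_along(levels_g), function(g) {
        mean(r[g_idx == g]^2)
      }, numeric(1))
    } else {
      sigma2_new <- rep(mean(r^2), length(levels_g))
    }
    if (any(sigma2_new <= 0)) stop("degenerate stratum variance", call. = FALSE)

    rho_new <- 0
    if (structure != "none") {
      z <- r / sqrt(sigma2_new[g_idx])
      num <- 0; den <- 0
      for (idx in blocks) {
        if (length(idx) < 2) next
        gi <- g_idx[idx]
        for (a in seq_along(idx)[-length(idx)]) {
          for (b in seq((a + 1), length(idx))) {
            lag <- abs(gi[b] - gi[a])
            if (structure == "AR1" && lag != 1) next
            num <- num + z[idx[a]] * z[idx[b]]
            den <- den + 1
          }
        }
      }
      if (den > 0) rho_new <- num / den
      rho_new <- max(min(rho_new, 0.98), if (structure == "CS")
        -1 / (length(levels_g) - 1) + 0.01 else -0.98)
    }

    # GLS step with the updated covariance
    if (structure == "none") {
      w <- 1 / sigma2_new[g_idx]
      a_mat <- crossprod(x * w, x)
      b_vec <- crossprod(x * w, y)
    } else {
      a_mat <- matrix(0, p, p)
      b_vec <- numeric(p)
      for (idx in blocks) {
        gi <- g_idx[idx]
        s <- sqrt(sigma2_new[gi])
        corr <- if (structure == "CS") {
          m <- matrix(rho_new, length(idx), length(idx)); diag(m) <- 1; m
        } else {
          rho_new^abs(outer(gi, gi, "-"))
        }
        sig <- corr * tcrossprod(s)
        sig_inv <- tryCatch(chol2inv(chol(sig)), error = function(e) {
          stop("non-positive-definite within-subject covariance", call. = FALSE)
        })
        xb <- x[idx, , drop = FALSE]
        a_mat <- a_mat + crossprod(xb, sig_inv %*% xb)
        b_vec <- b_vec + crossprod(xb, sig_inv %*% y[idx])
      }
    }
    beta_new <- drop(solve(a_mat, b_vec))

    theta_old <- c(beta, sigma2, rho)
    theta_new <- c(beta_new, sigma2_new, rho_new)
    delta <- max(abs(theta_new - theta_old) / (abs(theta_old) + 1e-10))
    trace <- c(trace, delta)
    beta <- beta_new; sigma2 <- sigma2_new; rho <- rho_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("feasible GLS did not converge in %d iterations ",
                    max_iter),
            sprintf("(last relative change %.3g)", utils::tail(trace, 1)),
            call. = FALSE)
  }

  r <- y - drop(x %*% beta)
  # Gaussian log-likelihood under the estimated covariance
  if (structure == "none") {
    quad <- sum(r^2 / sigma2[g_idx])
    logdet <- sum(log(sigma2[g_idx]))
  } else {
    quad <- 0; logdet <- 0
    for (idx in blocks) {
      gi <- g_idx[idx]
      s <- sqrt(sigma2[gi])
      corr <- if (structure == "CS") {
        m <- matrix(rho, length(idx), length(idx)); diag(m) <- 1; m
      } else rho^abs(outer(gi, gi, "-"))
      sig <- corr * tcrossprod(s)
      ch <- chol(sig)
      logdet <- logdet + 2 * sum(log(diag(ch)))
      quad <- quad + sum(backsolve(ch, r[idx], transpose = TRUE)^2)
    }
  }
  loglik <- -0.5 * (n * log(2 * pi) + logdet + quad)
  k <- p + (if (heteroscedastic) length(levels_g) else 1L) +
    (structure != "none")
  names(beta) <- colnames(x)
  sigma <- sqrt(sigma2)
  names(sigma) <- levels_g
  list(coefficients = beta, vcov = solve(a_mat), sigma = sigma,
       rho = if (structure == "none") NA_real_ else rho,
       structure = structure, logLik = loglik, AIC = -2 * loglik + 2 * k,
       n = n, p = p, iterations = length(trace), converged = converged,
       fitted = drop(x %*% beta), residuals = r, trace = trace)
}

seasonal_formula <- function() {
  ~ date + eCO2 + eT + I(eCO2^2) + date:eCO2 + date:eT + eCO2:eT +
    date:I(eCO2^2) + date:eCO2:eT
}

#' Seasonal heteroscedastic GLS over the three sampling dates
#'
#' Fits the season-spanning model of a physiology response on sampling date,
#' the coded treatment levels, the CO2 quadratic and the date interactions,
#' allowing a different residual variance per date and optional within-plot
#' correlation across dates (none, compound symmetry, or AR1), estimated by
#' iterative feasible GLS. When `correlation = "AIC"` all three structures
#' are fitted and the one with the lowest Gaussian AIC is kept. Per-term
#' significance is assessed by marginal Wald F tests with denominator
#' degrees of freedom `n - p`.
#'
#' @param data Physiology table (or any tibble with the response, `date` and
#'   `plot_id`); treatment codes are joined from `design` or taken from
#'   `eCO2`/`eT` columns.
#' @param response Response column name (`"G_m"`, `"R_m"`, `"CUE"`, ...).
#' @param design Optional plot-level design; its surface-response subset is
#'   used.
#' @param correlation `"AIC"` (default), `"none"`, `"CS"` or `"AR1"`.
#' @param log_transform Log the response? Default `TRUE` for `G_m`/`R_m`.
#' @param heteroscedastic One residual variance per date (default `TRUE`).
#' @param formula Right-hand-side fixed-effects formula in `date`, `eCO2`,
#'   `eT`; default the full seasonal model.
#' @param qc_filter Drop qc-flagged rows first (default `TRUE`).
#' @param max_iter,tol Iteration control for the FGLS loop.
#' @return An object of class `cue_gls` with `tidy()`/`glance()` methods;
#'   `$anova` holds the per-term F table, `$candidates` the AIC comparison
#'   when structure selection was requested.
#' @export
#' @examples
#' study <- generate_study(seed = 3)
#' phys <- compute_physiology(study$raw)
#' fit <- fit_seasonal_gls(phys, "G_m", design = study$design)
#' fit$anova
fit_seasonal_gls <- function(data, response, design = NULL,
                             correlation = c("AIC", "none", "CS", "AR1"),
                             log_transform = response %in% c("G_m", "R_m"),
                             heteroscedastic = TRUE,
                             formula = seasonal_formula(),
                             qc_filter = TRUE, max_iter = 100L, tol = 1e-8) {
  correlation <- match.arg(correlation)
  if (!is.null(design)) {
    codes <- design |>
      rsm_subset() |>
      add_coded_units() |>
      dplyr::select("plot_id", "eT", "eCO2")
    data <- dplyr::inner_join(data, codes, by = "plot_id")
  }
  if (qc_filter && "qc_flags" %in% names(data)) data <- drop_flagged(data)
  data <- dplyr::filter(data, !is.na(.data[[response]]))
  data$date <- date_factor(data$date)
  y <- data[[response]]
  if (log_transform) {
    if (any(y <= 0)) stop("cannot log-transform non-positive responses",
                          call. = FALSE)
    y <- log(y)
  }
  mm_terms <- stats::terms(formula)
  x <- stats::model.matrix(mm_terms, data = data)
  assign <- attr(x, "assign")
  term_labels <- attr(mm_terms, "term.labels")

  fit_one <- function(structure) {
    fgls(y, x, group = data$date, subject = data$plot_id,
         structure = structure, heteroscedastic = heteroscedastic,
         max_iter = max_iter, tol = tol)
  }
  if (correlation == "AIC") {
    fits <- lapply(c("none", "CS", "AR1"), fit_one)
    aics <- vapply(fits, `[[`, numeric(1), "AIC")
    best <- which.min(aics)
    engine <- fits[[best]]
    candidates <- dplyr::tibble(structure = c("none", "CS", "AR1"),
                                logLik = vapply(fits, `[[`, numeric(1), "logLik"),
                                AIC = aics)
  } else {
    engine <- fit_one(correlation)
    candidates <- NULL
  }

  # marginal Wald F per model term
  anova_tab <- purrr::map_dfr(seq_along(term_labels), function(t_i) {
    j <- which(assign == t_i)
    q <- length(j)
    b <- engine$coefficients[j]
    v <- engine$vcov[j, j, drop = FALSE]
    f <- drop(crossprod(b, solve(v, b))) / q
    dplyr::tibble(
      term = canonical_gls_term(term_labels[t_i]),
      df = q,
      statistic = f,
      p.value = stats::pf(f, q, engine$n - engine$p, lower.tail = FALSE)
    )
  })

  structure(
    list(engine = engine, anova = anova_tab, response = response,
         log_transform = log_transform, candidates = candidates,
         n = engine$n, data = data),
    class = "cue_gls"
  )
}

canonical_gls_term <- function(x) {
  x <- gsub("I\\(eCO2\\^2\\)", "eCO2^2", x)
  gsub("I\\(eT\\^2\\)", "eT^2", x)
}

#' @export
print.cue_gls <- function(x, ...) {
  e <- x$engine
  cat(sprintf("Seasonal GLS: %s%s (n = %d, structure = %s, AIC = %.2f)\n",
              if (x$log_transform) "log " else "", x$response, e$n,
              e$structure, e$AIC))
  cat("Per-date residual SD:",
      paste(sprintf("%s %.3f", names(e$sigma), e$sigma), collapse = ", "), "\n")
  if (!is.na(e$rho)) cat(sprintf("Within-plot correlation: %.3f\n", e$rho))
  print(x$anova)
  invisible(x)
}

#' Tidy the fixed effects of a seasonal GLS fit
#'
#' @param x A `cue_gls` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cue_gls <- function(x, ...) {
  e <- x$engine
  se <- sqrt(diag(e$vcov))
  stat <- e$coefficients / se
  dplyr::tibble(
    term = names(e$coefficients), estimate = unname(e$coefficients),
    std.error = unname(se), statistic = unname(stat),
    p.value = 2 * stats::pt(abs(stat), e$n - e$p, lower.tail = FALSE)
  )
}

#' One-row summary of a seasonal GLS fit
#'
#' @param x A `cue_gls` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.cue_gls <- function(x, ...) {
  e <- x$engine
  dplyr::tibble(
    structure = e$structure, rho = e$rho, logLik = e$logLik, AIC = e$AIC,
    nobs = e$n, iterations = e$iterations, converged = e$converged
  )
}
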