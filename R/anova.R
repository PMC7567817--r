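#' Two-way drought ANOVA for one sampling date
#'
#' The drought factorial contrasts ambient-climate plots against
#' future-climate plots (+3 degC, +300 ppm), sheltered or not, at a single
#' date. Fits `response ~ climate * drought` by [stats::aov()] with
#' sequential (Type I) sums of squares in the stated order (climate,
#' drought, interaction). Biomass-specific rates are log-transformed by
#' default, matching the season-level models.
#'
#' @param data Physiology table with `plot_id` and `date`.
#' @param design Plot-level design; its [drought_subset()] defines the
#'   factorial and the `climate` labels.
#' @param date Sampling date to analyse.
#' @param response Response column name.
#' @param log_transform Log the response? Default `TRUE` for `G_m`/`R_m`.
#' @param qc_filter Drop qc-flagged rows first (default `TRUE`).
#' @return An object of class `cue_anova`: `$table` holds term, df, sum of
#'   squares, mean squares, F and p; `$aov` the underlying fit; `$data` the
#'   analysed rows with `climate`, `drought` and `group` columns.
#' @export
#' @examples
#' study <- generate_study(seed = 5)
#' phys <- compute_physiology(study$raw)
#' fit <- anova_drought(phys, study$design, date = "July", response = "G_m")
#' fit$table
anova_drought <- function(data, design, date, response,
                          log_transform = response %in% c("G_m", "R_m"),
                          qc_filter = TRUE) {
  sub <- drought_subset(design) |>
    dplyr::select("plot_id", "climate", "drought")
  rows <- data |>
    dplyr::inner_join(sub, by = "plot_id") |>
    dplyr::filter(.data$date == !!date)
  if (qc_filter && "qc_flags" %in% names(rows)) rows <- drop_flagged(rows)
  rows <- dplyr::filter(rows, !is.na(.data[[response]]))
  counts <- rows |> dplyr::count(.data$climate, .data$drought)
  if (nrow(counts) < 4) {
    stop("empty cell(s) in the climate x drought factorial", call. = FALSE)
  }
  y <- rows[[response]]
  if (log_transform) {
    if (any(y <= 0)) stop("cannot log-transform non-positive responses",
                          call. = FALSE)
    y <- log(y)
  }
  df_fit <- dplyr::tibble(
    .y = y,
    climate = factor(rows$climate, levels = c("ambient", "future")),
    drought = factor(ifelse(rows$drought, "drought", "control"),
                     levels = c("control", "drought"))
  )
  fit <- stats::aov(.y ~ climate * drought, data = df_fit)
  tab <- summary(fit)[[1]]
  out <- dplyr::tibble(
    term = trimws(rownames(tab)),
    df = tab$Df, sumsq = tab$`Sum Sq`, meansq = tab$`Mean Sq`,
    statistic = tab$`F value`, p.value = tab$`Pr(>F)`
  )
  structure(
    list(table = out, aov = fit, response = response,
         log_transform = log_transform, date = as.character(date),
         data = dplyr::mutate(rows, group = interaction(
           df_fit$climate, df_fit$drought, sep = ":"), .y = y)),
    class = "cue_anova"
  )
}

#' @export
print.cue_anova <- function(x, ...) {
  cat(sprintf("Drought ANOVA: %s%s, %s\n",
              if (x$log_transform) "log " else "", x$response, x$date))
  print(x$table)
  invisible(x)
}

#' Tidy a drought ANOVA
#'
#' @param x A `cue_anova` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cue_anova <- function(x, ...) x$table

#' Tukey HSD comparisons with compact letters
#'
#' All-pairs mean comparisons of a grouping factor by the studentized-range
#' distribution, using the residual mean square and degrees of freedom of a
#' one-way fit on the groups (Tukey-Kramer for unequal group sizes), plus a
#' compact letter display assigned by a sweep from the largest group mean:
#' groups that cannot be distinguished at `alpha` share a letter.
#'
#' @param data A tibble with the response and grouping columns, or a
#'   `cue_anova` object (its four climate x drought cells are compared on
#'   the transformed response).
#' @param response Response column name (ignored for `cue_anova` input).
#' @param group Grouping column name (ignored for `cue_anova` input).
#' @param alpha Family-wise significance level, default 0.05.
#' @param log_transform Log the response first (default `FALSE` for raw
#'   tibble input).
#' @return A list of class `cue_tukey`: `$comparisons` (pair, difference,
#'   studentized-range statistic, adjusted p, confidence bounds) and
#'   `$letters` (group, mean, letters).
#' @export
tukey_hsd <- function(data, response = NULL, group = NULL, alpha = 0.05,
                      log_transform = FALSE) {
  if (inherits(data, "cue_anova")) {
    df <- dplyr::tibble(.y = data$data$.y, .g = factor(data$data$group))
  } else {
    y <- data[[response]]
    if (log_transform) y <- log(y)
    df <- dplyr::tibble(.y = y, .g = factor(data[[group]]))
  }
  df <- dplyr::filter(df, !is.na(.data$.y))
  sizes <- table(df$.g)
  if (length(sizes) < 2) stop("need at least two groups", call. = FALSE)
  if (any(sizes < 2)) {
    stop("each group needs at least two observations", call. = FALSE)
  }
  fit <- stats::aov(.y ~ .g, data = df)
  mse <- stats::deviance(fit) / stats::df.residual(fit)
  dfe <- stats::df.residual(fit)
  k <- length(sizes)
  means <- tapply(df$.y, df$.g, mean)

  pairs <- utils::combn(names(means), 2)
  comparisons <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    diff <- means[[g2]] - means[[g1]]
    se <- sqrt(mse / 2 * (1 / sizes[[g1]] + 1 / sizes[[g2]]))
    # degenerate zero-variance fits: identical values give q = 0, not 0/0
    q <- if (se > 0) abs(diff) / se else if (abs(diff) > 0) Inf else 0
    crit <- stats::qtukey(1 - alpha, k, dfe)
    dplyr::tibble(
      contrast = paste(g2, "-", g1),
      estimate = diff,
      statistic = q,
      adj.p.value = stats::ptukey(q, k, dfe, lower.tail = FALSE),
      conf.low = diff - crit * se,
      conf.high = diff + crit * se
    )
  })

  letters_tab <- compact_letters(means, comparisons, alpha)
  structure(list(comparisons = comparisons, letters = letters_tab,
                 mse = mse, df = dfe, alpha = alpha),
            class = "cue_tukey")
}

# sweep-style compact letter display: order groups by decreasing mean, find
# maximal runs of mutually non-significant groups, letter each new run
compact_letters <- function(means, comparisons, alpha) {
  ord <- names(sort(means, decreasing = TRUE))
  k <- length(ord)
  sig <- matrix(FALSE, k, k, dimnames = list(ord, ord))
  for (i in seq_len(nrow(comparisons))) {
    gs <- strsplit(comparisons$contrast[i], " - ", fixed = TRUE)[[1]]
    s <- comparisons$adj.p.value[i] < alpha
    sig[gs[1], gs[2]] <- s
    sig[gs[2], gs[1]] <- s
  }
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(sig[ord[i:(j + 1)], ord[i:(j + 1)]])) j <- j + 1
    run <- ord[i:j]
    covered <- any(vapply(runs, function(r) all(run %in% r), logical(1)))
    if (!covered) runs[[length(runs) + 1]] <- run
  }
  lab <- stats::setNames(rep("", k), ord)
  for (r in seq_along(runs)) {
    lab[runs[[r]]] <- paste0(lab[runs[[r]]], letters[r])
  }
  dplyr::tibble(group = ord, mean = as.numeric(means[ord]),
                letters = unname(lab))
}

#' @export
print.cue_tukey <- function(x, ...) {
  cat(sprintf("Tukey HSD (alpha = %g, df = %d)\n", x$alpha, x$df))
  print(x$comparisons)
  cat("Letters:\n")
  print(x$letters)
  invisible(x)
}

#' Tidy Tukey HSD comparisons
#'
#' @param x A `cue_tukey` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cue_tukey <- function(x, ...) x$comparisons
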