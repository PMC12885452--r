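#' Benjamini-Hochberg adjustment with rejection flags
#'
#' Standard step-up false-discovery-rate correction
#' (`stats::p.adjust(method = "BH")`): the adjusted i-th smallest p-value is
#' `min over j >= i of min(1, m * p_(j) / j)`. Output order matches input
#' order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level for the rejection flags.
#' @return List with `adjusted` (same order as input) and `reject`
#'   (`adjusted <= q`).
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(pvalues, q = 0.05) {
  if (!is.numeric(pvalues) || any(is.na(pvalues)) ||
      any(pvalues < 0 | pvalues > 1))
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  adjusted <- stats::p.adjust(pvalues, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= q)
}

#' Baseline characteristics table with cross-cluster tests
#'
#' Summarizes wave-1 rows: counts (percent) per level for categorical
#' variables and mean (SD) for continuous ones, overall and per cluster, with
#' a Pearson chi-square test (no continuity correction) for categoricals and
#' a one-way ANOVA F test for continuous variables across clusters.
#' Benjamini-Hochberg significance flags are computed over the table's
#' p-values as one family.
#'
#' @param panel Long panel data.frame.
#' @param categorical Categorical variables to summarize.
#' @param continuous Continuous variables; defaults to age plus every score
#'   column present in the panel.
#' @return An object of class `baseline_table` (a data.frame with columns
#'   `variable`, `type`, `overall`, one column per cluster, `statistic`,
#'   `df`, `p`, `bh_significant`).
#' @export
baseline_table <- function(panel,
                           categorical = c("gender", "profession",
                                           "contract", "trainee"),
                           continuous = NULL) {
  if (is.null(continuous))
    continuous <- intersect(c("age", score_columns()), names(panel))
  w1 <- panel[panel$wave == 1L, , drop = FALSE]
  if (!nrow(w1)) stop("no wave-1 rows in panel", call. = FALSE)
  empty <- setdiff(unique(panel$cluster), unique(w1$cluster))
  if (length(empty))
    warning("cluster(s) without wave-1 rows excluded: ",
            paste(empty, collapse = ", "), call. = FALSE)
  clusters <- sort(unique(w1$cluster))
  cl <- factor(w1$cluster, levels = clusters)

  fmt_np <- function(x, lev) {
    n <- sum(x == lev, na.rm = TRUE)
    sprintf("%d (%.1f)", n, 100 * n / sum(!is.na(x)))
  }
  fmt_ms <- function(x) sprintf("%.2f (%.2f)",
                                mean(x, na.rm = TRUE), stats::sd(x, na.rm = TRUE))

  rows <- list()
  for (v in intersect(categorical, names(w1))) {
    x <- as.character(w1[[v]])
    tab <- table(x, cl)
    ct <- tryCatch(
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)),
      error = function(e) list(statistic = NA_real_, parameter = NA_integer_,
                               p.value = NA_real_))
    lev <- rownames(tab)
    shown <- if (length(lev) == 2L) lev[2] else lev  # binary: show one level
    for (l in shown) {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = if (length(shown) == 1L) v else sprintf("%s: %s", v, l),
        type = "categorical",
        overall = fmt_np(x, l),
        t(vapply(clusters, function(c2) fmt_np(x[cl == c2], l), character(1))),
        statistic = unname(ct$statistic), df = sprintf("%d", ct$parameter),
        p = unname(ct$p.value), stringsAsFactors = FALSE)
    }
  }
  for (v in intersect(continuous, names(w1))) {
    x <- as.numeric(w1[[v]])
    ok <- !is.na(x)
    av <- stats::anova(stats::lm(x[ok] ~ cl[ok]))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, type = "continuous",
      overall = fmt_ms(x),
      t(vapply(clusters, function(c2) fmt_ms(x[cl == c2]), character(1))),
      statistic = av$`F value`[1],
      df = sprintf("%d, %d", av$Df[1], av$Df[2]),
      p = av$`Pr(>F)`[1], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  names(out)[4:(3 + length(clusters))] <- paste0("cluster_", clusters)
  out$p[!is.finite(out$p)] <- NA_real_
  # degenerate variables (no variation) carry no test; exclude from BH family
  out$bh_significant <- FALSE
  ok <- !is.na(out$p)
  if (any(ok)) out$bh_significant[ok] <- bh_adjust(out$p[ok])$reject
  rownames(out) <- NULL
  structure(out, class = c("baseline_table", "data.frame"))
}

#' @export
print.baseline_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$statistic <- sprintf("%.2f", y$statistic)
  y$p <- format_p(y$p)
  print(y, row.names = FALSE)
  invisible(x)
}

# p-values below the bootstrap resolution are reported as a bound
format_p <- function(p, n_boot = NULL) {
  lower <- if (is.null(n_boot)) 0.001 else 2 / n_boot
  ifelse(p < lower, sprintf("<%.3g", lower), sprintf("%.3f", p))
}

fmt_path <- function(label, s, n_boot = NULL, digits = 2) {
  sprintf("  %-38s %s (%s to %s)   P = %s", label,
          formatC(s$estimate, digits = digits, format = "f"),
          formatC(s$ci[1], digits = digits, format = "f"),
          formatC(s$ci[2], digits = digits, format = "f"),
          format_p(s$p, n_boot))
}

#' Render analysis results as text, CSV rows or JSON
#'
#' Deterministic formatting of mediation, multivariate, lagged and baseline
#' results. Text output mirrors the four-row path layout
#' (a, b, indirect a x b, direct); bootstrap p-values smaller than the
#' bootstrap resolution `2/n_boot` are rendered as a `<` bound.
#'
#' @param x A result object (`mediation_result`,
#'   `multivariate_mediation_result`, `empty_mediation_result`,
#'   `lagged_result`, or `baseline_table`).
#' @param format `"text"` (character vector of lines), `"csv"` (data.frame),
#'   or `"json"` (JSON string).
#' @param digits Decimal digits for estimates.
#' @return See `format`.
#' @export
render_results <- function(x, format = c("text", "csv", "json"), digits = 2) {
  format <- match.arg(format)
  UseMethod("render_results")
}

#' @export
render_results.default <- function(x, format = c("text", "csv", "json"),
                                   digits = 2) {
  stop("no rendering defined for class ", paste(class(x), collapse = "/"),
       call. = FALSE)
}

result_rows <- function(x) {
  if (inherits(x, "mediation_result")) {
    m <- x$mediator
    labs <- c(sprintf("a (treatment -> %s)", m),
              sprintf("b (%s -> %s)", m, x$outcome),
              "Indirect effect (a x b)",
              sprintf("Direct effect (treatment -> %s)", x$outcome))
    parts <- list(x$a, x$b, x$indirect, x$direct)
    data.frame(mediator = m, path = labs,
               estimate = vapply(parts, function(s) s$estimate, numeric(1)),
               ci_lower = vapply(parts, function(s) s$ci[1], numeric(1)),
               ci_upper = vapply(parts, function(s) s$ci[2], numeric(1)),
               p = vapply(parts, function(s) s$p, numeric(1)),
               stringsAsFactors = FALSE)
  } else {
    rows <- lapply(x$mediators, function(m) {
      s <- x$paths[[m]]$indirect
      data.frame(mediator = m, path = "Indirect effect (a x b)",
                 estimate = s$estimate, ci_lower = s$ci[1],
                 ci_upper = s$ci[2], p = s$p, stringsAsFactors = FALSE)
    })
    d <- x$direct
    rows[[length(rows) + 1L]] <- data.frame(
      mediator = "(shared)", path = "Direct effect",
      estimate = d$estimate, ci_lower = d$ci[1], ci_upper = d$ci[2],
      p = d$p, stringsAsFactors = FALSE)
    do.call(rbind, rows)
  }
}

#' @export
render_results.mediation_result <- function(x, format = c("text", "csv", "json"),
                                            digits = 2) {
  format <- match.arg(format)
  if (format == "csv") return(result_rows(x))
  if (format == "json")
    return(jsonlite::toJSON(c(result_rows(x),
                              list(n_boot_used = x$n_boot_used,
                                   seed = x$seed)),
                            dataframe = "columns", digits = NA,
                            auto_unbox = TRUE))
  nb <- x$n_boot_used
  c(sprintf("Mediation of treatment -> %s through %s", x$outcome, x$mediator),
    sprintf("  (%d participants, %d bootstrap draws, seed %d)",
            x$n_participants, nb, x$seed),
    fmt_path(sprintf("a (treatment -> %s)", x$mediator), x$a, nb, digits),
    fmt_path(sprintf("b (%s -> %s)", x$mediator, x$outcome), x$b, nb, digits),
    fmt_path("Indirect effect (a x b)", x$indirect, nb, digits),
    fmt_path(sprintf("Direct effect (treatment -> %s)", x$outcome),
             x$direct, nb, digits))
}

#' @export
render_results.multivariate_mediation_result <-
  function(x, format = c("text", "csv", "json"), digits = 2) {
  format <- match.arg(format)
  if (format == "csv") return(result_rows(x))
  if (format == "json")
    return(jsonlite::toJSON(c(result_rows(x),
                              list(n_boot_used = x$n_boot_used,
                                   seed = x$seed)),
                            dataframe = "columns", digits = NA,
                            auto_unbox = TRUE))
  nb <- x$n_boot_used
  c(sprintf("Multivariate mediation of treatment -> %s (%d mediators)",
            x$outcome, length(x$mediators)),
    sprintf("  (%d participants, %d bootstrap draws, seed %d)",
            x$n_participants, nb, x$seed),
    vapply(x$mediators, function(m)
      fmt_path(m, x$paths[[m]]$indirect, nb, digits), character(1)),
    fmt_path("Direct effect", x$direct, nb, digits))
}

#' @export
render_results.empty_mediation_result <-
  function(x, format = c("text", "csv", "json"), digits = 2) {
  format <- match.arg(format)
  if (format == "csv")
    return(data.frame(mediator = character(0), path = character(0),
                      estimate = numeric(0), ci_lower = numeric(0),
                      ci_upper = numeric(0), p = numeric(0)))
  if (format == "json")
    return(jsonlite::toJSON(list(status = x$status, message = x$message),
                            auto_unbox = TRUE))
  c("Sensitivity model: no mediators passed the univariate filter",
    paste(" ", x$message))
}

#' @export
render_results.lagged_result <- function(x, format = c("text", "csv", "json"),
                                         digits = 2) {
  format <- match.arg(format)
  row <- data.frame(mediator = x$mediator, outcome = x$outcome,
                    coefficient = x$coefficient, se = x$se,
                    ci_lower = x$ci[1], ci_upper = x$ci[2], p = x$p,
                    n_lagged_rows = x$n_lagged_rows,
                    stringsAsFactors = FALSE)
  if (format == "csv") return(row)
  if (format == "json")
    return(jsonlite::toJSON(row, dataframe = "columns", digits = NA,
                            auto_unbox = TRUE))
  c(sprintf("Lagged model: %s at wave t -> %s at wave t+1 (%d lagged rows)",
            x$mediator, x$outcome, x$n_lagged_rows),
    sprintf("  coefficient = %s (%s to %s), SE = %s, P = %s",
            formatC(x$coefficient, digits = digits, format = "f"),
            formatC(x$ci[1], digits = digits, format = "f"),
            formatC(x$ci[2], digits = digits, format = "f"),
            formatC(x$se, digits = digits, format = "f"),
            format_p(x$p)))
}

#' @export
render_results.baseline_table <- function(x, format = c("text", "csv", "json"),
                                          digits = 2) {
  format <- match.arg(format)
  if (format == "csv") return(as.data.frame(x))
  if (format == "json")
    return(jsonlite::toJSON(as.data.frame(x), dataframe = "columns",
                            digits = NA, auto_unbox = TRUE))
  utils::capture.output(print(x))
}
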