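# Four-parameter-logistic fitting of cell-blocking assay curves, IC50
# extraction, and candidate ranking against a benchmark antibody.

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of the 4PL model
#' \deqn{y = bottom + (top - bottom) / (1 + (x / ic50)^{hill})}
#' via [minpack.lm::nlsLM()] with multi-start initialization from data
#' quantiles (several Hill slopes and IC50 starting points; best RSS wins).
#' The fit is done on log-concentration with a log-IC50 parameter, so the
#' IC50 is positive by construction. Curve orientation (a blocking assay
#' signal decreases with dose) is auto-detected: the reported `hill` is
#' positive, `top >= bottom`, and `orientation` records the direction. IC50
#' units are the assay's concentration units; comparisons are only
#' meaningful within one assay run.
#'
#' @param concentrations Strictly positive doses; at least 4 distinct
#'   values.
#' @param responses Signal values, same length as `concentrations`.
#' @param label Optional antibody label carried into the result.
#' @return A `four_pl_fit`: list with `top`, `bottom`, `hill`, `ic50`,
#'   `rss`, `converged`, `orientation` (`"decreasing"`/`"increasing"`) and
#'   `label`. Non-convergence returns the best attempt flagged
#'   `converged = FALSE`; a flat response is an error ("no dose effect").
#' @export
fit_4pl <- function(concentrations, responses, label = NA_character_) {
  x <- as.numeric(concentrations)
  y <- as.numeric(responses)
  if (length(x) != length(y)) stop("concentration/response length mismatch")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in dose-response data")
  if (any(x <= 0)) stop("concentrations must be strictly positive")
  if (length(unique(x)) < 4L)
    stop("at least 4 distinct concentrations are required for a 4PL fit")
  if (diff(range(y)) < 1e-10 * max(1, abs(mean(y))))
    stop("no dose effect: response is flat")

  lx <- log(x)
  # direction of the raw curve: sign of the dose-response trend
  slope <- stats::coef(stats::lm(y ~ lx))[2L]
  decreasing <- slope <= 0

  # starting values from the data: asymptotes from extreme-dose means,
  # ic50 candidates from dose quantiles, several hill slopes
  ord <- order(x)
  a0 <- mean(y[x == min(x)])   # response at lowest dose
  d0 <- mean(y[x == max(x)])   # response at highest dose
  le_starts <- unique(as.numeric(quantile(lx, c(0.25, 0.5, 0.75))))
  # midpoint crossing as an extra start
  mid <- (a0 + d0) / 2
  cross <- lx[ord][which.min(abs(y[ord] - mid))]
  le_starts <- unique(c(cross, le_starts))
  b_starts <- c(0.5, 1, 2) * ifelse(decreasing, 1, -1)

  # y = A + (D - A) / (1 + exp(b*(lx - le)));  (x/ic50)^b = exp(b*(lx-le))
  # A = response as x -> 0 (top for a blocking curve), D = x -> Inf plateau
  best <- NULL
  for (le in le_starts) for (b in b_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A + (D - A) / (1 + exp(b * (lx - le))),
        start = list(A = a0, D = d0, b = b, le = le),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }

  if (is.null(best)) {
    # honest non-convergence: report the data-derived starting point
    return(structure(list(
      top = max(a0, d0), bottom = min(a0, d0), hill = 1,
      ic50 = exp(cross), rss = NA_real_, converged = FALSE,
      orientation = ifelse(decreasing, "decreasing", "increasing"),
      label = label), class = "four_pl_fit"))
  }

  cf <- stats::coef(best$fit)
  A <- cf[["A"]]; D <- cf[["D"]]; b <- cf[["b"]]; le <- cf[["le"]]
  # in this parameterization D is the zero-dose plateau and A the
  # high-dose plateau when b > 0 (roles swap with the sign of b);
  # normalize to positive hill and top >= bottom
  hill <- abs(b)
  zero_dose <- if (b > 0) D else A
  high_dose <- if (b > 0) A else D
  orientation <- if (zero_dose >= high_dose) "decreasing" else "increasing"
  structure(list(
    top = max(A, D), bottom = min(A, D), hill = hill, ic50 = exp(le),
    rss = best$rss,
    converged = isTRUE(best$fit$convInfo$isConv),
    orientation = orientation, label = label),
    class = "four_pl_fit")
}

#' @export
print.four_pl_fit <- function(x, ...) {
  cat("four_pl_fit", if (!is.na(x$label)) paste0(" [", x$label, "]") else "",
      ": ic50 = ", signif(x$ic50, 5), ", hill = ", signif(x$hill, 4),
      ", top = ", signif(x$top, 4), ", bottom = ", signif(x$bottom, 4),
      ", rss = ", signif(x$rss, 4),
      if (!x$converged) " (NOT converged)" else "", "\n", sep = "")
  invisible(x)
}

#' Predict 4PL responses
#' @param fit A `four_pl_fit` (oriented as fitted: decreasing curves fall
#'   from `top` to `bottom` with dose).
#' @param concentrations Doses to predict at.
#' @return Numeric responses.
#' @export
predict_4pl <- function(fit, concentrations) {
  x <- as.numeric(concentrations)
  if (fit$orientation == "decreasing") {
    fit$bottom + (fit$top - fit$bottom) / (1 + (x / fit$ic50)^fit$hill)
  } else {
    fit$top - (fit$top - fit$bottom) / (1 + (x / fit$ic50)^fit$hill)
  }
}

#' Fit 4PL curves for every antibody in a dose-response table
#'
#' @param data Data.frame with columns `label`, `concentration`,
#'   `response` (replicates are pooled into the fit).
#' @return Data.frame `label`, `ic50`, `hill`, `top`, `bottom`, `rss`,
#'   `converged`, one row per antibody.
#' @export
fit_ic50_table <- function(data) {
  req <- c("label", "concentration", "response")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("dose-response table missing column(s): ",
         paste(miss, collapse = ", "))
  fits <- lapply(split(data, data$label), function(d) {
    fit_4pl(d$concentration, d$response, label = d$label[1L])
  })
  out <- do.call(rbind, lapply(fits, function(f) {
    data.frame(label = f$label, ic50 = f$ic50, hill = f$hill, top = f$top,
               bottom = f$bottom, rss = f$rss, converged = f$converged,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Rank candidate antibodies by IC50 against a benchmark
#'
#' Lower IC50 = stronger blocking. Candidates (benchmark included) are
#' sorted by ascending IC50, ties broken alphabetically by label; each
#' candidate is flagged `better_than_benchmark` iff its IC50 is strictly
#' below the benchmark's.
#'
#' @param ic50_table Data.frame with columns `label`, `ic50`.
#' @param benchmark_label Label of the benchmark antibody; must be present
#'   in the table.
#' @return A `ranked_candidates` data.frame: `rank`, `label`, `ic50`,
#'   `is_benchmark`, `better_than_benchmark`, with attributes
#'   `benchmark_label` and `benchmark_ic50`.
#' @export
rank_candidates <- function(ic50_table, benchmark_label) {
  tbl <- as.data.frame(ic50_table)[, c("label", "ic50")]
  if (any(!is.finite(tbl$ic50)) || any(tbl$ic50 <= 0))
    stop("IC50 values must be positive and finite")
  if (anyDuplicated(tbl$label))
    stop("duplicate antibody labels in IC50 table")
  if (!benchmark_label %in% tbl$label)
    stop("benchmark '", benchmark_label, "' not present in IC50 table")
  bench_ic50 <- tbl$ic50[tbl$label == benchmark_label]
  out <- tbl[order(tbl$ic50, tbl$label), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$is_benchmark <- out$label == benchmark_label
  out$better_than_benchmark <- out$ic50 < bench_ic50
  out <- out[, c("rank", "label", "ic50", "is_benchmark",
                 "better_than_benchmark")]
  rownames(out) <- NULL
  attr(out, "benchmark_label") <- benchmark_label
  attr(out, "benchmark_ic50") <- bench_ic50
  class(out) <- c("ranked_candidates", "data.frame")
  out
}

#' Winner of a mutation round
#'
#' The non-benchmark candidate with the lowest IC50 (ties resolved
#' alphabetically and logged). The winner is returned even when it does not
#' beat the benchmark; the `better_than_benchmark` attribute says whether
#' it did.
#'
#' @param ranked A `ranked_candidates` data.frame.
#' @return The winning label, with attribute `better_than_benchmark`.
#' @export
select_round_winner <- function(ranked) {
  stopifnot(inherits(ranked, "ranked_candidates"))
  cand <- ranked[!ranked$is_benchmark, , drop = FALSE]
  if (nrow(cand) == 0L) stop("no non-benchmark candidates to select from")
  top <- cand[1L, ]
  if (nrow(cand) > 1L && isTRUE(all.equal(cand$ic50[2L], top$ic50)))
    message("IC50 tie at the top rank; choosing '", top$label,
            "' alphabetically")
  out <- top$label
  attr(out, "better_than_benchmark") <- top$better_than_benchmark
  out
}
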