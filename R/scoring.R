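# Core intolerance scoring: aggregate variants per unit (gene or protein
# domain), regress total mutation load on the damaging count, studentize the
# residuals, and convert them to percentile ranks. Under the default
# orientation a low (negative) residual means more damaging variants than the
# gene's mutational load predicts, i.e. intolerance; the most intolerant unit
# lands in the lowest percentile.

#' Aggregate variant-level predictions into per-unit counts
#'
#' Counts, for each gene or each protein domain, the total number of scored
#' variants and the number labelled `DAMAGING`. For `by = "domain"` a variant
#' is assigned either by an explicit `domain_id` column (which wins when both
#' are available) or by intersecting (`protein_id`, `protein_pos`) with the
#' 1-based inclusive intervals in `domains`; a position inside k overlapping
#' intervals contributes to all k domains, and variants falling in no domain
#' are counted nowhere.
#'
#' @param variants data.frame from [read_predictions()].
#' @param by aggregation unit, `"gene"` or `"domain"`.
#' @param domains data.frame from [read_domains()] (needed for `by = "domain"`
#'   unless every variant carries an explicit `domain_id`).
#' @return data.frame with columns `unit_id`, `n_total`, `n_damaging`.
#' @export
aggregate_counts <- function(variants, by = c("gene", "domain"), domains = NULL) {
  by <- match.arg(by)
  stopifnot(is.data.frame(variants), all(c("gene_id", "label") %in% names(variants)))
  dmg <- variants$label == "DAMAGING"
  if (by == "gene") {
    unit <- variants$gene_id
  } else {
    has_explicit <- "domain_id" %in% names(variants) &&
      any(!is.na(variants$domain_id) & variants$domain_id != "")
    if (!has_explicit && is.null(domains))
      stop("aggregate_counts: by = 'domain' needs a domain interval table or an explicit domain_id column",
           call. = FALSE)
    explicit <- if ("domain_id" %in% names(variants)) variants$domain_id else rep(NA_character_, nrow(variants))
    explicit[!is.na(explicit) & explicit == ""] <- NA_character_
    need_lookup <- which(is.na(explicit))
    assign_unit <- character(0); assign_dmg <- logical(0)
    keep <- which(!is.na(explicit))
    assign_unit <- explicit[keep]; assign_dmg <- dmg[keep]
    if (length(need_lookup) > 0L) {
      if (is.null(domains)) {
        warning(sprintf("aggregate_counts: %d variant(s) without explicit domain assignment and no interval table; excluded",
                        length(need_lookup)))
      } else {
        v <- variants[need_lookup, , drop = FALSE]
        no_pos <- is.na(v$protein_id) | is.na(v$protein_pos)
        if (any(no_pos))
          warning(sprintf("aggregate_counts: %d variant(s) lack protein_id/protein_pos under by = 'domain'; excluded",
                          sum(no_pos)))
        v <- v[!no_pos, , drop = FALSE]
        if (nrow(v) > 0L) {
          hit <- merge(v[, c("protein_id", "protein_pos", "label")], domains,
                       by = "protein_id")
          hit <- hit[hit$protein_pos >= hit$start & hit$protein_pos <= hit$end, , drop = FALSE]
          assign_unit <- c(assign_unit, hit$domain_id)
          assign_dmg <- c(assign_dmg, hit$label == "DAMAGING")
        }
      }
    }
    unit <- assign_unit; dmg <- assign_dmg
  }
  if (length(unit) == 0L)
    return(data.frame(unit_id = character(0), n_total = integer(0),
                      n_damaging = integer(0), stringsAsFactors = FALSE))
  n_total <- tapply(rep(1L, length(unit)), unit, sum)
  n_damaging <- tapply(as.integer(dmg), unit, sum)
  out <- data.frame(unit_id = names(n_total),
                    n_total = as.integer(n_total),
                    n_damaging = as.integer(n_damaging[names(n_total)]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$unit_id), , drop = FALSE]
}

#' Fit the mutation-load regression
#'
#' Ordinary least squares with intercept. Under the default orientation
#' `"total_on_damaging"` the response is `n_total` and the predictor is
#' `n_damaging`, so units carrying more damaging variants than their
#' mutational load predicts get negative residuals (= intolerant). The
#' reversed orientation is available and flips the ranking direction
#' downstream.
#'
#' @param counts data.frame from [aggregate_counts()].
#' @param orientation `"total_on_damaging"` (default) or `"damaging_on_total"`.
#' @return an object of class `intol_fit`: intercept, slope, residual standard
#'   error, named residuals and leverages, `n_units`, `orientation`.
#' @export
fit_regression <- function(counts, orientation = c("total_on_damaging", "damaging_on_total")) {
  orientation <- match.arg(orientation)
  stopifnot(all(c("unit_id", "n_total", "n_damaging") %in% names(counts)))
  if (any(counts$n_total < 1))
    stop("fit_regression: units with zero scored variants must not enter a fit", call. = FALSE)
  n <- nrow(counts)
  if (n < 3L) stop(sprintf("fit_regression: need at least 3 units, got %d", n), call. = FALSE)
  if (orientation == "total_on_damaging") {
    x <- counts$n_damaging; y <- counts$n_total
  } else {
    x <- counts$n_total; y <- counts$n_damaging
  }
  if (length(unique(x)) < 2L)
    stop("fit_regression: singular design (all predictor values identical)", call. = FALSE)
  fit <- stats::lm(y ~ x)
  e <- stats::residuals(fit)
  s <- sqrt(sum(e^2) / (n - 2))
  if (s <= 1e-10 * (stats::sd(y) + 1e-30))
    stop("fit_regression: degenerate fit (zero residual variance)", call. = FALSE)
  h <- stats::hatvalues(fit)
  structure(list(intercept = unname(stats::coef(fit)[1L]),
                 slope = unname(stats::coef(fit)[2L]),
                 residual_se = s,
                 residuals = stats::setNames(unname(e), counts$unit_id),
                 leverages = stats::setNames(unname(h), counts$unit_id),
                 n_units = n,
                 orientation = orientation),
            class = "intol_fit")
}

#' @export
print.intol_fit <- function(x, ...) {
  cat(sprintf("Mutation-load regression (%s): intercept %.4g, slope %.4g, residual SE %.4g, %d units\n",
              x$orientation, x$intercept, x$slope, x$residual_se, x$n_units))
  invisible(x)
}

#' Studentized residuals of a mutation-load fit
#'
#' Externally studentized (deletion) residuals by default:
#' \eqn{r_i = e_i / (s_{(i)} \sqrt{1 - h_i})}, where \eqn{s_{(i)}} is the
#' residual standard error of the fit excluding unit i, computed in closed
#' form from the full-fit residual sum of squares. Internally studentized
#' residuals (\eqn{e_i / (s \sqrt{1 - h_i})}) are available as an option.
#' Units whose leverage is numerically 1 are flagged `NA` with a warning.
#'
#' @param fit an `intol_fit`.
#' @param type `"external"` (default) or `"internal"`.
#' @return named numeric vector of studentized residuals.
#' @export
studentize <- function(fit, type = c("external", "internal")) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "intol_fit"))
  e <- fit$residuals; h <- fit$leverages; n <- fit$n_units
  p <- 2L  # intercept + slope
  out <- rep(NA_real_, n); names(out) <- names(e)
  ok <- (1 - h) > 1e-10
  if (any(!ok))
    warning(sprintf("studentize: %d unit(s) with leverage ~1; residual reported as NA", sum(!ok)))
  if (type == "internal") {
    out[ok] <- e[ok] / (fit$residual_se * sqrt(1 - h[ok]))
    return(out)
  }
  if (n <= p + 1L)
    stop("studentize: externally studentized residuals need at least 4 units", call. = FALSE)
  sse <- fit$residual_se^2 * (n - p)
  s_i2 <- (sse - e[ok]^2 / (1 - h[ok])) / (n - p - 1L)
  s_i2 <- pmax(s_i2, 0)
  r <- e[ok] / (sqrt(s_i2) * sqrt(1 - h[ok]))
  r[s_i2 == 0 & e[ok] != 0] <- NA_real_
  out[ok] <- r
  out
}

#' Convert studentized residuals to intolerance percentiles
#'
#' Units are ranked ascending by studentized residual (most negative = rank 1
#' = most intolerant) under the default direction; ties receive the mean of
#' their ranks, and `percentile = 100 * rank / N` over the N finite-valued
#' units, so percentiles lie in (0, 100] and a unique minimum among >= 100
#' units falls in the first percentile.
#'
#' @param studentized named numeric vector (unit id -> studentized residual).
#' @param direction `"ascending"` (low residual = intolerant; default) or
#'   `"descending"` (for the reversed regression orientation).
#' @return data.frame with `unit_id`, `studentized`, `rank`, `percentile`.
#' @export
to_percentiles <- function(studentized, direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  if (is.null(names(studentized)))
    stop("to_percentiles: studentized residuals must be named by unit id", call. = FALSE)
  fin <- is.finite(studentized)
  if (!any(fin)) stop("to_percentiles: no finite studentized residuals", call. = FALSE)
  if (any(!fin))
    warning(sprintf("to_percentiles: dropped %d unit(s) with non-finite residual", sum(!fin)))
  x <- studentized[fin]
  key <- if (direction == "ascending") x else -x
  rk <- rank(key, ties.method = "average")
  n <- length(x)
  out <- data.frame(unit_id = names(x), studentized = unname(x),
                    rank = unname(rk), percentile = unname(100 * rk / n),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$percentile, out$unit_id), , drop = FALSE]
}

#' Score units for evolutionary intolerance
#'
#' Composition of [aggregate_counts()], [fit_regression()], [studentize()],
#' and [to_percentiles()]: the full pipeline from a variant prediction table
#' to a ranked intolerance score table. Deterministic for fixed input and
#' invariant to input row order.
#'
#' @inheritParams aggregate_counts
#' @inheritParams fit_regression
#' @param type studentization type passed to [studentize()].
#' @return data.frame of class `intol_scores` with columns `unit_id`,
#'   `n_total`, `n_damaging`, `residual`, `studentized`, `rank`, `percentile`,
#'   ordered by ascending percentile.
#' @export
score_units <- function(variants, by = c("gene", "domain"), domains = NULL,
                        orientation = c("total_on_damaging", "damaging_on_total"),
                        type = c("external", "internal")) {
  by <- match.arg(by); orientation <- match.arg(orientation)
  counts <- aggregate_counts(variants, by = by, domains = domains)
  fit <- fit_regression(counts, orientation = orientation)
  stu <- studentize(fit, type = match.arg(type))
  direction <- if (orientation == "total_on_damaging") "ascending" else "descending"
  pct <- to_percentiles(stu, direction = direction)
  out <- merge(counts, data.frame(unit_id = names(fit$residuals),
                                  residual = unname(fit$residuals),
                                  stringsAsFactors = FALSE), by = "unit_id")
  out <- merge(out, pct, by = "unit_id")
  out <- out[order(out$percentile, out$unit_id),
             c("unit_id", "n_total", "n_damaging", "residual", "studentized", "rank", "percentile")]
  rownames(out) <- NULL
  attr(out, "orientation") <- orientation
  class(out) <- c("intol_scores", "data.frame")
  out
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Damaging fraction of a unit's scored variants
#'
#' `100 * n_damaging / n_total`, with a display value rounded
#' half-away-from-zero to the nearest integer percent (e.g. 426 damaging out
#' of 720 scored variants gives 59.17, displayed as 59).
#'
#' @param n_total total scored variants (>= 1).
#' @param n_damaging damaging count (0 <= n_damaging <= n_total).
#' @return list with `percent` (real) and `display` (integer percent).
#' @export
damaging_fraction <- function(n_total, n_damaging) {
  if (any(n_total < 1)) stop("damaging_fraction: undefined for n_total = 0", call. = FALSE)
  if (any(n_damaging < 0) || any(n_damaging > n_total))
    stop("damaging_fraction: need 0 <= n_damaging <= n_total", call. = FALSE)
  pct <- 100 * n_damaging / n_total
  list(percent = pct, display = as.integer(round_half_away(pct)))
}
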