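#' Entropy-based dispersal of quadrant occupancy
#'
#' The dispersal statistic is the base-2 Shannon entropy of the occupancy
#' proportions, `-sum(p_i * log2(p_i))` with `p_i = count_i / n_total` and
#' the convention `0 * log2(0) = 0`. For four quadrants it ranges from 0
#' (all worms in one quadrant) to 2 bits (uniform spread). Worms that spread
#' freely with no salient cue reach ~2; worms stuck near the central origin
#' (locomotion defect or attraction to the origin) give ~1 because only the
#' two central quadrants are occupied; accumulation in a single quadrant
#' (an unknown gradient within the arena) drives it towards 0.
#'
#' @param counts A [quadrant_counts()] object or a non-negative numeric
#'   vector of occupancy counts (any length >= 2).
#' @return Dispersal in bits, in `[0, log2(length(counts))]`.
#' @examples
#' compute_dispersal(quadrant_counts(25, 25, 25, 25)) # 2 bits, uniform
#' compute_dispersal(quadrant_counts(0, 50, 50, 0))   # 1 bit, central
#' compute_dispersal(quadrant_counts(100, 0, 0, 0))   # 0 bits
#' @export
compute_dispersal <- function(counts) {
  x <- as.numeric(counts)
  if (length(x) < 2L || any(!is.finite(x)) || any(x < 0)) {
    stop("counts must be >= 2 finite non-negative values", call. = FALSE)
  }
  n <- sum(x)
  if (n <= 0) stop("dispersal undefined: total count is zero", call. = FALSE)
  p <- x / n
  p <- p[p > 0]
  max(-sum(p * log2(p)), 0)
}

#' Response ratio: commitment to the extreme quadrants
#'
#' The fraction of worms in the two extreme quadrants,
#' `(q1 + q4) / (q1 + q2 + q3 + q4)`. It measures how many worms committed
#' to either end of the arena, regardless of direction, and disambiguates
#' chemotaxis indices computed from few versus many responding worms.
#'
#' @param counts A [quadrant_counts()] object or a length-4 non-negative
#'   numeric vector in canonical order `q1..q4`.
#' @return A fraction in `[0, 1]`.
#' @examples
#' compute_response_ratio(quadrant_counts(1, 45, 45, 9))   # 0.1
#' compute_response_ratio(quadrant_counts(5, 15, 35, 45))  # 0.5
#' @export
compute_response_ratio <- function(counts) {
  x <- as.numeric(counts)
  check_counts(x)
  n <- sum(x)
  if (n <= 0) {
    stop("response ratio undefined: total count is zero", call. = FALSE)
  }
  (x[1] + x[4]) / n
}

#' Chemotaxis index from the extreme quadrants
#'
#' `(q4 - q1) / (q4 + q1)`: +1 means every committed worm reached the
#' odorant end (attraction), -1 the vehicle end (aversion). When no worm is
#' in either extreme quadrant the index is undefined and `NA_real_` is
#' returned rather than an error: dispersal-only arenas legitimately have
#' all worms near the origin, and downstream code treats `NA` as
#' non-interpretable.
#'
#' @inheritParams compute_response_ratio
#' @return A value in `[-1, 1]`, or `NA_real_` when `q1 + q4 == 0`.
#' @examples
#' compute_chemotaxis_index(quadrant_counts(1, 45, 45, 9))  # 0.8
#' compute_chemotaxis_index(quadrant_counts(5, 15, 35, 45)) # 0.8
#' @export
compute_chemotaxis_index <- function(counts) {
  x <- as.numeric(counts)
  check_counts(x)
  ext <- x[1] + x[4]
  if (ext == 0) return(NA_real_)
  (x[4] - x[1]) / ext
}

#' Cohen's d effect size with equally weighted variances
#'
#' `d = (mean_test - mean_control) / sqrt((sd_test^2 + sd_control^2) / 2)`,
#' using sample (n-1) standard deviations. The denominator averages the two
#' variances with equal weight regardless of group sizes (it is not the
#' pooled-by-degrees-of-freedom variant).
#'
#' @param test,control Numeric vectors of per-arena metric values, each of
#'   length >= 2.
#' @return A list of class `effect_report` with element `cohens_d` (plus the
#'   group means and sds).
#' @examples
#' # same mean difference, different spread, different effect size:
#' compute_effect_size(c(0.7, 0.8, 0.9), c(-0.1, 0.0, 0.1))$cohens_d
#' @export
compute_effect_size <- function(test, control) {
  check_group(test, "test")
  check_group(control, "control")
  mt <- mean(test); mc <- mean(control)
  st <- stats::sd(test); sc <- stats::sd(control)
  if (st == 0 && sc == 0) {
    if (mt == mc) {
      d <- 0
    } else {
      stop("effect size infinite: both groups have zero sd but differ in mean",
           call. = FALSE)
    }
  } else {
    d <- (mt - mc) / sqrt((st^2 + sc^2) / 2)
  }
  structure(list(cohens_d = d, mean_test = mt, mean_control = mc,
                 sd_test = st, sd_control = sc),
            class = "effect_report")
}

check_group <- function(x, name) {
  if (length(x) < 2L || any(!is.finite(x))) {
    stop("insufficient data: group '", name,
         "' needs >= 2 finite values", call. = FALSE)
  }
  invisible(TRUE)
}

#' Two-sample unpaired t-test
#'
#' Student's pooled-variance two-sample test by default (the classical
#' reading of "unpaired t-test"); set `var_equal = FALSE` for the Welch
#' variant. Two identical constant groups return `t = 0, p = 1` rather than
#' an error.
#'
#' @inheritParams compute_effect_size
#' @param var_equal Use the pooled-variance (Student) test; `FALSE` gives
#'   Welch.
#' @return A list of class `effect_report` with `t_statistic`,
#'   `degrees_of_freedom`, and two-sided `p_value`.
#' @export
unpaired_t_test <- function(test, control, var_equal = TRUE) {
  check_group(test, "test")
  check_group(control, "control")
  n1 <- length(test); n2 <- length(control)
  v1 <- stats::var(test); v2 <- stats::var(control)
  if (v1 == 0 && v2 == 0) {
    if (mean(test) == mean(control)) {
      res <- list(t_statistic = 0, degrees_of_freedom = n1 + n2 - 2,
                  p_value = 1)
    } else {
      stop("t statistic infinite: both groups have zero variance but differ",
           call. = FALSE)
    }
  } else if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tstat <- (mean(test) - mean(control)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    res <- list(t_statistic = tstat, degrees_of_freedom = df,
                p_value = 2 * stats::pt(-abs(tstat), df))
  } else {
    ht <- stats::t.test(test, control, var.equal = FALSE)
    res <- list(t_statistic = unname(ht$statistic),
                degrees_of_freedom = unname(ht$parameter),
                p_value = ht$p.value)
  }
  structure(res, class = "effect_report")
}

#' Full effect report: Cohen's d plus unpaired t-test
#'
#' @inheritParams unpaired_t_test
#' @return An `effect_report` list combining [compute_effect_size()] and
#'   [unpaired_t_test()] fields.
#' @export
effect_report <- function(test, control, var_equal = TRUE) {
  es <- compute_effect_size(test, control)
  tt <- unpaired_t_test(test, control, var_equal = var_equal)
  structure(c(unclass(es), unclass(tt)), class = "effect_report")
}

#' @export
print.effect_report <- function(x, ...) {
  if (!is.null(x$cohens_d)) {
    cat(sprintf("Cohen's d = %.3f\n", x$cohens_d))
  }
  if (!is.null(x$t_statistic)) {
    cat(sprintf("t = %.3f, df = %.2f, p = %.4g\n",
                x$t_statistic, x$degrees_of_freedom, x$p_value))
  }
  invisible(x)
}

#' Replicate-level summary of a metric
#'
#' Mean, sample standard deviation, median, and a t-distribution confidence
#' interval on the mean. The median is the headline per-odorant summary; the
#' t interval is appropriate for the small replicate numbers typical of the
#' assay (a handful of populations per condition).
#'
#' @param values Numeric vector of per-arena metric values (length >= 1;
#'   >= 2 for sd and the interval). `NA` values are dropped with a warning.
#' @param confidence Confidence level, default 0.95.
#' @return A list of class `group_summary` with `values`, `n_arenas`,
#'   `mean`, `sd`, `median`, `ci_low`, `ci_high`, `confidence`.
#' @export
summarize_group <- function(values, confidence = 0.95) {
  if (anyNA(values)) {
    warning("dropping ", sum(is.na(values)), " undefined value(s)")
    values <- values[!is.na(values)]
  }
  n <- length(values)
  if (n < 1L) stop("insufficient data: no values to summarize", call. = FALSE)
  stopifnot(confidence > 0, confidence < 1)
  m <- mean(values)
  if (n >= 2L) {
    s <- stats::sd(values)
    half <- stats::qt((1 + confidence) / 2, df = n - 1) * s / sqrt(n)
    ci <- c(m - half, m + half)
  } else {
    s <- NA_real_
    ci <- c(NA_real_, NA_real_)
  }
  structure(list(values = values, n_arenas = n, mean = m, sd = s,
                 median = stats::median(values),
                 ci_low = ci[1], ci_high = ci[2], confidence = confidence),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf(
    "n = %d  mean = %.3f  sd = %.3f  median = %.3f  %d%% CI [%.3f, %.3f]\n",
    x$n_arenas, x$mean, x$sd, x$median, round(100 * x$confidence),
    x$ci_low, x$ci_high))
  invisible(x)
}

#' Per-arena metric table
#'
#' Canonicalizes every arena and computes the three per-arena metrics.
#'
#' @param arenas An [arena_tbl()] or [experiment_set()].
#' @return A data frame with columns `plate_id`, `assay_type`, `orientation`,
#'   `odorant`, `cohort`, `n_total`, `dispersal`, `response_ratio`,
#'   `chemotaxis_index` (`NA` when undefined).
#' @export
arena_metrics <- function(arenas) {
  if (inherits(arenas, "experiment_set")) arenas <- arenas$arenas
  stopifnot(inherits(arenas, "arena_tbl"))
  qc <- canonical_counts(arenas)
  data.frame(
    plate_id = arenas$plate_id,
    assay_type = arenas$assay_type,
    orientation = arenas$orientation,
    odorant = arenas$odorant,
    cohort = arenas$cohort,
    n_total = as.integer(rowSums(qc)),
    dispersal = apply(qc, 1, compute_dispersal),
    response_ratio = apply(qc, 1, compute_response_ratio),
    chemotaxis_index = apply(qc, 1, compute_chemotaxis_index),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Write the per-arena metric table as CSV
#'
#' Undefined chemotaxis indices are written as empty cells.
#'
#' @param metrics Output of [arena_metrics()].
#' @param path Output path.
#' @export
write_metrics_table <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Opposing-orientation consistency check
#'
#' A gradient in the laboratory frame (temperature, light, a stray odour)
#' pushes worms in the same physical direction in both arena sets, which
#' after canonicalization pulls the two orientations' chemotaxis indices
#' apart. This check groups canonical indices by physical orientation and
#' runs an unpaired t-test of orientation A versus B; a significant
#' difference flags an external gradient and explains inflated variance and
#' reduced overall effect size.
#'
#' @param exp An [experiment_set()] or [arena_tbl()] with >= 2 chemotaxis
#'   arenas in each orientation.
#' @param alpha Flagging level for the t-test (default 0.05).
#' @param var_equal Passed to [unpaired_t_test()].
#' @return A list of class `orientation_check`: per-orientation summaries,
#'   `difference` (mean A - mean B), `t_statistic`, `p_value`, `flagged`.
#' @export
orientation_consistency <- function(exp, alpha = 0.05, var_equal = TRUE) {
  met <- arena_metrics(exp)
  met <- met[met$assay_type == "chemotaxis", , drop = FALSE]
  ci_a <- met$chemotaxis_index[met$orientation == "A"]
  ci_b <- met$chemotaxis_index[met$orientation == "B"]
  ci_a <- ci_a[!is.na(ci_a)]; ci_b <- ci_b[!is.na(ci_b)]
  if (length(ci_a) < 2L || length(ci_b) < 2L) {
    stop("insufficient data: need >= 2 chemotaxis arenas with a defined ",
         "index in each orientation", call. = FALSE)
  }
  if (stats::var(ci_a) == 0 && stats::var(ci_b) == 0 &&
      mean(ci_a) != mean(ci_b)) {
    # saturated but unambiguous: every arena in one orientation agrees and
    # the two orientations disagree, a definitive orientation effect
    tt <- list(t_statistic = Inf,
               degrees_of_freedom = length(ci_a) + length(ci_b) - 2,
               p_value = 0)
  } else {
    tt <- unpaired_t_test(ci_a, ci_b, var_equal = var_equal)
  }
  structure(list(
    mean_A = mean(ci_a), mean_B = mean(ci_b),
    n_A = length(ci_a), n_B = length(ci_b),
    difference = mean(ci_a) - mean(ci_b),
    t_statistic = tt$t_statistic,
    degrees_of_freedom = tt$degrees_of_freedom,
    p_value = tt$p_value,
    alpha = alpha,
    flagged = tt$p_value < alpha),
    class = "orientation_check")
}

#' @export
print.orientation_check <- function(x, ...) {
  cat(sprintf(
    "orientation A: mean CI %.3f (n=%d); B: %.3f (n=%d); diff %.3f\n",
    x$mean_A, x$n_A, x$mean_B, x$n_B, x$difference))
  cat(sprintf("t = %.3f, p = %.4g -> %s\n", x$t_statistic, x$p_value,
              if (x$flagged) "FLAG: possible laboratory-frame gradient"
              else "no orientation effect detected"))
  invisible(x)
}
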