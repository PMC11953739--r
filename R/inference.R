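#' Thresholds for the decision rubric
#'
#' The rubric labels each metric "high" or "low"; the cut-offs are
#' conventions to be set by the researcher according to effect size and risk
#' tolerance, not measured constants. Defaults are chosen so the canonical
#' regimes classify sensibly: dispersal ~2 controls are high at 1.8 bits;
#' worked response ratios of 0.1 and 0.5 fall low and high around 0.4; and
#' clear indices (|CI| 0.8 and up) are high at 0.5.
#'
#' @param dispersal_high_min Bits; dispersal >= this is "high". Default 1.8.
#' @param response_ratio_high_min Fraction; default 0.4.
#' @param ci_high_min_abs Absolute chemotaxis index; default 0.5.
#' @param min_worms Strict minimum total worms per plate; default 101
#'   (the more-than-100 rule).
#' @return A list of class `chemo_thresholds`.
#' @export
chemo_thresholds <- function(dispersal_high_min = 1.8,
                             response_ratio_high_min = 0.4,
                             ci_high_min_abs = 0.5,
                             min_worms = 101L) {
  stopifnot(dispersal_high_min >= 0, dispersal_high_min <= 2,
            response_ratio_high_min >= 0, response_ratio_high_min <= 1,
            ci_high_min_abs >= 0, ci_high_min_abs <= 1,
            min_worms >= 1)
  structure(list(dispersal_high_min = dispersal_high_min,
                 response_ratio_high_min = response_ratio_high_min,
                 ci_high_min_abs = ci_high_min_abs,
                 min_worms = as.integer(min_worms)),
            class = "chemo_thresholds")
}

#' Read thresholds from a plain-text key:value file
#'
#' Lines of the form `key: value` (or `key = value`); `#` starts a comment.
#' Unknown keys are an error.
#'
#' @param path Path to the config file.
#' @return A [chemo_thresholds()] object.
#' @export
read_thresholds <- function(path) {
  kv <- read_kv_file(path)
  known <- c("dispersal_high_min", "response_ratio_high_min",
             "ci_high_min_abs", "min_worms")
  bad <- setdiff(names(kv), known)
  if (length(bad)) {
    stop("unknown threshold key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(chemo_thresholds, lapply(kv, as.numeric))
}

#' Classify metric levels for the decision rubric
#'
#' Each metric is labelled `high` iff it is at or above its threshold (the
#' absolute value for the chemotaxis index). An undefined chemotaxis index
#' classifies as `low` with sign `none`.
#'
#' @param dispersal,response_ratio,chemotaxis_index Per-experiment metric
#'   values (typically replicate medians). `chemotaxis_index` may be `NA`.
#' @param thresholds A [chemo_thresholds()] object.
#' @return A list with `dispersal_level`, `rr_level`, `ci_level` (each
#'   `"high"` or `"low"`) and `ci_sign` (`"positive"`, `"negative"`, or
#'   `"none"`).
#' @export
classify_levels <- function(dispersal, response_ratio, chemotaxis_index,
                            thresholds = chemo_thresholds()) {
  hl <- function(x, thr) if (x >= thr) "high" else "low"
  ci_level <- "low"; ci_sign <- "none"
  if (!is.na(chemotaxis_index)) {
    ci_level <- hl(abs(chemotaxis_index), thresholds$ci_high_min_abs)
    ci_sign <- if (chemotaxis_index > 0) "positive"
               else if (chemotaxis_index < 0) "negative" else "none"
  }
  list(dispersal_level = hl(dispersal, thresholds$dispersal_high_min),
       rr_level = hl(response_ratio, thresholds$response_ratio_high_min),
       ci_level = ci_level,
       ci_sign = ci_sign)
}

#' Classify the dispersal regime of a control arena
#'
#' Nearest-anchor assignment to the three canonical regimes, with boundaries
#' at 0.5 and 1.5 bits: `uniform~2` (free dispersal), `central~1` (worms
#' stuck in the two central quadrants: locomotion defect and/or attraction
#' to the origin), `single_quadrant~0` (accumulation in one quadrant:
#' response to an unknown gradient within the arena).
#'
#' @param dispersal Dispersal in bits.
#' @return One of `"uniform~2"`, `"central~1"`, `"single_quadrant~0"`.
#' @export
dispersal_regime <- function(dispersal) {
  stopifnot(is.finite(dispersal), dispersal >= 0)
  if (dispersal >= 1.5) "uniform~2"
  else if (dispersal >= 0.5) "central~1"
  else "single_quadrant~0"
}

#' Check the interpretability preconditions
#'
#' A chemotaxis verdict is allowed only if every plate carried enough worms
#' (strictly more than `min_worms - 1`) and the paired no-odorant dispersal
#' controls dispersed freely (dispersal at or above `dispersal_high_min`,
#' i.e. the ~2 regime). Failing controls are classified by regime: ~1 points
#' to attraction to the centre and/or defective locomotion, ~0 to a response
#' to an unknown gradient in the arena.
#'
#' @param exp An [experiment_set()] or [arena_tbl()].
#' @param metrics Optional precomputed [arena_metrics()] table.
#' @param thresholds A [chemo_thresholds()] object.
#' @return A list with `interpretable` (logical) and `reasons`
#'   (character vector of failures, empty when interpretable).
#' @export
check_preconditions <- function(exp, metrics = NULL,
                                thresholds = chemo_thresholds()) {
  if (is.null(metrics)) metrics <- arena_metrics(exp)
  disp <- metrics[metrics$assay_type == "dispersal", , drop = FALSE]
  if (nrow(disp) == 0L) {
    stop("insufficient data: no paired dispersal arena in the experiment",
         call. = FALSE)
  }
  reasons <- character(0)
  low_n <- metrics$n_total < thresholds$min_worms
  if (any(low_n)) {
    reasons <- c(reasons, sprintf(
      "arena %s: only %d worms, need > %d per plate",
      metrics$plate_id[low_n], metrics$n_total[low_n],
      thresholds$min_worms - 1L))
  }
  bad_ctrl <- disp$dispersal < thresholds$dispersal_high_min
  if (any(bad_ctrl)) {
    for (i in which(bad_ctrl)) {
      regime <- dispersal_regime(disp$dispersal[i])
      why <- switch(regime,
        "central~1" = "attraction to center and/or defective locomotion",
        "single_quadrant~0" = "response to an unknown gradient in the arena",
        "dispersal below threshold")
      reasons <- c(reasons, sprintf(
        "control arena %s: dispersal %.2f < %.2f (regime %s: %s)",
        disp$plate_id[i], disp$dispersal[i], thresholds$dispersal_high_min,
        regime, why))
    }
  }
  list(interpretable = length(reasons) == 0L, reasons = reasons)
}

# verdict templates for the 8 high/low combinations; {RESP} is resolved by
# the sign of the chemotaxis index when that index is high
RUBRIC_VERDICTS <- c(
  "high.high.high" = "{RESP} to the odorant",
  "high.high.low" = paste0(
    "no locomotion defect (high dispersal), aversion to the origin on ",
    "chemotaxis plates only and/or attraction to the vehicle ",
    "(low chemotaxis index and high response ratio)"),
  "high.low.high" = paste0(
    "no locomotion defect (high dispersal), attraction to the origin ",
    "and/or aversion to vehicle on chemotaxis plates only ",
    "(low response ratio) overcome by {RESP} to the odorant"),
  "low.high.high" = paste0(
    "locomotion defect and/or attraction to the origin on dispersal ",
    "plates only overcome (high response ratio) by {RESP} to the odorant"),
  "high.low.low" = paste0(
    "no locomotion defect (high dispersal), attraction to the origin on ",
    "chemotaxis plates only and/or aversion to the vehicle ",
    "(low chemotaxis index and low response ratio)"),
  "low.low.high" = paste0(
    "locomotion defect and/or attraction to the origin across all plates ",
    "with {RESP} to the odorant"),
  "low.high.low" = paste0(
    "locomotion defect and/or attraction to the origin on dispersal ",
    "plates overcome by aversion to origin and/or attraction to the ",
    "vehicle (low chemotaxis index but high response ratio)"),
  "low.low.low" =
    "locomotion defect and/or attraction to the origin across all plates")

#' Verdict lookup over the eight-row decision rubric
#'
#' Total, deterministic lookup over the 2x2x2 combinations of
#' (dispersal, response ratio, chemotaxis index) levels. When the index
#' level is high, its sign resolves the verdict to attraction (positive) or
#' aversion (negative); with sign `none` the unresolved alternation
#' "attraction (positive chemotaxis index) or aversion (negative chemotaxis
#' index)" is kept.
#'
#' @param dispersal_level,rr_level,ci_level `"high"` or `"low"`.
#' @param ci_sign `"positive"`, `"negative"`, or `"none"`.
#' @return The verdict string.
#' @examples
#' infer_verdict("high", "high", "high", "positive")
#' infer_verdict("low", "low", "low")
#' @export
infer_verdict <- function(dispersal_level, rr_level, ci_level,
                         ci_sign = "none") {
  lv <- c(dispersal_level, rr_level, ci_level)
  if (!all(lv %in% c("high", "low"))) {
    stop("levels must be 'high' or 'low'", call. = FALSE)
  }
  if (!ci_sign %in% c("positive", "negative", "none")) {
    stop("ci_sign must be 'positive', 'negative', or 'none'", call. = FALSE)
  }
  verdict <- RUBRIC_VERDICTS[[paste(lv, collapse = ".")]]
  resp <- switch(ci_sign,
    positive = "attraction",
    negative = "aversion",
    none = paste0("attraction (positive chemotaxis index) or aversion ",
                  "(negative chemotaxis index)"))
  gsub("{RESP}", resp, verdict, fixed = TRUE)
}

#' Run the full decision chart on an experiment
#'
#' Composes canonicalization, per-arena metrics, the interpretability
#' preconditions, level classification on replicate medians, and the
#' eight-row verdict lookup. Non-interpretable experiments get no verdict;
#' that is a normal analytical outcome, not an error. Level classification
#' uses replicate medians (the headline summary): response ratio and
#' chemotaxis index from the chemotaxis arenas, dispersal from the
#' no-odorant control arenas (free dispersal is only observable without an
#' odorant). Per-arena verdicts are also emitted for diagnostics.
#'
#' @param exp An [experiment_set()] or [arena_tbl()].
#' @param thresholds A [chemo_thresholds()] object.
#' @return A list of class `inference_result`: `interpretable`,
#'   `precondition_failures`, the median metrics, levels and `ci_sign`,
#'   `dispersal_regime` of the median control dispersal, `verdict` (`NULL`
#'   when not interpretable), and a `per_arena` diagnostic data frame.
#' @export
run_decision_chart <- function(exp, thresholds = chemo_thresholds()) {
  metrics <- arena_metrics(exp)
  pre <- check_preconditions(exp, metrics, thresholds)
  chem <- metrics[metrics$assay_type == "chemotaxis", , drop = FALSE]
  disp <- metrics[metrics$assay_type == "dispersal", , drop = FALSE]
  med_control_dispersal <- stats::median(disp$dispersal)
  res <- list(
    interpretable = pre$interpretable,
    precondition_failures = pre$reasons,
    control_dispersal_median = med_control_dispersal,
    control_regime = dispersal_regime(med_control_dispersal),
    verdict = NULL)
  if (nrow(chem) == 0L) {
    res$interpretable <- FALSE
    res$precondition_failures <- c(res$precondition_failures,
      "no chemotaxis arenas: metrics computed, no verdict possible")
    class(res) <- "inference_result"
    return(res)
  }
  ci <- chem$chemotaxis_index
  # The rubric's "dispersal" is the control measurement: free dispersal is only
  # observable on plates without an odorant (a responding population piles
  # into one quadrant, which is signal, not a locomotion problem)
  med <- list(
    dispersal = med_control_dispersal,
    response_ratio = stats::median(chem$response_ratio),
    chemotaxis_index = if (all(is.na(ci))) NA_real_
                       else stats::median(ci, na.rm = TRUE))
  lv <- classify_levels(med$dispersal, med$response_ratio,
                        med$chemotaxis_index, thresholds)
  res$medians <- med
  res <- c(res, lv)
  res$per_arena <- data.frame(
    plate_id = chem$plate_id,
    verdict = vapply(seq_len(nrow(chem)), function(i) {
      l <- classify_levels(med_control_dispersal, chem$response_ratio[i],
                           chem$chemotaxis_index[i], thresholds)
      infer_verdict(l$dispersal_level, l$rr_level, l$ci_level, l$ci_sign)
    }, character(1)),
    stringsAsFactors = FALSE)
  if (res$interpretable) {
    res$verdict <- infer_verdict(lv$dispersal_level, lv$rr_level,
                                lv$ci_level, lv$ci_sign)
  }
  class(res) <- "inference_result"
  res
}

#' @export
print.inference_result <- function(x, ...) {
  if (x$interpretable) {
    cat("INTERPRETABLE\n")
    cat(sprintf("median dispersal %.2f | response ratio %.2f | index %s\n",
                x$medians$dispersal, x$medians$response_ratio,
                if (is.na(x$medians$chemotaxis_index)) "undefined"
                else sprintf("%.2f", x$medians$chemotaxis_index)))
    cat("verdict:", x$verdict, "\n")
  } else {
    cat("NOT INTERPRETABLE\n")
    for (r in x$precondition_failures) cat(" -", r, "\n")
  }
  invisible(x)
}
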