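#' Quadrant counts in canonical orientation
#'
#' Constructs a validated set of four worm counts in the canonical frame of a
#' rectangular four-quadrant arena: `q1` is the extreme quadrant at the
#' vehicle end, `q4` the extreme quadrant at the odorant end, and `q2`/`q3`
#' flank the central origin where worms are released.
#'
#' @param q1,q2,q3,q4 Non-negative integer worm counts.
#' @return An object of class `quadrant_counts`: a named integer vector
#'   `c(q1, q2, q3, q4)`. The total count is `sum()` of the vector.
#' @examples
#' qc <- quadrant_counts(5, 15, 35, 45)
#' sum(qc)
#' @export
quadrant_counts <- function(q1, q2, q3, q4) {
  q <- c(q1 = q1, q2 = q2, q3 = q3, q4 = q4)
  check_counts(q)
  structure(as.integer(round(q)), names = names(q), class = "quadrant_counts")
}

check_counts <- function(q, where = "counts") {
  if (length(q) != 4L || any(!is.finite(q))) {
    stop(where, " must be four finite values", call. = FALSE)
  }
  if (any(q < 0)) {
    stop(where, " must be non-negative (got ",
         paste(q, collapse = ","), ")", call. = FALSE)
  }
  if (any(abs(q - round(q)) > 1e-8)) {
    stop(where, " must be integers (got ",
         paste(q, collapse = ","), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.quadrant_counts <- function(x, ...) {
  cat("quadrant counts (canonical, vehicle end = q1, odorant end = q4):\n")
  print(unclass(x))
  cat("n_total:", sum(x), "\n")
  invisible(x)
}

# required columns of the on-disk counts schema, in order
ARENA_COLUMNS <- c("plate_id", "assay_type", "orientation", "odorant",
                   "vehicle", "cohort",
                   "c_left", "c_midleft", "c_midright", "c_right")
COUNT_COLUMNS <- c("c_left", "c_midleft", "c_midright", "c_right")

#' Construct a table of arena records
#'
#' An arena table holds one row per arena: identifying metadata plus the four
#' physical quadrant counts listed left-to-right in the laboratory frame.
#' Physical counts are orientation-agnostic; use [canonicalize()] to map them
#' into the canonical (vehicle-to-odorant) frame.
#'
#' @param df A data frame with the columns
#'   `plate_id, assay_type, orientation, odorant, vehicle, cohort,
#'   c_left, c_midleft, c_midright, c_right`. Extra columns are preserved.
#' @return A data frame of class `arena_tbl`.
#' @export
arena_tbl <- function(df) {
  missing <- setdiff(ARENA_COLUMNS, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$assay_type <- as.character(df$assay_type)
  df$orientation <- as.character(df$orientation)
  for (col in c("plate_id", "odorant", "vehicle", "cohort")) {
    df[[col]] <- as.character(df[[col]])
  }
  problems <- character(0)
  bad <- !df$assay_type %in% c("dispersal", "chemotaxis")
  if (any(bad)) {
    problems <- c(problems, paste0("row ", which(bad),
      ": assay_type must be 'dispersal' or 'chemotaxis'"))
  }
  bad <- !df$orientation %in% c("A", "B")
  if (any(bad)) {
    problems <- c(problems, paste0("row ", which(bad),
      ": orientation must be 'A' or 'B'"))
  }
  for (col in COUNT_COLUMNS) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- is.na(v) | v < 0 | abs(v - round(v)) > 1e-8
    if (any(bad)) {
      problems <- c(problems, paste0("row ", which(bad), ": ", col,
        " must be a non-negative integer (got '", df[[col]][bad], "')"))
    } else {
      df[[col]] <- as.integer(round(v))
    }
  }
  disp <- df$assay_type == "dispersal" & !is.na(df$odorant) &
    df$odorant != "none"
  if (any(disp)) {
    problems <- c(problems, paste0("row ", which(disp),
      ": dispersal records must have odorant = 'none'"))
  }
  if (length(problems)) {
    stop("invalid arena record(s):\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  class(df) <- c("arena_tbl", "data.frame")
  df
}

#' Read a quadrant-count table from CSV
#'
#' Parses a UTF-8 CSV of per-arena quadrant counts. The header must contain
#' `plate_id, assay_type, orientation, odorant, vehicle, cohort, c_left,
#' c_midleft, c_midright, c_right`; unknown columns are carried through as
#' opaque metadata. A file with any malformed row fails as a whole with an
#' error listing every offending row; there is no partial load.
#'
#' @param path Path to a CSV file.
#' @return An [arena_tbl()] with one row per arena.
#' @export
read_counts_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  arena_tbl(df)
}

#' Write a quadrant-count table to CSV
#'
#' Inverse of [read_counts_table()]: writes the arena table in the same CSV
#' schema so valid files round-trip field-for-field.
#'
#' @param arenas An [arena_tbl()].
#' @param path Output path.
#' @export
write_counts_table <- function(arenas, path) {
  stopifnot(inherits(arenas, "arena_tbl"))
  extra <- setdiff(names(arenas), ARENA_COLUMNS)
  utils::write.csv(arenas[, c(ARENA_COLUMNS, extra), drop = FALSE],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Map physical counts into the canonical frame
#'
#' Arenas are run in two opposing physical orientations so that a true
#' odorant response moves worms in opposite laboratory directions.
#' Orientation `A` has the odorant end on the physical right, so the
#' left-to-right counts already read `q1..q4`; orientation `B` has the
#' odorant end on the left, so the counts are reversed. Dispersal arenas
#' (no odorant) adopt the orientation-A mapping by convention; their metrics
#' are invariant under reversal anyway.
#'
#' @param record A single arena: one row of an [arena_tbl()], or a list with
#'   elements `orientation` and the four physical counts.
#' @return A [quadrant_counts()] object in canonical orientation.
#' @export
canonicalize <- function(record) {
  counts <- as.numeric(unlist(record[COUNT_COLUMNS], use.names = FALSE))
  check_counts(counts, "physical_counts")
  orientation <- as.character(record[["orientation"]])
  assay_type <- as.character(record[["assay_type"]] %||% "chemotaxis")
  if (identical(assay_type, "dispersal")) orientation <- "A"
  if (!orientation %in% c("A", "B")) {
    stop("orientation must be 'A' or 'B'", call. = FALSE)
  }
  if (orientation == "B") counts <- rev(counts)
  quadrant_counts(counts[1], counts[2], counts[3], counts[4])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical count matrix for a whole arena table
#'
#' @param arenas An [arena_tbl()].
#' @return An integer matrix with one row per arena and columns `q1..q4`.
#' @export
canonical_counts <- function(arenas) {
  stopifnot(inherits(arenas, "arena_tbl"))
  out <- t(vapply(seq_len(nrow(arenas)), function(i) {
    as.integer(canonicalize(arenas[i, , drop = FALSE]))
  }, integer(4)))
  colnames(out) <- c("q1", "q2", "q3", "q4")
  rownames(out) <- arenas$plate_id
  out
}

#' Assemble an experiment set for one odorant
#'
#' An experiment set pairs the chemotaxis arenas for one odorant (in both
#' physical orientations) with the co-run no-odorant dispersal arenas that
#' control for locomotion defects and within-arena gradients.
#'
#' @param arenas An [arena_tbl()] containing dispersal and chemotaxis rows.
#' @param odorant Odorant to select; defaults to the single odorant present
#'   among chemotaxis arenas (an error if there are several).
#' @return An object of class `experiment_set`: a list with elements
#'   `odorant` and `arenas` (the subset arena table).
#' @export
experiment_set <- function(arenas, odorant = NULL) {
  stopifnot(inherits(arenas, "arena_tbl"))
  chem <- arenas[arenas$assay_type == "chemotaxis", , drop = FALSE]
  if (is.null(odorant)) {
    odos <- unique(chem$odorant)
    if (length(odos) > 1L) {
      stop("several odorants present (", paste(odos, collapse = ", "),
           "); pick one", call. = FALSE)
    }
    odorant <- if (length(odos)) odos else NA_character_
  }
  keep <- arenas$assay_type == "dispersal" |
    (arenas$assay_type == "chemotaxis" & arenas$odorant == odorant)
  sub <- arenas[keep, , drop = FALSE]
  class(sub) <- c("arena_tbl", "data.frame")
  structure(list(odorant = odorant, arenas = sub), class = "experiment_set")
}

#' @export
print.experiment_set <- function(x, ...) {
  tab <- table(x$arenas$assay_type, x$arenas$orientation)
  cat("experiment set, odorant:", x$odorant, "\n")
  print(tab)
  invisible(x)
}

#' Validate an experiment set against the assay's design rules
#'
#' Checks the rules that make a quadrant assay interpretable at the design
#' level: more than `min_worms - 1` worms on every plate, chemotaxis arenas
#' present in both opposing orientations, and every chemotaxis arena paired
#' with at least one same-cohort dispersal arena. Violations are returned as
#' data, not raised as errors.
#'
#' @param exp An [experiment_set()] (or an [arena_tbl()]).
#' @param min_worms Minimum worms per plate, strict (default 101, i.e. the
#'   more-than-100 rule).
#' @return A data frame with columns `plate_id`, `rule`, `detail`; zero rows
#'   when the experiment is clean.
#' @export
validate_experiment <- function(exp, min_worms = 101L) {
  arenas <- if (inherits(exp, "experiment_set")) exp$arenas else exp
  stopifnot(inherits(arenas, "arena_tbl"))
  v <- list()
  totals <- rowSums(as.matrix(arenas[, COUNT_COLUMNS]))
  low <- totals < min_worms
  if (any(low)) {
    v[[length(v) + 1L]] <- data.frame(
      plate_id = arenas$plate_id[low],
      rule = "min_worms",
      detail = sprintf("n_total = %d, need > %d worms per plate",
                       as.integer(totals[low]), min_worms - 1L),
      stringsAsFactors = FALSE)
  }
  chem <- arenas[arenas$assay_type == "chemotaxis", , drop = FALSE]
  if (nrow(chem) > 0L) {
    missing_or <- setdiff(c("A", "B"), unique(chem$orientation))
    if (length(missing_or)) {
      v[[length(v) + 1L]] <- data.frame(
        plate_id = "(experiment)",
        rule = "opposing_orientations",
        detail = paste0("no chemotaxis arena in orientation ",
                        paste(missing_or, collapse = " or "),
                        "; opposing sets are required to control for",
                        " laboratory-frame gradients"),
        stringsAsFactors = FALSE)
    }
    disp_cohorts <- unique(arenas$cohort[arenas$assay_type == "dispersal"])
    unpaired <- !chem$cohort %in% disp_cohorts
    if (any(unpaired)) {
      v[[length(v) + 1L]] <- data.frame(
        plate_id = chem$plate_id[unpaired],
        rule = "dispersal_pair",
        detail = sprintf("no dispersal arena in cohort '%s'",
                         chem$cohort[unpaired]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(v)) {
    do.call(rbind, v)
  } else {
    data.frame(plate_id = character(0), rule = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  }
}

#' Export validation violations as JSON
#'
#' @param violations Output of [validate_experiment()].
#' @param path Output path for the JSON array.
#' @export
violations_json <- function(violations, path) {
  jsonlite::write_json(violations, path, dataframe = "rows",
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
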