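# in-code fixtures and independent oracles shared across test files

# the two worked count configurations (canonical q1..q4) that both give a
# chemotaxis index of 0.8 from opposite response-ratio regimes
worked_few <- c(1, 45, 45, 9)
worked_many <- c(5, 15, 35, 45)

# brute-force entropy evaluator, independent of compute_dispersal
entropy_oracle <- function(counts) {
  n <- sum(counts)
  h <- 0
  for (c_i in counts) {
    if (c_i > 0) {
      p <- c_i / n
      h <- h - p * log(p) / log(2)
    }
  }
  h
}

# one arena row in the on-disk schema
arena_row <- function(plate_id, assay_type, orientation, counts,
                      odorant = if (assay_type == "dispersal") "none"
                                else "butanone 10%",
                      vehicle = if (odorant == "none") "none" else "ethanol",
                      cohort = "d1") {
  data.frame(plate_id = plate_id, assay_type = assay_type,
             orientation = orientation, odorant = odorant, vehicle = vehicle,
             cohort = cohort, c_left = counts[1], c_midleft = counts[2],
             c_midright = counts[3], c_right = counts[4],
             stringsAsFactors = FALSE)
}

make_arenas <- function(...) arena_tbl(do.call(rbind, list(...)))

# a clean paired experiment: uniform controls, clear attraction, both
# orientations, all plates comfortably over the worm-count rule
good_experiment <- function() {
  make_arenas(
    arena_row("D1", "dispersal", "A", c(37, 38, 37, 38)),
    arena_row("D2", "dispersal", "A", c(38, 37, 38, 37)),
    arena_row("C1", "chemotaxis", "A", c(5, 15, 35, 95)),
    arena_row("C2", "chemotaxis", "A", c(8, 12, 40, 90)),
    arena_row("C3", "chemotaxis", "B", c(95, 35, 15, 5)),
    arena_row("C4", "chemotaxis", "B", c(90, 40, 12, 8)))
}

# all weak compositions of total n into k non-negative parts
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, ncol = 1))
  out <- NULL
  for (i in 0:n) {
    sub <- compositions(n - i, k - 1L)
    out <- rbind(out, cbind(i, sub))
  }
  unname(out)
}

# short-duration config for fast structural tests (not used for the
# calibrated acceptance properties)
fast_config <- function(...) {
  simulation_config(duration = 300, ...)
}

write_temp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
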