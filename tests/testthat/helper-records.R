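# Builders for hand-tiled records and small oracles used across test files.

rec <- function(movie, hole, q_start, q_end, zmw_class = NA_character_,
                region_type = NA_character_, sequence = NULL,
                other_tags = "") {
  len <- q_end - q_start
  if (is.null(sequence)) {
    sequence <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                      collapse = "")
  }
  data.frame(qname = sprintf("%s/%d/%d_%d", movie, hole, q_start, q_end),
             movie = movie, hole = as.integer(hole),
             q_start = as.integer(q_start), q_end = as.integer(q_end),
             sequence = sequence, qualities = NA_character_,
             zmw_class = zmw_class, region_type = region_type,
             other_tags = other_tags, stringsAsFactors = FALSE)
}

recs <- function(...) {
  out <- rbind(...)
  rownames(out) <- NULL
  out
}

adapter <- function(movie, hole, q_start, q_end, zmw_class = "N") {
  rec(movie, hole, q_start, q_end, zmw_class = zmw_class, region_type = "A")
}

# Write a record pair to disk and return the cell handle.
write_cell <- function(subreads, scraps = NULL, dir = tempfile("cell")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  movie <- subreads$movie[1]
  sp <- file.path(dir, paste0(movie, ".subreads.sam"))
  write_records(subreads, sp, kind = "subreads", require_sequences = FALSE)
  cp <- NULL
  if (!is.null(scraps)) {
    cp <- file.path(dir, paste0(movie, ".scraps.sam"))
    write_records(scraps, cp, kind = "scraps", require_sequences = FALSE)
  }
  smrtcell_files(sp, cp, cell_id = movie)
}

# Brute-force N50/L50: walk the descending-sorted list accumulating until
# half the total is reached (independent of the cumsum/which implementation).
oracle_n50 <- function(lengths) {
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  total <- sum(s)
  acc <- 0
  for (i in seq_along(s)) {
    acc <- acc + s[i]
    if (acc >= total / 2) return(list(n50 = s[i], l50 = i))
  }
}

expect_records_equal <- function(actual, expected) {
  a <- actual
  b <- expected
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b, ignore_attr = TRUE)
}

expect_qc_equal <- function(actual, expected, tol = 1e-9) {
  expect_setequal(names(actual$groups), names(expected$groups))
  for (g in names(expected$groups)) {
    expect_equal(actual$groups[[g]], expected$groups[[g]], tolerance = tol)
  }
  expect_equal(actual$psr, expected$psr, tolerance = tol)
  expect_equal(actual$zor, expected$zor, tolerance = tol)
}

# Fixture specs used by both the property tests and the acceptance suite:
# sizes span 1-500 ZMWs and the parameter corners the contracts care about
# (no scraps-only ZMWs, many scraps-only ZMWs, many non-normal scraps,
# single-pass cells).
acceptance_specs <- function() {
  sizes <- c(1, 2, 3, 5, 8, 13, 21, 34, 55, 90, 140, 200, 300, 400, 500)
  specs <- lapply(seq_along(sizes), function(i) {
    fixture_spec(sizes[i], seed = 100L + i, emit_sequences = FALSE)
  })
  c(specs, list(
    fixture_spec(60, seed = 201L, p_nonnormal = 0.4, emit_sequences = FALSE),
    fixture_spec(60, seed = 202L, p_scraps_only = 0.4, emit_sequences = FALSE),
    fixture_spec(60, seed = 203L, p_scraps_only = 0, p_nonnormal = 0,
                 emit_sequences = FALSE),
    fixture_spec(60, seed = 204L, mean_passes = 1, p_scraps_only = 0,
                 emit_sequences = FALSE),
    fixture_spec(80, seed = 205L, mean_passes = 4, sigma_log = 0.9,
                 emit_sequences = FALSE)))
}
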