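movie <- "m54030_000030_000030"

test_that("longest mode keeps exactly the per-ZMW argmax", {
  subreads <- recs(rec(movie, 1, 0, 100), rec(movie, 1, 150, 400),
                   rec(movie, 2, 0, 80))
  cell <- write_cell(subreads)
  out <- run_subsample(cell, longest = TRUE, output_dir = tempfile("lg"))
  got <- read_records(out$subreads_path, "subreads")
  expect_equal(got$hole, c(1L, 2L))
  expect_equal(record_lengths(got), c(250L, 80L))
})

test_that("single-subread input is a fixed point of longest mode", {
  subreads <- recs(rec(movie, 1, 0, 100), rec(movie, 2, 0, 200))
  cell <- write_cell(subreads)
  out <- run_subsample(cell, longest = TRUE, output_dir = tempfile("fp"))
  expect_records_equal(read_records(out$subreads_path, "subreads"), subreads)
})

test_that("longest mode matches the group/argmax/tie oracle on a fixture", {
  g <- generate_cell(fixture_spec(50, seed = 81), tempfile("lor"))
  cell <- smrtcell_files(g$cell$subreads_path)
  out <- run_subsample(cell, longest = TRUE, output_dir = tempfile("lor-out"))
  got <- read_records(out$subreads_path, "subreads")
  sub <- read_records(g$cell$subreads_path, "subreads")
  picked <- do.call(rbind, lapply(split(sub, sub$hole), function(d) {
    len <- d$q_end - d$q_start
    best <- d[len == max(len), , drop = FALSE]
    best[which.min(best$q_start), , drop = FALSE]
  }))
  picked <- picked[order(picked$hole), ]
  expect_records_equal(got, picked)
  expect_equal(nrow(got), length(unique(sub$hole)))
})

test_that("longest-only with scraps warns and copies the scraps through", {
  g <- generate_cell(fixture_spec(15, seed = 82), tempfile("lsw"))
  expect_warning(
    out <- run_subsample(g$cell, longest = TRUE, output_dir = tempfile("lsw-out")),
    "not recommended")
  expect_records_equal(read_records(out$scraps_path, "scraps"),
                       read_records(g$cell$scraps_path, "scraps"))
})

test_that("random mode is an identity at fraction 1 and seed-deterministic", {
  g <- generate_cell(fixture_spec(20, seed = 83), tempfile("rnd"))
  out <- run_subsample(g$cell, random_clrs = TRUE, fraction = 1, seed = 5,
                       output_dir = tempfile("r1"))
  expect_records_equal(read_records(out$subreads_path, "subreads"),
                       read_records(g$cell$subreads_path, "subreads"))
  expect_records_equal(read_records(out$scraps_path, "scraps"),
                       read_records(g$cell$scraps_path, "scraps"))

  a <- run_subsample(g$cell, random_clrs = TRUE, fraction = 0.4, seed = 9,
                     output_dir = tempfile("ra"))
  b <- run_subsample(g$cell, random_clrs = TRUE, fraction = 0.4, seed = 9,
                     output_dir = tempfile("rb"))
  expect_identical(readLines(a$subreads_path), readLines(b$subreads_path))
  expect_identical(readLines(a$scraps_path), readLines(b$scraps_path))
  expect_identical(a$selected_holes, b$selected_holes)
})

test_that("random mode selects floor(fraction * N) ZMWs atomically", {
  g <- generate_cell(fixture_spec(10, seed = 84, p_scraps_only = 0.2),
                     tempfile("atom"))
  sub_in <- read_records(g$cell$subreads_path, "subreads")
  scr_in <- read_records(g$cell$scraps_path, "scraps")
  out <- run_subsample(g$cell, random_clrs = TRUE, fraction = 0.5, seed = 17,
                       output_dir = tempfile("atom-out"))
  expect_length(out$selected_holes, 5L)
  sub_out <- read_records(out$subreads_path, "subreads")
  scr_out <- read_records(out$scraps_path, "scraps")
  # ZMW-atomic: output holds every record of each selected hole and nothing else
  expect_records_equal(sub_out,
                       sub_in[sub_in$hole %in% out$selected_holes, ])
  expect_records_equal(scr_out,
                       scr_in[scr_in$hole %in% out$selected_holes, ])
  # sub-multiset of the input
  expect_true(all(sub_out$qname %in% sub_in$qname))
  expect_true(all(scr_out$qname %in% scr_in$qname))
})

test_that("combined mode selects ZMWs first, then the longest subread each", {
  g <- generate_cell(fixture_spec(12, seed = 85), tempfile("comb"))
  out <- run_subsample(g$cell, longest = TRUE, random_clrs = TRUE,
                       fraction = 0.5, seed = 3,
                       output_dir = tempfile("comb-out"))
  got <- read_records(out$subreads_path, "subreads")
  sub_in <- read_records(g$cell$subreads_path, "subreads")
  sel <- out$selected_holes
  expect_true(all(got$hole %in% sel))
  expect_equal(got$hole, sort(intersect(sel, unique(sub_in$hole))))
  # scraps of selected ZMWs pass through unchanged
  scr_in <- read_records(g$cell$scraps_path, "scraps")
  expect_records_equal(read_records(out$scraps_path, "scraps"),
                       scr_in[scr_in$hole %in% sel, ])
})

test_that("an exact ZMW count can be requested instead of a fraction", {
  g <- generate_cell(fixture_spec(9, seed = 86), tempfile("nz"))
  out <- run_subsample(g$cell, random_clrs = TRUE, n_zmws = 4L, seed = 2,
                       output_dir = tempfile("nz-out"))
  expect_length(out$selected_holes, 4L)
})

test_that("configuration errors are rejected up front", {
  g <- generate_cell(fixture_spec(3, seed = 87), tempfile("cfg"))
  expect_error(run_subsample(g$cell, output_dir = tempfile()), "at least one")
  expect_error(run_subsample(g$cell, random_clrs = TRUE, fraction = 1.2,
                             seed = 1, output_dir = tempfile()),
               "fraction")
  expect_error(run_subsample(g$cell, random_clrs = TRUE, fraction = 0.5,
                             output_dir = tempfile()),
               "seed")
})
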