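movie <- "m54040_000040_000040"

# one ZMW: adapter [0,45), subread [45,8045), adapter [8045,8090),
# low-quality scrap [8090,9090) -> CLR length 9090 counting all scraps
tiled_cell <- function(lq_class = "N") {
  subreads <- recs(rec(movie, 1, 45, 8045))
  scraps <- recs(adapter(movie, 1, 0, 45), adapter(movie, 1, 8045, 8090),
                 rec(movie, 1, 8090, 9090, zmw_class = lq_class,
                     region_type = "L"))
  write_cell(subreads, scraps)
}

read_pair <- function(out) {
  list(sub = read_records(out$subreads_path, "subreads"),
       scr = read_records(out$scraps_path, "scraps"))
}

test_that("minimum CLR length is inclusive and counts all provided scraps", {
  subreads <- recs(rec(movie, 1, 0, 100), rec(movie, 1, 120, 250))
  scraps <- recs(adapter(movie, 1, 100, 120))
  b <- group_by_zmw(subreads, scraps)
  expect_equal(filter_min_clr_length(b, 250), 1L)   # kept at the boundary
  expect_equal(filter_min_clr_length(b, 251), integer())
  expect_equal(filter_min_clr_length(b, 0), 1L)
  expect_error(filter_min_clr_length(b, -1), "non-negative")

  # scraps-only CLRs are still CLRs and can pass the length criterion
  lonely <- group_by_zmw(subreads[0, ], recs(rec(movie, 7, 0, 400, "N", "L")))
  expect_equal(filter_min_clr_length(lonely, 300), 7L)
})

test_that("complete pass means a subread flanked by adapters on both sides", {
  pass <- group_by_zmw(recs(rec(movie, 1, 50, 500)),
                       recs(adapter(movie, 1, 0, 50),
                            adapter(movie, 1, 500, 550)))
  expect_equal(filter_full_pass(pass), 1L)

  no_lead <- group_by_zmw(recs(rec(movie, 2, 0, 500)),
                          recs(adapter(movie, 2, 500, 550)))
  expect_equal(filter_full_pass(no_lead), integer())

  no_subread <- group_by_zmw(recs(rec(movie, 1, 0, 10))[0, ],
                             recs(adapter(movie, 3, 0, 45)))
  expect_equal(filter_full_pass(no_subread), integer())
})

test_that("exactly the (N, A) scraps survive the annotation filter", {
  combos <- expand.grid(cls = c("N", "C", "M", "S"),
                        reg = c("A", "B", "L"), stringsAsFactors = FALSE)
  scraps <- do.call(recs, lapply(seq_len(nrow(combos)), function(i) {
    rec(movie, i, 0, 100, zmw_class = combos$cls[i],
        region_type = combos$reg[i])
  }))
  keep <- filter_normal_adapters(scraps)
  expect_equal(sum(keep), 1L)
  expect_equal(scraps$zmw_class[keep], "N")
  expect_equal(scraps$region_type[keep], "A")
})

test_that("run_filter validates its configuration and inputs", {
  cell <- tiled_cell()
  expect_error(run_filter(cell, output_dir = tempfile()), "criterion")
  bare <- smrtcell_files(cell$subreads_path)
  expect_error(run_filter(bare, min_clr_length = 1, output_dir = tempfile()),
               "scraps")
})

test_that("the length criterion restricts both outputs to surviving ZMWs", {
  g <- generate_cell(fixture_spec(40, seed = 91), tempfile("fl"))
  thr <- stats::median(g$truth$clr_length)
  out <- run_filter(g$cell, min_clr_length = thr,
                    output_dir = tempfile("fl-out"))
  got <- read_pair(out)
  keep <- g$truth$hole[g$truth$clr_length >= thr]
  expect_setequal(unique(c(got$sub$hole, got$scr$hole)), keep)
  sub_in <- read_records(g$cell$subreads_path, "subreads")
  scr_in <- read_records(g$cell$scraps_path, "scraps")
  expect_records_equal(got$sub, sub_in[sub_in$hole %in% keep, ])
  expect_records_equal(got$scr, scr_in[scr_in$hole %in% keep, ])
})

test_that("combined criteria equal the intersection of single-criterion oracles", {
  g <- generate_cell(fixture_spec(60, seed = 92, p_nonnormal = 0.3),
                     tempfile("comm"))
  sub_in <- read_records(g$cell$subreads_path, "subreads")
  scr_in <- read_records(g$cell$scraps_path, "scraps")
  b <- group_by_zmw(sub_in, scr_in)
  thr <- stats::median(g$truth$clr_length)
  len_keep <- filter_min_clr_length(b, thr)
  fp_keep <- filter_full_pass(b)
  na_keep <- filter_normal_adapters(scr_in)
  out <- run_filter(g$cell, min_clr_length = thr, full_pass = TRUE,
                    normal_adapters = TRUE, output_dir = tempfile("comm-out"))
  got <- read_pair(out)
  expect_records_equal(got$sub, sub_in[sub_in$hole %in% len_keep, ])
  # any intersection order gives the same scrap set
  for (ord in list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))) {
    keep <- rep(TRUE, nrow(scr_in))
    for (k in ord) {
      keep <- keep & switch(k, scr_in$hole %in% len_keep,
                            scr_in$hole %in% fp_keep, na_keep)
    }
    expect_records_equal(got$scr, scr_in[keep, ])
  }
  # the generator's truth agrees on both criteria
  expect_setequal(fp_keep, g$truth$hole[g$truth$full_pass])
  expect_setequal(len_keep, g$truth$hole[g$truth$clr_length >= thr])
})

test_that("filtering is idempotent and monotone in the threshold", {
  g <- generate_cell(fixture_spec(50, seed = 93), tempfile("idem"))
  for (cfg in list(list(min_clr_length = stats::median(g$truth$clr_length)),
                   list(full_pass = TRUE),
                   list(normal_adapters = TRUE))) {
    out1 <- do.call(run_filter,
                    c(list(g$cell, output_dir = tempfile("idem1")), cfg))
    cell2 <- smrtcell_files(out1$subreads_path, out1$scraps_path)
    out2 <- do.call(run_filter,
                    c(list(cell2, output_dir = tempfile("idem2")), cfg))
    expect_identical(readLines(out1$subreads_path)[-(1:2)],
                     readLines(out2$subreads_path)[-(1:2)])
    expect_identical(readLines(out1$scraps_path)[-(1:2)],
                     readLines(out2$scraps_path)[-(1:2)])
  }

  thresholds <- sort(sample(g$truth$clr_length, 3))
  prev_sub <- NULL
  for (thr in thresholds) {
    out <- run_filter(g$cell, min_clr_length = thr,
                      output_dir = tempfile("mono"))
    got <- read_pair(out)
    if (!is.null(prev_sub)) {
      expect_true(all(got$sub$qname %in% prev_sub$qname))
      expect_true(all(got$scr$qname %in% prev_scr$qname))
    }
    prev_sub <- got$sub
    prev_scr <- got$scr
  }
})

test_that("the recommended two-run ordering changes which scraps count", {
  cell <- tiled_cell(lq_class = "N")
  # single combined run: CLR length 9090 >= 9000, the ZMW survives
  one <- run_filter(cell, min_clr_length = 9000, normal_adapters = TRUE,
                    output_dir = tempfile("one"))
  expect_equal(nrow(read_pair(one)$sub), 1L)
  # two-stage: drop non-adapter scraps first, then the CLR measures only
  # 8000 + 90 = 8090 and fails the same threshold
  stage1 <- run_filter(cell, normal_adapters = TRUE,
                       output_dir = tempfile("st1"))
  stage2 <- run_filter(smrtcell_files(stage1$subreads_path,
                                      stage1$scraps_path),
                       min_clr_length = 9000, output_dir = tempfile("st2"))
  expect_equal(nrow(read_pair(stage2)$sub), 0L)
})

test_that("idempotence holds because outputs never mutate records", {
  g <- generate_cell(fixture_spec(30, seed = 94, p_nonnormal = 0.2),
                     tempfile("sub"))
  out <- run_filter(g$cell, full_pass = TRUE, normal_adapters = TRUE,
                    output_dir = tempfile("sub-out"))
  got <- read_pair(out)
  sub_in <- read_records(g$cell$subreads_path, "subreads")
  scr_in <- read_records(g$cell$scraps_path, "scraps")
  expect_records_equal(got$sub, sub_in)  # scraps criteria leave subreads alone
  expect_true(all(got$scr$qname %in% scr_in$qname))
  m <- match(got$scr$qname, scr_in$qname)
  expect_records_equal(got$scr, scr_in[m, ])
})
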