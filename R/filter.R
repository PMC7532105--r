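#' @title Read filtering
#' @description
#' The Read Filtering tool normalizes a data set with up to three composable
#' criteria: (1) minimum CLR length — a ZMW survives iff the total length of
#' its CLR, including all provided scraps, is greater than or equal to the
#' threshold; (2) at least one complete pass of the DNA molecule through the
#' polymerase — operationalized as a subread flanked by adapter scraps on
#' both sides on polymerase-read coordinates; and (3) normal scraps
#' adapters — scraps with ZMW classification `N` and region type `A`. The
#' latter two criteria act on the scraps file only; minimum CLR length
#' removes failing ZMWs from both outputs. Criteria compose as an
#' intersection and therefore commute; filtering is idempotent.
#'
#' Because minimum CLR length counts all *provided* scraps, the recommended
#' two-run workflow (full-pass + normal-adapters first, then minimum length
#' on the first run's outputs) measures CLR length after the undesirable
#' scraps are gone, and so can drop ZMWs a single combined run would keep.
#' @name read-filter
NULL

#' Minimum-CLR-length criterion
#'
#' @param bundles `zmw_bundles` built from both files without the
#'   normal-only restriction (all provided scraps count toward CLR length).
#' @param threshold minimum CLR length in bases (inclusive).
#' @return integer vector of surviving hole numbers.
#' @export
filter_min_clr_length <- function(bundles, threshold) {
  if (is.na(threshold) || threshold < 0) stop("threshold must be non-negative")
  sm <- bundles$summary
  sm$hole[sm$clr_length >= threshold]
}

#' Complete-pass criterion
#'
#' A ZMW has at least one complete pass iff some subread is adapter-flanked:
#' an adapter scrap ends exactly at the subread's `q_start` and another
#' begins exactly at its `q_end`. Scraps of passing ZMWs survive; the
#' subreads file is untouched by this criterion.
#'
#' @param bundles `zmw_bundles` including scraps.
#' @return integer vector of hole numbers with at least one complete pass.
#' @export
filter_full_pass <- function(bundles) {
  sr <- bundles$subreads
  sc <- bundles$scraps
  if (is.null(sc) || nrow(sr) == 0L) return(integer())
  ad <- sc[sc$region_type == "A", , drop = FALSE]
  if (nrow(ad) == 0L) return(integer())
  left <- paste(sr$hole, sr$q_start) %in% paste(ad$hole, ad$q_end)
  right <- paste(sr$hole, sr$q_end) %in% paste(ad$hole, ad$q_start)
  sort(unique(sr$hole[left & right]))
}

#' Normal-adapter criterion
#'
#' @param scraps scrap record data frame.
#' @return logical vector: scrap kept iff ZMW classification is `N` and
#'   region type is `A`.
#' @export
filter_normal_adapters <- function(scraps) {
  scraps$zmw_class == "N" & scraps$region_type == "A"
}

#' Run the Read Filtering tool on one SMRTcell
#'
#' Requires both the subreads and the scraps file and at least one enabled
#' criterion. The subreads output is the input restricted to ZMWs surviving
#' the minimum-CLR-length criterion (all ZMWs when unset); the scraps output
#' is additionally restricted to full-pass ZMWs and/or normal-adapter scraps
#' when those criteria are enabled. Outputs preserve input order and content
#' exactly.
#'
#' @param cell an [smrtcell_files()] object with both files.
#' @param min_clr_length minimum CLR length in bases, or `NULL` to disable.
#' @param full_pass require at least one complete pass (scraps criterion).
#' @param normal_adapters keep only normal-adapter scraps.
#' @param emit_binary write BAM outputs.
#' @param output_dir output directory.
#' @return list with `subreads_path`, `scraps_path` and the surviving
#'   `holes` of the length criterion.
#' @export
run_filter <- function(cell, min_clr_length = NULL, full_pass = FALSE,
                       normal_adapters = FALSE, emit_binary = FALSE,
                       output_dir = ".") {
  cell <- as_smrtcell(cell)
  if (is.null(cell$scraps_path)) {
    stop("the Read Filtering tool requires both scraps and subreads files")
  }
  if (is.null(min_clr_length) && !full_pass && !normal_adapters) {
    stop("no filtering criterion enabled: set min_clr_length, full_pass and/or normal_adapters")
  }
  dat <- read_cell(cell, with_scraps = TRUE)
  subreads <- dat$subreads
  scraps <- dat$scraps
  bundles <- group_by_zmw(subreads, scraps, normal_only = FALSE)
  surviving <- bundles$summary$hole
  if (!is.null(min_clr_length)) {
    surviving <- filter_min_clr_length(bundles, min_clr_length)
  }
  keep_scrap <- scraps$hole %in% surviving
  if (full_pass) {
    keep_scrap <- keep_scrap & scraps$hole %in% filter_full_pass(bundles)
  }
  if (normal_adapters) {
    keep_scrap <- keep_scrap & filter_normal_adapters(scraps)
  }
  out_subreads <- subreads[subreads$hole %in% surviving, , drop = FALSE]
  out_scraps <- scraps[keep_scrap, , drop = FALSE]
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  movie <- dat$movie %||% cell$cell_id
  paths <- subsample_output_paths(movie, output_dir, emit_binary,
                                  has_scraps = TRUE, stem = "filtered")
  write_records(out_subreads, paths$subreads, emit_binary = emit_binary,
                kind = "subreads", require_sequences = FALSE)
  write_records(out_scraps, paths$scraps, emit_binary = emit_binary,
                kind = "scraps", require_sequences = FALSE)
  invisible(list(subreads_path = paths$subreads, scraps_path = paths$scraps,
                 holes = sort(surviving)))
}
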