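#' @title Read subsampling
#' @description
#' The Read Subsampling tool reduces data size by either keeping only the
#' longest subread of each CLR (a cheap alternative to circular consensus
#' when per-read accuracy is already high) or by keeping all reads of a
#' random subset of CLRs (ZMWs) — useful for bootstrapping and for building
#' test data sets. Random selection is ZMW-atomic: a selected CLR keeps every
#' one of its subreads and, when scraps are provided, every one of its
#' scraps.
#' @name subsample
NULL

# Restore the caller's RNG state after a seeded computation.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

subsample_output_paths <- function(movie, output_dir, emit_binary, has_scraps,
                                   stem = "subsampled") {
  ext <- if (emit_binary) "bam" else "sam"
  list(subreads = file.path(output_dir, sprintf("%s.%s.subreads.%s", movie, stem, ext)),
       scraps = if (has_scraps)
         file.path(output_dir, sprintf("%s.%s.scraps.%s", movie, stem, ext)))
}

#' Select ZMWs uniformly at random
#'
#' Selects `max(1, floor(fraction * N))` holes (or exactly `n_zmws` when
#' given) without replacement from `holes`, using a seeded generator so runs
#' are reproducible. The caller's RNG state is left untouched.
#'
#' @param holes vector of candidate hole numbers.
#' @param fraction fraction of ZMWs to keep, in (0, 1].
#' @param seed integer seed.
#' @param n_zmws absolute count, overriding `fraction`.
#' @return sorted integer vector of selected holes.
#' @export
select_random_zmws <- function(holes, fraction = NULL, seed = 1L,
                               n_zmws = NULL) {
  holes <- sort(unique(holes))
  n <- length(holes)
  if (n == 0L) return(integer())
  if (is.null(n_zmws)) {
    if (is.null(fraction) || is.na(fraction) || fraction <= 0 || fraction > 1) {
      stop("fraction must be in (0, 1]")
    }
    n_zmws <- max(1L, as.integer(floor(fraction * n)))
  }
  if (n_zmws > n) stop("cannot select ", n_zmws, " ZMWs from ", n)
  sort(with_seed(seed, sample(holes, n_zmws, replace = FALSE)))
}

#' Run the Read Subsampling tool on one SMRTcell
#'
#' With `longest`, the output subreads file holds exactly one record per
#' subread-bearing ZMW — its longest subread, ties broken by smallest
#' `q_start`; a provided scraps file is copied through unchanged (with a
#' warning, since pairing scraps with longest-only subsampling is rarely
#' useful). With `random_clrs`, a seeded random subset of ZMWs is kept and
#' the outputs contain every subread (and scrap) of the selected ZMWs,
#' nothing else, in input order. The two modes compose: random selection is
#' applied first, then longest-per-ZMW. Outputs are exact sub-multisets of
#' the inputs.
#'
#' @param cell an [smrtcell_files()] object.
#' @param longest keep only the longest subread per CLR.
#' @param random_clrs keep a random subset of CLRs.
#' @param fraction fraction of ZMWs for random mode, in (0, 1].
#' @param n_zmws absolute ZMW count for random mode (overrides `fraction`).
#' @param seed integer seed for random mode.
#' @param emit_binary write BAM outputs.
#' @param output_dir output directory.
#' @return list with `subreads_path`, `scraps_path` (or `NULL`) and, for
#'   random mode, the `selected_holes`.
#' @export
run_subsample <- function(cell, longest = FALSE, random_clrs = FALSE,
                          fraction = NULL, n_zmws = NULL, seed = NULL,
                          emit_binary = FALSE, output_dir = ".") {
  cell <- as_smrtcell(cell)
  if (!longest && !random_clrs) {
    stop("at least one of longest/random_clrs must be selected")
  }
  if (random_clrs && is.null(n_zmws) && is.null(fraction)) {
    stop("random CLR selection requires a fraction (or n_zmws)")
  }
  if (random_clrs && is.null(seed)) stop("random CLR selection requires a seed")
  has_scraps <- !is.null(cell$scraps_path)
  if (longest && !random_clrs && has_scraps) {
    warning("scraps provided with longest-only subsampling: the scraps ",
            "output is an identity copy of the input (not recommended)")
  }
  dat <- read_cell(cell, with_scraps = has_scraps)
  subreads <- dat$subreads
  scraps <- dat$scraps
  selected <- NULL
  if (random_clrs) {
    all_holes <- unique(c(subreads$hole, if (has_scraps) scraps$hole))
    selected <- select_random_zmws(all_holes, fraction = fraction,
                                   seed = seed, n_zmws = n_zmws)
    subreads <- subreads[subreads$hole %in% selected, , drop = FALSE]
    if (has_scraps) scraps <- scraps[scraps$hole %in% selected, , drop = FALSE]
  }
  if (longest) {
    bundles <- group_by_zmw(subreads, scraps = NULL)
    subreads <- longest_subreads(bundles)
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  movie <- dat$movie %||% cell$cell_id
  paths <- subsample_output_paths(movie, output_dir, emit_binary, has_scraps)
  write_records(subreads, paths$subreads, emit_binary = emit_binary,
                kind = "subreads", require_sequences = FALSE)
  if (has_scraps) {
    write_records(scraps, paths$scraps, emit_binary = emit_binary,
                  kind = "scraps", require_sequences = FALSE)
  }
  invisible(list(subreads_path = paths$subreads,
                 scraps_path = paths$scraps,
                 selected_holes = selected))
}
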