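#' @title ZMW bundling and read groups
#' @description
#' A polymerase read (CLR) is the contiguous sequence one ZMW produced; its
#' subreads and scraps are non-overlapping segments on the CLR coordinate
#' system carried in the read names. Bundling records by ZMW hole number
#' reconstructs CLRs from coordinates alone; from the bundles the QC tool
#' derives up to four read groups: (1) subreads, (2) longest subreads (the
#' longest subread of each subread-bearing ZMW), (3) CLRs, and (4) subedCLRs
#' (CLRs that contain at least one subread).
#' @name read-groups
NULL

#' Group records by ZMW
#'
#' Assigns every record to the bundle of its hole number and computes per-ZMW
#' summaries (subread count, adapter count, CLR length). CLR length is the
#' sum of member segment lengths — "all provided scraps" count. Overlapping
#' segments within a ZMW have no physical meaning on the linear polymerase
#' read and are rejected as corrupt input.
#'
#' @param subreads subread record data frame.
#' @param scraps scrap record data frame or `NULL`.
#' @param normal_only drop scraps whose ZMW classification is not `N`
#'   before bundling (the QC convention: only normal scraps are analysed).
#' @return An object of class `zmw_bundles`: list with the (possibly
#'   filtered) `subreads` and `scraps` record frames and a `summary` data
#'   frame (`hole`, `subread_count`, `adapter_count`, `clr_length`), one row
#'   per ZMW, ordered by hole.
#' @export
group_by_zmw <- function(subreads, scraps = NULL, normal_only = FALSE) {
  if (!is.null(scraps) && normal_only && nrow(scraps) > 0L) {
    scraps <- scraps[scraps$zmw_class == "N", , drop = FALSE]
    rownames(scraps) <- NULL
  }
  movies <- unique(c(subreads$movie, if (!is.null(scraps)) scraps$movie))
  if (length(movies) > 1L) {
    stop("records from multiple movies: ", paste(movies, collapse = ", "))
  }
  seg_hole <- c(subreads$hole, if (!is.null(scraps)) scraps$hole else integer())
  seg_start <- c(subreads$q_start, if (!is.null(scraps)) scraps$q_start else integer())
  seg_end <- c(subreads$q_end, if (!is.null(scraps)) scraps$q_end else integer())
  if (length(seg_hole) > 0L) {
    o <- order(seg_hole, seg_start, seg_end)
    h <- seg_hole[o]; s <- seg_start[o]; e <- seg_end[o]
    same <- which(h[-1L] == h[-length(h)])
    bad <- same[s[same + 1L] < e[same]]
    if (length(bad) > 0L) {
      stop(sprintf("overlapping segments within ZMW %d: [%d,%d) and [%d,%d)",
                   h[bad[1L]], s[bad[1L]], e[bad[1L]],
                   s[bad[1L] + 1L], e[bad[1L] + 1L]))
    }
  }
  holes <- sort(unique(seg_hole))
  f <- factor(seg_hole, levels = holes)
  seg_len <- seg_end - seg_start
  rs <- rowsum(as.numeric(seg_len), f)
  clr_length <- as.integer(rs[match(as.character(holes), rownames(rs)), 1L])
  subread_count <- as.integer(table(factor(subreads$hole, levels = holes)))
  if (!is.null(scraps) && nrow(scraps) > 0L) {
    adapters <- scraps$hole[scraps$region_type == "A"]
    adapter_count <- as.integer(table(factor(adapters, levels = holes)))
  } else {
    adapter_count <- integer(length(holes))
  }
  summary <- data.frame(hole = holes, subread_count = subread_count,
                        adapter_count = adapter_count,
                        clr_length = if (length(holes)) clr_length else integer(),
                        stringsAsFactors = FALSE)
  structure(list(subreads = subreads, scraps = scraps, summary = summary),
            class = "zmw_bundles")
}

#' @export
print.zmw_bundles <- function(x, ...) {
  cat("ZMW bundles:", nrow(x$summary), "ZMWs,",
      nrow(x$subreads), "subreads,",
      if (is.null(x$scraps)) "no scraps" else paste(nrow(x$scraps), "scraps"), "\n")
  invisible(x)
}

#' Longest subread of every subread-bearing ZMW
#'
#' Ties in length are broken deterministically by smallest `q_start`.
#'
#' @param bundles a `zmw_bundles` object.
#' @return record data frame, one row per ZMW with at least one subread,
#'   ordered by hole.
#' @export
longest_subreads <- function(bundles) {
  sr <- bundles$subreads
  if (nrow(sr) == 0L) return(sr)
  len <- sr$q_end - sr$q_start
  o <- order(sr$hole, -len, sr$q_start)
  picked <- sr[o, , drop = FALSE][!duplicated(sr$hole[o]), , drop = FALSE]
  picked <- picked[order(picked$hole), , drop = FALSE]
  rownames(picked) <- NULL
  picked
}

#' Longest subread of one ZMW
#'
#' @param bundles a `zmw_bundles` object.
#' @param hole ZMW hole number.
#' @return a single-row record data frame.
#' @export
longest_subread_of <- function(bundles, hole) {
  sr <- bundles$subreads[bundles$subreads$hole == hole, , drop = FALSE]
  if (nrow(sr) == 0L) {
    stop("ZMW ", hole, " has no subreads; longest subread is undefined")
  }
  len <- sr$q_end - sr$q_start
  o <- order(-len, sr$q_start)
  out <- sr[o[1L], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the QC read groups from ZMW bundles
#'
#' With scraps and `four_groups` (the default when scraps are present) the
#' groups are subreads, longest subreads, CLRs, subedCLRs; with scraps and
#' two groups only, subreads and subedCLRs; without scraps, subreads and
#' longest subreads. The per-ZMW spectra (subreads per subedCLR; adapters
#' per CLR, scraps mode only) and the ingredients of PSR and ZOR are always
#' recorded, whichever groups are reported.
#'
#' @param bundles a `zmw_bundles` object from [group_by_zmw()].
#' @param with_scraps were scraps provided (default: whether the bundles
#'   carry any)?
#' @param four_groups report all four read groups (scraps mode only).
#' @return An object of class `read_group_set`: `groups` is a named list of
#'   integer length vectors, `spectra` a named list of per-ZMW counts, plus
#'   the PSR/ZOR ingredients (`n_subreads`, `n_zmws_with_subreads`,
#'   `subread_total_bases`, `longest_total_bases`).
#' @export
build_read_groups <- function(bundles,
                              with_scraps = !is.null(bundles$scraps),
                              four_groups = with_scraps) {
  if (four_groups && !with_scraps) {
    stop("four read groups require scraps files; without scraps the groups are subreads and longest subreads")
  }
  sm <- bundles$summary
  subread_len <- record_lengths(bundles$subreads)
  longest <- longest_subreads(bundles)
  longest_len <- record_lengths(longest)
  subed <- sm$subread_count > 0L
  groups <- if (with_scraps && four_groups) {
    list(subreads = subread_len,
         longest_subreads = longest_len,
         clrs = sm$clr_length,
         subed_clrs = sm$clr_length[subed])
  } else if (with_scraps) {
    list(subreads = subread_len,
         subed_clrs = sm$clr_length[subed])
  } else {
    list(subreads = subread_len,
         longest_subreads = longest_len)
  }
  spectra <- list(subreads_per_subed_clr = sm$subread_count[subed])
  if (with_scraps) spectra$adapters_per_clr <- sm$adapter_count
  structure(list(groups = groups, spectra = spectra,
                 with_scraps = with_scraps, four_groups = four_groups,
                 n_subreads = length(subread_len),
                 n_zmws_with_subreads = sum(subed),
                 subread_total_bases = sum(as.numeric(subread_len)),
                 longest_total_bases = sum(as.numeric(longest_len))),
            class = "read_group_set")
}

#' @export
print.read_group_set <- function(x, ...) {
  cat("Read groups:", paste(names(x$groups), collapse = ", "), "\n")
  for (g in names(x$groups)) {
    cat(sprintf("  %-16s n=%d\n", g, length(x$groups[[g]])))
  }
  invisible(x)
}
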