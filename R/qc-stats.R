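#' @title Per-group summary statistics, PSR and ZOR
#' @name qc-stats
NULL

#' Length statistics for one read group
#'
#' N50 is the length of the read at which the cumulative sum of the
#' descending-sorted lengths first reaches at least half the total; L50 is
#' that read's 1-based rank. The median of an even-sized group is the
#' midpoint average. An empty group yields a row of `NA`s, not zeros, so
#' downstream reporting can skip it.
#'
#' @param lengths non-negative integer read lengths.
#' @return one-row data frame: `n_reads`, `total_bases`, `mean_length`,
#'   `median_length`, `n50`, `l50`.
#' @examples
#' length_stats(c(5, 4, 3, 2, 1))  # N50 = 4, L50 = 2
#' @export
length_stats <- function(lengths) {
  if (length(lengths) == 0L) {
    return(data.frame(n_reads = NA_integer_, total_bases = NA_real_,
                      mean_length = NA_real_, median_length = NA_real_,
                      n50 = NA_real_, l50 = NA_integer_))
  }
  if (any(is.na(lengths)) || any(lengths < 0)) {
    stop("read lengths must be non-negative and non-missing")
  }
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  total <- sum(s)
  i <- which(cumsum(s) >= total / 2)[1L]
  data.frame(n_reads = length(s), total_bases = total,
             mean_length = mean(s), median_length = stats::median(s),
             n50 = s[i], l50 = i)
}

#' Polymerase-to-subread ratio (PSR)
#'
#' Total bases of the longest subreads per CLR divided by total subread
#' bases: a measure of library-preparation effectiveness. It is 1 when every
#' ZMW yielded a single subread (the template was read once, all of it
#' insert) and decreases as more of each CLR is redundant re-reads of the
#' same insert. `NA` when there are no subreads.
#'
#' @param group_set a `read_group_set` from [build_read_groups()].
#' @return real in (0, 1], or `NA`.
#' @export
compute_psr <- function(group_set) {
  if (group_set$n_subreads == 0L || group_set$subread_total_bases == 0) {
    return(NA_real_)
  }
  group_set$longest_total_bases / group_set$subread_total_bases
}

#' ZMW occupancy ratio (ZOR)
#'
#' The number of subedCLRs (ZMWs that produced at least one subread) divided
#' by the number of subreads: a measure of how effectively templates were
#' matched to ZMWs. Ideally every productive ZMW yields exactly one subread
#' and the ratio is 1; many passes per template drive it below 1. `NA` when
#' there are no subreads.
#'
#' @param group_set a `read_group_set` from [build_read_groups()].
#' @return real in (0, 1], or `NA`.
#' @export
compute_zor <- function(group_set) {
  if (group_set$n_subreads == 0L) return(NA_real_)
  group_set$n_zmws_with_subreads / group_set$n_subreads
}

#' Summarize one SMRTcell
#'
#' Reads the cell's files (coordinates only — every statistic is coordinate
#' arithmetic), bundles records by ZMW, builds the requested read groups and
#' computes per-group length statistics plus PSR and ZOR. Only normal scraps
#' (ZMW classification `N`) enter the QC analysis. Deterministic: two runs on
#' the same files give identical results.
#'
#' @param cell an [smrtcell_files()] object (or subreads path).
#' @param with_scraps use the scraps file; default: use it if present.
#' @param four_groups report four read groups (scraps mode only); default
#'   `with_scraps`.
#' @return An object of class `qc_summary`: `cell_id`, `movie`, `groups`
#'   (named list of [length_stats()] rows), `psr`, `zor`, plus the underlying
#'   `group_set` and per-ZMW `zmw_table` for reporting.
#' @export
summarize_cell <- function(cell, with_scraps = NULL, four_groups = NULL) {
  cell <- as_smrtcell(cell)
  if (is.null(with_scraps)) with_scraps <- !is.null(cell$scraps_path)
  if (is.null(four_groups)) four_groups <- with_scraps
  dat <- read_cell(cell, with_scraps, coordinates_only = TRUE)
  bundles <- group_by_zmw(dat$subreads, dat$scraps, normal_only = with_scraps)
  gs <- build_read_groups(bundles, with_scraps = with_scraps,
                          four_groups = four_groups)
  structure(list(cell_id = cell$cell_id,
                 movie = dat$movie %||% NA_character_,
                 groups = lapply(gs$groups, length_stats),
                 psr = compute_psr(gs),
                 zor = compute_zor(gs),
                 group_set = gs,
                 zmw_table = bundles$summary),
            class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  cat("QC summary for SMRTcell", x$cell_id, "\n")
  print(qc_summary_table(list(x)), row.names = FALSE)
  invisible(x)
}

#' Combine QC summaries into the per-cell, per-group statistics table
#'
#' One row per (SMRTcell, read group); mean and median are reported at
#' 0.1-base resolution. PSR and ZOR are cross-group ratios and appear once
#' per cell, on its subreads row. Written as tab-delimited text by
#' [run_qc()], viewable in any spreadsheet.
#'
#' @param summaries list of `qc_summary` objects.
#' @return data frame with columns `cell`, `group`, `nReads`, `totalBases`,
#'   `mean`, `median`, `N50`, `L50`, `PSR`, `ZOR`.
#' @export
qc_summary_table <- function(summaries) {
  rows <- lapply(summaries, function(s) {
    do.call(rbind, lapply(names(s$groups), function(g) {
      st <- s$groups[[g]]
      data.frame(cell = s$cell_id, group = g,
                 nReads = st$n_reads, totalBases = st$total_bases,
                 mean = round(st$mean_length, 1),
                 median = round(st$median_length, 1),
                 N50 = st$n50, L50 = st$l50,
                 PSR = if (g == "subreads") s$psr else NA_real_,
                 ZOR = if (g == "subreads") s$zor else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
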