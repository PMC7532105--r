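#' @title QC plot suites and report rendering
#' @description
#' The QC report comprises ten plot types, identified by the letters A-J:
#' barplots of (A) N50s, (B) L50s, (C) total bases and (D) read-length
#' histograms; frequency plots of (E) subreads per subedCLR and (F) adapters
#' per CLR; boxplots of (G) subread lengths and (H) subedCLR lengths (both
#' with N50s marked as blue diamonds); and (I) ZOR and (J) PSR plots.
#' Plots A, B, C, G, H, I and J present all SMRTcells together in one file;
#' D, E and F get one file per SMRTcell. Every figure writes a tab-delimited
#' sidecar of its plotted numbers, the machine-readable extension point for
#' custom plotting.
#' @name qc-report
NULL

PLOT_INFO <- list(
  A = list(slug = "n50_barplot",               per_cell = FALSE),
  B = list(slug = "l50_barplot",               per_cell = FALSE),
  C = list(slug = "total_bases_barplot",       per_cell = FALSE),
  D = list(slug = "read_length_histograms",    per_cell = TRUE),
  E = list(slug = "subreads_per_subedclr_freq", per_cell = TRUE),
  F = list(slug = "adapters_per_clr_freq",     per_cell = TRUE),
  G = list(slug = "subread_length_boxplot",    per_cell = FALSE),
  H = list(slug = "subedclr_length_boxplot",   per_cell = FALSE),
  I = list(slug = "zor_plot",                  per_cell = FALSE),
  J = list(slug = "psr_plot",                  per_cell = FALSE)
)

#' Resolve a plot-suite selection to plot codes
#'
#' With scraps files the full suite is A-J, the intermediate suite (the
#' default) is A, C, G, H, I, J and the basic suite is A, C. Without scraps
#' the full suite is A, B, C, D, G, I, J, the intermediate suite A, C, G, I,
#' J and the basic suite A, C.
#'
#' @param suite `"basic"`, `"intermediate"` or `"full"`.
#' @param with_scraps are scraps files in play?
#' @return character vector of plot codes.
#' @export
resolve_plot_set <- function(suite = c("intermediate", "basic", "full"),
                             with_scraps = FALSE) {
  suite <- match.arg(suite)
  sets <- if (isTRUE(with_scraps)) {
    list(full = LETTERS[1:10],
         intermediate = c("A", "C", "G", "H", "I", "J"),
         basic = c("A", "C"))
  } else {
    list(full = c("A", "B", "C", "D", "G", "I", "J"),
         intermediate = c("A", "C", "G", "I", "J"),
         basic = c("A", "C"))
  }
  sets[[suite]]
}

write_sidecar <- function(df, pdf_path) {
  path <- sub("\\.pdf$", ".tsv", pdf_path)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# heights: groups x cells matrix of one statistic across all cells
group_stat_matrix <- function(summaries, field) {
  groups <- unique(unlist(lapply(summaries, function(s) names(s$groups))))
  cells <- vapply(summaries, function(s) s$cell_id, character(1L))
  m <- matrix(NA_real_, nrow = length(groups), ncol = length(cells),
              dimnames = list(groups, cells))
  for (s in summaries) {
    for (g in names(s$groups)) m[g, s$cell_id] <- s$groups[[g]][[field]]
  }
  m
}

plot_grouped_bars <- function(m, main, ylab) {
  m_plot <- m
  m_plot[is.na(m_plot)] <- 0
  graphics::barplot(m_plot, beside = TRUE, legend.text = rownames(m),
                    main = main, ylab = ylab, las = 2, cex.names = 0.7,
                    col = grDevices::hcl.colors(max(nrow(m), 2L), "Set 2"))
}

render_barplot <- function(summaries, field, main, ylab, path) {
  m <- group_stat_matrix(summaries, field)
  grDevices::pdf(path, width = 8, height = 6)
  on.exit(grDevices::dev.off())
  plot_grouped_bars(m, main, ylab)
  sidecar <- data.frame(cell = rep(colnames(m), each = nrow(m)),
                        group = rep(rownames(m), times = ncol(m)),
                        value = as.vector(m), stringsAsFactors = FALSE)
  write_sidecar(sidecar, path)
}

render_histograms <- function(summary, path) {
  groups <- summary$group_set$groups
  grDevices::pdf(path, width = 8, height = 6)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(ceiling(length(groups) / 2), 2))
  sidecars <- list()
  for (g in names(groups)) {
    lens <- groups[[g]]
    if (length(lens) == 0L) next
    h <- graphics::hist(lens, breaks = "Sturges", plot = FALSE)
    graphics::plot(h, main = paste(g, "-", summary$cell_id),
                   xlab = "read length (bases)", col = "grey70")
    sidecars[[g]] <- data.frame(group = g,
                                bin_left = h$breaks[-length(h$breaks)],
                                bin_right = h$breaks[-1L],
                                count = h$counts, stringsAsFactors = FALSE)
  }
  sc <- if (length(sidecars)) do.call(rbind, sidecars) else
    data.frame(group = character(), bin_left = numeric(),
               bin_right = numeric(), count = integer())
  rownames(sc) <- NULL
  write_sidecar(sc, path)
}

render_frequency <- function(summary, spectrum, xlab, path) {
  counts <- summary$group_set$spectra[[spectrum]]
  grDevices::pdf(path, width = 7, height = 5)
  on.exit(grDevices::dev.off())
  if (length(counts) > 0L) {
    tab <- table(counts)
    graphics::barplot(tab, main = paste(xlab, "-", summary$cell_id),
                      xlab = xlab, ylab = "frequency", col = "grey60")
    sc <- data.frame(value = as.integer(names(tab)),
                     count = as.integer(tab), stringsAsFactors = FALSE)
  } else {
    graphics::plot.new()
    graphics::title(main = paste(xlab, "- no data"))
    sc <- data.frame(value = integer(), count = integer())
  }
  write_sidecar(sc, path)
}

render_boxplot <- function(summaries, group, main, path) {
  lens <- lapply(summaries, function(s) s$group_set$groups[[group]] %||% numeric())
  names(lens) <- vapply(summaries, function(s) s$cell_id, character(1L))
  n50 <- vapply(summaries, function(s) {
    st <- s$groups[[group]]
    if (is.null(st)) NA_real_ else st$n50
  }, numeric(1L))
  grDevices::pdf(path, width = 8, height = 6)
  on.exit(grDevices::dev.off())
  graphics::boxplot(lens, main = main, ylab = "length (bases)", las = 2,
                    cex.axis = 0.7, col = "grey85")
  graphics::points(seq_along(n50), n50, pch = 18, col = "blue", cex = 1.6)
  write_sidecar(data.frame(cell = names(lens), n50 = n50,
                           stringsAsFactors = FALSE), path)
}

render_ratio_plot <- function(summaries, ratio, main, path) {
  vals <- vapply(summaries, function(s) s[[ratio]] %||% NA_real_, numeric(1L))
  cells <- vapply(summaries, function(s) s$cell_id, character(1L))
  grDevices::pdf(path, width = 7, height = 5)
  on.exit(grDevices::dev.off())
  plot_vals <- vals
  plot_vals[is.na(plot_vals)] <- 0
  graphics::barplot(plot_vals, names.arg = cells, main = main,
                    ylab = toupper(ratio), ylim = c(0, 1), las = 2,
                    cex.names = 0.7, col = "steelblue")
  graphics::abline(h = 1, lty = 2)
  write_sidecar(stats::setNames(data.frame(cells, vals, stringsAsFactors = FALSE),
                                c("cell", ratio)), path)
}

#' Render the QC plot report
#'
#' Renders the resolved plot set as PDF figures in `output_dir`. Cross-cell
#' plots (A, B, C, G, H, I, J) produce one file each, named
#' `<code>_<description>.pdf`; per-cell plots (D, E, F) produce one file per
#' SMRTcell, suffixed with the movie name. Each figure gets a `.tsv` sidecar
#' holding exactly the numbers plotted. Cells are ordered lexicographically
#' by movie name.
#'
#' @param summaries list of `qc_summary` objects (at least one).
#' @param suite plot suite, see [resolve_plot_set()].
#' @param with_scraps scraps mode; default: taken from the first summary.
#' @param output_dir directory for the figures (created if needed).
#' @return character vector of the PDF paths written, invisibly.
#' @export
render_report <- function(summaries, suite = "intermediate",
                          with_scraps = NULL, output_dir = ".") {
  if (length(summaries) == 0L) stop("no QC summaries to plot")
  if (is.null(with_scraps)) with_scraps <- summaries[[1L]]$group_set$with_scraps
  codes <- resolve_plot_set(suite, with_scraps)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  ord <- order(vapply(summaries, function(s) s$movie %||% s$cell_id, character(1L)))
  summaries <- summaries[ord]
  paths <- character()
  for (code in codes) {
    info <- PLOT_INFO[[code]]
    if (!info$per_cell) {
      path <- file.path(output_dir, sprintf("%s_%s.pdf", code, info$slug))
      switch(code,
        A = render_barplot(summaries, "n50", "N50 by read group", "N50 (bases)", path),
        B = render_barplot(summaries, "l50", "L50 by read group", "L50 (reads)", path),
        C = render_barplot(summaries, "total_bases", "Total bases by read group",
                           "total bases", path),
        G = render_boxplot(summaries, "subreads", "Subread lengths", path),
        H = render_boxplot(summaries, "subed_clrs", "subedCLR lengths", path),
        I = render_ratio_plot(summaries, "zor", "ZMW occupancy ratio", path),
        J = render_ratio_plot(summaries, "psr", "Polymerase-to-subread ratio", path))
      paths <- c(paths, path)
    } else {
      for (s in summaries) {
        path <- file.path(output_dir, sprintf("%s_%s_%s.pdf", code, info$slug,
                                              s$movie %||% s$cell_id))
        switch(code,
          D = render_histograms(s, path),
          E = render_frequency(s, "subreads_per_subed_clr",
                               "subreads per subedCLR", path),
          F = render_frequency(s, "adapters_per_clr", "adapters per CLR", path))
        paths <- c(paths, path)
      }
    }
  }
  invisible(paths)
}

#' Run the Quality Control tool
#'
#' End-to-end QC across one or more SMRTcells: summarizes each cell, writes
#' the combined tab-delimited statistics table (`qc_summary.tsv`), renders
#' the requested plot suite, and writes one per-ZMW intermediate table per
#' cell (`<movie>.zmw_summary.tsv`: hole, subread count, adapter count, CLR
#' length). Intermediate tables are deleted at the end of the run unless
#' `keep_intermediates` is set. Per-cell work may be parallelized; outputs
#' are independent of `threads`.
#'
#' @param cells list of [smrtcell_files()] (or a single one).
#' @param suite plot suite (default `"intermediate"`).
#' @param with_scraps use scraps files; default: use them where present
#'   (all cells must agree).
#' @param four_groups report four read groups (scraps mode only).
#' @param output_dir output directory.
#' @param keep_intermediates retain per-ZMW intermediate tables.
#' @param make_plots render the plot suite (disable for table-only runs).
#' @param threads number of worker processes for per-cell summarization.
#' @return list with `summaries`, `table` (data frame), `table_path`,
#'   `figures` (PDF paths) and `intermediates` (paths, kept or removed).
#' @export
run_qc <- function(cells, suite = "intermediate", with_scraps = NULL,
                   four_groups = NULL, output_dir = ".",
                   keep_intermediates = FALSE, make_plots = TRUE,
                   threads = 1L) {
  if (inherits(cells, "smrtcell_files")) cells <- list(cells)
  cells <- lapply(cells, as_smrtcell)
  if (length(cells) == 0L) stop("no SMRTcells given")
  if (is.null(with_scraps)) {
    has_scraps <- vapply(cells, function(c) !is.null(c$scraps_path), logical(1L))
    if (any(has_scraps) && !all(has_scraps)) {
      stop("some cells have scraps files and some do not; pass with_scraps explicitly")
    }
    with_scraps <- all(has_scraps)
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  summarize_one <- function(cell) {
    summarize_cell(cell, with_scraps = with_scraps, four_groups = four_groups)
  }
  summaries <- if (threads > 1L) {
    parallel::mclapply(cells, summarize_one, mc.cores = threads)
  } else {
    lapply(cells, summarize_one)
  }
  ord <- order(vapply(summaries, function(s) s$movie %||% s$cell_id, character(1L)))
  summaries <- summaries[ord]
  table <- qc_summary_table(summaries)
  table_path <- file.path(output_dir, "qc_summary.tsv")
  utils::write.table(table, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  intermediates <- vapply(summaries, function(s) {
    p <- file.path(output_dir, sprintf("%s.zmw_summary.tsv",
                                       s$movie %||% s$cell_id))
    utils::write.table(s$zmw_table, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p
  }, character(1L))
  figures <- character()
  if (make_plots) {
    figures <- render_report(summaries, suite = suite,
                             with_scraps = with_scraps,
                             output_dir = output_dir)
  }
  if (!keep_intermediates) file.remove(intermediates)
  invisible(list(summaries = summaries, table = table,
                 table_path = table_path, figures = figures,
                 intermediates = intermediates,
                 intermediates_kept = keep_intermediates))
}
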