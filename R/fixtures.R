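#' @title Synthetic SMRTcell simulator
#' @description
#' Deterministic generator of paired subreads/scraps files with the tiled
#' polymerase-read structure every other tool assumes. Each simulated ZMW is
#' a CLR tiled exactly by its segments (consecutive `q_end == q_start`): an
#' optional low-quality region and barcode, then alternating adapter and
#' subread segments (k subreads, up to k+1 adapters; the leading/trailing
#' adapter may be missing, emulating a polymerase that starts or stops
#' mid-pass). A fraction of ZMWs are scraps-only (no subread was recovered),
#' and each scrap may carry a non-normal ZMW classification. Alongside the
#' files, a per-ZMW truth table is written from which every QC statistic,
#' subsampling result and filtering decision is computable in closed form —
#' the independent oracle for the rest of the package.
#' @name synthetic-fixtures
NULL

#' Specify a synthetic SMRTcell
#'
#' Defaults describe a realistic, moderately multi-pass Sequel cell: insert
#' (subread) lengths log-normal with median ~8.1 kb (`mu_log = 9`,
#' `sigma_log = 0.55`), a mean of 2 passes per ZMW (1 + geometric), 45-base
#' adapters, 16-base barcodes, 5% scraps-only ZMWs, 5% non-normal scraps.
#'
#' @param n_zmws number of ZMWs to simulate.
#' @param seed integer seed; the same spec always produces byte-identical
#'   files.
#' @param mu_log,sigma_log log-normal parameters of subread length
#'   (log-bases).
#' @param mean_passes mean number of polymerase passes (subreads) per
#'   subread-bearing ZMW; passes are `1 + Geometric`.
#' @param adapter_length SMRTbell adapter length in bases (constant).
#' @param barcode_length barcode length in bases (constant).
#' @param p_scraps_only probability a ZMW yielded no subread (its CLR is a
#'   single low-quality scrap).
#' @param p_nonnormal probability a scrap carries a non-normal ZMW
#'   classification, drawn from `class_weights`.
#' @param class_weights sampling weights over the non-normal classes C
#'   (control), M (malformed), S (sentinel).
#' @param p_barcode,p_lq probability of a leading barcode / low-quality
#'   scrap on the CLR.
#' @param p_missing_first_adapter,p_missing_last_adapter probability the
#'   CLR starts/ends mid-pass, i.e. lacks the flanking adapter.
#' @param emit_sequences write random ACGT sequences of the correct lengths;
#'   disable for fast coordinate-only fixtures (SEQ/QUAL become `*`).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_zmws, seed = 1L, mu_log = 9, sigma_log = 0.55,
                         mean_passes = 2, adapter_length = 45L,
                         barcode_length = 16L, p_scraps_only = 0.05,
                         p_nonnormal = 0.05,
                         class_weights = c(C = 0.4, M = 0.4, S = 0.2),
                         p_barcode = 0.1, p_lq = 0.15,
                         p_missing_first_adapter = 0.25,
                         p_missing_last_adapter = 0.25,
                         emit_sequences = TRUE) {
  stopifnot(n_zmws >= 0, mean_passes >= 1, adapter_length > 0)
  structure(as.list(environment()), class = "fixture_spec")
}

random_seq <- function(total, lengths) {
  if (total == 0L) return(character())
  big <- paste(c("A", "C", "G", "T")[sample.int(4L, total, replace = TRUE)],
               collapse = "")
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1L
  substring(big, starts, ends)
}

# Segment layout for one subread-bearing ZMW. Returns a data frame of
# segments in CLR order with kind ("subread"/"scrap") and region type.
simulate_zmw_layout <- function(spec) {
  k <- 1L + stats::rgeom(1L, prob = 1 / spec$mean_passes)
  sub_len <- pmax(50L, as.integer(round(stats::rlnorm(k, spec$mu_log,
                                                      spec$sigma_log))))
  kinds <- character()
  regions <- character()
  lens <- integer()
  add <- function(kind, region, len) {
    kinds <<- c(kinds, kind); regions <<- c(regions, region)
    lens <<- c(lens, as.integer(len))
  }
  if (stats::runif(1) < spec$p_lq) {
    add("scrap", "L", max(10L, round(stats::rlnorm(1, log(500), 0.8))))
  }
  if (stats::runif(1) < spec$p_barcode) add("scrap", "B", spec$barcode_length)
  first_adapter <- stats::runif(1) >= spec$p_missing_first_adapter
  last_adapter <- stats::runif(1) >= spec$p_missing_last_adapter
  if (first_adapter) add("scrap", "A", spec$adapter_length)
  for (i in seq_len(k)) {
    add("subread", NA_character_, sub_len[i])
    if (i < k) add("scrap", "A", spec$adapter_length)
  }
  if (last_adapter) add("scrap", "A", spec$adapter_length)
  data.frame(kind = kinds, region = regions, len = lens,
             stringsAsFactors = FALSE)
}

#' Generate one synthetic SMRTcell
#'
#' Writes a subreads file, a scraps file and a tab-delimited per-ZMW truth
#' table (`<movie>.truth.tsv`) to `out_dir`. The truth table records, per
#' ZMW: subread lengths, the longest subread, CLR length over all segments
#' and over subreads + normal scraps only, scrap and adapter counts, and
#' whether the ZMW has a complete pass (a subread flanked by adapters on
#' both sides). File content is a pure function of the spec.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created if needed).
#' @param movie movie name; derived from the seed by default.
#' @return list with `cell` ([smrtcell_files()]), `truth` (data frame) and
#'   `truth_path`.
#' @export
generate_cell <- function(spec, out_dir = tempdir(), movie = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.null(movie)) {
    movie <- sprintf("m%d_%06d_%06d", 54000L + spec$seed %% 1000L,
                     spec$seed %% 1000000L, spec$n_zmws %% 1000000L)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- with_seed(spec$seed, {
    n <- spec$n_zmws
    holes <- if (n > 0L) cumsum(1L + stats::rpois(n, 10)) else integer()
    zmws <- lapply(seq_len(n), function(i) {
      if (stats::runif(1) < spec$p_scraps_only) {
        data.frame(kind = "scrap", region = "L",
                   len = max(10L, round(stats::rlnorm(1, spec$mu_log,
                                                      spec$sigma_log))),
                   stringsAsFactors = FALSE)
      } else {
        simulate_zmw_layout(spec)
      }
    })
    # per-scrap ZMW classification
    zmws <- lapply(zmws, function(z) {
      is_scrap <- z$kind == "scrap"
      cls <- rep(NA_character_, nrow(z))
      nn <- is_scrap & stats::runif(nrow(z)) < spec$p_nonnormal
      cls[is_scrap] <- "N"
      if (any(nn)) {
        cls[nn] <- sample(names(spec$class_weights), sum(nn), replace = TRUE,
                          prob = spec$class_weights)
      }
      z$zmw_class <- cls
      z
    })
    list(holes = holes, zmws = zmws)
  })
  holes <- res$holes
  zmws <- res$zmws

  per_zmw <- lapply(seq_along(zmws), function(i) {
    z <- zmws[[i]]
    ends <- cumsum(z$len)
    starts <- ends - z$len
    z$q_start <- starts
    z$q_end <- ends
    z$hole <- holes[i]
    is_sub <- z$kind == "subread"
    sub_len <- z$len[is_sub]
    ad_end <- z$q_end[!is_sub & z$region == "A"]
    ad_start <- z$q_start[!is_sub & z$region == "A"]
    full_pass <- any(is_sub & z$q_start %in% ad_end & z$q_end %in% ad_start)
    normal <- !is_sub & z$zmw_class == "N"
    truth <- data.frame(
      hole = holes[i],
      n_subreads = sum(is_sub),
      subread_lengths = paste(sub_len, collapse = ","),
      longest_subread = if (any(is_sub)) max(sub_len) else NA_integer_,
      n_scraps = sum(!is_sub),
      n_normal_scraps = sum(normal),
      normal_scrap_bases = sum(z$len[normal]),
      n_normal_adapters = sum(normal & z$region == "A"),
      n_adapters = sum(!is_sub & z$region == "A"),
      clr_length = sum(z$len),
      clr_length_normal = sum(sub_len) + sum(z$len[normal]),
      full_pass = full_pass,
      stringsAsFactors = FALSE)
    list(segments = z, truth = truth)
  })
  segments <- do.call(rbind, lapply(per_zmw, `[[`, "segments"))
  truth <- do.call(rbind, lapply(per_zmw, `[[`, "truth"))
  if (is.null(truth)) truth <- data.frame(
    hole = integer(), n_subreads = integer(), subread_lengths = character(),
    longest_subread = integer(), n_scraps = integer(),
    n_normal_scraps = integer(), normal_scrap_bases = integer(),
    n_normal_adapters = integer(), n_adapters = integer(),
    clr_length = integer(), clr_length_normal = integer(),
    full_pass = logical(), stringsAsFactors = FALSE)

  make_records <- function(seg) {
    n <- nrow(seg)
    if (n == 0L) {
      return(empty_records())
    }
    sequence <- rep(NA_character_, n)
    if (spec$emit_sequences && n > 0L) {
      sequence <- with_seed(spec$seed + 1L,
                            random_seq(sum(seg$len), seg$len))
    }
    data.frame(qname = sprintf("%s/%d/%d_%d", movie, seg$hole, seg$q_start,
                               seg$q_end),
               movie = movie, hole = seg$hole,
               q_start = seg$q_start, q_end = seg$q_end,
               sequence = sequence, qualities = NA_character_,
               zmw_class = seg$zmw_class,
               region_type = seg$region,
               other_tags = "", stringsAsFactors = FALSE)
  }
  seg_sub <- if (is.null(segments)) NULL else
    segments[segments$kind == "subread", , drop = FALSE]
  seg_scr <- if (is.null(segments)) NULL else
    segments[segments$kind == "scrap", , drop = FALSE]
  if (is.null(seg_sub)) seg_sub <- data.frame()
  if (is.null(seg_scr)) seg_scr <- data.frame()
  subreads <- if (nrow(seg_sub)) make_records(seg_sub) else empty_records()
  scraps <- if (nrow(seg_scr)) make_records(seg_scr) else empty_records()
  attr(subreads, "movie") <- movie
  attr(scraps, "movie") <- movie
  subreads_path <- file.path(out_dir, paste0(movie, ".subreads.sam"))
  scraps_path <- file.path(out_dir, paste0(movie, ".scraps.sam"))
  truth_path <- file.path(out_dir, paste0(movie, ".truth.tsv"))
  write_records(subreads, subreads_path, kind = "subreads",
                require_sequences = FALSE)
  write_records(scraps, scraps_path, kind = "scraps",
                require_sequences = FALSE)
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(cell = smrtcell_files(subreads_path, scraps_path, cell_id = movie),
       truth = truth, truth_path = truth_path, movie = movie)
}

#' QC summary computed directly from a fixture truth table
#'
#' The independent oracle for [summarize_cell()]: recomputes every read
#' group, statistic and ratio from the generator's per-ZMW truth table,
#' bypassing file parsing and ZMW bundling entirely. Applies the same
#' normal-only convention as QC: a ZMW enters the CLR group iff it has a
#' subread or at least one normal scrap, and only normal scrap bases count
#' toward its CLR length.
#'
#' @param truth truth table from [generate_cell()].
#' @param with_scraps analyse scraps (the CLR/subedCLR groups)?
#' @param four_groups report four read groups (scraps mode only).
#' @return An object of class `qc_summary` (without the file-derived
#'   `group_set`/`zmw_table` internals).
#' @export
truth_qc <- function(truth, with_scraps = TRUE, four_groups = with_scraps) {
  if (four_groups && !with_scraps) {
    stop("four read groups require scraps")
  }
  has_sub <- truth$n_subreads > 0L
  sub_lens <- as.integer(unlist(strsplit(truth$subread_lengths[has_sub], ",",
                                         fixed = TRUE)))
  longest <- truth$longest_subread[has_sub]
  in_qc <- has_sub | truth$n_normal_scraps > 0L
  groups <- if (with_scraps && four_groups) {
    list(subreads = sub_lens,
         longest_subreads = longest,
         clrs = truth$clr_length_normal[in_qc],
         subed_clrs = truth$clr_length_normal[has_sub])
  } else if (with_scraps) {
    list(subreads = sub_lens,
         subed_clrs = truth$clr_length_normal[has_sub])
  } else {
    list(subreads = sub_lens, longest_subreads = longest)
  }
  n_sub <- length(sub_lens)
  psr <- if (n_sub == 0L) NA_real_ else sum(as.numeric(longest)) / sum(as.numeric(sub_lens))
  zor <- if (n_sub == 0L) NA_real_ else sum(has_sub) / n_sub
  structure(list(cell_id = "truth", movie = NA_character_,
                 groups = lapply(groups, length_stats),
                 psr = psr, zor = zor),
            class = "qc_summary")
}
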