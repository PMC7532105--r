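#' @title PacBio Sequel read records
#' @description
#' Records are stored as plain data frames, one row per read, with columns
#' `qname`, `movie`, `hole`, `q_start`, `q_end`, `sequence`, `qualities`,
#' `zmw_class`, `region_type`, `other_tags`. Subreads carry `NA` in
#' `zmw_class`/`region_type`; scraps always carry both. `sequence` and
#' `qualities` are `NA` for coordinates-only records (SAM `*`). `other_tags`
#' holds any further SAM tags verbatim (tab-joined) so that filtering and
#' subsampling are lossless.
#' @name pacbio-records
NULL

RECORD_COLUMNS <- c("qname", "movie", "hole", "q_start", "q_end",
                    "sequence", "qualities", "zmw_class", "region_type",
                    "other_tags")

ZMW_CLASSES <- c("N", "C", "M", "S")   # normal, control, malformed, sentinel
REGION_TYPES <- c("A", "B", "L", "F")  # adapter, barcode, LQ region, filtered

empty_records <- function() {
  data.frame(qname = character(), movie = character(), hole = integer(),
             q_start = integer(), q_end = integer(),
             sequence = character(), qualities = character(),
             zmw_class = character(), region_type = character(),
             other_tags = character(), stringsAsFactors = FALSE)
}

#' Parse PacBio read names
#'
#' PacBio Sequel raw reads are named `movie/holeNumber/qStart_qEnd`: the movie
#' identifies the SMRTcell, the hole number the ZMW, and `qStart`/`qEnd` are
#' 0-based half-open coordinates on the polymerase read (CLR). Zero-length
#' reads (`q_end <= q_start`) are rejected.
#'
#' @param name character vector of read names.
#' @return A data frame with columns `movie`, `hole`, `q_start`, `q_end`,
#'   one row per name.
#' @examples
#' parse_read_name("m54138_180610_050652/4194370/0_9972")
#' @export
parse_read_name <- function(name) {
  if (!is.character(name)) stop("read names must be a character vector")
  if (length(name) == 0L) {
    return(data.frame(movie = character(), hole = integer(),
                      q_start = integer(), q_end = integer(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(name, "/", fixed = TRUE)
  n_fields <- lengths(parts)
  if (any(bad <- n_fields != 3L)) {
    stop(sprintf("malformed read name '%s': expected movie/hole/qStart_qEnd (3 fields), got %d",
                 name[bad][1L], n_fields[bad][1L]))
  }
  m <- matrix(unlist(parts, use.names = FALSE), ncol = 3L, byrow = TRUE)
  movie <- m[, 1L]
  if (any(bad <- !nzchar(movie))) {
    stop(sprintf("malformed read name '%s': empty movie field", name[bad][1L]))
  }
  if (any(bad <- !grepl("^[0-9]+$", m[, 2L]))) {
    stop(sprintf("malformed read name '%s': hole number '%s' is not a non-negative integer",
                 name[bad][1L], m[bad, 2L][1L]))
  }
  hole <- as.integer(m[, 2L])
  if (any(bad <- !grepl("^[0-9]+_[0-9]+$", m[, 3L]))) {
    stop(sprintf("malformed read name '%s': coordinates '%s' are not qStart_qEnd",
                 name[bad][1L], m[bad, 3L][1L]))
  }
  coord <- strsplit(m[, 3L], "_", fixed = TRUE)
  cm <- matrix(as.integer(unlist(coord, use.names = FALSE)), ncol = 2L, byrow = TRUE)
  q_start <- cm[, 1L]
  q_end <- cm[, 2L]
  if (any(bad <- q_end <= q_start)) {
    stop(sprintf("malformed read name '%s': q_end (%d) must be greater than q_start (%d)",
                 name[bad][1L], q_end[bad][1L], q_start[bad][1L]))
  }
  data.frame(movie = movie, hole = hole, q_start = q_start, q_end = q_end,
             stringsAsFactors = FALSE)
}

#' Format a read identity back into a PacBio read name
#'
#' Inverse of [parse_read_name()]: `format_read_name(parse_read_name(x))`
#' reproduces `x` for any valid name.
#'
#' @param identity data frame with columns `movie`, `hole`, `q_start`, `q_end`.
#' @return character vector of `movie/hole/qStart_qEnd` names.
#' @export
format_read_name <- function(identity) {
  sprintf("%s/%d/%d_%d", identity$movie, identity$hole,
          identity$q_start, identity$q_end)
}

#' Read lengths implied by polymerase-read coordinates
#' @param records record data frame (or identity data frame).
#' @return integer vector `q_end - q_start`.
#' @export
record_lengths <- function(records) {
  as.integer(records$q_end - records$q_start)
}

is_bam_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  # BAM is BGZF (gzip) compressed; SAM is plain text
  length(magic) == 2L && magic[1L] == as.raw(0x1f) && magic[2L] == as.raw(0x8b)
}

samtools_path <- function() {
  p <- Sys.which("samtools")
  if (!nzchar(p)) stop("BAM support requires 'samtools' on the PATH")
  p
}

extract_tag <- function(tag_lists, prefix) {
  vapply(tag_lists, function(tags) {
    hit <- tags[startsWith(tags, prefix)]
    if (length(hit) == 0L) NA_character_ else substring(hit[1L], nchar(prefix) + 1L)
  }, character(1L))
}

#' Read a subreads or scraps file
#'
#' Reads a per-SMRTcell SAM (or BAM, via samtools) file into a record data
#' frame. Every read name must parse as `movie/hole/qStart_qEnd` and all
#' records must share one movie. For `kind = "scraps"` every record must
#' carry a ZMW classification tag (`sz:A:`, one of N/C/M/S) and a scrap
#' region-type tag (`sc:A:`, one of A/B/L/F); a missing annotation is a
#' parse error. The `zm`/`qs`/`qe` coordinate tags are redundant with the
#' read name and are regenerated on write; all other tags are preserved
#' verbatim in `other_tags`.
#'
#' @param path path to a SAM or BAM file.
#' @param kind `"subreads"` or `"scraps"`.
#' @param coordinates_only drop sequences and qualities after validation,
#'   keeping only identities and annotations (fast path for QC, which is pure
#'   coordinate arithmetic).
#' @return record data frame (see [pacbio-records]) with attributes `kind`
#'   and `movie`.
#' @export
read_records <- function(path, kind = c("subreads", "scraps"),
                         coordinates_only = FALSE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is_bam_file(path)) {
    lines <- suppressWarnings(
      system2(samtools_path(), c("view", "-h", shQuote(path)), stdout = TRUE))
    status <- attr(lines, "status")
    if (!is.null(status) && status != 0L) stop("samtools view failed on ", path)
  } else {
    lines <- readLines(path)
  }
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(body) == 0L) {
    out <- empty_records()
    attr(out, "kind") <- kind
    attr(out, "movie") <- NA_character_
    return(out)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(bad <- lengths(fields) < 11L)) {
    stop(sprintf("malformed SAM record (fewer than 11 fields) at line %d of %s",
                 which(bad)[1L], path))
  }
  qname <- vapply(fields, `[[`, character(1L), 1L)
  id <- parse_read_name(qname)
  if (length(unique(id$movie)) > 1L) {
    stop("mixed movies within one file: ", path, " contains ",
         paste(unique(id$movie), collapse = ", "))
  }
  sequence <- vapply(fields, `[[`, character(1L), 10L)
  qualities <- vapply(fields, `[[`, character(1L), 11L)
  sequence[sequence == "*"] <- NA_character_
  qualities[qualities == "*"] <- NA_character_
  len <- id$q_end - id$q_start
  has_seq <- !is.na(sequence)
  if (any(bad <- has_seq & nchar(sequence) != len)) {
    stop(sprintf("record '%s': sequence length %d does not match coordinates (%d bases)",
                 qname[bad][1L], nchar(sequence[bad][1L]), len[bad][1L]))
  }
  tag_lists <- lapply(fields, function(x) {
    if (length(x) > 11L) x[12:length(x)] else character()
  })
  zmw_class <- extract_tag(tag_lists, "sz:A:")
  region_type <- extract_tag(tag_lists, "sc:A:")
  if (kind == "scraps") {
    if (any(bad <- is.na(zmw_class))) {
      stop(sprintf("scraps record '%s' lacks the ZMW classification tag (sz:A:)",
                   qname[bad][1L]))
    }
    if (any(bad <- is.na(region_type))) {
      stop(sprintf("scraps record '%s' lacks the region-type tag (sc:A:)",
                   qname[bad][1L]))
    }
    if (any(bad <- !zmw_class %in% ZMW_CLASSES)) {
      stop(sprintf("scraps record '%s': ZMW classification '%s' not one of N/C/M/S",
                   qname[bad][1L], zmw_class[bad][1L]))
    }
    if (any(bad <- !region_type %in% REGION_TYPES)) {
      stop(sprintf("scraps record '%s': region type '%s' not one of A/B/L/F",
                   qname[bad][1L], region_type[bad][1L]))
    }
  }
  drop_prefixes <- c("zm:", "qs:", "qe:", "sz:", "sc:")
  other_tags <- vapply(tag_lists, function(tags) {
    keep <- tags[!substring(tags, 1L, 3L) %in% drop_prefixes]
    paste(keep, collapse = "\t")
  }, character(1L))
  if (coordinates_only) {
    sequence[] <- NA_character_
    qualities[] <- NA_character_
  }
  out <- data.frame(qname = qname, movie = id$movie, hole = id$hole,
                    q_start = id$q_start, q_end = id$q_end,
                    sequence = sequence, qualities = qualities,
                    zmw_class = zmw_class, region_type = region_type,
                    other_tags = other_tags, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "kind") <- kind
  attr(out, "movie") <- id$movie[1L]
  out
}

sam_header <- function(movie, kind) {
  read_type <- if (identical(kind, "scraps")) "SCRAP" else "SUBREAD"
  c("@HD\tVN:1.6\tSO:unknown",
    sprintf("@RG\tID:%s\tPL:PACBIO\tPU:%s\tDS:READTYPE=%s",
            movie, movie, read_type))
}

records_to_sam <- function(records, kind, movie) {
  lines <- sam_header(movie, kind)
  if (nrow(records) == 0L) return(lines)
  seq_field <- ifelse(is.na(records$sequence), "*", records$sequence)
  qual_field <- ifelse(is.na(records$qualities), "*", records$qualities)
  tags <- sprintf("zm:i:%d\tqs:i:%d\tqe:i:%d",
                  records$hole, records$q_start, records$q_end)
  if (identical(kind, "scraps")) {
    tags <- sprintf("%s\tsz:A:%s\tsc:A:%s", tags,
                    records$zmw_class, records$region_type)
  }
  extra <- records$other_tags
  tags <- ifelse(!is.na(extra) & nzchar(extra), paste(tags, extra, sep = "\t"), tags)
  c(lines,
    sprintf("%s\t4\t*\t0\t255\t*\t*\t0\t0\t%s\t%s\t%s",
            format_read_name(records), seq_field, qual_field, tags))
}

#' Write records to a subreads or scraps file
#'
#' Writes a record data frame as headered SAM (or BAM, via samtools). The
#' output round-trips: [read_records()] on the written file recovers the
#' identities, sequences, annotations and preserved tags exactly. All records
#' must share one movie. By contract, coordinates-only records (missing
#' sequences) cannot be written; `require_sequences = FALSE` relaxes this for
#' internal uses such as the coordinate-only fixture generator, emitting `*`
#' in the SEQ/QUAL columns.
#'
#' @param records record data frame.
#' @param path output path.
#' @param emit_binary write BAM instead of SAM (requires samtools).
#' @param kind `"subreads"` or `"scraps"`; by default inferred from the
#'   presence of scrap annotations.
#' @param require_sequences error if any record lacks a sequence.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, emit_binary = FALSE, kind = NULL,
                          require_sequences = TRUE) {
  if (is.null(kind)) {
    kind <- if (nrow(records) > 0L && any(!is.na(records$zmw_class)))
      "scraps" else attr(records, "kind") %||% "subreads"
  }
  kind <- match.arg(kind, c("subreads", "scraps"))
  movie <- unique(records$movie)
  if (length(movie) > 1L) {
    stop("records from multiple movies cannot share one file: ",
         paste(movie, collapse = ", "))
  }
  if (length(movie) == 0L || nrow(records) == 0L) {
    movie <- attr(records, "movie") %||% "unknown"
    if (is.na(movie)) movie <- "unknown"
  }
  if (require_sequences && nrow(records) > 0L && anyNA(records$sequence)) {
    stop("records lack sequences (coordinates-only input cannot be written)")
  }
  if (kind == "scraps" && nrow(records) > 0L &&
      (anyNA(records$zmw_class) || anyNA(records$region_type))) {
    stop("scraps records must carry zmw_class and region_type annotations")
  }
  lines <- records_to_sam(records, kind, movie)
  if (emit_binary) {
    tmp <- tempfile(fileext = ".sam")
    on.exit(unlink(tmp))
    writeLines(lines, tmp)
    status <- system2(samtools_path(),
                      c("view", "-b", "-o", shQuote(path), shQuote(tmp)))
    if (status != 0L) stop("samtools view -b failed writing ", path)
  } else {
    writeLines(lines, path)
  }
  invisible(path)
}

#' Describe one SMRTcell's input files
#'
#' Pairs a subreads file with an optional scraps file. Tools that read both
#' files verify that they share one movie name and error on mismatch.
#'
#' @param subreads_path path to the subreads SAM/BAM file (required).
#' @param scraps_path path to the matching scraps file, or `NULL`.
#' @param cell_id cell identifier; defaults to the subreads file stem.
#' @return An object of class `smrtcell_files`.
#' @export
smrtcell_files <- function(subreads_path, scraps_path = NULL, cell_id = NULL) {
  if (!file.exists(subreads_path)) stop("subreads file not found: ", subreads_path)
  if (!is.null(scraps_path) && !file.exists(scraps_path)) {
    stop("scraps file not found: ", scraps_path)
  }
  if (is.null(cell_id)) {
    cell_id <- sub("\\.(sam|bam)$", "", basename(subreads_path))
    cell_id <- sub("\\.(subreads|scraps)$", "", cell_id)
  }
  structure(list(cell_id = cell_id, subreads_path = subreads_path,
                 scraps_path = scraps_path),
            class = "smrtcell_files")
}

#' @export
print.smrtcell_files <- function(x, ...) {
  cat("SMRTcell", x$cell_id, "\n")
  cat("  subreads:", x$subreads_path, "\n")
  cat("  scraps:  ", if (is.null(x$scraps_path)) "(none)" else x$scraps_path, "\n")
  invisible(x)
}

as_smrtcell <- function(x) {
  if (inherits(x, "smrtcell_files")) return(x)
  if (is.list(x) && !is.null(x$subreads_path)) {
    return(smrtcell_files(x$subreads_path, x$scraps_path, x$cell_id))
  }
  if (is.character(x) && length(x) == 1L) return(smrtcell_files(x))
  stop("cannot interpret input as an SMRTcell file pair")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Read both files of a cell, enforcing the movie-pairing invariant.
read_cell <- function(cell, with_scraps, coordinates_only = FALSE) {
  cell <- as_smrtcell(cell)
  subreads <- read_records(cell$subreads_path, "subreads",
                           coordinates_only = coordinates_only)
  scraps <- NULL
  if (with_scraps) {
    if (is.null(cell$scraps_path)) {
      stop("cell '", cell$cell_id, "' has no scraps file but scraps were requested")
    }
    scraps <- read_records(cell$scraps_path, "scraps",
                           coordinates_only = coordinates_only)
    m1 <- attr(subreads, "movie")
    m2 <- attr(scraps, "movie")
    if (!is.na(m1) && !is.na(m2) && m1 != m2) {
      stop("subreads/scraps movie mismatch for cell '", cell$cell_id,
           "': ", m1, " vs ", m2)
    }
  }
  list(cell = cell, subreads = subreads, scraps = scraps,
       movie = attr(subreads, "movie"))
}
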