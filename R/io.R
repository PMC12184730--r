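segment_columns <- c("whisker_id", "animal_id", "sex", "sampling_year",
                     "collection_date", "segment_index", "start_mm", "end_mm",
                     "d13C", "d15N", "cn_ratio")

#' Validate a whisker segment table
#'
#' Checks the per-whisker invariants of the segment schema: segments ordered by
#' `segment_index`, intervals `[start_mm, end_mm)` contiguous, non-overlapping
#' and increasing from the root, finite isotope values, and consistent
#' whisker-level metadata.
#'
#' @param segments A segment data frame (schema of [read_segments_csv()]).
#' @param tol Numeric tolerance for contiguity of segment intervals, mm.
#' @return The input, invisibly, with segments sorted by whisker then index.
#' @export
validate_segments <- function(segments, tol = 1e-6) {
  stopifnot(is.data.frame(segments))
  missing_cols <- setdiff(segment_columns, names(segments))
  if (length(missing_cols)) {
    stop("segment table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!nrow(segments)) stop("segment table is empty", call. = FALSE)
  num <- c("start_mm", "end_mm", "d13C", "d15N")
  for (cl in num) {
    if (!all(is.finite(segments[[cl]]))) {
      stop("non-finite values in column '", cl, "' (row ",
           which(!is.finite(segments[[cl]]))[1], ")", call. = FALSE)
    }
  }
  segments <- segments[order(segments$whisker_id, segments$segment_index), ,
                       drop = FALSE]
  for (w in split(seq_len(nrow(segments)), segments$whisker_id)) {
    sub <- segments[w, , drop = FALSE]
    id <- sub$whisker_id[1]
    if (anyDuplicated(sub$segment_index)) {
      stop("whisker '", id, "': duplicated segment_index", call. = FALSE)
    }
    if (any(sub$start_mm >= sub$end_mm)) {
      bad <- w[which(sub$start_mm >= sub$end_mm)[1]]
      stop("whisker '", id, "': start_mm >= end_mm at row ", bad, call. = FALSE)
    }
    if (nrow(sub) > 1) {
      gaps <- sub$start_mm[-1] - sub$end_mm[-nrow(sub)]
      if (any(abs(gaps) > tol)) {
        bad <- w[which(abs(gaps) > tol)[1] + 1]
        stop("whisker '", id, "': segment intervals overlap or leave gaps ",
             "at row ", bad, call. = FALSE)
      }
    }
    meta <- c("animal_id", "sex", "sampling_year", "collection_date")
    for (cl in meta) {
      if (length(unique(sub[[cl]])) > 1) {
        stop("whisker '", id, "': inconsistent '", cl, "' across segments",
             call. = FALSE)
      }
    }
  }
  invisible(segments)
}

#' Read a segment-level whisker isotope CSV
#'
#' Expects one row per whisker segment with columns `whisker_id`, `animal_id`,
#' `sex` (F/M), `sampling_year`, `collection_date` (ISO-8601), `segment_index`
#' (0-based from the root), `start_mm`, `end_mm` (mm from the root, half-open
#' intervals), `d13C`, `d15N` (per mil), `cn_ratio`, and optionally `mass_kg`.
#' All per-whisker invariants are enforced; see [validate_segments()].
#'
#' @param path Path to a UTF-8, comma-separated file with a header.
#' @return A validated segment data frame sorted by whisker and segment index,
#'   with `collection_date` parsed as `Date`.
#' @export
read_segments_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$collection_date <- as.Date(as.character(df$collection_date),
                                format = "%Y-%m-%d")
  if (anyNA(df$collection_date)) {
    stop("unparseable collection_date (expect ISO-8601) at row ",
         which(is.na(df$collection_date))[1], call. = FALSE)
  }
  validate_segments(df)
}

#' Write a segment table to CSV
#'
#' Inverse of [read_segments_csv()]: writes the documented schema with ISO
#' dates so that a write/read round trip is lossless.
#'
#' @param segments A segment data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_csv <- function(segments, path) {
  out <- segments
  out$collection_date <- format(as.Date(out$collection_date), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged whisker-level summary table
#'
#' Loads the transcription of the published per-whisker summary table for the
#' Cape Shirreff leopard seal population: 46 whiskers from 34 individuals, each
#' with segment count, mean/SD/range of delta15N and delta13C, individual SEAc,
#' and the delta15N specialization category (H-Specialist, ML-Specialist,
#' Intermediate, Generalist). The table is shipped as printed; its segment
#' counts sum to 2199.
#'
#' @return A data frame with one row per whisker.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_whisker_summaries.csv",
                      package = "whiskerniche", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 46, length(unique(df$animal_id)) == 34,
            all(df$n_segments >= 1),
            all(df$d15N_min <= df$d15N_mean & df$d15N_mean <= df$d15N_max),
            all(df$d13C_min <= df$d13C_mean & df$d13C_mean <= df$d13C_max))
  df$category <- factor(df$category, levels = c("H-Specialist", "ML-Specialist",
                                                "Intermediate", "Generalist"))
  df
}
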