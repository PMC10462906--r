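# Reading, writing, and validation of annotated IGH rearrangements.
#
# Internal convention: rearrangements are rows of a data.frame, one row per
# sequenced V(D)J rearrangement (= one B cell). All coordinates held in
# memory are 0-based, half-open on the ungapped `sequence`. On disk the AIRR
# Rearrangement TSV dialect is used, whose coordinates are 1-based inclusive;
# conversion happens only at the I/O boundary. Non-standard fields (gc_id,
# replicate_id, n1_*/n2_* N-region bounds) travel as extension columns.

.REGIONS <- c("fwr1", "cdr1", "fwr2", "cdr2", "fwr3", "cdr3", "fwr4")

.BOUND_COLS <- as.vector(t(outer(.REGIONS, c("_start", "_end"), paste0)))

.AIRR_COLS <- c("sequence_id", "sequence", "v_call", "j_call", "junction",
                "junction_length", "vj_in_frame", "duplicate_count",
                .BOUND_COLS,
                "n1_start", "n1_end", "n2_start", "n2_end",
                "gc_id", "replicate_id")

.REQUIRED_COLS <- c("sequence_id", "sequence", "v_call", "j_call",
                    "junction", "junction_length")

#' Validate rearrangement records
#'
#' Checks every row of a rearrangement table against the structural
#' invariants: the junction length matches the junction string (and is a
#' codon multiple when the junction is in frame), region intervals are
#' disjoint, ordered FWR1 < CDR1 < FWR2 < CDR2 < FWR3 < CDR3 < FWR4 and lie
#' within the sequence, the junction occupies `[fwr3_end, fwr3_end +
#' junction_length)` on the sequence, N-region intervals fall inside the
#' junction span, and duplicate counts are positive integers.
#'
#' @param records data.frame of rearrangements (internal 0-based bounds).
#' @return list with `valid` (rows passing all checks), `rejected` (failing
#'   rows with a `reason` column).
#' @export
validate_rearrangements <- function(records) {
  reason <- rep(NA_character_, nrow(records))
  note <- function(bad, msg) {
    bad[is.na(bad)] <- TRUE
    reason[is.na(reason) & bad] <<- msg
  }
  note(records$junction_length != nchar(records$junction),
       "junction_length does not match junction")
  note(records$in_frame_junction & records$junction_length %% 3L != 0L,
       "in-frame junction length not a codon multiple")
  note(records$duplicate_count < 1 |
         records$duplicate_count != round(records$duplicate_count),
       "duplicate_count not a positive integer")

  starts <- as.matrix(records[paste0(.REGIONS, "_start")])
  ends <- as.matrix(records[paste0(.REGIONS, "_end")])
  note(rowSums(starts > ends) > 0, "region interval with start > end")
  note(starts[, 1] < 0 | ends[, 7] > nchar(records$sequence),
       "region interval outside sequence")
  # ordered + disjoint: each region must end at or before the next begins
  note(rowSums(ends[, -7, drop = FALSE] > starts[, -1, drop = FALSE]) > 0,
       "region intervals overlap or are out of order")

  jstart <- records$fwr3_end
  jend <- jstart + records$junction_length
  note(substr(records$sequence, jstart + 1L, jend) != records$junction,
       "junction does not match sequence at expected span")
  in_span <- function(s, e) {
    empty <- is.na(s) | s == e
    empty | (s >= jstart & e <= jend)
  }
  note(!in_span(records$n1_start, records$n1_end) |
         !in_span(records$n2_start, records$n2_end),
       "N-region interval outside junction span")

  ok <- is.na(reason)
  rejected <- records[!ok, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!ok]
  list(valid = records[ok, , drop = FALSE], rejected = rejected)
}

#' Read annotated rearrangements
#'
#' Reads rearrangements from an AIRR Rearrangement TSV (or a FASTA plus TSV
#' annotation sidecar), converts on-disk 1-based inclusive coordinates to
#' the internal 0-based half-open convention, and validates every row.
#' Rows violating the invariants are dropped with a warning naming their
#' sequence ids; they remain available in the `rejected` attribute of the
#' result. Row order of valid records is preserved.
#'
#' @param path file path to the TSV (or FASTA when `format =
#'   "fasta_sidecar"`).
#' @param format `"airr_tsv"` or `"fasta_sidecar"`.
#' @param sidecar path to the annotation TSV when reading FASTA.
#' @return data.frame of validated rearrangements.
#' @export
read_rearrangements <- function(path, format = c("airr_tsv", "fasta_sidecar"),
                                sidecar = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "airr_tsv") {
    df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                            check.names = FALSE)
  } else {
    if (is.null(sidecar)) stop("fasta_sidecar format requires `sidecar`")
    fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
    seqs <- data.frame(sequence_id = names(fa),
                       sequence = toupper(unlist(fa, use.names = FALSE)),
                       stringsAsFactors = FALSE)
    ann <- utils::read.delim(sidecar, sep = "\t", colClasses = "character",
                             check.names = FALSE)
    ann$sequence <- NULL
    df <- merge(seqs, ann, by = "sequence_id", sort = FALSE)
  }
  missing <- setdiff(.REQUIRED_COLS, c(names(df), "sequence"))
  if (length(missing)) {
    stop("required column(s) missing: ", paste(missing, collapse = ", "))
  }
  for (col in setdiff(.AIRR_COLS, names(df))) df[[col]] <- NA
  df <- df[.AIRR_COLS]

  int_cols <- c("junction_length", "duplicate_count", .BOUND_COLS,
                "n1_start", "n1_end", "n2_start", "n2_end")
  for (col in int_cols) df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  df$in_frame_junction <- toupper(df$vj_in_frame) %in% c("T", "TRUE")
  df$vj_in_frame <- NULL
  # AIRR 1-based inclusive [start, end]  ->  0-based half-open [start-1, end)
  for (col in grep("_start$", names(df), value = TRUE)) {
    df[[col]] <- df[[col]] - 1L
  }
  if (nrow(df) == 0) {
    df$in_frame_junction <- logical(0)
    return(df)
  }
  checked <- validate_rearrangements(df)
  if (nrow(checked$rejected)) {
    warning(nrow(checked$rejected), " record(s) failed validation and were ",
            "dropped: ",
            paste(checked$rejected$sequence_id, collapse = ", "))
  }
  out <- checked$valid
  rownames(out) <- NULL
  attr(out, "rejected") <- checked$rejected
  out
}

#' Write rearrangements to an AIRR Rearrangement TSV
#'
#' Writes records with a stable column order; internal 0-based half-open
#' coordinates are converted to the AIRR 1-based inclusive dialect so that
#' `read_rearrangements(write_rearrangements(x))` is the identity on all
#' modeled fields.
#'
#' @param records data.frame of rearrangements.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rearrangements <- function(records, path) {
  df <- records
  df$vj_in_frame <- ifelse(df$in_frame_junction, "T", "F")
  df$in_frame_junction <- NULL
  for (col in grep("_start$", names(df), value = TRUE)) {
    df[[col]] <- df[[col]] + 1L
  }
  df <- df[.AIRR_COLS]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
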