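#' Note annotation records
#'
#' Annotations are plain data frames with columns `begin_s`, `end_s`,
#' `low_hz`, `high_hz` and `source_id`; times are seconds from the start of
#' the source recording. The frequency bounds are optional record-keeping.
#'
#' @param begin_s,end_s note time bounds (s), `end_s > begin_s`.
#' @param low_hz,high_hz optional frequency bounds (Hz).
#' @param source_id recording identifier.
#' @return a data frame of class `note_annotations`.
#' @export
note_annotations <- function(begin_s, end_s, low_hz = NA_real_,
                             high_hz = NA_real_, source_id = "unknown") {
  if (any(end_s <= begin_s)) stop("invalid input: end_s must exceed begin_s")
  n <- length(begin_s)
  df <- data.frame(begin_s = as.numeric(begin_s), end_s = as.numeric(end_s),
                   low_hz = rep_len(low_hz, n), high_hz = rep_len(high_hz, n),
                   source_id = rep_len(source_id, n), stringsAsFactors = FALSE)
  class(df) <- c("note_annotations", "data.frame")
  df
}

.sel_cols <- c(begin_s = "Begin Time (s)", end_s = "End Time (s)",
               low_hz = "Low Freq (Hz)", high_hz = "High Freq (Hz)")

#' Read a Raven-style selection table
#'
#' Tab-separated with a header row; requires columns "Begin Time (s)" and
#' "End Time (s)"; "Low Freq (Hz)" and "High Freq (Hz)" are optional.
#'
#' @param path file path.
#' @param source_id recording identifier attached to the annotations
#'   (defaults to the file name).
#' @return a [note_annotations()] data frame sorted by begin time.
#' @export
read_selection_table <- function(path, source_id = basename(path)) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in .sel_cols[c("begin_s", "end_s")])
    if (!col %in% names(tab))
      stop("selection table format error: missing column \"", col, "\" in ", path)
  if (nrow(tab) == 0)
    return(note_annotations(numeric(0), numeric(0), source_id = character(0)))
  getcol <- function(nm, default) if (nm %in% names(tab)) as.numeric(tab[[nm]]) else default
  ann <- note_annotations(
    begin_s = as.numeric(tab[[.sel_cols["begin_s"]]]),
    end_s = as.numeric(tab[[.sel_cols["end_s"]]]),
    low_hz = getcol(.sel_cols["low_hz"], NA_real_),
    high_hz = getcol(.sel_cols["high_hz"], NA_real_),
    source_id = source_id)
  ann[order(ann$begin_s), , drop = FALSE]
}

#' Write annotations as a Raven-style selection table
#'
#' @param annotations a [note_annotations()] data frame.
#' @param path output path.
#' @return `path`, invisibly. `read_selection_table(write_selection_table(x))`
#'   round-trips up to float formatting.
#' @export
write_selection_table <- function(annotations, path) {
  out <- data.frame(
    Selection = seq_len(nrow(annotations)),
    View = rep("Spectrogram 1", nrow(annotations)),
    Channel = rep(1L, nrow(annotations)),
    check.names = FALSE)
  out[[.sel_cols["begin_s"]]] <- annotations$begin_s
  out[[.sel_cols["end_s"]]] <- annotations$end_s
  out[[.sel_cols["low_hz"]]] <- annotations$low_hz
  out[[.sel_cols["high_hz"]]] <- annotations$high_hz
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Label grid segments against ground-truthed notes
#'
#' A segment is `POSITIVE` when it fully contains at least one note (closed
#' containment: segment start <= note begin and note end <= segment end),
#' `PARTIAL` when some note overlaps it but none is fully contained, and
#' `NEGATIVE` otherwise. The three states partition the grid; downstream,
#' PARTIAL tiles are excluded from CNN training but retained inside hybrid
#' input sequences.
#'
#' @param grid a [make_segment_grid()] result.
#' @param annotations a [note_annotations()] data frame (empty allowed).
#' @return character vector of length `grid$n_segments` with values in
#'   `c("POSITIVE", "PARTIAL", "NEGATIVE")`.
#' @export
label_segments <- function(grid, annotations) {
  n <- grid$n_segments
  labels <- rep("NEGATIVE", n)
  if (is.null(annotations) || nrow(annotations) == 0) return(labels)
  starts <- grid$start_times_s
  ends <- starts + grid$segment_duration_s
  for (i in seq_len(nrow(annotations))) {
    b <- annotations$begin_s[i]; e <- annotations$end_s[i]
    overlaps <- which(starts < e & ends > b)
    contained <- overlaps[starts[overlaps] <= b & e <= ends[overlaps]]
    labels[contained] <- "POSITIVE"
    part <- setdiff(overlaps, contained)
    labels[part][labels[part] != "POSITIVE"] <- "PARTIAL"
  }
  labels
}

#' Inter-note intervals for one source
#'
#' INIs are measured start-to-start between chronologically successive notes
#' of a single recording; n notes yield n - 1 intervals.
#'
#' @param annotations a [note_annotations()] data frame.
#' @param source_id restrict to this source (default: require a single
#'   source present).
#' @return data frame with columns `value_s`, `from_idx`, `to_idx` (indices
#'   into the chronologically sorted annotations).
#' @export
compute_inis <- function(annotations, source_id = NULL) {
  if (!is.null(source_id))
    annotations <- annotations[annotations$source_id == source_id, , drop = FALSE]
  if (nrow(annotations) > 0 && length(unique(annotations$source_id)) > 1)
    stop("invalid input: INIs are defined within a single recording; pass source_id")
  if (nrow(annotations) < 2)
    return(data.frame(value_s = numeric(0), from_idx = integer(0), to_idx = integer(0)))
  ord <- order(annotations$begin_s)
  ann <- annotations[ord, , drop = FALSE]
  if (any(ann$end_s[-nrow(ann)] > ann$begin_s[-1]))
    warning("overlapping notes; INIs emitted anyway")
  data.frame(value_s = diff(ann$begin_s),
             from_idx = seq_len(nrow(ann) - 1), to_idx = 2:nrow(ann))
}

#' Cross-validation fold plan over recordings
#'
#' Randomly partitions recording identifiers into `k` disjoint subsets whose
#' sizes differ by at most one; each fold tests on one subset and trains on
#' the other k - 1 (a 9:1 grouping at the default k = 10).
#'
#' @param source_ids character vector of recording identifiers.
#' @param k fold count (default 10).
#' @param seed RNG seed; the plan is reproducible under a fixed seed.
#' @return an object of class `fold_plan` with fields `k`,
#'   `subset_assignment` (named integer vector) and `folds` (list of
#'   `list(train, test)` id vectors).
#' @export
make_folds <- function(source_ids, k = 10, seed = 1) {
  source_ids <- as.character(source_ids)
  if (length(unique(source_ids)) != length(source_ids))
    stop("invalid input: duplicate source_ids")
  if (length(source_ids) < k)
    stop("invalid input: need at least k sources (", k, "), got ", length(source_ids))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  shuffled <- sample(source_ids)
  assign <- rep(seq_len(k), length.out = length(shuffled))  # round-robin deal
  names(assign) <- shuffled
  folds <- lapply(seq_len(k), function(i) {
    list(test = shuffled[assign == i], train = shuffled[assign != i])
  })
  structure(list(k = k, subset_assignment = assign[source_ids], folds = folds,
                 seed = seed), class = "fold_plan")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
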