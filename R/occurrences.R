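#' Occurrence point set
#'
#' A thin data.frame subclass holding presence records: coordinates, an
#' optional stand (management-polygon) identifier, and a train/test partition
#' label used consistently across every candidate model.
#'
#' @param x,y numeric coordinates (map units).
#' @param stand_id optional identifier per point.
#' @param partition one of `"train"`, `"test"`, `"unassigned"` per point
#'   (recycled).
#' @return data.frame of class `"occurrence_set"` with columns `x`, `y`,
#'   `stand_id`, `partition`.
#' @export
occurrence_set <- function(x, y, stand_id = NA, partition = "unassigned") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  partition <- rep_len(as.character(partition), length(x))
  ok <- partition %in% c("train", "test", "unassigned")
  if (!all(ok))
    stop("invalid partition label(s): ",
         paste(unique(partition[!ok]), collapse = ", "))
  out <- data.frame(x = x, y = y, stand_id = rep_len(stand_id, length(x)),
                    partition = partition, stringsAsFactors = FALSE)
  class(out) <- c("occurrence_set", "data.frame")
  out
}

#' Read occurrence points from a delimited text file
#'
#' Comma-separated with a header row; coordinate column names configurable
#' (the conventional samples-file layout minus the species column). Rows with
#' missing or non-numeric coordinates raise an error naming the row.
#'
#' @param path CSV path.
#' @param x_col,y_col names of the coordinate columns.
#' @param stand_col optional name of a stand-identifier column.
#' @return an [occurrence_set()] with `partition = "unassigned"`.
#' @export
read_occurrences <- function(path, x_col = "x", y_col = "y",
                             stand_col = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cl in c(x_col, y_col))
    if (!cl %in% names(df))
      stop(sprintf("'%s': missing coordinate column '%s'", path, cl))
  if (nrow(df) == 0L) return(occurrence_set(numeric(0), numeric(0)))
  xs <- suppressWarnings(as.numeric(df[[x_col]]))
  ys <- suppressWarnings(as.numeric(df[[y_col]]))
  bad <- which(is.na(xs) | is.na(ys))
  if (length(bad))
    stop(sprintf("'%s': missing or non-numeric coordinates in data row(s) %s",
                 path, paste(bad, collapse = ", ")))
  sid <- if (!is.null(stand_col) && stand_col %in% names(df))
    df[[stand_col]] else NA
  occurrence_set(xs, ys, stand_id = sid)
}

#' Write occurrence points to CSV
#'
#' @param occ an [occurrence_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ), path, row.names = FALSE)
  invisible(path)
}
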