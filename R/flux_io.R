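# CSV + JSON-sidecar serialization of pH traces.

#' Write a pH trace to CSV with a JSON sidecar
#'
#' The CSV holds \code{time_s}, \code{value}, \code{value_kind}; events,
#' calibration points, and bath compositions go to \code{<path>.json}.
#'
#' @param trace a \code{ph_trace}.
#' @param path CSV output path.
#' @return The path, invisibly.
#' @export
write_ph_trace <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$time, value = trace$value,
                              value_kind = attr(trace, "value_kind")),
                   path, row.names = FALSE)
  side <- list(events = attr(trace, "events"),
               calibration = attr(trace, "calibration"),
               baths = attr(trace, "baths"))
  side <- side[!vapply(side, is.null, TRUE)]
  jsonlite::write_json(side, paste0(path, ".json"), dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pH trace written by \code{\link{write_ph_trace}}
#'
#' @param path CSV path (the \code{<path>.json} sidecar is read when
#'   present).
#' @return A \code{ph_trace}.
#' @export
read_ph_trace <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time_s", "value", "value_kind") %in% names(d)))
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path))
    jsonlite::read_json(side_path, simplifyVector = TRUE) else list()
  as_df <- function(x) if (is.null(x)) NULL else as.data.frame(x)
  ph_trace(d$time_s, d$value, value_kind = d$value_kind[1],
           events = as_df(side$events),
           calibration = as_df(side$calibration),
           baths = as_df(side$baths))
}
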