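#' Write replay traces to disk
#'
#' Two formats: a flat CSV (epoch, step, s, a, r, s_next) and JSON lines (one
#' epoch per line with its metadata and the list of replayed tuples).
#'
#' @param traces a trace tibble (column `trace` identifies the epoch).
#' @param path output file.
#' @param format "csv" or "jsonl".
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "csv") {
    out <- dplyr::select(tibble::as_tibble(traces), epoch = "trace", "step",
                         "s", "a", "r", "s_next")
    readr::write_csv(out, path)
  } else {
    modes <- attr(traces, "modes")
    con <- file(path, "w")
    on.exit(close(con))
    ids <- unique(traces$trace)
    for (k in seq_along(ids)) {
      tr <- traces[traces$trace == ids[k], ]
      obj <- list(
        epoch = ids[k],
        mode = if (!is.null(modes)) modes[k] else attr(traces, "mode_used"),
        init_kind = attr(traces, "init_kind"),
        stop_reason = attr(traces, "stop_reason"),
        steps = unname(Map(function(s, a, r, sn) list(s = s, a = a, r = r,
                                                      s_next = sn),
                           tr$s, tr$a, tr$r, tr$s_next))
      )
      writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' Export a Q-table to a tidy tibble / CSV
#'
#' @param q an `sfma_q`.
#' @param path optional CSV path.
#' @export
q_to_table <- function(q, path = NULL) {
  out <- tibble::tibble(
    state = rep(seq_len(nrow(q$values)), times = 4L),
    action = rep(colnames(q$values), each = nrow(q$values)),
    value = as.vector(q$values)
  )
  if (!is.null(path)) readr::write_csv(out, path)
  out
}
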