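# File formats: RFC-4180 CSV for trial tables and walks, JSON / TSV edge
# lists for graphs. Lines starting with '#' are treated as comments so
# pipeline outputs can carry their config hash and seed.

trial_table_columns <- c("subject_id", "trial", "stage", "node",
                         "target_combo", "rt_ms", "correct")

#' Read a serial-response trial table
#'
#' Strict CSV reader for the long-format behavioral schema: one row per
#' trial with columns `subject_id, trial, stage, node, target_combo,
#' rt_ms, correct` (optional `segment`, `violation_distance`, `graph`).
#' Validates types, the 0-14 node range, and that trials are contiguous
#' from 1 within each subject and stage; errors name the offending row.
#'
#' @param path CSV file path.
#' @return named list of per-subject data.frames.
#' @export
read_trial_table <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  require_columns(raw, trial_table_columns, path)
  if (any(bad <- !is.finite(raw$rt_ms) | raw$rt_ms <= 0)) {
    stop(path, ": non-positive rt_ms at row ", which(bad)[1])
  }
  if (any(bad <- raw$node < 0L | raw$node > 14L | raw$node != round(raw$node))) {
    stop(path, ": node outside 0..14 at row ", which(bad)[1])
  }
  raw$correct <- as.logical(raw$correct)
  if (anyNA(raw$correct)) {
    stop(path, ": unreadable `correct` flag at row ", which(is.na(raw$correct))[1])
  }
  grp <- paste(raw$subject_id, raw$stage)
  for (g in unique(grp)) {
    tr <- raw$trial[grp == g]
    if (!identical(as.integer(tr), seq_along(tr))) {
      stop(path, ": trials for subject/stage '", g,
           "' are not contiguous from 1 (first break at row ",
           which(grp == g)[which(as.integer(tr) != seq_along(tr))[1]], ")")
    }
  }
  split_subjects(raw)
}

#' Write a trial table (inverse of [read_trial_table()])
#'
#' @param x a trial data.frame, or a list of them (rows are concatenated).
#' @param path output CSV path.
#' @param header_comment optional `"# ..."` comment line written first.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(x, path, header_comment = NULL) {
  if (!is.data.frame(x)) x <- do.call(rbind, x)
  require_columns(x, trial_table_columns, "write_trial_table")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(header_comment, con)
  write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' Export / import a transition graph as JSON
#'
#' The JSON carries `name`, `n_nodes`, the 0-based edge list and optional
#' community labels; the import rebuilds the row-stochastic matrix through
#' [build_graph()].
#'
#' @param graph a `transition_graph`.
#' @param path JSON file path.
#' @return `graph_to_json`: `path` invisibly; `graph_from_json`: a
#'   `transition_graph`.
#' @export
graph_to_json <- function(graph, path) {
  stopifnot(inherits(graph, "transition_graph"))
  obj <- list(name = graph$name, n_nodes = graph$n_nodes,
              edges = lapply(seq_len(nrow(graph$edges)),
                             function(k) unname(graph$edges[k, ])),
              communities = graph$communities)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname graph_to_json
#' @export
graph_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  e <- if (is.matrix(obj$edges)) obj$edges else do.call(rbind, obj$edges)
  storage.mode(e) <- "integer"
  g <- build_graph("custom", edge_list = e, name = obj$name)
  if (!is.null(obj$communities) && length(obj$communities)) {
    g$communities <- as.integer(obj$communities)
  }
  g
}

#' Export / import a graph edge list as two-column TSV
#'
#' @param graph a `transition_graph`.
#' @param path TSV file path (columns `from`, `to`, 0-based).
#' @return `write_edge_list`: `path` invisibly; `read_edge_list`: a
#'   `transition_graph` built from the list.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "transition_graph"))
  write.table(graph$edges, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  e <- read.delim(path)
  build_graph("custom", edge_list = as.matrix(e))
}

#' Export / import a walk as CSV
#'
#' Columns `trial` (1-based), `node`, `segment`, `violation_distance`.
#'
#' @param walk a `walk_sequence`.
#' @param path CSV file path.
#' @param graph graph to attach on import (required to rebuild a full
#'   `walk_sequence`).
#' @return `write_walk_csv`: `path` invisibly; `read_walk_csv`: a
#'   `walk_sequence`.
#' @export
write_walk_csv <- function(walk, path) {
  stopifnot(inherits(walk, "walk_sequence"))
  write.csv(as.data.frame(walk), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_walk_csv
#' @export
read_walk_csv <- function(path, graph) {
  d <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  require_columns(d, c("trial", "node", "segment", "violation_distance"), path)
  new_walk_sequence(d$node, d$segment, d$violation_distance, graph, seed = NULL)
}
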