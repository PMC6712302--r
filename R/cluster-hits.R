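#' Load a 12-column similarity hit table
#'
#' Reads BLAST `-outfmt 6`-style tabular hits and applies the E-value cutoff
#' (default 1e-5, the all-vs-all search cutoff): rows with `evalue` above the
#' cutoff are dropped. Self-hits are retained but flagged. Malformed rows
#' (wrong column count) are counted and reported as an attribute; a file
#' where more than 1% of rows are malformed is rejected.
#'
#' @param path Path to the tabular file (no header).
#' @param evalue_cutoff Keep rows with `evalue <= evalue_cutoff`.
#' @return Tibble of hits (`qseqid`, `sseqid`, `pident`, `length`,
#'   `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`, `evalue`,
#'   `bitscore`, `self_hit`), with attributes `n_dropped_evalue` and
#'   `n_malformed`.
#' @export
load_hits <- function(path, evalue_cutoff = 1e-5) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read hits file `%s`", path), call. = FALSE)
  }
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty hits file: ", path, call. = FALSE)
    out <- as_tibble(setNames(
      c(list(character(0), character(0)), rep(list(numeric(0)), 10)), cols))
    out$self_hit <- logical(0)
    attr(out, "n_dropped_evalue") <- 0L
    attr(out, "n_malformed") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) == 12L
  n_bad <- sum(!ok)
  if (n_bad > 0.01 * length(lines)) {
    stop(sprintf("hits file `%s`: %d of %d rows are not 12-column",
                 path, n_bad, length(lines)), call. = FALSE)
  }
  m <- do.call(rbind, fields[ok])
  out <- tibble(
    qseqid = m[, 1], sseqid = m[, 2],
    pident = as.numeric(m[, 3]), length = as.integer(m[, 4]),
    mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12])
  )
  n_total <- nrow(out)
  out <- filter(out, .data$evalue <= evalue_cutoff)
  out$self_hit <- out$qseqid == out$sseqid
  attr(out, "n_dropped_evalue") <- n_total - nrow(out)
  attr(out, "n_malformed") <- n_bad
  out
}

#' Build the undirected ortholog similarity graph from hits
#'
#' Edge weight between two proteins is the mean bitscore of the reciprocal
#' hit pair when both directions are present, else the single direction's
#' bitscore; self-loops are removed. Proteins listed in `proteins` but
#' hitting nothing are kept as isolated singleton nodes. Optionally restricts
#' edges to reciprocal best hits (`bbh_filter = TRUE`).
#'
#' @param hits Tibble from [load_hits()] (or [emit_hits()]).
#' @param proteins Optional character vector (or tibble with `protein_id`) of
#'   all proteins to include as nodes; hits referencing proteins outside this
#'   index raise a warning but are kept.
#' @param bbh_filter Keep only reciprocal-best-hit edges (default FALSE).
#' @return An object of class `ortho_graph`: list with `edges` (tibble
#'   `from`, `to`, `weight`) and `nodes` (character vector).
#' @export
build_graph <- function(hits, proteins = NULL, bbh_filter = FALSE) {
  if (is.data.frame(proteins)) proteins <- proteins$protein_id
  h <- filter(hits, .data$qseqid != .data$sseqid)
  if (!is.null(proteins)) {
    missing <- setdiff(unique(c(h$qseqid, h$sseqid)), proteins)
    if (length(missing)) {
      warning(sprintf("%d hit proteins absent from the proteome index (e.g. %s); edges kept",
                      length(missing), missing[1]), call. = FALSE)
    }
  }
  if (bbh_filter && nrow(h) > 0) {
    best <- h |>
      group_by(.data$qseqid) |>
      filter(.data$bitscore == max(.data$bitscore)) |>
      ungroup()
    key <- paste(best$qseqid, best$sseqid)
    rev_key <- paste(best$sseqid, best$qseqid)
    h <- best[rev_key %in% key, ]
  }
  edges <- h |>
    mutate(from = pmin(.data$qseqid, .data$sseqid),
           to = pmax(.data$qseqid, .data$sseqid)) |>
    group_by(.data$from, .data$to) |>
    summarise(weight = mean(.data$bitscore), .groups = "drop")
  edges <- filter(edges, .data$weight > 0)
  nodes <- sort(unique(c(edges$from, edges$to, proteins,
                         hits$qseqid, hits$sseqid)))
  structure(list(edges = edges, nodes = nodes), class = "ortho_graph")
}

#' @export
print.ortho_graph <- function(x, ...) {
  cat(sprintf("<ortho_graph> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}
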