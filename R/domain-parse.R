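#' Parse a HMMER3 per-domain table (domtblout layout)
#'
#' Whitespace-delimited `hmmscan --domtblout` rows; comment lines (leading
#' `#`) are ignored. Hits with independent E-value above `evalue_cutoff`
#' (default 1e-2, the Pfam-scan analysis cutoff) are dropped.
#'
#' @param path Path to the domtblout file.
#' @param evalue_cutoff Keep rows with `i_evalue <= evalue_cutoff`.
#' @param proteins Optional tibble (`protein_id`, `taxon_id`) used to attach
#'   the taxon of each protein; without it, `taxon_id` is the text before the
#'   first `|` of the protein id.
#' @return Tibble of domain hits: `protein_id`, `taxon_id`, `domain_name`,
#'   `domain_accession`, `i_evalue`, `score`, `env_start`, `env_end`.
#' @export
parse_domtbl <- function(path, evalue_cutoff = 1e-2, proteins = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read domtblout file `%s`", path), call. = FALSE)
  }
  lines <- readr::read_lines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(tibble(protein_id = character(0), taxon_id = character(0),
                  domain_name = character(0), domain_accession = character(0),
                  i_evalue = numeric(0), score = numeric(0),
                  env_start = integer(0), env_end = integer(0)))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) < 22L)
  if (length(bad)) {
    stop(sprintf("malformed domtblout row at data line %d (%d fields, expected >= 22)",
                 bad[1], length(fields[[bad[1]]])), call. = FALSE)
  }
  m <- t(vapply(fields, function(f) f[1:22], character(22)))
  out <- tibble(
    protein_id = m[, 4],
    domain_name = m[, 1],
    domain_accession = m[, 2],
    i_evalue = as.numeric(m[, 13]),
    score = as.numeric(m[, 14]),
    env_start = as.integer(m[, 20]),
    env_end = as.integer(m[, 21])
  )
  if (anyNA(out$i_evalue) || anyNA(out$env_start)) {
    stop("malformed domtblout: non-numeric E-value or envelope coordinate",
         call. = FALSE)
  }
  out <- filter(out, .data$i_evalue <= evalue_cutoff)
  if (!is.null(proteins)) {
    out$taxon_id <- proteins$taxon_id[match(out$protein_id, proteins$protein_id)]
  } else {
    out$taxon_id <- sub("\\|.*$", "", out$protein_id)
  }
  select(out, "protein_id", "taxon_id", "domain_name", "domain_accession",
         "i_evalue", "score", "env_start", "env_end")
}

#' Read a taxon-to-lineage-group map
#'
#' Two-column TSV (`taxon_id`, `group`), groups drawn from: `recipient`,
#' `outgroup`, `other_fungi`, `animal`, `plant`, `bacteria`, `archaea`,
#' `protist`.
#'
#' @param path Path to the TSV (header required).
#' @return Tibble (`taxon_id`, `group`).
#' @export
read_lineage_map <- function(path) {
  lineage <- readr::read_tsv(path, show_col_types = FALSE)
  validate_lineage(lineage)
}

validate_lineage <- function(lineage) {
  allowed <- c("recipient", "outgroup", "other_fungi", "animal", "plant",
               "bacteria", "archaea", "protist")
  if (!all(c("taxon_id", "group") %in% names(lineage))) {
    stop("lineage map needs columns `taxon_id` and `group`", call. = FALSE)
  }
  bad <- setdiff(unique(lineage$group), allowed)
  if (length(bad)) {
    stop(sprintf("unknown lineage group(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(lineage$taxon_id)) {
    stop("each taxon must be assigned exactly one group", call. = FALSE)
  }
  if (!any(lineage$group == "recipient") || !any(lineage$group == "outgroup")) {
    stop("lineage map must contain at least one recipient and one outgroup taxon",
         call. = FALSE)
  }
  as_tibble(lineage[c("taxon_id", "group")])
}
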