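#' Per-protein ordered domain architectures
#'
#' Orders each protein's domain hits by envelope start. Overlapping
#' envelopes of the *same* domain are merged (their union envelope is kept);
#' overlapping envelopes of different domains are both kept, ordered by
#' start.
#'
#' @param hits Domain-hit tibble from [parse_domtbl()].
#' @return Tibble: `protein_id`, `domain_name`, `env_start`, `env_end`,
#'   `position` (1-based order along the protein).
#' @export
architectures <- function(hits) {
  if (nrow(hits) == 0L) {
    return(tibble(protein_id = character(0), domain_name = character(0),
                  env_start = integer(0), env_end = integer(0),
                  position = integer(0)))
  }
  merged <- hits |>
    arrange(.data$protein_id, .data$domain_name, .data$env_start) |>
    group_by(.data$protein_id, .data$domain_name) |>
    mutate(.grp = cumsum(
      .data$env_start > dplyr::lag(cummax(.data$env_end), default = -1L))) |>
    group_by(.data$protein_id, .data$domain_name, .data$.grp) |>
    summarise(env_start = min(.data$env_start),
              env_end = max(.data$env_end), .groups = "drop") |>
    select(-".grp")
  merged |>
    arrange(.data$protein_id, .data$env_start, .data$domain_name) |>
    group_by(.data$protein_id) |>
    mutate(position = row_number()) |>
    ungroup()
}

#' Detect foreign/native domain fusions
#'
#' Flags proteins that carry at least one foreign-classified domain *and* at
#' least one native-classified domain — the architecture signature arguing
#' that a transferred domain truly resides in the recipient genome (e.g.
#' eukaryotic domains fused 3' of a bacterium-derived domain). For every
#' (foreign, native) domain pair on a protein the native domain's position
#' relative to the foreign domain (5' or 3') is recorded.
#'
#' @param arch Architecture tibble from [architectures()].
#' @param foreign_domains Character vector of foreign-classified domain names
#'   (e.g. the `unique_recipient` domains from [classify_domains()]).
#' @param native_domains Character vector of native-classified domain names
#'   (e.g. the `shared` domains).
#' @return Tibble: `protein_id`, `foreign_domain`, `native_domain`,
#'   `native_side` (`"5prime"` or `"3prime"`).
#' @export
detect_fusions <- function(arch, foreign_domains, native_domains) {
  f <- filter(arch, .data$domain_name %in% foreign_domains)
  n <- filter(arch, .data$domain_name %in% native_domains)
  if (nrow(f) == 0L || nrow(n) == 0L) {
    return(tibble(protein_id = character(0), foreign_domain = character(0),
                  native_domain = character(0), native_side = character(0)))
  }
  pairs <- inner_join(
    select(f, "protein_id", foreign_domain = "domain_name",
           f_start = "env_start"),
    select(n, "protein_id", native_domain = "domain_name",
           n_start = "env_start"),
    by = "protein_id", relationship = "many-to-many"
  )
  pairs |>
    mutate(native_side = ifelse(.data$n_start > .data$f_start,
                                "3prime", "5prime")) |>
    select("protein_id", "foreign_domain", "native_domain", "native_side") |>
    distinct() |>
    arrange(.data$protein_id, .data$foreign_domain, .data$native_domain)
}
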