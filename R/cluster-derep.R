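#' Dereplicate near-identical sequences (CD-HIT-style)
#'
#' Greedy longest-first clustering: sequences are processed in order of
#' decreasing length (ties broken by id), and each sequence joins the first
#' existing representative with global identity above `identity` (default
#' 0.90, the >90% redundancy threshold used for transcriptome variants);
#' otherwise it founds a new cluster. Identity follows the CD-HIT
#' convention: matches in a global alignment (match = 1, mismatch = 0,
#' gap = -1) divided by the shorter sequence's length. An exact-word
#' prescreen skips representatives that cannot reach the threshold.
#'
#' @param sequences Named character vector, or tibble with `protein_id`,
#'   `sequence`.
#' @param identity Identity threshold in (0, 1); a sequence joins a cluster
#'   only if identity is strictly greater.
#' @return An object of class `derep_result`: list with `representatives`
#'   (named character vector) and `members` (tibble `representative`,
#'   `protein_id`, `identity`).
#' @examples
#' dereplicate(c(a = "ACDEFGHIKLACDEFGHIKLACDEFGHIKL",
#'               b = "ACDEFGHIKLACDEFGHIKLACDEFGHIKL",
#'               c = "YYYYYYYYYYWWWWWWWWWWYYYYYYYYYY"))
#' @export
dereplicate <- function(sequences, identity = 0.90) {
  if (is.data.frame(sequences)) {
    sequences <- setNames(sequences$sequence, sequences$protein_id)
  }
  if (identity <= 0 || identity >= 1) {
    stop_config("derep_identity", "must be in (0, 1)")
  }
  if (length(sequences) == 0L) {
    return(structure(
      list(representatives = character(0),
           members = tibble(representative = character(0),
                            protein_id = character(0),
                            identity = numeric(0))),
      class = "derep_result"
    ))
  }
  ord <- order(-nchar(sequences), names(sequences))
  ids <- names(sequences)[ord]
  seqs <- unname(sequences[ord])
  lens <- nchar(seqs)

  words <- lapply(seqs, function(s) {
    n <- nchar(s)
    k <- 6L
    if (n < k) return(character(0))
    starts <- seq(1L, n - k + 1L, by = 3L)
    unique(paste0(starts, ":", substring(s, starts, starts + k - 1L)))
  })

  sub_mat <- derep_submat()
  rep_idx <- integer(0)
  assigned_rep <- integer(length(seqs))
  assigned_id <- numeric(length(seqs))
  for (i in seq_along(seqs)) {
    hit <- 0L
    hit_id <- 0
    if (length(rep_idx)) {
      shared <- vapply(rep_idx, function(r) {
        any(words[[i]] %in% words[[r]])
      }, logical(1))
      cand <- rep_idx[shared]
      if (length(cand)) {
        aln <- Biostrings::pairwiseAlignment(
          pattern = Biostrings::AAStringSet(seqs[cand]),
          subject = seqs[i],
          substitutionMatrix = sub_mat,
          gapOpening = 0, gapExtension = 1, type = "global"
        )
        idents <- Biostrings::nmatch(aln) / pmin(lens[cand], lens[i])
        best <- which.max(idents)
        if (idents[best] > identity) {
          hit <- cand[best]
          hit_id <- idents[best]
        }
      }
    }
    if (hit > 0L) {
      assigned_rep[i] <- hit
      assigned_id[i] <- hit_id
    } else {
      rep_idx <- c(rep_idx, i)
      assigned_rep[i] <- i
      assigned_id[i] <- 1
    }
  }
  members <- tibble(
    representative = ids[assigned_rep],
    protein_id = ids,
    identity = round(assigned_id, 4)
  )
  structure(
    list(representatives = setNames(seqs[rep_idx], ids[rep_idx]),
         members = arrange(members, .data$representative, .data$protein_id)),
    class = "derep_result"
  )
}

derep_submat <- function() {
  letters25 <- c(AA_ALPHABET, "B", "J", "O", "U", "X", "Z", "*", "-", "+", ".")
  m <- matrix(0, length(letters25), length(letters25),
              dimnames = list(letters25, letters25))
  diag(m) <- 1
  m
}

#' @export
print.derep_result <- function(x, ...) {
  cat(sprintf("<derep_result> %d sequences -> %d representatives\n",
              nrow(x$members), length(x$representatives)))
  invisible(x)
}

#' @export
tidy.derep_result <- function(x, ...) x$members
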