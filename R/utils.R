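# Internal helpers shared across modules.

AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched, so pipeline stages are individually reproducible.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation; keeps results < 2^31 for R's RNG.
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 7919L + as.integer(offset)) %% 2147483587L
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

# Ungapped identity between two co-linear sequences (character strings):
# matches over the common prefix. Returns c(matches, aln_length).
prefix_matches <- function(a_raw, b_raw) {
  m <- min(length(a_raw), length(b_raw))
  if (m == 0L) return(c(0L, 0L))
  c(sum(a_raw[seq_len(m)] == b_raw[seq_len(m)]), m)
}

# Sampled seed words (exact k-mers at fixed positions) used to prescreen
# candidate pairs before identity computation, analogous to word seeding in
# BLAST-family tools: pairs sharing no word at any sampled position are
# assumed unrelated. Sensitivity: for pairwise identity q the chance a given
# word survives is q^k; with words every `stride` positions the miss
# probability is (1 - q^k)^(L/stride), negligible above ~65% identity for
# k = 6, stride = 3, L >= 100.
seed_words <- function(seqs, k = 6L, stride = 3L) {
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    n <- nchar(s)
    if (n < k) {
      out[[i]] <- character(0)
      next
    }
    starts <- seq(1L, n - k + 1L, by = stride)
    out[[i]] <- paste0(starts, ":", substring(s, starts, starts + k - 1L))
  }
  out
}

# Candidate unordered pairs (i < j as integer indices) sharing >= 1 seed word.
candidate_pairs <- function(seqs, k = 6L, stride = 3L, max_bucket = 5000L) {
  words <- seed_words(seqs, k = k, stride = stride)
  id <- rep.int(seq_along(seqs), lengths(words))
  buckets <- split(id, unlist(words, use.names = FALSE))
  buckets <- buckets[lengths(buckets) >= 2L & lengths(buckets) <= max_bucket]
  if (length(buckets) == 0L) {
    return(matrix(integer(0), ncol = 2L))
  }
  n <- length(seqs)
  enc <- unlist(lapply(buckets, function(b) {
    b <- sort.int(unique.default(b))
    if (length(b) < 2L) return(numeric(0))
    cmb <- utils::combn(b, 2L)
    cmb[1L, ] * n + cmb[2L, ]
  }), use.names = FALSE)
  enc <- unique.default(enc)
  i <- floor(enc / n)
  j <- enc - i * n
  fix <- j == 0
  if (any(fix)) {
    i[fix] <- i[fix] - 1
    j[fix] <- n
  }
  cbind(as.integer(i), as.integer(j))
}
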