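#' Approximately unbiased (AU) topology test via multiscale RELL bootstrap
#'
#' For each scale factor `r`, `nboot` RELL replicates resample site columns
#' (with replacement) to size `ceiling(r * n)` and record how often each
#' topology attains the highest resampled log-likelihood (ties broken at
#' random). The bootstrap proportion curve of each topology is converted to
#' normal quantiles `z(r) = qnorm(1 - BP(r))` and fitted by weighted least
#' squares to `z(r) = d * sqrt(r) + c / sqrt(r)`; the AU p-value is
#' `1 - pnorm(d - c)`. A topology that never (or always) wins at every
#' scale carries no curvature information and is assigned p = 0 (or 1) and
#' flagged degenerate — the standard boundary behaviour.
#'
#' @param site_ll Matrix `[topology x site]` of per-site log-likelihoods
#'   (e.g. from [site_loglik_matrix()]); at least 2 topologies, 10 sites.
#' @param nboot RELL replicates per scale (default 1000).
#' @param scales Scale factors (default `seq(0.5, 1.4, by = 0.1)`).
#' @param seed Integer seed (required for reproducibility).
#' @return Object of class `au_result`: list with `table` (tibble:
#'   `topology`, `p_au`, `d`, `c`, `degenerate`), `bp` (topology x scale
#'   bootstrap proportions), `scales`, `nboot`, `seed`.
#' @examples
#' ll <- rbind(t1 = rnorm(50), t2 = rnorm(50))
#' au_test(ll, nboot = 200, seed = 1)$table
#' @export
au_test <- function(site_ll, nboot = 1000L, scales = seq(0.5, 1.4, by = 0.1),
                    seed = 1L) {
  stopifnot(is.matrix(site_ll))
  if (nrow(site_ll) < 2L) stop("need at least 2 topologies", call. = FALSE)
  if (ncol(site_ll) < 10L) stop("need at least 10 sites", call. = FALSE)
  if (any(!is.finite(site_ll))) {
    stop("site log-likelihoods must be finite", call. = FALSE)
  }
  K <- nrow(site_ll)
  n <- ncol(site_ll)
  topo <- rownames(site_ll) %||% paste0("topology", seq_len(K))
  wins <- matrix(0L, K, length(scales), dimnames = list(topo, scales))
  with_seed(seed, {
    for (s in seq_along(scales)) {
      m <- ceiling(scales[s] * n)
      counts <- stats::rmultinom(nboot, size = m, prob = rep(1 / n, n))
      tot <- site_ll %*% counts  # K x nboot resampled log-likelihoods
      for (b in seq_len(nboot)) {
        mx <- which(tot[, b] >= max(tot[, b]) - 1e-12)
        w <- if (length(mx) > 1L) sample(mx, 1L) else mx
        wins[w, s] <- wins[w, s] + 1L
      }
    }
  })
  bp <- wins / nboot
  fit_one <- function(k) {
    usable <- wins[k, ] > 0L & wins[k, ] < nboot
    if (sum(usable) < 2L) {
      p <- if (mean(bp[k, ]) > 0.5) 1 else 0
      return(tibble(topology = topo[k], p_au = p, d = NA_real_, c = NA_real_,
                    degenerate = TRUE))
    }
    r <- scales[usable]
    z <- qnorm(1 - bp[k, usable])
    w <- nboot * dnorm(z)^2 / (bp[k, usable] * (1 - bp[k, usable]))
    X <- cbind(sqrt(r), 1 / sqrt(r))
    coefs <- solve(crossprod(X, w * X), crossprod(X, w * z))
    p <- 1 - pnorm(coefs[1] - coefs[2])
    tibble(topology = topo[k], p_au = min(max(p, 0), 1),
           d = coefs[1], c = coefs[2], degenerate = FALSE)
  }
  table <- bind_rows(lapply(seq_len(K), fit_one))
  structure(
    list(table = table, bp = bp, scales = scales, nboot = nboot, seed = seed,
         n_sites = n),
    class = "au_result"
  )
}

#' @export
print.au_result <- function(x, ...) {
  cat(sprintf("<au_result> %d topologies, %d sites resampled at %d scales, B = %d\n",
              nrow(x$table), x$n_sites, length(x$scales), x$nboot))
  print(x$table)
  invisible(x)
}

#' @export
tidy.au_result <- function(x, ...) x$table

#' @export
glance.au_result <- function(x, ...) {
  tibble(
    n_topologies = nrow(x$table),
    n_scales = length(x$scales),
    nboot = x$nboot,
    best_topology = x$table$topology[which.max(x$table$p_au)],
    min_p_au = min(x$table$p_au)
  )
}

#' Bootstrap-proportion curves behind an AU test
#'
#' One line per topology: bootstrap proportion against the resampling scale
#' factor. Flat curves near 0.5 indicate indistinguishable topologies;
#' curves pinned at 0 indicate clear rejection.
#'
#' @param object An `au_result`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.au_result <- function(object, ...) {
  df <- as_tibble(as.table(object$bp), .name_repair = "minimal")
  names(df) <- c("topology", "scale", "bp")
  df$scale <- as.numeric(as.character(df$scale))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scale, y = .data$bp,
                                   colour = .data$topology)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "resampling scale r", y = "bootstrap proportion",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
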