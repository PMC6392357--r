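# Size-controlled comparison of the observation web against randomized
# subwebs of the molecular web, and rare-link pruning.

#' Sample a random induced subweb
#'
#' Uniformly samples row and column subsets without replacement and
#' takes the induced submatrix, rejection-resampling until no all-zero
#' row or column remains, so the requested node counts are kept exact.
#'
#' @param mol molecular web (count matrix).
#' @param n_insects,n_plants requested row and column counts.
#' @param max_tries rejection cap before erroring.
#' @return The induced `bipartite_web` submatrix.
#' @export
sample_subweb <- function(mol, n_insects, n_plants, max_tries = 10000) {
  if (n_insects > nrow(mol) || n_plants > ncol(mol)) {
    stopf("requested subweb (%d x %d) exceeds the molecular web (%d x %d)",
          n_insects, n_plants, nrow(mol), ncol(mol))
  }
  for (t in seq_len(max_tries)) {
    ri <- sort(sample.int(nrow(mol), n_insects))
    ci <- sort(sample.int(ncol(mol), n_plants))
    sub <- mol[ri, ci, drop = FALSE]
    if (all(rowSums(sub) > 0) && all(colSums(sub) > 0)) {
      attr(sub, "level") <- attr(mol, "level")
      return(sub)
    }
  }
  stopf("no subweb without empty rows/columns in %d draws; request a smaller size",
        max_tries)
}

#' Null envelope of metrics from randomized subwebs
#'
#' Draws `n_draws` random subwebs of the molecular web matched to the
#' observation web's insect and plant node counts, computes the metric
#' set on each, and reports the null mean, the percentile 95% interval,
#' and whether each observed metric falls outside it.
#'
#' @param obs observation web (its metrics are the observed values).
#' @param mol molecular web to subsample.
#' @param n_draws number of randomized subwebs (default 1000).
#' @param seed integer seed; the envelope is fully reproducible.
#' @param metrics metric names passed to [metric_set()].
#' @param n_restarts modularity restarts per subweb.
#' @param ci percentile interval coverage (default 0.95).
#' @return List of class `null_envelope` with `table` (metric, observed,
#'   null mean, CI bounds, outside flag, NA count), `n_draws`, `seed`.
#' @export
null_envelope <- function(obs, mol, n_draws = 1000, seed = 1,
                          metrics = c("h2_prime", "interaction_evenness",
                                      "generality_qual", "vulnerability_qual",
                                      "generality_quant", "vulnerability_quant",
                                      "nodf_qual", "nodf_quant",
                                      "modularity_q"),
                          n_restarts = 5, ci = 0.95) {
  observed <- metric_set(obs, seed = seed, n_restarts = n_restarts,
                         metrics = metrics)
  draws <- matrix(NA_real_, n_draws, length(metrics),
                  dimnames = list(NULL, metrics))
  with_seed(seed, {
    for (d in seq_len(n_draws)) {
      sub <- sample_subweb(mol, nrow(obs), ncol(obs))
      mseed <- sample.int(.Machine$integer.max - 1, 1)
      draws[d, ] <- metric_set(sub, seed = mseed, n_restarts = n_restarts,
                               metrics = metrics)
    }
  })
  alpha <- (1 - ci) / 2
  tab <- do.call(rbind, lapply(metrics, function(m) {
    x <- draws[, m]
    n_na <- sum(is.na(x))
    x <- x[!is.na(x)]
    if (!length(x)) {
      return(data.frame(metric = m, observed = observed[[m]],
                        null_mean = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, outside_ci = NA, n_na = n_na))
    }
    qs <- stats::quantile(x, c(alpha, 1 - alpha), names = FALSE, type = 7)
    data.frame(metric = m, observed = observed[[m]], null_mean = mean(x),
               ci_lower = qs[1], ci_upper = qs[2],
               outside_ci = !is.na(observed[[m]]) &&
                 (observed[[m]] < qs[1] || observed[[m]] > qs[2]),
               n_na = n_na)
  }))
  bad <- tab$metric[tab$n_na > 0.05 * n_draws]
  if (length(bad)) {
    warning(sprintf("metrics NA in >5%% of draws: %s (NA draws excluded)",
                    paste(bad, collapse = ", ")))
  }
  structure(list(table = tab, n_draws = n_draws, seed = seed, ci = ci),
            class = "null_envelope")
}

#' @export
print.null_envelope <- function(x, ...) {
  cat(sprintf("Null envelope: %d randomized subwebs (seed %d, %.0f%% CI)\n",
              x$n_draws, x$seed, 100 * x$ci))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Remove low-frequency links from a web
#'
#' Sets cells with counts at or below `max_count` to zero and drops the
#' resulting all-zero rows and columns.
#'
#' @param web count matrix.
#' @param max_count largest count treated as a rare link (default 2).
#' @return The pruned `bipartite_web`, with attributes
#'   `n_links_removed` and `n_nodes_removed`.
#' @export
prune_rare_links <- function(web, max_count = 2) {
  pruned <- unclass(web)
  removed <- pruned > 0 & pruned <= max_count
  pruned[removed] <- 0L
  keep_r <- rowSums(pruned) > 0
  keep_c <- colSums(pruned) > 0
  if (!any(keep_r) || !any(keep_c)) {
    stopf("pruning at max_count = %d removed every link", max_count)
  }
  out <- pruned[keep_r, keep_c, drop = FALSE]
  attr(out, "level") <- attr(web, "level")
  attr(out, "n_links_removed") <- sum(removed)
  attr(out, "n_nodes_removed") <- sum(!keep_r) + sum(!keep_c)
  class(out) <- c("bipartite_web", class(out))
  out
}

#' Serialize a null envelope to JSON
#'
#' @param env a [null_envelope()] result.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_envelope <- function(env, path) {
  jsonlite::write_json(
    list(n_draws = env$n_draws, seed = env$seed, ci = env$ci,
         table = env$table),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(path)
}
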