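# Bipartite network metric suite: H2' specialization, interaction
# evenness, qualitative/quantitative generality and vulnerability,
# NODF / weighted NODF nestedness, and Barber bipartite modularity
# maximized by weighted label propagation with agglomerative refinement.

degenerate_web <- function(web) {
  is.null(dim(web)) || nrow(web) < 2 || ncol(web) < 2 || sum(web) <= 0
}

# ---------------------------------------------------------------------
# H2' specialization

# enumerate all non-negative integer matrices with the given margins,
# tracking min and max Shannon entropy; aborts (returns NULL) past `cap`
# tables
entropy_bounds_exhaustive <- function(rs, cs, cap = 2e5) {
  nr <- length(rs)
  nc <- length(cs)
  count <- 0L
  hmin <- Inf
  hmax <- -Inf
  total <- sum(rs)
  rec_row <- function(i, cs_left, cells) {
    if (count > cap) return(FALSE)
    if (i > nr) {
      count <<- count + 1L
      h <- shannon(cells)
      if (h < hmin) hmin <<- h
      if (h > hmax) hmax <<- h
      return(TRUE)
    }
    # enumerate compositions of rs[i] over nc cells bounded by cs_left
    comp <- function(j, left, acc) {
      if (count > cap) return(FALSE)
      if (j == nc) {
        if (left > cs_left[nc]) return(TRUE)
        return(rec_row(i + 1, cs_left - c(acc, left), c(cells, acc, left)))
      }
      for (v in 0:min(left, cs_left[j])) {
        if (!comp(j + 1, left - v, c(acc, v))) return(FALSE)
      }
      TRUE
    }
    comp(1, rs[i], integer())
  }
  ok <- rec_row(1, cs, integer())
  if (!ok || count == 0) return(NULL)
  list(hmin = hmin, hmax = hmax)
}

# greedy mass-concentration heuristic for the minimum-entropy filling:
# repeatedly place as much weight as possible in a single cell
entropy_min_greedy <- function(rs, cs) {
  cells <- numeric()
  while (sum(rs) > 1e-9) {
    i <- which.max(rs)
    j <- which.max(cs)
    m <- min(rs[i], cs[j])
    cells <- c(cells, m)
    rs[i] <- rs[i] - m
    cs[j] <- cs[j] - m
  }
  shannon(cells)
}

#' H2' network-level specialization
#'
#' Standardized two-dimensional Shannon entropy of the interaction
#' matrix: H2' = (H2max - H2) / (H2max - H2min), where the bounds are
#' taken over interaction matrices with the observed marginal totals.
#' For small integer webs (up to 4 x 4 with a modest table space) the
#' bounds are found by exhaustive enumeration; otherwise H2max is the
#' independence (outer-product) entropy and H2min comes from a greedy
#' mass-concentration heuristic. 1 denotes maximal specialization, 0 the
#' neutral configuration expected from the marginals alone.
#'
#' @param web non-negative interaction matrix (at least 2 x 2).
#' @return Value in \[0, 1\], or `NA` for degenerate webs.
#' @export
h2_prime <- function(web) {
  if (degenerate_web(web)) return(NA_real_)
  total <- sum(web)
  p <- web / total
  h2 <- shannon(p)
  rs <- rowSums(web)
  cs <- colSums(web)
  h_indep <- shannon(rs) + shannon(cs)

  integerish <- max(abs(web - round(web))) < 1e-9
  bounds <- NULL
  if (integerish && nrow(web) <= 4 && ncol(web) <= 4) {
    # cheap upper bound on the enumeration work (compositions per row);
    # enumerate only when the table space is genuinely small
    work <- prod(choose(round(rs) + ncol(web) - 1, ncol(web) - 1))
    if (is.finite(work) && work <= 2e4) {
      bounds <- entropy_bounds_exhaustive(round(rs), round(cs))
    }
  }
  if (!is.null(bounds) && bounds$hmax - bounds$hmin > 1e-12) {
    hmax <- bounds$hmax
    hmin <- bounds$hmin
  } else {
    hmax <- h_indep
    hmin <- min(entropy_min_greedy(rs, cs), h2)
  }
  if (hmax - hmin < 1e-12) return(NA_real_)
  min(1, max(0, (hmax - h2) / (hmax - hmin)))
}

# ---------------------------------------------------------------------
# evenness and partner diversity

#' Shannon interaction evenness
#'
#' Shannon entropy of the interaction proportions scaled by its maximum;
#' by default the denominator is log(R x C) (all cells), switchable to
#' log of the number of realized links.
#'
#' @param web non-negative interaction matrix.
#' @param denominator `"cells"` (log(R*C), default) or `"links"`
#'   (log of nonzero cells).
#' @return Value in \[0, 1\], or `NA` for degenerate webs.
#' @export
interaction_evenness <- function(web, denominator = c("cells", "links")) {
  denominator <- match.arg(denominator)
  if (degenerate_web(web)) return(NA_real_)
  h <- shannon(web)
  denom <- switch(denominator,
    cells = log(nrow(web) * ncol(web)),
    links = log(sum(web > 0))
  )
  if (denom <= 0) return(NA_real_)
  h / denom
}

#' Generality / vulnerability: mean (effective) partner counts
#'
#' Qualitative: the mean number of partners per node on the binary web.
#' Quantitative: the mean effective number of partners, exp of the
#' node's interaction entropy, weighted by the node's share of the
#' total interaction weight.
#'
#' @param web non-negative interaction matrix.
#' @param axis `"rows"` (insects: generality) or `"columns"` (plants:
#'   vulnerability).
#' @param weighted logical; effective (weighted) or raw partner counts.
#' @return Mean partner count, or `NA` for degenerate webs.
#' @export
partner_diversity <- function(web, axis = c("rows", "columns"),
                              weighted = FALSE) {
  axis <- match.arg(axis)
  if (degenerate_web(web)) return(NA_real_)
  m <- if (axis == "rows") web else t(web)
  tot <- rowSums(m)
  keep <- tot > 0
  m <- m[keep, , drop = FALSE]
  tot <- tot[keep]
  if (weighted) {
    eff <- vapply(seq_len(nrow(m)), function(i) exp(shannon(m[i, ])),
                  numeric(1))
    sum(tot / sum(tot) * eff)
  } else {
    mean(rowSums(m > 0))
  }
}

# ---------------------------------------------------------------------
# NODF nestedness

nodf_pairs <- function(m, weighted) {
  # rows assumed sorted by decreasing fill; vectorized over the pairs of
  # each leading row
  fill <- rowSums(m > 0)
  n <- nrow(m)
  if (n < 2) return(numeric())
  vals <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    jj <- (i + 1):n
    mj <- m[jj, , drop = FALSE]
    mi <- matrix(m[i, ], length(jj), ncol(m), byrow = TRUE)
    cnt <- if (weighted) rowSums(mj > 0 & mj < mi) else rowSums(mj > 0 & mi > 0)
    v <- 100 * cnt / fill[jj]
    v[fill[i] <= fill[jj] | fill[jj] == 0 | fill[i] == 0] <- 0
    vals[[i]] <- v
  }
  unlist(vals)
}

#' NODF / weighted NODF nestedness
#'
#' Paired-overlap nestedness with decreasing fill, averaged over all row
#' pairs and column pairs, on the 0-100 scale. Rows and columns are
#' first sorted into the canonical order (decreasing fill; in the
#' weighted variant ties broken by decreasing marginal totals, then
#' original index), so the value is invariant to input permutation. A
#' pair contributes only when fill strictly decreases; the weighted
#' score counts cells where the poorer node's weight is positive but
#' strictly below the richer node's.
#'
#' @param web non-negative interaction matrix.
#' @param weighted logical; weighted (WNODF) or binary NODF.
#' @return Value in \[0, 100\], or `NA` for degenerate webs.
#' @export
nodf <- function(web, weighted = FALSE) {
  if (degenerate_web(web)) return(NA_real_)
  m <- unclass(web)
  bin <- (m > 0) * 1
  if (weighted) {
    m <- m[order(rowSums(bin), rowSums(m), decreasing = TRUE),
           order(colSums(bin), colSums(m), decreasing = TRUE), drop = FALSE]
  } else {
    m <- bin[order(rowSums(bin), decreasing = TRUE),
             order(colSums(bin), decreasing = TRUE), drop = FALSE]
  }
  vals <- c(nodf_pairs(m, weighted), nodf_pairs(t(m), weighted))
  mean(vals)
}

# ---------------------------------------------------------------------
# Barber bipartite modularity (LPAwb+-style optimizer)

#' Barber bipartite modularity of a given partition
#'
#' Q = (1/F) * sum_ij (A_ij - k_i d_j / F) * delta(g_i, h_j) with F the
#' total weight and k, d the row and column strengths.
#'
#' @param web non-negative interaction matrix.
#' @param row_labels,col_labels integer module labels per row / column.
#' @return Modularity Q.
#' @export
barber_modularity <- function(web, row_labels, col_labels) {
  f <- sum(web)
  b <- web - outer(rowSums(web), colSums(web)) / f
  sum(b[outer(row_labels, col_labels, "==")]) / f
}

# one label-propagation sweep; returns updated labels and whether any
# label changed. B is the modularity matrix (A - expectation).
lpa_sweep <- function(b, gr, gc) {
  changed <- FALSE
  for (j in sample.int(ncol(b))) {
    scores <- tapply(b[, j], gr, sum)
    best <- names(scores)[which.max(scores)]
    if (max(scores) < 0) best <- paste0("c", j)  # own empty module
    if (!identical(best, gc[j])) {
      gc[j] <- best
      changed <- TRUE
    }
  }
  for (i in sample.int(nrow(b))) {
    scores <- tapply(b[i, ], gc, sum)
    best <- names(scores)[which.max(scores)]
    if (max(scores) < 0) best <- paste0("r", i)
    if (!identical(best, gr[i])) {
      gr[i] <- best
      changed <- TRUE
    }
  }
  list(gr = gr, gc = gc, changed = changed)
}

propagate_labels <- function(b, gr, gc, max_iter = 100) {
  for (it in seq_len(max_iter)) {
    sw <- lpa_sweep(b, gr, gc)
    gr <- sw$gr
    gc <- sw$gc
    if (!sw$changed) break
  }
  list(gr = gr, gc = gc)
}

# agglomerative refinement: greedily merge the module pair with the
# largest modularity gain while any gain exceeds the tolerance,
# re-propagating after each accepted merge
agglomerate <- function(web, b, f, gr, gc, tol = 1e-12) {
  repeat {
    mods <- unique(c(gr, gc))
    if (length(mods) < 2) break
    best_gain <- 0
    best_pair <- NULL
    for (a in seq_along(mods)) {
      for (z in seq_along(mods)) {
        if (a >= z) next
        ra <- gr == mods[a]; ca <- gc == mods[a]
        rz <- gr == mods[z]; cz <- gc == mods[z]
        gain <- (sum(b[ra, cz, drop = FALSE]) +
                 sum(b[rz, ca, drop = FALSE])) / f
        if (gain > best_gain + tol) {
          best_gain <- gain
          best_pair <- c(mods[a], mods[z])
        }
      }
    }
    if (is.null(best_pair)) break
    gr[gr == best_pair[2]] <- best_pair[1]
    gc[gc == best_pair[2]] <- best_pair[1]
    pr <- propagate_labels(b, gr, gc)
    gr <- pr$gr
    gc <- pr$gc
  }
  list(gr = gr, gc = gc)
}

#' Maximize Barber modularity by weighted label propagation
#'
#' Weighted label propagation seeded from one module per insect node,
#' followed by agglomerative module merging accepted only for positive
#' modularity gain, restarted with randomized sweep orders; the best
#' partition over restarts is returned. Falls back to the single-module
#' partition (Q = 0) if no restart betters it.
#'
#' @param web non-negative interaction matrix.
#' @param n_restarts number of randomized restarts.
#' @param seed integer seed making the search reproducible.
#' @return List with `Q`, `row_modules`, `col_modules` (integer labels
#'   renumbered in row-major first-appearance order) and `n_modules`;
#'   `Q = NA` for degenerate webs.
#' @export
modularity_lpawb <- function(web, n_restarts = 10, seed = 1) {
  if (degenerate_web(web)) {
    return(list(Q = NA_real_, row_modules = NULL, col_modules = NULL,
                n_modules = NA_integer_))
  }
  f <- sum(web)
  b <- web - outer(rowSums(web), colSums(web)) / f
  best <- list(q = 0, gr = rep("m1", nrow(web)), gc = rep("m1", ncol(web)))
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      # first restart starts fully split (one module per insect node)
      # with greedy column attachment; later restarts seed rows and
      # columns jointly from a random pool of labels so different basins
      # of the modularity landscape are explored
      if (r == 1) {
        gr <- paste0("r", seq_len(nrow(web)))
        gc <- rep("", ncol(web))
        for (j in seq_len(ncol(web))) {
          scores <- tapply(b[, j], gr, sum)
          gc[j] <- names(scores)[which.max(scores)]
        }
      } else {
        k <- sample(2:max(2, min(nrow(web), ncol(web)) + 1), 1)
        gr <- paste0("r", sample.int(k, nrow(web), replace = TRUE))
        gc <- paste0("r", sample.int(k, ncol(web), replace = TRUE))
      }
      pr <- propagate_labels(b, gr, gc)
      ag <- agglomerate(web, b, f, pr$gr, pr$gc)
      q <- sum(b[outer(ag$gr, ag$gc, "==")]) / f
      if (q > best$q + 1e-12) best <- list(q = q, gr = ag$gr, gc = ag$gc)
    }
  })
  labs <- unique(c(best$gr, best$gc))
  renum <- stats::setNames(seq_along(labs), labs)
  list(Q = best$q,
       row_modules = stats::setNames(unname(renum[best$gr]), rownames(web)),
       col_modules = stats::setNames(unname(renum[best$gc]), colnames(web)),
       n_modules = length(unique(c(renum[best$gr], renum[best$gc]))))
}

# ---------------------------------------------------------------------

#' Compute the full metric set for one web
#'
#' @param web non-negative interaction matrix.
#' @param seed seed for the modularity search.
#' @param n_restarts restarts for the modularity search.
#' @param evenness_denominator passed to [interaction_evenness()].
#' @param metrics character vector naming the metrics to compute
#'   (default all).
#' @return Named numeric vector; all `NA` (with a warning) for webs
#'   smaller than 2 x 2.
#' @export
metric_set <- function(web, seed = 1, n_restarts = 10,
                       evenness_denominator = "cells",
                       metrics = c("h2_prime", "interaction_evenness",
                                   "generality_qual", "vulnerability_qual",
                                   "generality_quant", "vulnerability_quant",
                                   "nodf_qual", "nodf_quant",
                                   "modularity_q")) {
  out <- stats::setNames(rep(NA_real_, length(metrics)), metrics)
  if (degenerate_web(web)) {
    warning("web smaller than 2x2: all metrics NA")
    return(out)
  }
  for (m in metrics) {
    out[[m]] <- switch(m,
      h2_prime = h2_prime(web),
      interaction_evenness = interaction_evenness(web, evenness_denominator),
      generality_qual = partner_diversity(web, "rows", weighted = FALSE),
      vulnerability_qual = partner_diversity(web, "columns", weighted = FALSE),
      generality_quant = partner_diversity(web, "rows", weighted = TRUE),
      vulnerability_quant = partner_diversity(web, "columns", weighted = TRUE),
      nodf_qual = nodf(web, weighted = FALSE),
      nodf_quant = nodf(web, weighted = TRUE),
      modularity_q = modularity_lpawb(web, n_restarts, seed)$Q,
      stopf("unknown metric '%s'", m)
    )
  }
  out
}
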