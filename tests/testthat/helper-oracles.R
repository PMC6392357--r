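# Independent oracles used to verify package computations. Each is a
# deliberately naive implementation (enumeration or direct formula),
# kept separate from the code paths it checks.

# All set partitions of n items as restricted-growth label vectors.
set_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1)) rec(c(prefix, lab), max(maxlab, lab))
  }
  rec(integer(), 0L)
  out
}

# Exhaustive maximum of Barber bipartite modularity over all partitions
# of the row+column node set.
max_barber_q_oracle <- function(web) {
  parts <- set_partitions(nrow(web) + ncol(web))
  f <- sum(web)
  b <- web - outer(rowSums(web), colSums(web)) / f
  best <- -Inf
  for (p in parts) {
    gr <- p[seq_len(nrow(web))]
    gc <- p[nrow(web) + seq_len(ncol(web))]
    q <- sum(b[outer(gr, gc, "==")]) / f
    if (q > best) best <- q
  }
  best
}

# Brute-force min/max Shannon entropy over all non-negative integer
# matrices with the given margins, via a full grid filter. Only viable
# for tiny margins.
entropy_bounds_oracle <- function(rs, cs) {
  nr <- length(rs)
  nc <- length(cs)
  grid <- do.call(expand.grid, rep(list(0:max(rs)), nr * nc))
  hmin <- Inf
  hmax <- -Inf
  found <- FALSE
  for (k in seq_len(nrow(grid))) {
    m <- matrix(as.numeric(grid[k, ]), nr, nc)
    if (all(rowSums(m) == rs) && all(colSums(m) == cs)) {
      found <- TRUE
      p <- m[m > 0] / sum(m)
      h <- -sum(p * log(p))
      hmin <- min(hmin, h)
      hmax <- max(hmax, h)
    }
  }
  stopifnot(found)
  list(hmin = hmin, hmax = hmax)
}

# Exhaustive greedy-free average-linkage agglomeration: repeatedly merge
# the globally closest pair of clusters until the minimum mean
# inter-cluster distance exceeds the threshold.
avg_linkage_oracle <- function(dm, threshold) {
  cl <- as.list(rownames(dm))
  repeat {
    if (length(cl) < 2) break
    bd <- Inf
    bi <- NULL
    for (i in seq_len(length(cl) - 1)) {
      for (j in (i + 1):length(cl)) {
        d <- mean(dm[cl[[i]], cl[[j]]])
        if (d < bd) {
          bd <- d
          bi <- c(i, j)
        }
      }
    }
    if (bd > threshold) break
    cl[[bi[1]]] <- c(cl[[bi[1]]], cl[[bi[2]]])
    cl[[bi[2]]] <- NULL
  }
  membership <- character()
  for (k in seq_along(cl)) membership[cl[[k]]] <- paste0("g", k)
  membership[rownames(dm)]
}

# TRUE iff two cluster membership vectors induce the same partition.
same_partition <- function(a, b) {
  stopifnot(identical(names(a), names(b)) || length(a) == length(b))
  pa <- outer(a, a, "==")
  pb <- outer(b, b, "==")
  identical(pa, pb)
}

# Mean nearest-neighbour distance with the minimum-image (torus)
# convention, so the homogeneous-Poisson closed form 1/(2*sqrt(lambda))
# applies without edge effects.
mean_nn_torus <- function(x, y, w, h) {
  n <- length(x)
  dx <- abs(outer(x, x, "-"))
  dx <- pmin(dx, w - dx)
  dy <- abs(outer(y, y, "-"))
  dy <- pmin(dy, h - dy)
  d <- sqrt(dx^2 + dy^2)
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

# A random web with no empty rows/columns.
random_web <- function(nr, nc, max_count = 3, prob = NULL) {
  repeat {
    w <- matrix(sample(0:max_count, nr * nc, replace = TRUE, prob = prob),
                nr, nc, dimnames = list(paste0("i", seq_len(nr)),
                                        paste0("p", seq_len(nc))))
    if (all(rowSums(w) > 0) && all(colSums(w) > 0)) return(w)
  }
}
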