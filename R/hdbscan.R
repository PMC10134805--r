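#' Hierarchical density-based clustering (HDBSCAN) with noise
#'
#' In-package implementation of the HDBSCAN algorithm: core distances at
#' `min_cluster_size` neighbours, a minimum spanning tree of the mutual
#' reachability graph, the single-linkage hierarchy it induces, condensation
#' of that hierarchy at minimum cluster size `min_cluster_size`, and
#' excess-of-mass cluster selection. Points not assigned to any selected
#' cluster receive the noise label `0`.
#'
#' @param coords Numeric matrix of point coordinates (rows = points).
#' @param min_cluster_size Minimum cluster size (the `minPts` grid parameter);
#'   also used as the core-distance neighbourhood size.
#' @return An integer vector of cluster labels (`0` = noise, clusters
#'   numbered `1..K` in order of discovery).
#' @export
density_cluster <- function(coords, min_cluster_size) {
  stopifnot(min_cluster_size >= 2)
  X <- as.matrix(coords)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (n < 2 * min_cluster_size) {
    # no split into two clusters of the required size is possible
    return(rep(0L, n))
  }
  mst <- hdbscan_mst_cpp(X, as.integer(min_cluster_size))
  hier <- single_linkage(mst$from, mst$to, mst$w, n)
  cond <- condense_tree(hier, n, min_cluster_size)
  if (is.null(cond)) {
    return(rep(0L, n))
  }
  selected <- eom_select(cond)
  labels <- rep(0L, n)
  lab <- 0L
  for (cid in selected) {
    lab <- lab + 1L
    labels[subtree_points(cond, cid)] <- lab
  }
  labels
}

# single-linkage hierarchy from MST edges; nodes 1..n are points, internal
# nodes n+1..2n-1 carry merge height and size
single_linkage <- function(from, to, w, n) {
  ord <- order(w, method = "radix")
  parent_uf <- seq_len(2L * n - 1L)
  root_of <- seq_len(2L * n - 1L) # current hierarchy node of each UF root
  find <- function(x) {
    while (parent_uf[x] != x) {
      parent_uf[x] <<- parent_uf[parent_uf[x]]
      x <- parent_uf[x]
    }
    x
  }
  left <- right <- integer(n - 1)
  height <- numeric(n - 1)
  size <- integer(2L * n - 1L)
  size[seq_len(n)] <- 1L
  nxt <- n
  for (e in ord) {
    ra <- find(from[e])
    rb <- find(to[e])
    na <- root_of[ra]
    nb <- root_of[rb]
    nxt <- nxt + 1L
    left[nxt - n] <- na
    right[nxt - n] <- nb
    height[nxt - n] <- w[e]
    size[nxt] <- size[na] + size[nb]
    parent_uf[ra] <- rb
    root_of[rb] <- nxt
  }
  list(left = left, right = right, height = height, size = size, root = 2L * n - 1L)
}

# all leaf points under a hierarchy node (iterative)
hier_points <- function(hier, node, n) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (nd <= n) {
      out <- c(out, nd)
    } else {
      stack <- c(stack, hier$left[nd - n], hier$right[nd - n])
    }
  }
  out
}

# Condense the single-linkage hierarchy: clusters smaller than
# min_cluster_size "fall out" of their parent as points; splits into two
# sufficiently large children create new condensed clusters.
condense_tree <- function(hier, n, mcs) {
  lam <- function(node) {
    # lambda value at which `node` (an internal hierarchy node) splits
    h <- hier$height[node - n]
    1 / max(h, 1e-10)
  }
  # condensed cluster bookkeeping
  c_parent <- integer(0)
  c_birth <- numeric(0)
  c_size <- integer(0)
  ev_point <- integer(0)
  ev_cluster <- integer(0)
  ev_lambda <- numeric(0)
  new_cluster <- function(parent, birth, size) {
    c_parent[length(c_parent) + 1L] <<- parent
    c_birth[length(c_birth) + 1L] <<- birth
    c_size[length(c_size) + 1L] <<- size
    length(c_parent)
  }
  drop_points <- function(pts, cid, lambda) {
    m <- length(pts)
    ev_point[length(ev_point) + seq_len(m)] <<- pts
    ev_cluster[length(ev_cluster) + seq_len(m)] <<- rep(cid, m)
    ev_lambda[length(ev_lambda) + seq_len(m)] <<- rep(lambda, m)
  }
  root <- hier$root
  if (root <= n) {
    return(NULL)
  }
  root_cid <- new_cluster(0L, 0, hier$size[root])
  stack_node <- root
  stack_cid <- root_cid
  while (length(stack_node)) {
    node <- stack_node[length(stack_node)]
    cid <- stack_cid[length(stack_cid)]
    stack_node <- stack_node[-length(stack_node)]
    stack_cid <- stack_cid[-length(stack_cid)]
    # walk down chains of this condensed cluster
    repeat {
      l <- hier$left[node - n]
      r <- hier$right[node - n]
      sl <- hier$size[l]
      sr <- hier$size[r]
      lambda <- lam(node)
      if (sl >= mcs && sr >= mcs) {
        cl <- new_cluster(cid, lambda, sl)
        cr <- new_cluster(cid, lambda, sr)
        for (ch in c(l, r)) {
          chid <- if (ch == l) cl else cr
          if (ch <= n) {
            # cannot happen (size >= mcs >= 2) but keep safe
            drop_points(ch, chid, lambda)
          } else {
            stack_node <- c(stack_node, ch)
            stack_cid <- c(stack_cid, chid)
          }
        }
        break
      } else if (sl < mcs && sr < mcs) {
        drop_points(hier_points(hier, l, n), cid, lambda)
        drop_points(hier_points(hier, r, n), cid, lambda)
        break
      } else {
        small <- if (sl < mcs) l else r
        big <- if (sl < mcs) r else l
        drop_points(hier_points(hier, small, n), cid, lambda)
        if (big <= n) {
          drop_points(big, cid, lambda)
          break
        }
        node <- big
      }
    }
  }
  list(
    parent = c_parent, birth = c_birth, size = c_size,
    ev_point = ev_point, ev_cluster = ev_cluster, ev_lambda = ev_lambda,
    n_clusters = length(c_parent)
  )
}

# cluster stability: sum over points of (lambda_leave - lambda_birth) plus,
# for each child cluster, size * (child birth lambda - own birth lambda)
cluster_stability <- function(cond) {
  nc <- cond$n_clusters
  stab <- numeric(nc)
  ev <- tapply(cond$ev_lambda - cond$birth[cond$ev_cluster], cond$ev_cluster, sum)
  idx <- as.integer(names(ev))
  stab[idx] <- as.numeric(ev)
  for (c in seq_len(nc)) {
    p <- cond$parent[c]
    if (p > 0) {
      stab[p] <- stab[p] + cond$size[c] * (cond$birth[c] - cond$birth[p])
    }
  }
  stab
}

# excess-of-mass selection; the root cluster is never selected
eom_select <- function(cond) {
  nc <- cond$n_clusters
  if (nc <= 1) {
    return(integer(0))
  }
  stab <- cluster_stability(cond)
  children <- split(seq_len(nc), factor(cond$parent, levels = 0:nc))
  kids <- function(c) children[[as.character(c)]] %||% integer(0)
  selected <- rep(FALSE, nc)
  value <- numeric(nc)
  # process deepest-first: children always created after parents, so reverse
  for (c in rev(seq_len(nc))) {
    ch <- kids(c)
    if (length(ch) == 0) {
      selected[c] <- TRUE
      value[c] <- stab[c]
    } else {
      sub <- sum(value[ch])
      if (c == 1L) { # root: never selectable
        value[c] <- sub
      } else if (stab[c] > sub) {
        selected[c] <- TRUE
        value[c] <- stab[c]
        # unselect entire subtree below
        stack <- ch
        while (length(stack)) {
          x <- stack[length(stack)]
          stack <- stack[-length(stack)]
          selected[x] <- FALSE
          stack <- c(stack, kids(x))
        }
      } else {
        value[c] <- sub
      }
    }
  }
  which(selected)
}

# all points whose fall-out event lies in the subtree rooted at cid
subtree_points <- function(cond, cid) {
  nc <- cond$n_clusters
  in_sub <- rep(FALSE, nc)
  stack <- cid
  while (length(stack)) {
    x <- stack[length(stack)]
    stack <- stack[-length(stack)]
    in_sub[x] <- TRUE
    stack <- c(stack, which(cond$parent == x))
  }
  cond$ev_point[in_sub[cond$ev_cluster]]
}
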