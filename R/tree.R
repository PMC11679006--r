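## Weak learner: binary axis-aligned decision tree grown best-first by weighted
## Gini impurity reduction, capped at a fixed number of internal split nodes.
## Stored as a node table (data.frame) so trees serialize to JSON trivially.

gini_impurity <- function(p) 2 * p * (1 - p)

## Best weighted-Gini split of rows `idx`; ties broken by lowest feature index,
## then lowest threshold. Returns NULL when no split has positive gain.
best_split <- function(X, y01, w, idx) {
  wp <- sum(w[idx])
  pp <- sum(w[idx] * y01[idx]) / wp
  if (pp <= 0 || pp >= 1) return(NULL)       # pure node
  parent <- wp * gini_impurity(pp)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    xj <- X[idx, j]
    o <- order(xj)
    xs <- xj[o]
    ws <- w[idx][o]
    wy <- ws * y01[idx][o]
    cw <- cumsum(ws)
    cwy <- cumsum(wy)
    n <- length(xs)
    cut <- which(xs[-n] < xs[-1])          # split between distinct values
    if (!length(cut)) next
    wl <- cw[cut]
    wr <- wp - wl
    pl <- cwy[cut] / wl
    pr <- (cwy[n] - cwy[cut]) / wr
    gain <- parent - (wl * gini_impurity(pl) + wr * gini_impurity(pr))
    ## zero-gain splits on an impure node are admissible (XOR-like structure
    ## only pays off one level deeper); ties keep the lowest feature/threshold
    k <- which.max(gain)                   # first max: lowest threshold wins
    if (gain[k] > -1e-12 && (is.null(best) || gain[k] > best$gain + 1e-15)) {
      best <- list(feature = j, threshold = (xs[cut[k]] + xs[cut[k] + 1]) / 2,
                   gain = gain[k])
    }
  }
  best
}

#' Fit a shallow decision tree by weighted Gini reduction
#'
#' Best-first growth: the leaf with the largest weighted impurity decrease is
#' split next, until `max_splits` internal nodes or purity. Rows go left when
#' `x <= threshold`. Leaf values are the weighted posterior of the target
#' class. Deterministic: ties between candidate splits go to the lowest
#' feature index then the lowest threshold; ties between leaves to the
#' earliest-created leaf.
#'
#' @param X numeric feature matrix.
#' @param y character/logical vector; the positive class is `"TARGET"` (or
#'   `TRUE`).
#' @param w observation weights (default uniform).
#' @param max_splits cap on internal split nodes.
#' @return object of class `fog_tree`: a node table with columns `feature`,
#'   `threshold`, `left`, `right` (0 for leaves) and `value` (target
#'   posterior).
#' @export
fit_tree <- function(X, y, w = NULL, max_splits = 5) {
  X <- as.matrix(X)
  y01 <- as.integer(y == "TARGET" | y == TRUE)
  if (is.null(w)) w <- rep(1 / nrow(X), nrow(X))
  nodes <- data.frame(feature = 0L, threshold = NA_real_, left = 0L, right = 0L,
                      value = sum(w * y01) / sum(w))
  open <- list(list(node = 1L, idx = seq_len(nrow(X)),
                    split = best_split(X, y01, w, seq_len(nrow(X)))))
  n_splits <- 0L
  while (n_splits < max_splits) {
    gains <- vapply(open, function(o) if (is.null(o$split)) -Inf else o$split$gain,
                    numeric(1))
    if (!length(gains) || is.infinite(max(gains))) break
    b <- which.max(gains)                  # first max: earliest leaf wins ties
    o <- open[[b]]
    open[[b]] <- NULL
    go_left <- X[o$idx, o$split$feature] <= o$split$threshold
    li <- o$idx[go_left]
    ri <- o$idx[!go_left]
    for (child_idx in list(li, ri)) {
      nodes <- rbind(nodes, data.frame(
        feature = 0L, threshold = NA_real_, left = 0L, right = 0L,
        value = sum(w[child_idx] * y01[child_idx]) / sum(w[child_idx])))
    }
    nl <- nrow(nodes) - 1L
    nodes$feature[o$node] <- o$split$feature
    nodes$threshold[o$node] <- o$split$threshold
    nodes$left[o$node] <- nl
    nodes$right[o$node] <- nl + 1L
    open <- c(open,
              list(list(node = nl, idx = li, split = best_split(X, y01, w, li)),
                   list(node = nl + 1L, idx = ri, split = best_split(X, y01, w, ri))))
    n_splits <- n_splits + 1L
  }
  structure(list(nodes = nodes, n_splits = n_splits), class = "fog_tree")
}

#' Target-class posterior of a tree for each row
#'
#' @param tree a `fog_tree`.
#' @param X numeric feature matrix.
#' @return numeric vector of posteriors in `[0, 1]`.
#' @export
predict_tree <- function(tree, X) {
  X <- as.matrix(X)
  nodes <- tree$nodes
  cur <- rep(1L, nrow(X))
  repeat {
    at_split <- nodes$left[cur] != 0L
    if (!any(at_split)) break
    i <- which(at_split)
    nd <- cur[i]
    go_left <- X[cbind(i, nodes$feature[nd])] <= nodes$threshold[nd]
    cur[i] <- ifelse(go_left, nodes$left[nd], nodes$right[nd])
  }
  nodes$value[cur]
}
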