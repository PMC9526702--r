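# Internal classification-tree engine.
#
# Trees are grown on bootstrap resamples with Gini split search over a
# random subset of sqrt(p) features per node. A node stops splitting when
# its majority class reaches `purity_stop` (the "grow until 95% of classes
# are accurately classified" rule), when it is too small, or when no feature
# admits a split. Trees are stored as flat parallel vectors; prediction
# routes whole sample blocks down the tree, so it is vectorized over
# samples.

# node-local feature-sampling seed: a deterministic function of the tree
# seed and the node's sample multiset, so the same node (same bootstrap rows)
# draws the same candidate features regardless of how much of the tree was
# grown before it. A tree stopped early at 95% purity is then exactly a
# pruned version of the fully grown tree, and predictions are invariant to
# protein row order.
node_seed <- function(tree_seed, idx) {
  as.integer((as.numeric(tree_seed) %% 1048573 * 2039 +
                sum(idx * seq_along(idx)) + length(idx)) %% 2147483647)
}

grow_tree <- function(X, y, K, mtry, purity_stop, tree_seed, min_split = 2L) {
  cap <- 64L
  var_ <- integer(cap); split_ <- numeric(cap)
  left_ <- integer(cap); right_ <- integer(cap); pred_ <- integer(cap)
  n_nodes <- 0L
  p <- ncol(X)

  new_node <- function() {
    n_nodes <<- n_nodes + 1L
    if (n_nodes > cap) {
      cap <<- cap * 2L
      length(var_) <<- cap; length(split_) <<- cap
      length(left_) <<- cap; length(right_) <<- cap; length(pred_) <<- cap
    }
    n_nodes
  }

  build <- function(idx) {
    nd <- new_node()
    yn <- y[idx]
    n <- length(idx)
    cnt <- tabulate(yn, K)
    maj <- which.max(cnt)           # ties -> lowest class index (canonical order)
    if (n < min_split || cnt[maj] / n >= purity_stop) {
      var_[nd] <<- 0L; pred_[nd] <<- maj
      return(nd)
    }
    set.seed(node_seed(tree_seed, idx))
    feats <- sample.int(p, mtry)
    best_gain <- -Inf; best_f <- 0L; best_s <- NA_real_
    seq_n <- seq_len(n)
    for (f in feats) {
      x <- X[idx, f]
      o <- order(x)
      xs <- x[o]
      ok <- which(xs[-n] < xs[-1L])
      if (!length(ok)) next
      ys <- yn[o]
      C <- matrix(0L, n, K)
      C[cbind(seq_n, ys)] <- 1L
      C <- apply(C, 2L, cumsum)
      CR <- sweep(-C, 2L, cnt, "+")
      nl <- seq_n
      nr <- n - nl
      # maximizing sum_child n_c * sum_k p_ck^2 is equivalent to minimizing
      # the weighted Gini impurity
      gain <- rowSums(C * C) / nl + rowSums(CR * CR) / pmax(nr, 1L)
      gain <- gain[ok]
      j <- which.max(gain)
      if (gain[j] > best_gain) {
        best_gain <- gain[j]; best_f <- f
        best_s <- (xs[ok[j]] + xs[ok[j] + 1L]) / 2
      }
    }
    if (best_f == 0L) {
      var_[nd] <<- 0L; pred_[nd] <<- maj
      return(nd)
    }
    go_l <- X[idx, best_f] <= best_s
    var_[nd] <<- best_f; split_[nd] <<- best_s
    l <- build(idx[go_l])
    r <- build(idx[!go_l])
    left_[nd] <<- l; right_[nd] <<- r
    nd
  }

  build(seq_len(nrow(X)))
  keep <- seq_len(n_nodes)
  list(var = var_[keep], split = split_[keep], left = left_[keep],
       right = right_[keep], pred = pred_[keep])
}

tree_depth <- function(tr) {
  rec <- function(nd) {
    if (tr$var[nd] == 0L) return(0L)
    1L + max(rec(tr$left[nd]), rec(tr$right[nd]))
  }
  rec(1L)
}

predict_tree <- function(tr, X) {
  out <- integer(nrow(X))
  route <- function(nd, idx) {
    repeat {
      if (tr$var[nd] == 0L) { out[idx] <<- tr$pred[nd]; return(invisible(NULL)) }
      go_l <- X[idx, tr$var[nd]] <= tr$split[nd]
      if (any(go_l)) route(tr$left[nd], idx[go_l])
      idx <- idx[!go_l]
      if (!length(idx)) return(invisible(NULL))
      nd <- tr$right[nd]
    }
  }
  if (nrow(X) > 0) route(1L, seq_len(nrow(X)))
  out
}

# hard-vote fractions over the forest: n x K matrix of tree-vote shares
forest_votes <- function(trees, X, K) {
  n <- nrow(X)
  votes <- matrix(0L, n, K)
  ii <- seq_len(n)
  for (tr in trees) {
    pr <- predict_tree(tr, X)
    votes[cbind(ii, pr)] <- votes[cbind(ii, pr)] + 1L
  }
  votes / length(trees)
}

# one-vs-rest AUC from scores, by the rank-sum (Mann-Whitney) identity,
# with average ranks for ties
binary_auc <- function(scores, is_pos) {
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
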