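#' Fit a RUSBoost ensemble of shallow decision trees
#'
#' Boosting for a heavily imbalanced binary problem: each round draws a random
#' undersample of the majority class (without replacement, selection
#' probabilities proportional to the current boosting weights) so that the
#' round's class counts reach `sampling_ratio` (default 1:1), fits a
#' [fit_tree()] weak learner on the round sample, then scores it on the FULL
#' weighted training set. With weighted error `e`, the learner weight is
#' `alpha = learn_rate * log((1 - e)/e)`; weights of correctly classified
#' examples are multiplied by `exp(-alpha)` and renormalized. Rounds with
#' `e = 0` keep the learner with a capped `alpha`; rounds with `e >= 0.5`
#' discard the learner and resample (the ensemble may therefore end up shorter
#' than `n_learners`).
#'
#' Rows are canonically sorted before any random draw, so predictions do not
#' depend on input row order; per-round seeds are derived from `seed` via a
#' counter, making fits bit-for-bit reproducible.
#'
#' @param X numeric feature matrix (or data.frame of numeric columns).
#' @param y class vector; positive class `"TARGET"`.
#' @param n_learners maximum number of boosting rounds.
#' @param max_splits internal-split cap per tree.
#' @param sampling_ratio majority:minority count ratio in each round sample
#'   (1 = balanced).
#' @param learn_rate shrinkage on the learner weights.
#' @param seed integer root seed.
#' @return object of class `rusboost`: list of trees, `alpha` weights, the
#'   parameters, and `feature_names`.
#' @export
fit_rusboost <- function(X, y, n_learners = 100, max_splits = 5,
                         sampling_ratio = 1, learn_rate = 0.1, seed = 1) {
  X <- as.matrix(X)
  y <- ifelse(y == "TARGET" | y == TRUE, "TARGET", "NONTARGET")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  ## canonicalize row order so permuted inputs give identical models
  ord <- do.call(order, c(as.data.frame(X), list(y)))
  X <- X[ord, , drop = FALSE]
  y <- y[ord]
  n <- nrow(X)
  ytarget <- y == "TARGET"
  w <- rep(1 / n, n)
  trees <- list()
  alpha <- numeric()
  counter <- 0L
  retries <- 0L
  alpha_cap <- learn_rate * log(1e12)
  while (length(trees) < n_learners && retries < 50L) {
    counter <- counter + 1L
    set.seed(round_seed(seed, counter))
    samp <- rus_sample(ytarget, w, sampling_ratio)
    tree <- fit_tree(X[samp, , drop = FALSE], y[samp],
                     w = w[samp] / sum(w[samp]), max_splits = max_splits)
    vote_target <- predict_tree(tree, X) > 0.5
    err <- sum(w[vote_target != ytarget])
    if (err >= 0.5) { retries <- retries + 1L; next }
    retries <- 0L
    a <- if (err <= 0) alpha_cap else min(learn_rate * log((1 - err) / err), alpha_cap)
    trees[[length(trees) + 1L]] <- tree
    alpha <- c(alpha, a)
    correct <- vote_target == ytarget
    w[correct] <- w[correct] * exp(-a)
    w <- w / sum(w)
  }
  structure(list(trees = trees, alpha = alpha,
                 params = list(n_learners = n_learners, max_splits = max_splits,
                               sampling_ratio = sampling_ratio,
                               learn_rate = learn_rate, seed = seed),
                 feature_names = colnames(X)),
            class = "rusboost")
}

## deterministic per-round seed from a root seed and a counter (kept < 2^31)
round_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(counter) * 9973) %% 2147483629 + 1)
}

## indices of one round's balanced sample: all of the minority class plus a
## weighted undersample (without replacement) of the majority class
rus_sample <- function(ytarget, w, sampling_ratio = 1) {
  pos <- which(ytarget)
  neg <- which(!ytarget)
  if (length(pos) <= length(neg)) {
    minority <- pos; majority <- neg
  } else {
    minority <- neg; majority <- pos
  }
  n_take <- min(length(majority),
                max(1L, as.integer(round(length(minority) * sampling_ratio))))
  take <- sample(majority, n_take, replace = FALSE, prob = w[majority])
  sort(c(minority, take))
}

#' Ensemble score: weighted fraction of trees voting TARGET
#'
#' @param ens a fitted `rusboost` ensemble.
#' @param X feature matrix with the same columns as at fit time.
#' @return numeric scores in `[0, 1]`, `sum(alpha_i * vote_i) / sum(alpha_i)`.
#' @export
predict_score <- function(ens, X) {
  if (!length(ens$trees)) stop("ensemble has no fitted learners")
  X <- as.matrix(X)
  if (!is.null(ens$feature_names) && !is.null(colnames(X))) {
    X <- X[, ens$feature_names, drop = FALSE]
  }
  votes <- vapply(ens$trees, function(tr) as.numeric(predict_tree(tr, X) > 0.5),
                  numeric(nrow(X)))
  votes <- matrix(votes, nrow = nrow(X))
  as.vector(votes %*% ens$alpha) / sum(ens$alpha)
}

#' Threshold an ensemble score into a class
#'
#' @param score numeric scores in `[0, 1]`.
#' @param threshold decision threshold; `TARGET` iff `score > threshold`
#'   (strict, so a 0.5 tie is `NONTARGET`).
#' @export
predict_class <- function(score, threshold = 0.5) {
  ifelse(score > threshold, "TARGET", "NONTARGET")
}

#' @export
print.rusboost <- function(x, ...) {
  cat(sprintf("<rusboost> %d trees (max %d splits), learn_rate %g, seed %s\n",
              length(x$trees), x$params$max_splits, x$params$learn_rate,
              format(x$params$seed)))
  invisible(x)
}

#' Serialize / restore an ensemble as JSON
#'
#' @param ens a `rusboost` ensemble.
#' @param path file path.
#' @export
write_model <- function(ens, path) {
  doc <- list(trees = lapply(ens$trees, function(tr) tr$nodes),
              alpha = ens$alpha, params = ens$params,
              feature_names = ens$feature_names)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  trees <- lapply(doc$trees, function(nd) {
    nodes <- as.data.frame(lapply(nd, unlist), stringsAsFactors = FALSE)
    nodes$threshold <- as.numeric(nodes$threshold)
    structure(list(nodes = nodes, n_splits = sum(nodes$left != 0L)),
              class = "fog_tree")
  })
  structure(list(trees = trees, alpha = as.numeric(unlist(doc$alpha)),
                 params = doc$params,
                 feature_names = as.character(unlist(doc$feature_names))),
            class = "rusboost")
}
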