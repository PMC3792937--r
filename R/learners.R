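# A minimal regression-tree engine shared by the boosted-tree and
# random-forest learners. No tree package is assumed to be installed, and the
# training sets here are small (hundreds of rows, a handful of predictors),
# so a plain-R CART with variance splitting is adequate.

# flat tree: parallel vectors indexed by node id; node 1 is the root
fit_rtree <- function(X, y, w = NULL, max_depth = 3L, min_node = 5L, mtry = ncol(X)) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(w)) w <- rep(1, n)
  var_ <- integer(0); cut_ <- numeric(0); left_ <- integer(0); right_ <- integer(0)
  val_ <- numeric(0); leaf_ <- logical(0)
  new_node <- function() {
    var_ <<- c(var_, NA_integer_); cut_ <<- c(cut_, NA_real_)
    left_ <<- c(left_, NA_integer_); right_ <<- c(right_, NA_integer_)
    val_ <<- c(val_, NA_real_); leaf_ <<- c(leaf_, TRUE)
    length(val_)
  }
  best_split <- function(rows, feats) {
    best <- NULL; best_gain <- 1e-10
    yw <- y[rows]; ww <- w[rows]
    sw <- sum(ww); swy <- sum(ww * yw)
    base <- sum(ww * yw^2) - swy^2 / sw
    for (j in feats) {
      x <- X[rows, j]
      o <- order(x)
      xs <- x[o]; ys <- yw[o]; ws <- ww[o]
      cw <- cumsum(ws); cwy <- cumsum(ws * ys); cwy2 <- cumsum(ws * ys^2)
      m <- length(xs)
      cand <- which(xs[-m] < xs[-1])          # split between distinct values
      if (!length(cand)) next
      lw <- cw[cand]; lwy <- cwy[cand]
      rw <- sw - lw; rwy <- swy - lwy
      sse <- (sum(ws * ys^2)) - lwy^2 / lw - rwy^2 / rw
      gain <- base - sse
      i <- which.max(gain)
      if (gain[i] > best_gain) {
        best_gain <- gain[i]
        best <- list(var = j, cut = (xs[cand[i]] + xs[cand[i] + 1L]) / 2)
      }
    }
    best
  }
  grow <- function(rows, depth) {
    id <- new_node()
    val_[id] <<- sum(w[rows] * y[rows]) / sum(w[rows])
    if (depth >= max_depth || length(rows) < 2L * min_node ||
        stats::var(y[rows]) < 1e-12) return(id)
    feats <- if (mtry >= p) seq_len(p) else sample.int(p, mtry)
    sp <- best_split(rows, feats)
    if (is.null(sp)) return(id)
    go_left <- X[rows, sp$var] <= sp$cut
    if (sum(go_left) < min_node || sum(!go_left) < min_node) return(id)
    leaf_[id] <<- FALSE; var_[id] <<- sp$var; cut_[id] <<- sp$cut
    left_[id] <<- grow(rows[go_left], depth + 1L)
    right_[id] <<- grow(rows[!go_left], depth + 1L)
    id
  }
  grow(seq_len(n), 0L)
  list(var = var_, cut = cut_, left = left_, right = right_,
       value = val_, leaf = leaf_)
}

# returns the leaf node id of each row
rtree_leaf <- function(tree, X) {
  n <- nrow(X)
  out <- integer(n)
  assign_rows <- function(id, rows) {
    if (!length(rows)) return(invisible())
    if (tree$leaf[id]) { out[rows] <<- id; return(invisible()) }
    go_left <- X[rows, tree$var[id]] <= tree$cut[id]
    assign_rows(tree$left[id], rows[go_left])
    assign_rows(tree$right[id], rows[!go_left])
  }
  assign_rows(1L, seq_len(n))
  out
}

predict_rtree <- function(tree, X) tree$value[rtree_leaf(tree, X)]

# learner contract ------------------------------------------------------------

#' Construct a learner object
#'
#' A learner is a named pair of functions: `fit(X, y)` returning a model, and
#' `predict(model, X)` returning habitat-suitability scores in `[0, 1]`.
#' `X` is a numeric design matrix (continuous predictors plus one-hot
#' land-cover columns) and `y` a 0/1 vector.
#'
#' @param name Learner name.
#' @param fit,predict The two functions.
#' @return An object of class `sdm_learner`.
#' @export
sdm_learner <- function(name, fit, predict) {
  structure(list(name = name, fit = fit, predict = predict),
            class = "sdm_learner")
}

#' Linear-logistic learner (GLM analogue)
#' @return An `sdm_learner`.
#' @export
learner_logistic <- function() {
  sdm_learner(
    "logistic",
    fit = function(X, y) {
      df <- data.frame(y = y, X)
      suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
    },
    predict = function(model, X) {
      p <- suppressWarnings(stats::predict(model, newdata = data.frame(X), type = "response"))
      pmin(pmax(as.numeric(p), 0), 1)
    })
}

#' Boosted-tree learner (GBM analogue)
#'
#' Gradient boosting of shallow regression trees under the logistic loss,
#' with Newton leaf updates.
#'
#' @param n_trees Number of boosting rounds.
#' @param shrinkage Learning rate.
#' @param max_depth Tree depth.
#' @param min_node Minimum rows per leaf.
#' @return An `sdm_learner`.
#' @export
learner_brt <- function(n_trees = 60L, shrinkage = 0.1, max_depth = 2L, min_node = 8L) {
  sdm_learner(
    "brt",
    fit = function(X, y) {
      n <- length(y)
      p0 <- min(max(mean(y), 1e-3), 1 - 1e-3)
      f0 <- log(p0 / (1 - p0))
      Fv <- rep(f0, n)
      trees <- vector("list", n_trees)
      for (t in seq_len(n_trees)) {
        pr <- stats::plogis(Fv)
        g <- y - pr
        tr <- fit_rtree(X, g, max_depth = max_depth, min_node = min_node)
        lf <- rtree_leaf(tr, X)
        h <- pmax(pr * (1 - pr), 1e-6)
        for (id in unique(lf)) {
          rows <- lf == id
          tr$value[id] <- max(min(sum(g[rows]) / sum(h[rows]), 4), -4)
        }
        Fv <- Fv + shrinkage * tr$value[lf]
        trees[[t]] <- tr
      }
      list(f0 = f0, shrinkage = shrinkage, trees = trees)
    },
    predict = function(model, X) {
      Fv <- rep(model$f0, nrow(X))
      for (tr in model$trees) Fv <- Fv + model$shrinkage * predict_rtree(tr, X)
      stats::plogis(Fv)
    })
}

#' Randomized-tree-ensemble learner (random-forest analogue)
#'
#' Bagged regression trees on the 0/1 response with per-split feature
#' subsampling; the prediction is the across-tree mean leaf frequency.
#'
#' @param n_trees Number of trees.
#' @param mtry Features tried per split (default `ceiling(sqrt(p))`).
#' @param max_depth Tree depth.
#' @param min_node Minimum rows per leaf.
#' @return An `sdm_learner`.
#' @export
learner_rf <- function(n_trees = 80L, mtry = NULL, max_depth = 6L, min_node = 4L) {
  sdm_learner(
    "rf",
    fit = function(X, y) {
      n <- length(y)
      m <- if (is.null(mtry)) max(1L, ceiling(sqrt(ncol(X)))) else mtry
      trees <- lapply(seq_len(n_trees), function(t) {
        rows <- sample.int(n, n, replace = TRUE)
        fit_rtree(X[rows, , drop = FALSE], y[rows],
                  max_depth = max_depth, min_node = min_node, mtry = m)
      })
      list(trees = trees)
    },
    predict = function(model, X) {
      preds <- vapply(model$trees, function(tr) predict_rtree(tr, X),
                      numeric(nrow(X)))
      pmin(pmax(rowMeans(preds), 0), 1)
    })
}

#' Default learner set
#'
#' The shipped ensemble: a linear-logistic learner, a boosted-tree learner and
#' a randomized-tree-ensemble learner. The ensemble machinery is
#' learner-agnostic; any list of [sdm_learner()] objects may be substituted.
#'
#' @return Named list of `sdm_learner`s.
#' @export
default_learners <- function() {
  ls <- list(learner_logistic(), learner_brt(), learner_rf())
  stats::setNames(ls, vapply(ls, `[[`, "", "name"))
}
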