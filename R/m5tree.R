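#' Control parameters for M5 model trees
#'
#' Defaults follow the conventional M5/M5P settings: a minimum of four
#' instances per leaf, splitting stopped once a node's target standard
#' deviation falls below 5% of the root's, smoothing constant 15, and
#' pruning on.
#'
#' @param min_leaf Minimum instances per leaf (>= 2).
#' @param sd_stop_fraction Stop splitting when node sd < this fraction of
#'   the root sd.
#' @param smoothing_k Smoothing constant `k` in `(n p + k q) / (n + k)`;
#'   0 disables smoothing.
#' @param prune Logical; apply error-based bottom-up pruning.
#' @param prune_multiplier Weight on the parameter count in the
#'   `(n + prune_multiplier * v) / (n - v)` error inflation used for term
#'   dropping and pruning (2, the M5P convention, penalises complexity
#'   enough to collapse structureless trees).
#' @return A list of class `m5_control`.
#' @export
m5_control <- function(min_leaf = 4, sd_stop_fraction = 0.05,
                       smoothing_k = 15, prune = TRUE,
                       prune_multiplier = 2) {
  stopifnot(min_leaf >= 2, sd_stop_fraction > 0, sd_stop_fraction < 1,
            smoothing_k >= 0, prune_multiplier >= 1)
  structure(list(min_leaf = min_leaf, sd_stop_fraction = sd_stop_fraction,
                 smoothing_k = smoothing_k, prune = prune,
                 prune_multiplier = prune_multiplier),
            class = "m5_control")
}

adj_error <- function(mae, v, n, mult) {
  if (n - v <= 0) return(mae * 10)
  mae * min(10, (n + mult * v) / (n - v))
}

pop_sd <- function(y) {
  n <- length(y)
  if (n == 0) return(NA_real_)
  sqrt(max(0, mean(y^2) - mean(y)^2))
}

#' Standard-deviation reduction of a candidate split
#'
#' `sd(parent) - (|L|/|parent|) sd(L) - (|R|/|parent|) sd(R)` with the
#' population standard deviation; the CART-style impurity criterion used to
#' select M5 splits. An empty side yields `-Inf` (split rejected).
#'
#' @param parent,left,right Numeric target vectors; `left` and `right` must
#'   partition `parent`.
#' @return The reduction (larger is better).
#' @export
sdr <- function(parent, left, right) {
  if (length(left) == 0L || length(right) == 0L) return(-Inf)
  if (length(left) + length(right) != length(parent)) {
    stop("left and right must partition parent", call. = FALSE)
  }
  n <- length(parent)
  pop_sd(parent) - (length(left) / n) * pop_sd(left) -
    (length(right) / n) * pop_sd(right)
}

# best (feature, threshold) by SDR; candidate thresholds are midpoints of
# consecutive distinct sorted values; ties resolved by (feature index,
# threshold) for determinism
best_split <- function(x, y, min_size = 1L) {
  best <- NULL
  n <- length(y)
  for (j in seq_len(ncol(x))) {
    xj <- x[[j]]
    ord <- order(xj)
    xs <- xj[ord]; ys <- y[ord]
    cs <- cumsum(ys); cs2 <- cumsum(ys^2)
    tot <- cs[n]; tot2 <- cs2[n]
    sd_parent <- sqrt(max(0, tot2 / n - (tot / n)^2))
    distinct_end <- which(diff(xs) > 0)
    for (i in distinct_end) {
      nl <- i; nr <- n - i
      if (nl < min_size || nr < min_size) next
      sd_l <- sqrt(max(0, cs2[i] / nl - (cs[i] / nl)^2))
      sd_r <- sqrt(max(0, (tot2 - cs2[i]) / nr - ((tot - cs[i]) / nr)^2))
      red <- sd_parent - (nl / n) * sd_l - (nr / n) * sd_r
      thr <- (xs[i] + xs[i + 1]) / 2
      if (is.null(best) || red > best$sdr + 1e-12) {
        best <- list(feature = j, threshold = thr, sdr = red)
      }
    }
  }
  best
}

# leaf/node linear model with greedy backward feature dropping that
# minimises the (n+v)/(n-v)-adjusted mean absolute residual
fit_node_model <- function(x, y, features, mult = 2) {
  n <- length(y)
  adj <- function(mae, v) adj_error(mae, v, n, mult)
  usable <- features[vapply(features, function(f) {
    vals <- x[[f]]
    length(unique(vals)) > 1L
  }, logical(1))]
  # never start with more terms than the data can identify
  if (length(usable) > max(0, n - 2)) usable <- usable[seq_len(max(0, n - 2))]
  fit_with <- function(fs) {
    if (length(fs) == 0L) {
      res <- y - mean(y)
      return(list(coef = numeric(0), intercept = mean(y),
                  mae = mean(abs(res)), v = 1L))
    }
    df <- x[, fs, drop = FALSE]
    df$.y <- y
    fit <- lm(.y ~ ., data = df)
    cf <- coef(fit)
    keep <- !is.na(cf)
    cf <- cf[keep]
    pred <- as.numeric(predict(fit, newdata = df))
    res <- y - pred
    list(coef = cf[setdiff(names(cf), "(Intercept)")],
         intercept = unname(cf["(Intercept)"]),
         mae = mean(abs(res)), v = length(cf))
  }
  cur_fs <- usable
  cur <- fit_with(cur_fs)
  cur_err <- adj(cur$mae, cur$v)
  repeat {
    if (length(cur_fs) == 0L) break
    errs <- vapply(seq_along(cur_fs), function(k) {
      cand <- fit_with(cur_fs[-k])
      adj(cand$mae, cand$v)
    }, numeric(1))
    k <- which.min(errs)
    if (errs[k] <= cur_err + 1e-12) {
      cur_fs <- cur_fs[-k]
      cur <- fit_with(cur_fs)
      cur_err <- adj(cur$mae, cur$v)
    } else break
  }
  cur$adj_err <- cur_err
  cur
}

model_value <- function(model, xrow) {
  val <- model$intercept
  for (f in names(model$coef)) val <- val + model$coef[[f]] * xrow[[f]]
  unname(val)
}

grow_node <- function(x, y, cfg, root_sd, depth = 0L) {
  n <- length(y)
  node <- list(n = n, sd = pop_sd(y))
  node$model <- fit_node_model(x, y, names(x), cfg$prune_multiplier)
  make_leaf <- function(node) {
    node$type <- "leaf"
    node
  }
  if (n < 2 * cfg$min_leaf || node$sd < cfg$sd_stop_fraction * root_sd) {
    return(make_leaf(node))
  }
  sp <- best_split(x, y, min_size = cfg$min_leaf)
  if (is.null(sp) || sp$sdr <= 0) return(make_leaf(node))
  sel <- x[[sp$feature]] <= sp$threshold
  node$type <- "split"
  node$split_feature <- names(x)[sp$feature]
  node$split_value <- sp$threshold
  node$left <- grow_node(x[sel, , drop = FALSE], y[sel], cfg, root_sd, depth + 1L)
  node$right <- grow_node(x[!sel, , drop = FALSE], y[!sel], cfg, root_sd, depth + 1L)
  node
}

# Bottom-up error-based pruning. The subtree is charged for its aggregate
# complexity: its raw error is the instance-weighted mean absolute residual
# of its leaves, adjusted by (n + mult*v)/(n - v) with v the total number
# of leaf model terms plus two per split (each data-optimised split
# estimates an attribute choice and a cutpoint, so it consumes more than
# one effective degree of freedom). A subtree that does not beat the
# node's own (similarly adjusted) linear model is cut off.
prune_node <- function(node, mult = 2) {
  adj <- function(mae, v, n) adj_error(mae, v, n, mult)
  if (node$type == "leaf") {
    node$subtree_mae <- node$model$mae
    node$subtree_v <- node$model$v
    node$subtree_err <- node$model$adj_err
    return(node)
  }
  node$left <- prune_node(node$left, mult)
  node$right <- prune_node(node$right, mult)
  sub_mae <- (node$left$n * node$left$subtree_mae +
              node$right$n * node$right$subtree_mae) / node$n
  sub_v <- node$left$subtree_v + node$right$subtree_v + 2L
  sub_err <- adj(sub_mae, sub_v, node$n)
  if (node$model$adj_err <= sub_err * (1 + 1e-9) + 1e-12) {
    node <- list(n = node$n, sd = node$sd, model = node$model,
                 type = "leaf", subtree_mae = node$model$mae,
                 subtree_v = node$model$v,
                 subtree_err = node$model$adj_err)
  } else {
    node$subtree_mae <- sub_mae
    node$subtree_v <- sub_v
    node$subtree_err <- sub_err
  }
  node
}

#' Fit an M5 pruned model tree
#'
#' Grows a regression tree by standard-deviation-reduction splitting, fits a
#' multivariate linear model (with greedy term dropping) at every node,
#' prunes bottom-up by comparing each internal node's adjusted error with
#' its subtree's, and predicts with optional smoothing along the root path.
#' Missing feature values are imputed with per-feature training medians at
#' both fit and predict time.
#'
#' @param x Data.frame of numeric features.
#' @param y Numeric target.
#' @param control An [m5_control()] list.
#' @return An object of class `m5tree`.
#' @export
m5tree <- function(x, y, control = m5_control()) {
  x <- as.data.frame(x)
  stopifnot(nrow(x) == length(y), nrow(x) >= 2, all(is.finite(y)))
  if (!all(vapply(x, is.numeric, logical(1)))) {
    stop("all features must be numeric", call. = FALSE)
  }
  medians <- vapply(x, function(col) {
    m <- median(col, na.rm = TRUE)
    if (is.na(m)) 0 else m
  }, numeric(1))
  for (j in seq_along(x)) {
    miss <- is.na(x[[j]])
    if (any(miss)) x[[j]][miss] <- medians[[j]]
  }
  root_sd <- pop_sd(y)
  root <- grow_node(x, y, control, root_sd)
  if (control$prune) root <- prune_node(root, control$prune_multiplier)
  structure(list(root = root, control = control, medians = medians,
                 feature_names = names(x), n = length(y)),
            class = "m5tree")
}

predict_row <- function(node, xrow, k) {
  if (node$type == "leaf") {
    return(list(p = model_value(node$model, xrow), n = node$n))
  }
  child <- if (xrow[[node$split_feature]] <= node$split_value)
    node$left else node$right
  below <- predict_row(child, xrow, k)
  p <- below$p
  if (k > 0) {
    q <- model_value(node$model, xrow)
    p <- (below$n * p + k * q) / (below$n + k)
  }
  list(p = p, n = below$n)
}

#' Predict from an M5 tree
#'
#' @param object An `m5tree`.
#' @param newdata Data.frame with the training features (missing values and
#'   absent columns are imputed with training medians).
#' @param smoothing_k Override for the smoothing constant (default: the
#'   fitted control's value; 0 gives raw leaf predictions).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.m5tree <- function(object, newdata, smoothing_k = NULL, ...) {
  newdata <- as.data.frame(newdata)
  k <- if (is.null(smoothing_k)) object$control$smoothing_k else smoothing_k
  for (f in object$feature_names) {
    if (is.null(newdata[[f]])) newdata[[f]] <- object$medians[[f]]
    miss <- is.na(newdata[[f]])
    if (any(miss)) newdata[[f]][miss] <- object$medians[[f]]
  }
  vapply(seq_len(nrow(newdata)), function(i) {
    predict_row(object$root, newdata[i, , drop = FALSE], k)$p
  }, numeric(1))
}

n_leaves <- function(node) {
  if (node$type == "leaf") return(1L)
  n_leaves(node$left) + n_leaves(node$right)
}

format_model <- function(model, digits = 4) {
  terms <- sprintf("%+.*g * %s", digits, model$coef, names(model$coef))
  paste0(format(model$intercept, digits = digits),
         if (length(terms)) paste0(" ", paste(terms, collapse = " ")) else "")
}

print_node <- function(node, indent = "") {
  if (node$type == "leaf") {
    cat(indent, "leaf (n=", node$n, "): y = ", format_model(node$model),
        "\n", sep = "")
  } else {
    cat(indent, node$split_feature, " <= ",
        format(node$split_value, digits = 6), ":\n", sep = "")
    print_node(node$left, paste0(indent, "  "))
    cat(indent, node$split_feature, " > ",
        format(node$split_value, digits = 6), ":\n", sep = "")
    print_node(node$right, paste0(indent, "  "))
  }
}

#' @export
print.m5tree <- function(x, ...) {
  cat("M5 pruned model tree:", n_leaves(x$root), "leaf/leaves,",
      x$n, "training instances\n")
  print_node(x$root)
  invisible(x)
}

#' Leave-one-out evaluation of an M5 tree
#'
#' Refits the tree `n` times, each time holding out one instance, and
#' returns the held-out predictions aligned to the input order. The
#' procedure is deterministic.
#'
#' @param x Feature data.frame.
#' @param y Numeric target.
#' @param control An [m5_control()].
#' @return Numeric vector of length `length(y)`.
#' @export
m5_loo <- function(x, y, control = m5_control()) {
  x <- as.data.frame(x)
  n <- length(y)
  stopifnot(n >= 3)
  vapply(seq_len(n), function(i) {
    fit <- m5tree(x[-i, , drop = FALSE], y[-i], control)
    predict(fit, x[i, , drop = FALSE])
  }, numeric(1))
}
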