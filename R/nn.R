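#' Activation and loss primitives
#'
#' `leaky_relu(x, alpha)` is `x` for `x >= 0` and `alpha * x` otherwise,
#' elementwise. `logistic(x)` is the numerically stable standard logistic
#' `1 / (1 + exp(-x))`. `bce_loss` is the mean binary cross-entropy of
#' predicted probabilities against 0/1 targets; `mse_loss` the mean squared
#' error.
#'
#' @param x numeric vector or matrix.
#' @param alpha negative-side slope of the leaky ReLU.
#' @param y targets (0/1 for `bce_loss`).
#' @param p predicted probabilities in (0, 1).
#' @param y_hat predicted values.
#' @name nn_primitives
NULL

#' @rdname nn_primitives
#' @export
leaky_relu <- function(x, alpha = 0.01) {
  ifelse(x >= 0, x, alpha * x)
}

#' @rdname nn_primitives
#' @export
logistic <- function(x) stats::plogis(x)

#' @rdname nn_primitives
#' @export
bce_loss <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' @rdname nn_primitives
#' @export
mse_loss <- function(y, y_hat) mean((y - y_hat)^2)

#' Specify a feed-forward base network
#'
#' Architecture and training constants for one base learner. The hidden
#' widths form a chain: each layer's width is the integer division of the
#' previous layer's output count by its divisor (so `n_inputs = 10`,
#' divisor 2 gives one hidden layer of width 5). A chain reaching width
#' below 1 is invalid. Every hidden layer is affine, then batch
#' normalisation (if enabled), then Leaky ReLU, then dropout (if enabled);
#' the output is a single unit with a logistic head for binary traits and
#' an identity head for quantitative ones.
#'
#' @param depth number of hidden layers, 0 to 4 (0 is a purely affine
#'   model, used for degenerate-model checks).
#' @param divisors per-layer width divisors in 1 to 4, recycled to `depth`.
#' @param dropout apply dropout (rate 0.5) after every hidden activation.
#' @param batchnorm apply batch normalisation before every hidden
#'   activation.
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param max_epochs,patience,min_delta early-stopping constants: training
#'   stops once the validation loss has failed to improve by `min_delta`
#'   for `patience` consecutive epochs, and the best-validation weights are
#'   restored.
#' @param batch_size minibatch size; training is full-batch when the
#'   training set has fewer than 512 samples.
#' @param leaky_alpha negative-side slope of the activation.
#' @param seed integer seed making initialisation, shuffling and dropout
#'   reproducible.
#' @return An object of class `nn_spec`.
#' @export
nn_spec <- function(depth = 1, divisors = 2, dropout = FALSE,
                    batchnorm = FALSE, learning_rate = 1e-3,
                    max_epochs = 500, patience = 10, min_delta = 1e-5,
                    batch_size = 256, leaky_alpha = 0.01, seed = 1) {
  if (depth < 0 || depth > 4) stop("depth must be between 0 and 4")
  divisors <- rep_len(as.integer(divisors), max(depth, 1))[seq_len(depth)]
  if (depth > 0 && any(divisors < 1 | divisors > 4)) {
    stop("width divisors must be between 1 and 4")
  }
  structure(list(depth = as.integer(depth), divisors = divisors,
                 dropout = isTRUE(dropout), batchnorm = isTRUE(batchnorm),
                 learning_rate = learning_rate, max_epochs = max_epochs,
                 patience = patience, min_delta = min_delta,
                 batch_size = batch_size, leaky_alpha = leaky_alpha,
                 seed = as.integer(seed)),
            class = "nn_spec")
}

# Hidden width chain; NULL when the spec is invalid for this input count.
nn_widths <- function(spec, n_inputs) {
  w <- integer(spec$depth)
  prev <- n_inputs
  for (l in seq_len(spec$depth)) {
    w[l] <- prev %/% spec$divisors[l]
    if (w[l] < 1) return(NULL)
    prev <- w[l]
  }
  w
}

# Trainable parameter count for a spec at a given input width.
nn_param_count <- function(spec, n_inputs) {
  w <- nn_widths(spec, n_inputs)
  if (is.null(w) && spec$depth > 0) return(NA_integer_)
  dims <- c(n_inputs, w)
  total <- 0L
  for (l in seq_len(spec$depth)) {
    total <- total + dims[l] * dims[l + 1] + dims[l + 1] +
      if (spec$batchnorm) 2L * dims[l + 1] else 0L
  }
  total + dims[length(dims)] + 1L
}

# Build an untrained network: weight matrices, biases, batch-norm state.
nn_build <- function(spec, n_inputs, trait_type) {
  w <- nn_widths(spec, n_inputs)
  if (is.null(w) && spec$depth > 0) {
    stop("width chain falls below 1 unit for ", n_inputs, " inputs")
  }
  dims <- c(n_inputs, w)
  layers <- vector("list", spec$depth)
  for (l in seq_len(spec$depth)) {
    layers[[l]] <- list(
      W = matrix(stats::rnorm(dims[l] * dims[l + 1], sd = sqrt(2 / dims[l])),
                 dims[l], dims[l + 1]),
      b = numeric(dims[l + 1]),
      gamma = if (spec$batchnorm) rep(1, dims[l + 1]),
      beta = if (spec$batchnorm) numeric(dims[l + 1]),
      rmean = if (spec$batchnorm) numeric(dims[l + 1]),
      rvar = if (spec$batchnorm) rep(1, dims[l + 1]))
  }
  out <- list(W = matrix(stats::rnorm(dims[length(dims)], sd =
                                        sqrt(1 / dims[length(dims)])),
                         dims[length(dims)], 1),
              b = 0)
  list(spec = spec, layers = layers, out = out, n_inputs = n_inputs,
       trait_type = trait_type)
}

bn_eps <- 1e-5
bn_momentum <- 0.9

# Forward pass. training=TRUE uses batch statistics, draws dropout masks
# (mutating the RNG stream) and returns the caches needed for backprop.
nn_forward <- function(model, X, training = FALSE) {
  spec <- model$spec
  A <- X
  caches <- vector("list", spec$depth)
  for (l in seq_len(spec$depth)) {
    ly <- model$layers[[l]]
    Z <- A %*% ly$W + rep(ly$b, each = nrow(A))
    if (spec$batchnorm) {
      if (training) {
        mu <- colMeans(Z)
        va <- colMeans(Z^2) - mu^2
        model$layers[[l]]$rmean <- bn_momentum * ly$rmean + (1 - bn_momentum) * mu
        model$layers[[l]]$rvar <- bn_momentum * ly$rvar + (1 - bn_momentum) * va
      } else {
        mu <- ly$rmean
        va <- ly$rvar
      }
      xhat <- sweep(sweep(Z, 2, mu), 2, sqrt(va + bn_eps), "/")
      act_in <- sweep(sweep(xhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
    } else {
      mu <- va <- xhat <- NULL
      act_in <- Z
    }
    H <- leaky_relu(act_in, spec$leaky_alpha)
    mask <- NULL
    if (spec$dropout && training) {
      mask <- (matrix(stats::runif(length(H)), nrow(H)) >= 0.5) / 0.5
      H <- H * mask
    }
    caches[[l]] <- list(A = A, va = va, xhat = xhat, act_in = act_in,
                        mask = mask)
    A <- H
  }
  lin <- as.vector(A %*% model$out$W + model$out$b)
  out <- if (model$trait_type == "binary") stats::plogis(lin) else lin
  list(out = out, lin = lin, H = A, caches = caches, model = model)
}

# Backward pass; returns gradients in the same shape as the parameters.
nn_backward <- function(fw, y) {
  model <- fw$model
  spec <- model$spec
  n <- length(y)
  # both heads reduce to the same linear-gradient form (1/n scale for BCE,
  # 2/n for MSE)
  dlin <- if (model$trait_type == "binary") (fw$out - y) / n else
    2 * (fw$lin - y) / n
  grads <- list(layers = vector("list", spec$depth), out = NULL)
  grads$out <- list(W = crossprod(fw$H, dlin), b = sum(dlin))
  dA <- dlin %*% t(model$out$W)
  for (l in rev(seq_len(spec$depth))) {
    cache <- fw$caches[[l]]
    ly <- model$layers[[l]]
    if (!is.null(cache$mask)) dA <- dA * cache$mask
    dact <- dA * ifelse(cache$act_in >= 0, 1, spec$leaky_alpha)
    if (spec$batchnorm) {
      dgamma <- colSums(dact * cache$xhat)
      dbeta <- colSums(dact)
      dxhat <- sweep(dact, 2, ly$gamma, "*")
      nb <- nrow(dact)
      inv <- 1 / sqrt(cache$va + bn_eps)
      dZ <- sweep(nb * dxhat -
                    rep(colSums(dxhat), each = nb) -
                    cache$xhat * rep(colSums(dxhat * cache$xhat), each = nb),
                  2, inv / nb, "*")
    } else {
      dgamma <- dbeta <- NULL
      dZ <- dact
    }
    grads$layers[[l]] <- list(W = crossprod(cache$A, dZ), b = colSums(dZ),
                              gamma = dgamma, beta = dbeta)
    dA <- dZ %*% t(ly$W)
  }
  grads
}

# Adam optimiser over the nested parameter lists.
adam_init <- function(model) {
  zero_like <- function(p) {
    lapply(p, function(x) if (is.null(x)) NULL else x * 0)
  }
  list(m = list(layers = lapply(model$layers, function(l)
                  zero_like(l[c("W", "b", "gamma", "beta")])),
                out = zero_like(model$out)),
       v = list(layers = lapply(model$layers, function(l)
                  zero_like(l[c("W", "b", "gamma", "beta")])),
                out = zero_like(model$out)),
       t = 0L)
}

adam_step <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(p = p, m = m, v = v)
  }
  for (l in seq_along(model$layers)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      if (is.null(model$layers[[l]][[nm]])) next
      r <- upd(model$layers[[l]][[nm]], grads$layers[[l]][[nm]],
               state$m$layers[[l]][[nm]], state$v$layers[[l]][[nm]])
      model$layers[[l]][[nm]] <- r$p
      state$m$layers[[l]][[nm]] <- r$m
      state$v$layers[[l]][[nm]] <- r$v
    }
  }
  for (nm in c("W", "b")) {
    r <- upd(model$out[[nm]], grads$out[[nm]],
             state$m$out[[nm]], state$v$out[[nm]])
    model$out[[nm]] <- r$p
    state$m$out[[nm]] <- r$m
    state$v$out[[nm]] <- r$v
  }
  list(model = model, state = state)
}

#' Train one base network
#'
#' Standardises the input columns with training-set mean and standard
#' deviation (stored on the returned model), then optimises binary
#' cross-entropy (binary trait) or mean squared error (quantitative) with
#' Adam at the spec's learning rate. Training is full-batch below 512
#' training samples and minibatched otherwise, monitors the validation loss
#' every epoch, stops early per the spec's patience, and restores the
#' best-validation weights. Deterministic for a fixed spec seed.
#'
#' @param spec an [nn_spec()].
#' @param X_train,X_val numeric matrices (dosages; missing values must
#'   already be imputed).
#' @param y_train,y_val targets.
#' @param trait_type `"binary"` or `"quantitative"`.
#' @return An object of class `base_model`: the trained network plus
#'   standardisation constants, epochs run and validation-loss history.
#' @export
nn_train <- function(spec, X_train, y_train, X_val, y_val,
                     trait_type = c("binary", "quantitative")) {
  trait_type <- match.arg(trait_type)
  X_train <- as.matrix(X_train)
  X_val <- as.matrix(X_val)
  mu <- colMeans(X_train)
  sdv <- apply(X_train, 2, stats::sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  Zt <- sweep(sweep(X_train, 2, mu), 2, sdv, "/")
  Zv <- sweep(sweep(X_val, 2, mu), 2, sdv, "/")

  set.seed(spec$seed)
  model <- nn_build(spec, ncol(Zt), trait_type)
  state <- adam_init(model)
  n <- nrow(Zt)
  full_batch <- n < 512

  loss_fun <- if (trait_type == "binary") bce_loss else mse_loss
  val_loss <- function(m) {
    loss_fun(y_val, nn_forward(m, Zv, training = FALSE)$out)
  }

  best <- list(model = model, loss = val_loss(model), epoch = 0L)
  history <- numeric(0)
  wait <- 0L
  epochs_run <- 0L
  if (spec$max_epochs > 0) {
    for (epoch in seq_len(spec$max_epochs)) {
      batches <- if (full_batch) list(seq_len(n)) else {
        perm <- sample(n)
        split(perm, ceiling(seq_along(perm) / spec$batch_size))
      }
      bad <- FALSE
      for (b in batches) {
        fw <- nn_forward(model, Zt[b, , drop = FALSE], training = TRUE)
        model <- fw$model  # batch-norm running stats updated in forward
        if (!all(is.finite(fw$lin))) { bad <- TRUE; break }
        grads <- nn_backward(fw, y_train[b])
        r <- adam_step(model, grads, state, spec$learning_rate)
        model <- r$model
        state <- r$state
      }
      if (bad) {
        stop("non-finite network output during training (epoch ", epoch,
             "); inputs may be unscaled or the learning rate too high")
      }
      vl <- val_loss(model)
      if (!is.finite(vl)) stop("non-finite validation loss at epoch ", epoch)
      history <- c(history, vl)
      epochs_run <- epoch
      if (best$loss - vl > spec$min_delta) {
        best <- list(model = model, loss = vl, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= spec$patience) break
      }
    }
  }
  structure(list(spec = spec, model = best$model, mu = mu, sd = sdv,
                 trait_type = trait_type, val_loss = best$loss,
                 epochs_run = epochs_run, best_epoch = best$epoch,
                 history = history),
            class = "base_model")
}

#' Predict from a trained base network
#'
#' Inference mode: dropout disabled, batch normalisation using the stored
#' running statistics; repeated calls give identical output.
#'
#' @param object a `base_model` from [nn_train()].
#' @param X dosage matrix with the model's input columns, in order.
#' @param ... unused.
#' @return Probabilities in (0, 1) for binary traits, real scores for
#'   quantitative ones.
#' @export
predict.base_model <- function(object, X, ...) {
  X <- as.matrix(X)
  Z <- sweep(sweep(X, 2, object$mu), 2, object$sd, "/")
  out <- nn_forward(object$model, Z, training = FALSE)$out
  if (object$trait_type == "binary") {
    out <- pmin(pmax(out, 1e-12), 1 - 1e-12)
  }
  out
}

#' @export
print.base_model <- function(x, ...) {
  w <- nn_widths(x$spec, length(x$mu))
  cat("base_model: ", length(x$mu), " inputs -> [",
      paste(w, collapse = ", "), "] -> 1 (", x$trait_type, ")\n", sep = "")
  cat("  dropout:", x$spec$dropout, " batchnorm:", x$spec$batchnorm, "\n")
  cat("  best validation loss", signif(x$val_loss, 6), "at epoch",
      x$best_epoch, "of", x$epochs_run, "\n")
  invisible(x)
}

#' Build a grid of network specs
#'
#' Cartesian product of depths, (uniform) width divisors and
#' regularisation on/off, as explored by the architecture search: depth 1
#' to 4, divisor 1 to 4, with and without dropout + batch normalisation.
#'
#' @param depths,divisors integer vectors.
#' @param regularised logical vector; `TRUE` turns on both dropout (0.5)
#'   and batch normalisation.
#' @param ... further arguments passed to every [nn_spec()].
#' @return List of `nn_spec` objects.
#' @export
nn_grid <- function(depths = 1:4, divisors = 1:4,
                    regularised = c(FALSE, TRUE), ...) {
  combos <- expand.grid(depth = depths, divisor = divisors,
                        reg = regularised)
  lapply(seq_len(nrow(combos)), function(i) {
    nn_spec(depth = combos$depth[i], divisors = combos$divisor[i],
            dropout = combos$reg[i], batchnorm = combos$reg[i], ...)
  })
}

#' Grid search over network specs
#'
#' Trains every valid spec (those whose width chain stays at least 1 for
#' the given input count) on the training rows and scores it on the
#' validation rows with the trait-appropriate metric (Nagelkerke pseudo-R2
#' for binary, squared correlation for quantitative). Returns the argmax;
#' ties go to the spec with fewer parameters, then earlier grid order.
#'
#' @param X dosage matrix (all samples; missing values imputed upstream).
#' @param y target vector for all samples.
#' @param split a [make_split()].
#' @param grid list of [nn_spec()]s.
#' @param trait_type `"binary"` or `"quantitative"`.
#' @param seed base seed; spec `j` trains with `seed + j`.
#' @return List with `best` (a `base_model`), `best_spec_index` and
#'   `table` (one row per spec: architecture, validation loss and metric,
#'   epochs run; skipped specs marked).
#' @export
nn_grid_search <- function(X, y, split, grid,
                           trait_type = c("binary", "quantitative"),
                           seed = 1) {
  trait_type <- match.arg(trait_type)
  if (!length(grid)) stop("empty spec grid")
  Xi <- impute_dosages(as.matrix(X))
  rows <- vector("list", length(grid))
  models <- vector("list", length(grid))
  metrics <- rep(NA_real_, length(grid))
  params <- rep(NA_integer_, length(grid))
  for (j in seq_along(grid)) {
    spec <- grid[[j]]
    spec$seed <- as.integer((seed + j) %% .Machine$integer.max)
    valid <- spec$depth == 0 || !is.null(nn_widths(spec, ncol(Xi)))
    row <- data.frame(spec = j, depth = spec$depth,
                      divisors = paste(spec$divisors, collapse = "/"),
                      dropout = spec$dropout, batchnorm = spec$batchnorm,
                      valid = valid, params = NA_integer_,
                      val_loss = NA_real_, val_metric = NA_real_,
                      epochs = NA_integer_)
    if (valid) {
      bm <- nn_train(spec, Xi[split$train, , drop = FALSE], y[split$train],
                     Xi[split$val, , drop = FALSE], y[split$val], trait_type)
      pred <- predict(bm, Xi[split$val, , drop = FALSE])
      m <- if (stats::var(pred) == 0) 0 else if (trait_type == "binary") {
        nagelkerke_r2(y[split$val], pred)
      } else {
        r_squared(y[split$val], pred)
      }
      metrics[j] <- m
      params[j] <- nn_param_count(spec, ncol(Xi))
      models[[j]] <- bm
      row$params <- params[j]
      row$val_loss <- bm$val_loss
      row$val_metric <- m
      row$epochs <- bm$epochs_run
    }
    rows[[j]] <- row
  }
  if (all(is.na(metrics))) stop("no spec in the grid is valid for ",
                                ncol(Xi), " inputs")
  best_metric <- max(metrics, na.rm = TRUE)
  cand <- which(!is.na(metrics) & metrics >= best_metric - 0)
  cand <- cand[order(params[cand], cand)]
  best <- cand[1]
  list(best = models[[best]], best_spec_index = best,
       table = do.call(rbind, rows))
}
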