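# Small dense multi-layer perceptron (ReLU hidden layers, softmax output)
# trained with Adam and early stopping on an internal validation split.
# Sized for stacked-score inputs (a dozen features, a few hundred rows).

#' Fit a multi-layer perceptron classifier
#'
#' @param X numeric matrix, rows x features (standardized internally)
#' @param y factor/character labels
#' @param hidden integer vector of hidden-layer widths
#' @param lr Adam learning rate
#' @param epochs maximum epochs
#' @param batch minibatch size
#' @param valFraction early-stopping validation fraction
#' @param patience epochs without validation improvement before stopping
#' @param seed integer seed
#' @return Fitted model list for [mlpPredict()].
#' @export
mlpFit <- function(X, y, hidden = c(16L, 16L), lr = 0.01, epochs = 300L,
                   batch = 16L, valFraction = 0.15, patience = 30L, seed = 1L) {
  y <- factor(y)
  classes <- levels(y)
  K <- length(classes)
  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- scaleCols(X, ctr, scl)
  n <- nrow(Xs)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), as.integer(y))] <- 1

  dims <- c(ncol(Xs), hidden, K)
  L <- length(dims) - 1L
  withSeed(seed, {
    W <- lapply(seq_len(L), function(l)
      matrix(stats::rnorm(dims[l] * dims[l + 1L], sd = sqrt(2 / dims[l])),
             dims[l], dims[l + 1L]))
    b <- lapply(seq_len(L), function(l) numeric(dims[l + 1L]))
    nVal <- max(1L, round(valFraction * n))
    valIdx <- sample.int(n, nVal)
    trIdx <- setdiff(seq_len(n), valIdx)

    forward <- function(Xb, W, b) {
      A <- list(Xb)
      for (l in seq_len(L)) {
        Z <- sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+")
        A[[l + 1L]] <- if (l < L) pmax(Z, 0) else {
          Z <- Z - apply(Z, 1, max)
          E <- exp(Z); E / rowSums(E)
        }
      }
      A
    }
    xent <- function(P, Yb) -mean(rowSums(Yb * log(pmax(P, 1e-12))))

    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; epsA <- 1e-8; t <- 0L
    bestW <- W; bestB <- b; bestVal <- Inf; wait <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample(trIdx)
      for (s in seq(1L, length(ord), by = batch)) {
        ix <- ord[s:min(s + batch - 1L, length(ord))]
        A <- forward(Xs[ix, , drop = FALSE], W, b)
        delta <- (A[[L + 1L]] - Y[ix, , drop = FALSE]) / length(ix)
        t <- t + 1L
        for (l in rev(seq_len(L))) {
          gW <- t(A[[l]]) %*% delta
          gb <- colSums(delta)
          if (l > 1L) delta <- (delta %*% t(W[[l]])) * (A[[l]] > 0)
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          hat <- function(m, v) (m / (1 - beta1^t)) / (sqrt(v / (1 - beta2^t)) + epsA)
          W[[l]] <- W[[l]] - lr * hat(mW[[l]], vW[[l]])
          b[[l]] <- b[[l]] - lr * hat(mb[[l]], vb[[l]])
        }
      }
      val <- xent(forward(Xs[valIdx, , drop = FALSE], W, b)[[L + 1L]],
                  Y[valIdx, , drop = FALSE])
      if (val < bestVal - 1e-5) {
        bestVal <- val; bestW <- W; bestB <- b; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    list(W = bestW, b = bestB, classes = classes, center = ctr, scale = scl,
         hidden = hidden, lr = lr, valLoss = bestVal)
  })
}

#' Predict class probabilities from a fitted MLP
#' @param model fit from [mlpFit()]
#' @param X numeric matrix
#' @return Probability matrix, rows x classes (rows sum to 1).
#' @export
mlpPredict <- function(model, X) {
  A <- scaleCols(X, model$center, model$scale)
  L <- length(model$W)
  for (l in seq_len(L)) {
    Z <- sweep(A %*% model$W[[l]], 2, model$b[[l]], "+")
    A <- if (l < L) pmax(Z, 0) else {
      Z <- Z - apply(Z, 1, max)
      E <- exp(Z); E / rowSums(E)
    }
  }
  colnames(A) <- model$classes
  A
}
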