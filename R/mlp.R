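# Two-hidden-layer function-fitting network (tanh hidden units, linear
# output), trained by full-batch L-BFGS with Armijo backtracking on the
# mean-squared error of min-max-scaled targets.  The stopping rule follows
# the method's training protocol: a hard iteration cap, a gradient-norm
# threshold, and a patience counter on consecutive iterations without a
# gradient-norm decrease (a validation-loss reading of the same counter is
# available behind `stop_rule`).

#' Training configuration for the function-fitting networks
#'
#' @param hidden_sizes Integer pair of hidden-layer widths (default
#'   `c(250, 100)`).
#' @param max_iterations Iteration cap; one iteration is one accepted
#'   full-batch quasi-Newton step (default 2000).
#' @param grad_tolerance Stop when the gradient norm falls below this
#'   (default 1e-6).
#' @param patience Consecutive iterations without a gradient-norm (or
#'   validation-loss) decrease before stopping early (default 6).
#' @param seed Integer seed for the weight initialization (and validation
#'   split, if used).
#' @param validation_fraction Fraction of rows held out when
#'   `stop_rule = "validation"` (default 0.15).
#' @param stop_rule `"gradient"` (default) or `"validation"`.
#' @return A `train_config` list.
#' @export
train_config <- function(hidden_sizes = c(250, 100), max_iterations = 2000,
                         grad_tolerance = 1e-6, patience = 6, seed = 1,
                         validation_fraction = 0.15,
                         stop_rule = c("gradient", "validation")) {
  stop_rule <- match.arg(stop_rule)
  stopifnot(length(hidden_sizes) == 2L, all(hidden_sizes >= 1),
            max_iterations >= 1, grad_tolerance > 0, patience >= 1,
            validation_fraction >= 0, validation_fraction < 0.5)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 max_iterations = as.integer(max_iterations),
                 grad_tolerance = grad_tolerance,
                 patience = as.integer(patience),
                 seed = as.integer(seed),
                 validation_fraction = validation_fraction,
                 stop_rule = stop_rule),
            class = "train_config")
}

mlp_dims <- function(d_in, hidden, d_out) {
  list(d_in = d_in, h1 = hidden[1L], h2 = hidden[2L], d_out = d_out)
}

mlp_init_params <- function(dims, seed) {
  with_local_seed(seed + 179424673L, {
    ru <- function(nr, nc) {
      matrix(runif(nr * nc, -1, 1) * sqrt(1 / nr), nr, nc)
    }
    list(W1 = ru(dims$d_in, dims$h1), b1 = numeric(dims$h1),
         W2 = ru(dims$h1, dims$h2), b2 = numeric(dims$h2),
         W3 = ru(dims$h2, dims$d_out), b3 = numeric(dims$d_out))
  })
}

pack_params <- function(p) c(p$W1, p$b1, p$W2, p$b2, p$W3, p$b3)

unpack_params <- function(theta, dims) {
  i <- 0L
  take <- function(n) {
    out <- theta[(i + 1L):(i + n)]
    i <<- i + n
    out
  }
  list(
    W1 = matrix(take(dims$d_in * dims$h1), dims$d_in, dims$h1),
    b1 = take(dims$h1),
    W2 = matrix(take(dims$h1 * dims$h2), dims$h1, dims$h2),
    b2 = take(dims$h2),
    W3 = matrix(take(dims$h2 * dims$d_out), dims$h2, dims$d_out),
    b3 = take(dims$d_out)
  )
}

mlp_forward <- function(p, X) {
  A1 <- tanh(sweep(X %*% p$W1, 2L, p$b1, "+"))
  A2 <- tanh(sweep(A1 %*% p$W2, 2L, p$b2, "+"))
  Yh <- sweep(A2 %*% p$W3, 2L, p$b3, "+")
  list(A1 = A1, A2 = A2, Yh = Yh)
}

mlp_loss <- function(p, X, Y) {
  Yh <- mlp_forward(p, X)$Yh
  mean((Yh - Y)^2)
}

mlp_loss_grad <- function(p, X, Y) {
  fw <- mlp_forward(p, X)
  n <- nrow(X)
  k <- ncol(Y)
  R <- fw$Yh - Y
  loss <- mean(R^2)
  D3 <- R * (2 / (n * k))
  gW3 <- crossprod(fw$A2, D3)
  gb3 <- colSums(D3)
  D2 <- (D3 %*% t(p$W3)) * (1 - fw$A2^2)
  gW2 <- crossprod(fw$A1, D2)
  gb2 <- colSums(D2)
  D1 <- (D2 %*% t(p$W2)) * (1 - fw$A1^2)
  gW1 <- crossprod(X, D1)
  gb1 <- colSums(D1)
  list(loss = loss,
       grad = c(gW1, gb1, gW2, gb2, gW3, gb3))
}

# L-BFGS two-loop recursion
lbfgs_direction <- function(g, mem) {
  q <- g
  k <- length(mem$s)
  if (k == 0L) return(-g)
  alpha <- numeric(k)
  for (i in k:1) {
    alpha[i] <- mem$rho[[i]] * sum(mem$s[[i]] * q)
    q <- q - alpha[i] * mem$y[[i]]
  }
  gamma <- sum(mem$s[[k]] * mem$y[[k]]) / sum(mem$y[[k]]^2)
  r <- gamma * q
  for (i in 1:k) {
    beta <- mem$rho[[i]] * sum(mem$y[[i]] * r)
    r <- r + mem$s[[i]] * (alpha[i] - beta)
  }
  -r
}

#' Train a function-fitting neural network
#'
#' Fits a two-hidden-layer tanh network with linear output by full-batch
#' L-BFGS with Armijo backtracking (monotone descent on the mean-squared
#' error of the scaled targets).  Inputs and targets are min-max scaled to
#' `[-1, 1]` using the training data; the scalers are stored in the model so
#' prediction is self-contained.  Training stops at the iteration cap, when
#' the gradient norm drops below `grad_tolerance`, after `patience`
#' consecutive iterations without a gradient-norm decrease, or when the line
#' search cannot find a descent step.  Deterministic given `config$seed`.
#'
#' @param X Numeric feature matrix (>= 100 rows, finite).
#' @param Y Numeric target matrix/vector, same row count.
#' @param config A [train_config()].
#' @return An `mlp_model` with weights, scalers, a per-iteration `history`
#'   tibble (`iteration`, `loss`, `grad_norm`) and the stop reason.
#' @export
train_mlp <- function(X, Y, config = train_config()) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) abort("X and Y must have equal row counts.",
                                class = "imu2grf_shape")
  if (nrow(X) < 100L) abort("Training requires at least 100 samples.",
                            class = "imu2grf_too_few_samples")
  if (any(!is.finite(X)) || any(!is.finite(Y))) {
    abort("Training data must be finite.", class = "imu2grf_nonfinite")
  }
  in_cols <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  out_cols <- colnames(Y) %||% paste0("y", seq_len(ncol(Y)))

  sx <- fit_scaler(X)
  sy <- fit_scaler(Y)
  Xs <- apply_scaler(X, sx)
  Ys <- apply_scaler(Y, sy)

  val_idx <- integer(0)
  if (config$stop_rule == "validation" && config$validation_fraction > 0) {
    val_idx <- with_local_seed(config$seed + 7368787L,
                               sample.int(nrow(Xs), max(1L, round(config$validation_fraction * nrow(Xs)))))
  }
  if (length(val_idx) > 0L) {
    Xv <- Xs[val_idx, , drop = FALSE]; Yv <- Ys[val_idx, , drop = FALSE]
    Xt <- Xs[-val_idx, , drop = FALSE]; Yt <- Ys[-val_idx, , drop = FALSE]
  } else {
    Xv <- NULL; Yv <- NULL; Xt <- Xs; Yt <- Ys
  }

  dims <- mlp_dims(ncol(Xt), config$hidden_sizes, ncol(Yt))
  p <- mlp_init_params(dims, config$seed)
  theta <- pack_params(p)

  fg <- mlp_loss_grad(p, Xt, Yt)
  loss <- fg$loss
  g <- fg$grad
  mem <- list(s = list(), y = list(), rho = list())
  history <- vector("list", config$max_iterations)
  stop_reason <- "max_iterations"
  best_metric <- Inf
  prev_metric <- Inf
  stall <- 0L
  iter <- 0L

  while (iter < config$max_iterations) {
    gn <- sqrt(sum(g^2))
    if (gn < config$grad_tolerance) {
      stop_reason <- "grad_tolerance"
      break
    }
    d <- lbfgs_direction(g, mem)
    gd <- sum(g * d)
    if (!is.finite(gd) || gd >= 0) {   # not a descent direction: reset
      mem <- list(s = list(), y = list(), rho = list())
      d <- -g
      gd <- -sum(g^2)
    }
    alpha <- if (length(mem$s) == 0L) min(1, 1 / max(1e-8, sqrt(sum(g^2)))) else 1
    accepted <- FALSE
    for (bt in 1:30) {
      theta_new <- theta + alpha * d
      p_new <- unpack_params(theta_new, dims)
      loss_new <- mlp_loss(p_new, Xt, Yt)
      if (is.finite(loss_new) && loss_new <= loss + 1e-4 * alpha * gd) {
        accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!accepted) {
      stop_reason <- "line_search_failure"
      break
    }
    fg_new <- mlp_loss_grad(p_new, Xt, Yt)
    s_step <- theta_new - theta
    yv <- fg_new$grad - g
    curv <- sum(s_step * yv)
    if (curv > 1e-12) {
      mem$s <- c(mem$s, list(s_step))
      mem$y <- c(mem$y, list(yv))
      mem$rho <- c(mem$rho, list(1 / curv))
      if (length(mem$s) > 8L) {
        mem$s <- mem$s[-1L]; mem$y <- mem$y[-1L]; mem$rho <- mem$rho[-1L]
      }
    }
    theta <- theta_new
    p <- p_new
    loss <- fg_new$loss
    g <- fg_new$grad
    iter <- iter + 1L
    gn_new <- sqrt(sum(g^2))
    metric <- if (config$stop_rule == "validation") {
      mlp_loss(p, Xv, Yv)
    } else {
      gn_new
    }
    history[[iter]] <- c(iteration = iter, loss = loss, grad_norm = gn_new,
                         metric = metric)
    if (config$stop_rule == "validation") {
      # classic early stopping: consecutive iterations above the best
      # validation loss seen so far
      if (metric < best_metric - .Machine$double.eps) {
        best_metric <- metric
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
    } else {
      # literal reading of the protocol: the gradient "did not decrease"
      # compares each iteration with its predecessor
      if (metric < prev_metric - .Machine$double.eps) {
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      prev_metric <- metric
    }
    if (stall >= config$patience) {
      stop_reason <- if (config$stop_rule == "validation") {
        "validation_patience"
      } else "gradient_patience"
      break
    }
  }

  hist <- tibble::as_tibble(do.call(rbind, history[seq_len(iter)]))
  structure(list(
    weights = p,
    dims = dims,
    activation = "tanh",
    input_scaler = sx,
    output_scaler = sy,
    input_columns = in_cols,
    output_columns = out_cols,
    history = hist,
    stop_reason = stop_reason,
    iterations = iter,
    final_loss = loss,
    config = config
  ), class = "mlp_model")
}

#' Predict from a trained network
#'
#' Applies the stored input scaler, the network, and the inverse output
#' scaler.  If `X` has column names they must match the training schema.
#'
#' @param object An `mlp_model`.
#' @param X Feature matrix with the model's input columns.
#' @param ... Unused.
#' @return Matrix of predictions (original target units), one row per input
#'   row.
#' @export
predict.mlp_model <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != object$dims$d_in) {
    abort(sprintf("Expected %d input columns, got %d.", object$dims$d_in,
                  ncol(X)), class = "imu2grf_schema")
  }
  if (!is.null(colnames(X)) && !identical(colnames(X), object$input_columns)) {
    bad <- colnames(X)[colnames(X) != object$input_columns]
    abort(paste0("Input columns do not match the training schema: ",
                 paste(bad, collapse = ", ")), class = "imu2grf_schema")
  }
  Xs <- apply_scaler(X, object$input_scaler)
  Yh <- mlp_forward(object$weights, Xs)$Yh
  out <- invert_scaler(Yh, object$output_scaler)
  colnames(out) <- object$output_columns
  out
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model %d-%d-%d-%d (tanh), %d iterations, stop: %s>\n",
              x$dims$d_in, x$dims$h1, x$dims$h2, x$dims$d_out,
              x$iterations, x$stop_reason))
  invisible(x)
}

#' Tidy the training history of a network
#' @param x An `mlp_model`.
#' @param ... Unused.
#' @return The per-iteration history tibble.
#' @exportS3Method generics::tidy
tidy.mlp_model <- function(x, ...) x$history

#' One-row model summary
#' @param x An `mlp_model`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.mlp_model <- function(x, ...) {
  tibble::tibble(
    inputs = x$dims$d_in, outputs = x$dims$d_out,
    hidden1 = x$dims$h1, hidden2 = x$dims$h2,
    iterations = x$iterations, final_loss = x$final_loss,
    stop_reason = x$stop_reason
  )
}
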