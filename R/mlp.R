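# The deep network: a fixed four-layer 512-unit multilayer perceptron with
# leaky-ReLU activations, 50% dropout between layers and a softmax output,
# trained by mini-batch RMSprop with early stopping on validation loss.
# Implemented directly in matrix algebra; at these input sizes a CPU is
# entirely sufficient.

#' Network architecture specification
#'
#' The architecture is deliberately fixed: four fully connected hidden
#' layers of 512 units each (the first power of two above typical input
#' lengths), 50% dropout after each hidden activation, leaky rectified
#' linear units, and a softmax output over the classes.
#'
#' @param input_dim length of the standardized input vectors.
#' @param n_classes number of target classes (labels are coded 0..N-1).
#' @param hidden hidden layer widths.
#' @param dropout dropout probability between layers.
#' @param leaky_slope negative-side slope of the leaky ReLU.
#' @export
mlp_spec <- function(input_dim, n_classes, hidden = rep(512L, 4L),
                     dropout = 0.5, leaky_slope = 0.01) {
  check_scalar(input_dim, "input_dim"); check_scalar(n_classes, "n_classes")
  structure(list(input_dim = as.integer(input_dim),
                 n_classes = as.integer(n_classes),
                 hidden = as.integer(hidden), dropout = dropout,
                 leaky_slope = leaky_slope), class = "mlp_spec")
}

#' Training configuration
#'
#' @param learning_rate constant learning rate for RMSprop.
#' @param batch_size mini-batch size (100 for bin-level inputs, 2000 for
#'   detection-level inputs are the working defaults).
#' @param patience epochs without validation improvement before stopping.
#' @param max_epochs hard cap on training epochs.
#' @param seed integer seed for weight initialization, shuffling, dropout.
#' @param monitor early-stopping quantity: validation `"loss"` (default)
#'   or `"accuracy"`.
#' @param rho,epsilon RMSprop decay and stabilizer.
#' @export
train_config <- function(learning_rate = 3e-4, batch_size = 2000,
                         patience = 3, max_epochs = 15, seed = 1L,
                         monitor = c("loss", "accuracy"),
                         rho = 0.9, epsilon = 1e-8) {
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 patience = patience, max_epochs = max_epochs,
                 seed = as.integer(seed), monitor = match.arg(monitor),
                 rho = rho, epsilon = epsilon), class = "train_config")
}

init_weights <- function(spec) {
  dims <- c(spec$input_dim, spec$hidden, spec$n_classes)
  lapply(seq_len(length(dims) - 1L), function(l) {
    list(W = matrix(rnorm(dims[l] * dims[l + 1L], sd = sqrt(2 / dims[l])),
                    dims[l], dims[l + 1L]),
         b = numeric(dims[l + 1L]))
  })
}

leaky_relu <- function(z, slope) ifelse(z > 0, z, slope * z)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# forward pass; when training, applies inverted dropout with the supplied
# RNG stream and returns the per-layer activations for backprop
mlp_forward <- function(layers, spec, x, training = FALSE) {
  acts <- list(x)
  masks <- list()
  h <- x
  nl <- length(layers)
  for (l in seq_len(nl - 1L)) {
    z <- sweep(h %*% layers[[l]]$W, 2, layers[[l]]$b, `+`)
    h <- leaky_relu(z, spec$leaky_slope)
    if (training && spec$dropout > 0) {
      m <- matrix(runif(length(h)) >= spec$dropout, nrow(h), ncol(h)) /
        (1 - spec$dropout)
      h <- h * m
      masks[[l]] <- m
    }
    acts[[l + 1L]] <- h
  }
  z_out <- sweep(h %*% layers[[nl]]$W, 2, layers[[nl]]$b, `+`)
  p <- softmax_rows(z_out)
  list(p = p, acts = acts, masks = masks)
}

cross_entropy <- function(p, y) {
  -mean(log(pmax(p[cbind(seq_along(y), y + 1L)], 1e-12)))
}

#' Train the classifier network
#'
#' Mini-batch RMSprop at a constant learning rate with softmax
#' cross-entropy loss. After each epoch the validation set is evaluated;
#' when the monitored quantity has not improved for `patience` consecutive
#' epochs training stops and the best-epoch weights are restored. Training
#' is fully reproducible given `cfg$seed`.
#'
#' @param spec [mlp_spec()]; `input_dim` must match the training matrix.
#' @param cfg [train_config()].
#' @param train,val `training_set` objects sharing one class encoding.
#' @return a `click_mlp` model with the fitted `layers`, `spec`,
#'   `class_names`, `history` (per-epoch train/val loss and accuracy) and
#'   `best_epoch`.
#' @export
train_mlp <- function(spec, cfg, train, val) {
  if (ncol(train$x) != spec$input_dim) {
    stopf("input_dim mismatch: spec %d vs data %d", spec$input_dim,
          ncol(train$x))
  }
  if (!nrow(val$x)) stopf("validation set is empty")
  if (!identical(train$class_names, val$class_names)) {
    stopf("train and validation sets use different class encodings")
  }
  with_seed(cfg$seed, {
    layers <- init_weights(spec)
    cache <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
    n <- nrow(train$x)
    nl <- length(layers)
    history <- data.frame()
    best <- list(metric = Inf, epoch = 0L, layers = layers)
    stall <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      ep_loss <- 0; ep_correct <- 0
      for (s in starts) {
        bi <- ord[s:min(s + cfg$batch_size - 1L, n)]
        xb <- train$x[bi, , drop = FALSE]
        yb <- train$y[bi]
        fw <- mlp_forward(layers, spec, xb, training = TRUE)
        m <- length(bi)
        ep_loss <- ep_loss + cross_entropy(fw$p, yb) * m
        ep_correct <- ep_correct + sum(max.col(fw$p) - 1L == yb)
        # backprop
        delta <- fw$p
        delta[cbind(seq_len(m), yb + 1L)] <-
          delta[cbind(seq_len(m), yb + 1L)] - 1
        delta <- delta / m
        for (l in nl:1) {
          gW <- crossprod(fw$acts[[l]], delta)
          gb <- colSums(delta)
          if (l > 1L) {
            back <- tcrossprod(delta, layers[[l]]$W)
            h_pre <- fw$acts[[l]]           # post-activation (post-dropout)
            if (spec$dropout > 0) back <- back * fw$masks[[l - 1L]]
            slope_mask <- ifelse(h_pre > 0, 1, spec$leaky_slope)
            delta <- back * slope_mask
          }
          cache[[l]]$W <- cfg$rho * cache[[l]]$W + (1 - cfg$rho) * gW^2
          cache[[l]]$b <- cfg$rho * cache[[l]]$b + (1 - cfg$rho) * gb^2
          layers[[l]]$W <- layers[[l]]$W -
            cfg$learning_rate * gW / (sqrt(cache[[l]]$W) + cfg$epsilon)
          layers[[l]]$b <- layers[[l]]$b -
            cfg$learning_rate * gb / (sqrt(cache[[l]]$b) + cfg$epsilon)
        }
        if (!is.finite(ep_loss)) {
          stopf("training diverged (non-finite loss) at epoch %d", epoch)
        }
      }
      vp <- mlp_forward(layers, spec, val$x)$p
      val_loss <- cross_entropy(vp, val$y)
      val_acc <- mean(max.col(vp) - 1L == val$y)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = ep_loss / n, train_acc = ep_correct / n,
        val_loss = val_loss, val_acc = val_acc))
      metric <- if (cfg$monitor == "loss") val_loss else -val_acc
      if (metric < best$metric - 1e-12) {
        best <- list(metric = metric, epoch = epoch, layers = layers)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
    structure(list(layers = best$layers, spec = spec,
                   class_names = train$class_names, history = history,
                   best_epoch = best$epoch, config = cfg),
              class = "click_mlp")
  })
}

#' @export
print.click_mlp <- function(x, ...) {
  cat(sprintf(
    "<click_mlp> %d -> %s -> %d classes; trained %d epoch(s), best %d\n",
    x$spec$input_dim, paste(x$spec$hidden, collapse = "-"),
    x$spec$n_classes, nrow(x$history), x$best_epoch))
  invisible(x)
}

#' Class probabilities for new inputs
#'
#' Inference is deterministic: dropout is disabled and each row yields a
#' probability vector over the classes summing to 1. The maximum
#' probability serves as the label's confidence score.
#'
#' @param object a `click_mlp`.
#' @param x matrix of standardized input rows.
#' @param ... unused.
#' @return a `prediction_set`: `prob` matrix, `label` (character),
#'   `label_code` (0-based), `score` (max probability), `class_names`.
#' @export
predict.click_mlp <- function(object, x, ...) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != object$spec$input_dim) {
    stopf("input_dim mismatch: model %d vs data %d",
          object$spec$input_dim, ncol(x))
  }
  p <- mlp_forward(object$layers, object$spec, x)$p
  colnames(p) <- object$class_names
  code <- max.col(p, ties.method = "first") - 1L
  structure(list(prob = p, label = object$class_names[code + 1L],
                 label_code = code, score = p[cbind(seq_len(nrow(p)),
                                                    code + 1L)],
                 class_names = object$class_names),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set> %d items over %d classes\n",
              length(x$label), length(x$class_names)))
  invisible(x)
}

#' Retain labels above a probability threshold
#'
#' @param preds a `prediction_set`.
#' @param tau minimum confidence score; labels below it are marked
#'   discarded.
#' @return data.frame with `label`, `score`, `retained`.
#' @export
apply_threshold <- function(preds, tau) {
  data.frame(label = preds$label, score = preds$score,
             retained = preds$score >= tau)
}
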