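#' Forward connectivity patterns
#'
#' Seven ways of wiring the layers \code{IN}, \code{L1} (internal), \code{L2}
#' (hidden) and \code{OUT} with fully connected, strictly forward edge
#' blocks. \code{net1}/\code{net2} are one-layer networks (no \code{L2});
#' the rest are hidden-layer networks. Beyond the chain of adjacent layers,
#' patterns add skip blocks: \code{net2} input-to-output, \code{net4}
#' input-to-hidden ("not-fully input connectivity"), \code{net5}
#' internal-to-output ("internal connectivity"), \code{net6} both of those,
#' and \code{net7} all input skips ("fully input connectivity"). The exact
#' edge sets are a documented convention; alternatives can be expressed by
#' constructing the object directly.
#'
#' @param id one of \code{"net1"} ... \code{"net7"}.
#' @return An object of class \code{connectivity_pattern}: list with
#'   \code{id}, \code{layers}, and \code{blocks} (character vector of
#'   \code{"SRC->DST"} edge blocks).
#' @export
#' @examples
#' connectivity_pattern("net7")$blocks
connectivity_pattern <- function(id = paste0("net", 1:7)) {
  id <- match.arg(id)
  blocks <- switch(id,
    net1 = c("IN->L1", "L1->OUT"),
    net2 = c("IN->L1", "L1->OUT", "IN->OUT"),
    net3 = c("IN->L1", "L1->L2", "L2->OUT"),
    net4 = c("IN->L1", "L1->L2", "L2->OUT", "IN->L2"),
    net5 = c("IN->L1", "L1->L2", "L2->OUT", "L1->OUT"),
    net6 = c("IN->L1", "L1->L2", "L2->OUT", "IN->L2", "L1->OUT"),
    net7 = c("IN->L1", "L1->L2", "L2->OUT", "IN->L2", "IN->OUT"))
  layers <- if (id %in% c("net1", "net2")) c("IN", "L1", "OUT")
            else c("IN", "L1", "L2", "OUT")
  structure(list(id = id, layers = layers, blocks = blocks),
            class = "connectivity_pattern")
}

.block_ends <- function(block) strsplit(block, "->", fixed = TRUE)[[1]]

#' Describe a network architecture
#'
#' @param n_inputs number of input units (4 for dialect A, 8 for dialect B).
#' @param units_internal units in the internal layer \code{L1} (1--20).
#' @param units_hidden units in the hidden layer \code{L2}; 0 for a
#'   one-layer network.
#' @param pattern a \code{\link{connectivity_pattern}} or its id.
#' @param n_outputs number of output classes (3).
#' @param activation sigmoid for internal/hidden units: the \code{"tanh"}
#'   sigmoid (default, the transfer the training constants and the
#'   Nguyen-Widrow scale are calibrated for) or the \code{"logistic"} one.
#' @return Object of class \code{network_spec}.
#' @export
#' @examples
#' network_spec(4, 12)                 # the 4-12-3 one-layer network
#' network_spec(8, 11, 8, "net3")      # the 8-11-8-3 hidden-layer network
network_spec <- function(n_inputs, units_internal, units_hidden = 0L,
                         pattern = "net1", n_outputs = 3L,
                         activation = c("tanh", "logistic")) {
  activation <- match.arg(activation)
  if (is.character(pattern)) pattern <- connectivity_pattern(pattern)
  stopifnot(inherits(pattern, "connectivity_pattern"),
            n_inputs >= 1, units_internal >= 1, units_hidden >= 0,
            n_outputs >= 2)
  has_l2 <- "L2" %in% pattern$layers
  if (has_l2 && units_hidden < 1)
    stop(sprintf("pattern %s has a hidden layer; units_hidden must be >= 1",
                 pattern$id), call. = FALSE)
  if (!has_l2 && units_hidden > 0)
    stop(sprintf("pattern %s is a one-layer pattern; units_hidden must be 0",
                 pattern$id), call. = FALSE)
  structure(list(n_inputs = as.integer(n_inputs),
                 units_internal = as.integer(units_internal),
                 units_hidden = as.integer(units_hidden),
                 n_outputs = as.integer(n_outputs),
                 pattern = pattern, activation = activation),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  sizes <- .layer_sizes(x)
  cat(sprintf("Network %s: %s (%d connections)\n", x$pattern$id,
              paste(sizes, collapse = "-"), count_connections(x)))
  invisible(x)
}

.layer_sizes <- function(spec) {
  s <- c(IN = spec$n_inputs, L1 = spec$units_internal)
  if ("L2" %in% spec$pattern$layers) s <- c(s, L2 = spec$units_hidden)
  c(s, OUT = spec$n_outputs)
}

#' Total number of connections of an architecture
#'
#' Counts every weight in every edge block of the pattern plus one bias per
#' non-input unit, covering the entire structure including input and output
#' connections.
#'
#' @param spec a \code{\link{network_spec}}.
#' @return Integer connection count.
#' @export
#' @examples
#' count_connections(network_spec(4, 12))            # 99
#' count_connections(network_spec(8, 11, 8, "net3")) # 222
count_connections <- function(spec) {
  sizes <- .layer_sizes(spec)
  w <- sum(vapply(spec$pattern$blocks, function(b) {
    e <- .block_ends(b)
    sizes[[e[1]]] * sizes[[e[2]]]
  }, numeric(1)))
  as.integer(w + sum(sizes[names(sizes) != "IN"]))
}

# incoming blocks of a layer under a pattern
.incoming <- function(pattern, layer) {
  pattern$blocks[vapply(pattern$blocks,
                        function(b) .block_ends(b)[2] == layer, logical(1))]
}

#' Nguyen-Widrow weight initialization
#'
#' Sigmoid layers (\code{L1}, \code{L2}) get unit weight vectors of random
#' direction rescaled to the Nguyen-Widrow magnitude
#' \eqn{0.7 H^{1/F}} (H units in the layer, F total fan-in over all incoming
#' blocks) so that the units' active regions tile the input space; their
#' biases are spread uniformly over \eqn{[-0.7 H^{1/F}, 0.7 H^{1/F}]}. The
#' softmax output layer gets small uniform weights and zero biases.
#'
#' @param spec a \code{\link{network_spec}}.
#' @param seed integer seed; equal seeds give identical states.
#' @return Object of class \code{weight_state}: list of weight matrices
#'   \code{W[["SRC->DST"]]} (source units by destination units) and bias
#'   vectors \code{b[[layer]]}.
#' @export
nguyen_widrow_init <- function(spec, seed = 1L) {
  set.seed(seed)
  sizes <- .layer_sizes(spec)
  W <- list()
  b <- list()
  for (layer in setdiff(spec$pattern$layers, "IN")) {
    inc <- .incoming(spec$pattern, layer)
    fan_in <- sum(vapply(inc, function(bl) sizes[[.block_ends(bl)[1]]],
                         numeric(1)))
    h <- sizes[[layer]]
    if (layer == "OUT") {
      for (bl in inc) {
        src <- sizes[[.block_ends(bl)[1]]]
        W[[bl]] <- matrix(stats::runif(src * h, -0.5, 0.5), src, h)
      }
      b[[layer]] <- rep(0, h)
    } else {
      beta <- nw_scale(h, fan_in)
      raw <- matrix(stats::runif(fan_in * h, -1, 1), fan_in, h)
      raw <- sweep(raw, 2, sqrt(colSums(raw^2)), "/") * beta
      offset <- 0L
      for (bl in inc) {
        src <- sizes[[.block_ends(bl)[1]]]
        W[[bl]] <- raw[offset + seq_len(src), , drop = FALSE]
        offset <- offset + src
      }
      b[[layer]] <- if (h == 1L) 0 else beta * seq(-1, 1, length.out = h)
    }
  }
  structure(list(W = W, b = b, spec_sizes = sizes), class = "weight_state")
}

#' @rdname nguyen_widrow_init
#' @param h units in the layer.
#' @param fan_in total number of incoming units.
#' @export
nw_scale <- function(h, fan_in) 0.7 * h^(1 / fan_in)

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

.sigmoid_of <- function(spec) {
  if (identical(spec$activation, "logistic")) function(z) 1 / (1 + exp(-z))
  else tanh
}

# per-column min-max mapping of integer inputs to [-1, 1]; constant columns
# (e.g. the zero-filled second placement) map to -1
.input_map <- function(x) {
  lo <- apply(x, 2, min)
  span <- pmax(apply(x, 2, max) - lo, 1)
  list(lo = lo, span = span)
}

.apply_input_map <- function(x, map) {
  2 * sweep(sweep(x, 2, map$lo), 2, map$span, "/") - 1
}

#' Forward pass
#'
#' Propagates a batch of inputs through the network: internal and hidden
#' units apply the spec's sigmoid to the sum of all their incoming edge
#' blocks plus bias; output units apply softmax. If the weight state carries
#' an input mapping (attached by \code{\link{train_network}}), raw integer
#' inputs are min-max mapped to \code{[-1, 1]} first.
#'
#' @param spec a \code{\link{network_spec}}.
#' @param weights a \code{weight_state}.
#' @param x input matrix (samples by \code{n_inputs}) or a single vector.
#' @param keep_activations return per-layer activations (for backprop).
#' @return Matrix of class probabilities (rows sum to 1); with
#'   \code{keep_activations}, a list \code{(prob, activations)}.
#' @export
forward <- function(spec, weights, x, keep_activations = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  dimnames(x) <- NULL
  if (ncol(x) != spec$n_inputs)
    stop(sprintf("input has %d columns; spec expects %d", ncol(x),
                 spec$n_inputs), call. = FALSE)
  if (!is.null(weights$input_map))
    x <- .apply_input_map(x, weights$input_map)
  sigmoid <- .sigmoid_of(spec)
  act <- list(IN = x)
  for (layer in setdiff(spec$pattern$layers, "IN")) {
    z <- matrix(weights$b[[layer]], nrow(x), length(weights$b[[layer]]),
                byrow = TRUE)
    for (bl in .incoming(spec$pattern, layer)) {
      z <- z + act[[.block_ends(bl)[1]]] %*% weights$W[[bl]]
    }
    act[[layer]] <- if (layer == "OUT") .softmax(z) else sigmoid(z)
  }
  if (keep_activations) list(prob = act$OUT, activations = act)
  else act$OUT
}

#' Mean cross-entropy loss
#'
#' \eqn{CE = -t \log y} summed over classes and averaged over samples.
#' Predicted probabilities are clamped at \code{1e-12} to avoid
#' \eqn{-\log 0}.
#'
#' @param targets one-hot target matrix.
#' @param outputs predicted probability matrix.
#' @return Non-negative scalar.
#' @export
cross_entropy <- function(targets, outputs) {
  stopifnot(all(dim(targets) == dim(outputs)))
  -mean(rowSums(targets * log(pmax(outputs, 1e-12))))
}

# analytic gradient of mean CE wrt every weight/bias; same shapes as weights
.gradients <- function(spec, weights, x, y) {
  y <- unname(y)
  fw <- forward(spec, weights, x, keep_activations = TRUE)
  act <- fw$activations
  n <- nrow(x)
  delta <- list(OUT = (fw$prob - y) / n)   # softmax + CE shortcut
  rev_layers <- rev(setdiff(spec$pattern$layers, c("IN", "OUT")))
  for (layer in rev_layers) {
    out_blocks <- spec$pattern$blocks[vapply(
      spec$pattern$blocks, function(b) .block_ends(b)[1] == layer,
      logical(1))]
    back <- 0
    for (bl in out_blocks) {
      back <- back + delta[[.block_ends(bl)[2]]] %*% t(weights$W[[bl]])
    }
    a <- act[[layer]]
    delta[[layer]] <- back * (if (identical(spec$activation, "logistic"))
      a * (1 - a) else 1 - a^2)
  }
  gW <- lapply(stats::setNames(nm = spec$pattern$blocks), function(bl) {
    e <- .block_ends(bl)
    t(act[[e[1]]]) %*% delta[[e[2]]]
  })
  gb <- lapply(stats::setNames(nm = setdiff(spec$pattern$layers, "IN")),
               function(l) colSums(delta[[l]]))
  list(W = gW, b = gb)
}

#' Training hyper-parameters
#'
#' The adaptive-learning-rate batch gradient-descent constants: initial
#' learning rate 0.01, increase factor 1.05 on kept epochs, decrease factor
#' 0.7 with the epoch's update discarded when the training error grows by
#' more than the ratio 1.04, stop at a cross-entropy of 0.001, after 10
#' epochs without a new best validation error, or at \code{max_epochs}.
#'
#' @param lr0 initial learning rate.
#' @param lr_up,lr_down multiplicative learning-rate adaptation factors.
#' @param err_ratio_threshold revert threshold on consecutive-epoch error
#'   ratio (strict inequality).
#' @param max_validation_failures epochs without validation improvement
#'   tolerated before stopping.
#' @param performance_goal cross-entropy stopping goal.
#' @param max_epochs epoch cap.
#' @return Object of class \code{train_config}.
#' @export
train_config <- function(lr0 = 0.01, lr_up = 1.05, lr_down = 0.7,
                         err_ratio_threshold = 1.04,
                         max_validation_failures = 10L,
                         performance_goal = 0.001, max_epochs = 1000L) {
  stopifnot(lr0 > 0, lr_down < 1, lr_up > 1, err_ratio_threshold > 0,
            max_validation_failures >= 1, performance_goal > 0,
            max_epochs >= 1)
  structure(list(lr0 = lr0, lr_up = lr_up, lr_down = lr_down,
                 err_ratio_threshold = err_ratio_threshold,
                 max_validation_failures = as.integer(max_validation_failures),
                 performance_goal = performance_goal,
                 max_epochs = as.integer(max_epochs)),
            class = "train_config")
}

#' One step of the adaptive learning-rate rule
#'
#' If the new training error exceeds the previous one by more than the
#' configured ratio (strictly), the epoch's update is discarded and the
#' learning rate shrinks by \code{lr_down}; otherwise the update is kept
#' and the learning rate grows by \code{lr_up}.
#'
#' @param ce_new,ce_prev training cross-entropy after and before the update.
#' @param lr current learning rate.
#' @param config a \code{\link{train_config}}.
#' @return List \code{(keep, lr)}.
#' @export
#' @examples
#' adapt_lr(1.05, 1.00, 0.01, train_config()) # revert, lr 0.007
#' adapt_lr(1.04, 1.00, 0.01, train_config()) # keep (strict), lr 0.0105
adapt_lr <- function(ce_new, ce_prev, lr, config = train_config()) {
  if (ce_new / ce_prev > config$err_ratio_threshold) {
    list(keep = FALSE, lr = config$lr_down * lr)
  } else {
    list(keep = TRUE, lr = config$lr_up * lr)
  }
}

.apply_update <- function(weights, grads, lr, lr_mask = NULL) {
  for (bl in names(grads$W)) {
    step <- lr * grads$W[[bl]]
    if (!is.null(lr_mask)) step <- step * lr_mask$W[[bl]]
    weights$W[[bl]] <- weights$W[[bl]] - step
  }
  for (l in names(grads$b)) {
    step <- lr * grads$b[[l]]
    if (!is.null(lr_mask)) step <- step * lr_mask$b[[l]]
    weights$b[[l]] <- weights$b[[l]] - step
  }
  weights
}

#' All-ones learning-rate mask for a spec
#'
#' @param spec a \code{\link{network_spec}}.
#' @param value fill value (default 1).
#' @return A mask with the same block structure as a \code{weight_state}.
#' @export
ones_mask <- function(spec, value = 1) {
  w0 <- nguyen_widrow_init(spec, seed = 0L)
  list(W = lapply(w0$W, function(m) array(value, dim(m))),
       b = lapply(w0$b, function(v) rep(value, length(v))))
}

#' Random 70/15/15 division of sample indices
#'
#' The division used by one training call: uniformly random, non-stratified,
#' re-drawn per call from its seed (so repeated trials see different
#' divisions, as the 20-trial protocol intends).
#'
#' @param n number of samples.
#' @param seed integer seed.
#' @param fractions split fractions.
#' @return Character vector of \code{train}/\code{validation}/\code{test}.
#' @export
divide_random <- function(n, seed = 1L,
                          fractions = c(0.70, 0.15, 0.15)) {
  set.seed((as.numeric(seed) * 77) %% .Machine$integer.max)
  idx <- sample.int(n)
  n_tr <- round(fractions[1] * n)
  n_va <- round(fractions[2] * n)
  out <- character(n)
  out[idx[seq_len(n_tr)]] <- "train"
  out[idx[n_tr + seq_len(n_va)]] <- "validation"
  out[idx[seq.int(n_tr + n_va + 1L, n)]] <- "test"
  out
}

#' Train a network on an OHC subset
#'
#' Full-batch gradient descent on the training split with the adaptive
#' learning-rate rule of \code{\link{adapt_lr}}. Inputs are min-max mapped
#' to \code{[-1, 1]} per column; the mapping is stored on the returned
#' weights so that later forward passes accept raw integer inputs. Training
#' stops when the training cross-entropy reaches \code{performance_goal},
#' when the validation cross-entropy has not improved on its best value for
#' \code{max_validation_failures} epochs, or at \code{max_epochs}. An
#' optional \code{lr_mask} scales the update of designated parameters (0
#' freezes them exactly).
#'
#' @param spec a \code{\link{network_spec}}.
#' @param subset an \code{ohc_subset} whose encoded width matches
#'   \code{spec$n_inputs}.
#' @param config a \code{\link{train_config}}.
#' @param initial optional starting \code{weight_state}; by default a fresh
#'   Nguyen-Widrow state seeded with \code{seed}.
#' @param lr_mask optional per-parameter step scale (see
#'   \code{\link{ones_mask}}).
#' @param seed seed for the initialization and the random division.
#' @param division \code{"resample"} (default) draws a fresh random
#'   70/15/15 division from the seed, as one trial of the repeated-trial
#'   protocol; \code{"stored"} uses the subset's stratified split.
#' @return Object of class \code{train_result}: final weights, stop reason
#'   (\code{goal_met}, \code{validation_failures}, \code{max_epochs} or
#'   \code{diverged}), epochs run, per-epoch trace, and accuracies on the
#'   train/validation/test divisions and the full subset.
#' @export
train_network <- function(spec, subset, config = train_config(),
                          initial = NULL, lr_mask = NULL, seed = 1L,
                          division = c("resample", "stored")) {
  stopifnot(inherits(spec, "network_spec"), inherits(subset, "ohc_subset"))
  division <- match.arg(division)
  if (ncol(subset$x) != spec$n_inputs)
    stop(sprintf("subset encodes %d inputs; spec expects %d",
                 ncol(subset$x), spec$n_inputs), call. = FALSE)
  div <- if (division == "resample") divide_random(nrow(subset$x), seed)
         else as.character(subset$split)
  tr <- div == "train"
  va <- div == "validation"

  weights <- if (is.null(initial)) nguyen_widrow_init(spec, seed = seed)
             else initial
  weights$input_map <- weights$input_map %||% .input_map(subset$x)
  x_all <- .apply_input_map(subset$x, weights$input_map)
  mapped <- weights; mapped$input_map <- NULL   # train on pre-mapped inputs
  x_tr <- x_all[tr, , drop = FALSE]; y_tr <- subset$y[tr, , drop = FALSE]
  x_va <- x_all[va, , drop = FALSE]; y_va <- subset$y[va, , drop = FALSE]
  has_val <- nrow(x_va) > 0

  lr <- config$lr0
  ce_prev <- cross_entropy(y_tr, forward(spec, mapped, x_tr))
  best_val <- if (has_val) cross_entropy(y_va, forward(spec, mapped, x_va))
              else NA_real_
  val_fails <- 0L
  stop_reason <- "max_epochs"
  trace <- vector("list", config$max_epochs)
  ep <- 0L

  while (ep < config$max_epochs) {
    ep <- ep + 1L
    grads <- .gradients(spec, mapped, x_tr, y_tr)
    cand <- .apply_update(mapped, grads, lr, lr_mask)
    ce_new <- cross_entropy(y_tr, forward(spec, cand, x_tr))
    if (!is.finite(ce_new)) { stop_reason <- "diverged"; ep <- ep - 1L; break }
    step <- adapt_lr(ce_new, ce_prev, lr, config)
    kept <- step$keep
    if (kept) {
      mapped <- cand
      ce_prev <- ce_new
    }
    val_ce <- NA_real_
    if (has_val) {
      # validation watched every epoch on the current (possibly reverted)
      # weights; failures accumulate since the best value seen
      val_ce <- cross_entropy(y_va, forward(spec, mapped, x_va))
      if (val_ce < best_val) {
        best_val <- val_ce
        val_fails <- 0L
      } else {
        val_fails <- val_fails + 1L
      }
    }
    lr <- step$lr
    trace[[ep]] <- c(epoch = ep, lr = lr, train_ce = ce_prev,
                     val_ce = val_ce, kept = as.integer(kept))
    if (ce_prev <= config$performance_goal) { stop_reason <- "goal_met"; break }
    if (has_val && val_fails >= config$max_validation_failures) {
      stop_reason <- "validation_failures"; break
    }
  }
  weights$W <- mapped$W
  weights$b <- mapped$b

  trace <- as.data.frame(do.call(rbind, trace[seq_len(ep)]))
  acc_of <- function(keep) {
    if (!any(keep)) return(NA_real_)
    accuracy(spec, weights, subset$x[keep, , drop = FALSE],
             subset$y[keep, , drop = FALSE])
  }
  acc <- c(train = acc_of(tr), validation = acc_of(va),
           test = acc_of(div == "test"),
           full = accuracy(spec, weights, subset$x, subset$y))
  structure(list(spec = spec, weights = weights, stop_reason = stop_reason,
                 epochs_run = ep, trace = trace, accuracy = acc,
                 division = div, final_ce = ce_prev, seed = seed),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf(
    "Training run: %d epochs, stop = %s, train CE %.4g, full accuracy %.2f%%\n",
    x$epochs_run, x$stop_reason, x$final_ce, 100 * x$accuracy["full"]))
  invisible(x)
}

#' Classification accuracy
#'
#' Fraction of samples whose argmax predicted class matches the target;
#' argmax ties go to the lowest class index.
#'
#' @param spec a \code{\link{network_spec}}.
#' @param weights a \code{weight_state}.
#' @param x input matrix.
#' @param y one-hot target matrix.
#' @return Fraction in \code{[0, 1]}.
#' @export
accuracy <- function(spec, weights, x, y) {
  if (is.null(dim(x)) || nrow(x) == 0)
    stop("accuracy is undefined on an empty sample set", call. = FALSE)
  p <- forward(spec, weights, x)
  mean(max.col(p, ties.method = "first") ==
         max.col(y, ties.method = "first"))
}

#' Serialize / restore a weight state as structured text
#'
#' Writes named blocks with their shapes to JSON so that a trained state can
#' be archived and reloaded exactly.
#'
#' @param weights a \code{weight_state}.
#' @param path file path.
#' @export
write_weights <- function(weights, path) {
  payload <- list(
    W = lapply(weights$W, function(m) list(dim = dim(m), values = as.vector(m))),
    b = weights$b,
    input_map = weights$input_map)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- lapply(payload$W, function(blk) {
    matrix(blk$values, blk$dim[1], blk$dim[2])
  })
  b <- lapply(payload$b, as.numeric)
  im <- if (!is.null(payload$input_map))
    lapply(payload$input_map, as.numeric)
  structure(list(W = W, b = b, input_map = im), class = "weight_state")
}

#' Write a per-epoch training log
#'
#' One row per epoch (epoch, learning rate, training CE, validation CE,
#' kept/reverted flag) as tab-separated text.
#'
#' @param result a \code{train_result}.
#' @param path file path.
#' @export
write_train_log <- function(result, path) {
  utils::write.table(result$trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
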