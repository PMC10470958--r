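#' Embed a lower-order network's weights into a larger structure
#'
#' The trained weights of the lower-order network become the initial weights
#' of the higher-order one: for every edge block and bias present in both
#' patterns, the lower-order values are copied into the leading unit indices
#' of the corresponding higher-order block; every new unit and every block
#' absent from the lower-order pattern is freshly Nguyen-Widrow initialized.
#'
#' @param lower a trained \code{weight_state} (or a \code{train_result}).
#' @param lower_spec,higher_spec the two \code{\link{network_spec}}s; the
#'   higher spec must contain the lower one (equal input/output width,
#'   unit counts per shared layer at least as large).
#' @param seed seed for the fresh part of the initialization.
#' @return List with the combined \code{weights} and a logical \code{mask}
#'   of the same block structure flagging the lower-order parameters.
#' @export
#' @examples
#' lo <- network_spec(8, 1); hi <- network_spec(8, 12)
#' emb <- embed_weights(nguyen_widrow_init(lo, 1), lo, hi)
#' sum(emb$mask$W[["IN->L1"]])  # the copied column
embed_weights <- function(lower, lower_spec, higher_spec, seed = 1L) {
  if (inherits(lower, "train_result")) lower <- lower$weights
  stopifnot(inherits(higher_spec, "network_spec"),
            inherits(lower_spec, "network_spec"))
  lo_sizes <- .layer_sizes(lower_spec)
  hi_sizes <- .layer_sizes(higher_spec)
  if (lo_sizes[["IN"]] != hi_sizes[["IN"]])
    stop("input widths differ between lower and higher specs", call. = FALSE)
  for (l in intersect(names(lo_sizes), names(hi_sizes))) {
    if (lo_sizes[[l]] > hi_sizes[[l]])
      stop(sprintf(
        "higher spec does not contain the lower one: layer %s shrinks (%d -> %d)",
        l, lo_sizes[[l]], hi_sizes[[l]]), call. = FALSE)
  }

  weights <- nguyen_widrow_init(higher_spec, seed = seed)
  mask <- list(W = lapply(weights$W, function(m) array(FALSE, dim(m))),
               b = lapply(weights$b, function(v) rep(FALSE, length(v))))
  shared <- intersect(lower_spec$pattern$blocks, higher_spec$pattern$blocks)
  for (bl in shared) {
    e <- .block_ends(bl)
    ns <- lo_sizes[[e[1]]]; nd <- lo_sizes[[e[2]]]
    weights$W[[bl]][seq_len(ns), seq_len(nd)] <- lower$W[[bl]]
    mask$W[[bl]][seq_len(ns), seq_len(nd)] <- TRUE
  }
  for (l in intersect(names(lower$b), names(weights$b))) {
    k <- lo_sizes[[l]]
    weights$b[[l]][seq_len(k)] <- lower$b[[l]]
    mask$b[[l]][seq_len(k)] <- TRUE
  }
  list(weights = weights, mask = mask)
}

#' Extract the embedded lower-order substructure
#'
#' Inverse of \code{\link{embed_weights}}: reads the leading unit indices of
#' each shared block back out of a (possibly further trained) higher-order
#' state, yielding a standalone lower-order \code{weight_state}.
#'
#' @param higher a \code{weight_state} of \code{higher_spec}.
#' @inheritParams embed_weights
#' @return A \code{weight_state} for \code{lower_spec}.
#' @export
extract_weights <- function(higher, lower_spec, higher_spec) {
  if (inherits(higher, "train_result")) higher <- higher$weights
  lo_sizes <- .layer_sizes(lower_spec)
  shared <- intersect(lower_spec$pattern$blocks, higher_spec$pattern$blocks)
  if (!setequal(shared, lower_spec$pattern$blocks))
    stop(sprintf("higher pattern lacks block(s) %s of the lower pattern",
                 paste(setdiff(lower_spec$pattern$blocks, shared),
                       collapse = ", ")), call. = FALSE)
  W <- list(); b <- list()
  for (bl in lower_spec$pattern$blocks) {
    e <- .block_ends(bl)
    W[[bl]] <- higher$W[[bl]][seq_len(lo_sizes[[e[1]]]),
                              seq_len(lo_sizes[[e[2]]]), drop = FALSE]
  }
  for (l in setdiff(lower_spec$pattern$layers, "IN")) {
    b[[l]] <- higher$b[[l]][seq_len(lo_sizes[[l]])]
  }
  structure(list(W = W, b = b, spec_sizes = lo_sizes), class = "weight_state")
}

# lr mask from a logical lower-order mask: lr_scale on the lower block,
# 1 elsewhere
.mask_to_lr <- function(mask, lr_scale) {
  list(W = lapply(mask$W, function(m) ifelse(m, lr_scale, 1)),
       b = lapply(mask$b, function(v) ifelse(v, lr_scale, 1)))
}

#' Train one order-to-order transition under a learning-rate condition
#'
#' Trains the embedded higher-order network on the higher-order subset while
#' the learning rate over the lower-order weight block is scaled by
#' \code{lr_scale} (0.8/0.7/0.5 for the 20/30/50\% reductions, 0 for frozen).
#' The scaled rate still follows the global adaptive rule.
#'
#' @param embedded the \code{(weights, mask)} pair from
#'   \code{\link{embed_weights}}.
#' @param higher_spec the higher-order \code{\link{network_spec}}.
#' @param subset the higher-order \code{ohc_subset}.
#' @param lr_scale learning-rate scale on the lower-order block, in
#'   \code{[0, 1]}.
#' @param config a \code{\link{train_config}}.
#' @param seed seed for the training call's random division.
#' @return Object of class \code{transition_result}: the underlying
#'   \code{train_result}, the accuracy on the higher-order subset, the drift
#'   (root-mean-square change) of the lower-order block, and the trained
#'   weights.
#' @export
train_transition <- function(embedded, higher_spec, subset, lr_scale,
                             config = train_config(), seed = 1L) {
  stopifnot(lr_scale >= 0, lr_scale <= 1)
  lr_mask <- .mask_to_lr(embedded$mask, lr_scale)
  res <- train_network(higher_spec, subset, config = config,
                       initial = embedded$weights, lr_mask = lr_mask,
                       seed = seed)
  before <- unlist(lapply(names(embedded$mask$W), function(bl)
    embedded$weights$W[[bl]][embedded$mask$W[[bl]]]))
  after <- unlist(lapply(names(embedded$mask$W), function(bl)
    res$weights$W[[bl]][embedded$mask$W[[bl]]]))
  before <- c(before, unlist(lapply(names(embedded$mask$b), function(l)
    embedded$weights$b[[l]][embedded$mask$b[[l]]])))
  after <- c(after, unlist(lapply(names(embedded$mask$b), function(l)
    res$weights$b[[l]][embedded$mask$b[[l]]])))
  drift <- if (length(before)) sqrt(mean((after - before)^2)) else 0
  structure(list(result = res, lr_scale = lr_scale,
                 accuracy = res$accuracy[["full"]],
                 lower_block_drift = drift,
                 lower_block_identical = identical(before, after)),
            class = "transition_result")
}

#' @export
print.transition_result <- function(x, ...) {
  cat(sprintf(
    "Transition (lr scale %.1f): accuracy %.2f%%, lower-block drift %.3g%s\n",
    x$lr_scale, 100 * x$accuracy, x$lower_block_drift,
    if (x$lower_block_identical) " (bit-identical)" else ""))
  invisible(x)
}

#' Built-in network progression options
#'
#' Three configurable progressions of network structures across the four
#' problem orders (concrete 9 through systematic 12), all starting from the
#' single-unit one-layer network that solves the counting and sum problems:
#' option 1 grows the internal layer for the multiplication problems and
#' then adds a small hidden layer; option 2 adds a hidden layer first and
#' then doubles its units; option 3 uses the densest input-connectivity
#' pattern with a hidden layer, then doubles the internal layer. Structures
#' never shrink along a progression. Options can also be read from a YAML
#' file (see \code{\link{read_progression}}).
#'
#' @param option 1, 2 or 3.
#' @param n_inputs input width (8 for dialect B).
#' @return Named list of \code{\link{network_spec}}s for the four orders
#'   (class \code{progression_option}).
#' @export
progression_option <- function(option = 1L, n_inputs = 8L) {
  base <- list(concrete9_weight = network_spec(n_inputs, 1),
               abstract10 = network_spec(n_inputs, 1))
  rest <- switch(as.character(option),
    "1" = list(formal11 = network_spec(n_inputs, 12),
               systematic12 = network_spec(n_inputs, 12, 4, "net3")),
    "2" = list(formal11 = network_spec(n_inputs, 1, 10, "net3"),
               systematic12 = network_spec(n_inputs, 1, 20, "net3")),
    "3" = list(formal11 = network_spec(n_inputs, 1, 8, "net7"),
               systematic12 = network_spec(n_inputs, 16, 8, "net7")),
    stop("option must be 1, 2 or 3", call. = FALSE))
  structure(c(base, rest), class = "progression_option")
}

#' Read / write a progression option as structured text
#'
#' One entry per order with unit counts and pattern id.
#'
#' @param path YAML file path.
#' @param option a \code{progression_option}.
#' @return \code{read_progression} returns a \code{progression_option}.
#' @export
read_progression <- function(path) {
  raw <- yaml::read_yaml(path)
  specs <- lapply(raw$orders, function(o)
    network_spec(raw$n_inputs, o$units_internal, o$units_hidden %||% 0L,
                 o$pattern %||% "net1"))
  structure(specs, class = "progression_option")
}

#' @rdname read_progression
#' @export
write_progression <- function(option, path) {
  n_inputs <- option[[1]]$n_inputs
  orders <- lapply(option, function(s)
    list(units_internal = s$units_internal, units_hidden = s$units_hidden,
         pattern = s$pattern$id))
  yaml::write_yaml(list(n_inputs = n_inputs, orders = orders), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a full developmental progression
#'
#' Runs the sequential-transfer experiment: the network for the lowest order
#' is trained from scratch on its subset; at each transition its final
#' weights are embedded into the next structure, which is trained on the
#' next subset under each learning-rate condition. For every transition and
#' condition the table records the accuracy on the new subset, the drift of
#' the lower-order block, and a retention audit: the accuracy of the
#' extracted lower-order substructure on its own subset before and after the
#' higher-order training.
#'
#' @param option a \code{\link{progression_option}}.
#' @param subsets named list of \code{ohc_subset}s covering the option's
#'   orders.
#' @param lr_scales learning-rate conditions on the lower-order block.
#' @param config a \code{\link{train_config}}.
#' @param seed base seed.
#' @return A data.frame (class \code{progression_table}) with one row per
#'   transition and condition.
#' @export
evaluate_progression <- function(option, subsets,
                                 lr_scales = c(0.8, 0.7, 0.5, 0.0),
                                 config = train_config(), seed = 1L) {
  orders <- names(option)
  missing <- setdiff(orders, names(subsets))
  if (length(missing))
    stop("missing subset(s) for order(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  rows <- list()
  # each condition runs its own sequential chain from the lowest order up
  for (sc in lr_scales) {
    current <- train_network(option[[1]], subsets[[orders[1]]],
                             config = config, seed = seed)
    current_spec <- option[[1]]
    for (k in seq_along(orders)[-1]) {
      hi_spec <- option[[k]]
      lo_acc_before <- accuracy(current_spec, current$weights,
                                subsets[[orders[k - 1]]]$x,
                                subsets[[orders[k - 1]]]$y)
      emb <- embed_weights(current, current_spec, hi_spec, seed = seed + k)
      tr <- train_transition(emb, hi_spec, subsets[[orders[k]]],
                             lr_scale = sc, config = config, seed = seed + k)
      # the embedded substructure can only be audited in place when the
      # higher pattern retains every lower-order block; across a pattern
      # change the preserved standalone copy carries the retention claim
      lo_acc_after <- if (all(current_spec$pattern$blocks %in%
                                hi_spec$pattern$blocks)) {
        extracted <- extract_weights(tr$result$weights, current_spec, hi_spec)
        extracted$input_map <- current$weights$input_map
        accuracy(current_spec, extracted,
                 subsets[[orders[k - 1]]]$x,
                 subsets[[orders[k - 1]]]$y)
      } else {
        NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        transition = sprintf("%s->%s", orders[k - 1], orders[k]),
        lr_scale = sc,
        accuracy = tr$accuracy,
        lower_block_drift = tr$lower_block_drift,
        lower_acc_before = lo_acc_before,
        lower_acc_after_extracted = lo_acc_after,
        lower_acc_preserved = lo_acc_before,  # the standalone copy is untouched
        stringsAsFactors = FALSE)
      current <- tr$result
      current_spec <- hi_spec
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("progression_table", class(out))
  out
}

#' Write a progression table
#'
#' Delimited text mirroring the sequential-performance table layout:
#' learning-rate condition by transition, with accuracies in percent and the
#' retention audit columns.
#'
#' @param table a \code{progression_table}.
#' @param path file path.
#' @export
write_progression_table <- function(table, path) {
  df <- table
  for (col in c("accuracy", "lower_acc_before", "lower_acc_after_extracted",
                "lower_acc_preserved"))
    df[[col]] <- round(100 * df[[col]], 2)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
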