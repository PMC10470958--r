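#' Balance-beam problem dialects
#'
#' A dialect fixes the input encoding of a balance-beam configuration.
#' Dialect \code{"A"} encodes one placement per side as a 4-integer vector
#' \code{[w_right, w_left, d_right, d_left]} with values in 1--20.
#' Dialect \code{"B"} encodes up to two placements per side as an 8-integer
#' vector \code{[w1_r, w1_l, d1_r, d1_l, w2_r, w2_l, d2_r, d2_l]} with values
#' in 1--5; single-placement problems carry a zero-filled second placement.
#'
#' @param name \code{"A"} or \code{"B"}.
#' @return An object of class \code{beam_dialect} with fields \code{name},
#'   \code{vector_length} and \code{value_range}.
#' @export
#' @examples
#' beam_dialect("A")
beam_dialect <- function(name = c("A", "B")) {
  name <- match.arg(name)
  out <- if (name == "A") {
    list(name = "A", vector_length = 4L, value_range = c(1L, 20L))
  } else {
    list(name = "B", vector_length = 8L, value_range = c(1L, 5L))
  }
  structure(out, class = "beam_dialect")
}

#' @export
print.beam_dialect <- function(x, ...) {
  cat(sprintf("Balance-beam dialect %s: %d-integer vectors, values %d-%d\n",
              x$name, x$vector_length, x$value_range[1], x$value_range[2]))
  invisible(x)
}

#' Orders of hierarchical complexity of balance-beam problems
#'
#' The five problem classes, named by the arithmetic operation that solves
#' them: counting over weights or over distances (concrete, stage 9), the sum
#' rule (abstract, stage 10), multiplication / the torque rule (formal,
#' stage 11) and the distributive law over two placements per side
#' (systematic, stage 12).
#' @return Character vector of the five labels.
#' @export
ohc_labels <- function() {
  c("concrete9_weight", "concrete9_distance", "abstract10", "formal11",
    "systematic12")
}

.outcome_levels <- c("fall_left", "balance", "fall_right")

#' Construct a single balance-beam configuration
#'
#' @param right,left placements on each side of the fulcrum: either a length-2
#'   vector \code{c(weight, distance)} or a 2-column matrix with one row per
#'   placement (at most two rows). Both sides must carry the same number of
#'   placements, and all values must be positive integers.
#' @return An object of class \code{beam_config}.
#' @export
#' @examples
#' beam_config(right = c(4, 2), left = c(2, 3))
#' beam_config(right = rbind(c(2, 5), c(1, 1)), left = rbind(c(3, 3), c(1, 2)))
beam_config <- function(right, left) {
  as_mat <- function(x, side) {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    x <- as.matrix(x)
    if (ncol(x) != 2L || nrow(x) < 1L || nrow(x) > 2L)
      stop(sprintf("'%s' must give 1 or 2 placements as (weight, distance)",
                   side), call. = FALSE)
    if (any(x < 1) || any(x != round(x)))
      stop(sprintf("'%s' placements must be positive integers", side),
           call. = FALSE)
    storage.mode(x) <- "integer"
    colnames(x) <- c("weight", "distance")
    x
  }
  right <- as_mat(right, "right")
  left <- as_mat(left, "left")
  if (nrow(right) != nrow(left))
    stop("both sides must have the same number of placements", call. = FALSE)
  structure(list(right = right, left = left, n_placements = nrow(right)),
            class = "beam_config")
}

#' @export
print.beam_config <- function(x, ...) {
  fmt <- function(m) paste(sprintf("(w=%d, d=%d)", m[, 1], m[, 2]),
                           collapse = " + ")
  cat("Balance-beam configuration\n")
  cat("  left : ", fmt(x$left), "\n", sep = "")
  cat("  right: ", fmt(x$right), "\n", sep = "")
  cat("  torque outcome: ", torque_outcome(x), "\n", sep = "")
  invisible(x)
}

# vectorised torque comparison on an encoded matrix (4 or 8 columns)
.torque_sign <- function(m) {
  r <- m[, 1] * m[, 3]
  l <- m[, 2] * m[, 4]
  if (ncol(m) == 8L) {
    r <- r + m[, 5] * m[, 7]
    l <- l + m[, 6] * m[, 8]
  }
  sign(r - l)
}

.sum_sign <- function(m) {
  sign((m[, 1] + m[, 3]) - (m[, 2] + m[, 4]))
}

.sign_to_outcome <- function(s) {
  .outcome_levels[s + 2L]
}

#' Outcome of a configuration under the torque rule
#'
#' The ground-truth physics: the side with the larger total torque
#' (sum of weight times distance over its placements) falls.
#'
#' @param config a \code{\link{beam_config}}.
#' @return One of \code{"fall_left"}, \code{"balance"}, \code{"fall_right"}.
#' @export
#' @examples
#' torque_outcome(beam_config(right = c(4, 2), left = c(2, 3))) # 8 vs 6
torque_outcome <- function(config) {
  stopifnot(inherits(config, "beam_config"))
  r <- sum(config$right[, 1] * config$right[, 2])
  l <- sum(config$left[, 1] * config$left[, 2])
  .sign_to_outcome(sign(r - l))
}

#' Outcome of a configuration under the additive (sum) rule
#'
#' Compares weight + distance across sides. This heuristic is only correct on
#' abstract-stage-10 configurations; its disagreement with the torque rule is
#' what defines formal-stage-11 membership. It is undefined for two-placement
#' configurations.
#'
#' @inheritParams torque_outcome
#' @return One of \code{"fall_left"}, \code{"balance"}, \code{"fall_right"}.
#' @export
sum_rule_outcome <- function(config) {
  stopifnot(inherits(config, "beam_config"))
  if (config$n_placements != 1L)
    stop("the sum rule is only defined for single-placement configurations",
         call. = FALSE)
  r <- config$right[1, 1] + config$right[1, 2]
  l <- config$left[1, 1] + config$left[1, 2]
  .sign_to_outcome(sign(r - l))
}

# vectorised classifier on an encoded matrix; returns character labels
.classify_rows <- function(m) {
  out <- character(nrow(m))
  two <- if (ncol(m) == 8L) m[, 5] > 0L & m[, 6] > 0L else rep(FALSE, nrow(m))
  out[two] <- "systematic12"
  s1 <- !two
  w_eq <- m[, 1] == m[, 2]
  d_eq <- m[, 3] == m[, 4]
  ts <- .torque_sign(m)
  ss <- .sum_sign(m)
  # all-equal ties are counting problems: assigned to the weight variant
  out[s1 & d_eq] <- "concrete9_weight"
  out[s1 & w_eq & !d_eq] <- "concrete9_distance"
  both <- s1 & !w_eq & !d_eq
  out[both & ss == ts] <- "abstract10"
  out[both & ss != ts] <- "formal11"
  out
}

#' Classify a configuration by order of hierarchical complexity
#'
#' Membership rules: \code{concrete9_weight} when distances are equal across
#' sides (including the fully symmetric tie), \code{concrete9_distance} when
#' weights are equal and distances differ, \code{abstract10} when both
#' dimensions differ and the sum rule agrees with the torque rule,
#' \code{formal11} when both differ and the rules disagree, and
#' \code{systematic12} for two-placement configurations. The five classes
#' partition the configuration space.
#'
#' @inheritParams torque_outcome
#' @return One of \code{\link{ohc_labels}}.
#' @export
#' @examples
#' classify_ohc(beam_config(right = c(4, 3), left = c(2, 3))) # concrete9_weight
#' classify_ohc(beam_config(right = c(5, 1), left = c(2, 3))) # formal11
classify_ohc <- function(config) {
  stopifnot(inherits(config, "beam_config"))
  .classify_rows(matrix(encode_config(config, beam_dialect(
    if (config$n_placements == 2L) "B" else "A")), nrow = 1))
}

#' Encode a configuration as a dialect input vector
#'
#' @inheritParams torque_outcome
#' @param dialect a \code{\link{beam_dialect}}.
#' @return Integer vector of length 4 (dialect A) or 8 (dialect B). In
#'   dialect B a single-placement configuration has its second placement
#'   zero-filled.
#' @export
#' @examples
#' encode_config(beam_config(c(4, 2), c(2, 3)), beam_dialect("A"))
encode_config <- function(config, dialect) {
  stopifnot(inherits(config, "beam_config"), inherits(dialect, "beam_dialect"))
  if (dialect$name == "A" && config$n_placements != 1L)
    stop("dialect A cannot encode two-placement configurations",
         call. = FALSE)
  vals <- c(config$right[, 1], config$left[, 1],
            config$right[, 2], config$left[, 2])
  if (any(vals < dialect$value_range[1]) || any(vals > dialect$value_range[2]))
    stop(sprintf("configuration values outside dialect %s range [%d, %d]",
                 dialect$name, dialect$value_range[1], dialect$value_range[2]),
         call. = FALSE)
  v <- c(config$right[1, 1], config$left[1, 1],
         config$right[1, 2], config$left[1, 2])
  if (dialect$name == "A") return(as.integer(v))
  v2 <- if (config$n_placements == 2L) {
    c(config$right[2, 1], config$left[2, 1],
      config$right[2, 2], config$left[2, 2])
  } else {
    c(0L, 0L, 0L, 0L)
  }
  as.integer(c(v, v2))
}

#' Decode an encoded input vector back into a configuration
#'
#' @param x integer vector of length 4 or 8 (zero-filled second placement
#'   allowed in the 8-slot layout).
#' @return A \code{\link{beam_config}}.
#' @export
decode_config <- function(x) {
  stopifnot(length(x) %in% c(4L, 8L))
  right <- rbind(c(x[1], x[3]))
  left <- rbind(c(x[2], x[4]))
  if (length(x) == 8L && any(x[5:8] > 0)) {
    right <- rbind(right, c(x[5], x[7]))
    left <- rbind(left, c(x[6], x[8]))
  }
  beam_config(right = right, left = left)
}

.col_names <- function(vector_length) {
  if (vector_length == 4L) c("w1r", "w1l", "d1r", "d1l")
  else c("w1r", "w1l", "d1r", "d1l", "w2r", "w2l", "d2r", "d2l")
}

#' Enumerate every configuration of one complexity class
#'
#' Exhaustively lists the in-range encoded input vectors whose
#' \code{\link{classify_ohc}} label equals \code{ohc}, in canonical
#' (lexicographic) order. For \code{systematic12} the space is the full
#' two-placement grid of the dialect-B range.
#'
#' @param ohc one of \code{\link{ohc_labels}}.
#' @param dialect a \code{\link{beam_dialect}}.
#' @return Integer matrix, one encoded configuration per row.
#' @export
enumerate_configs <- function(ohc, dialect) {
  ohc <- match.arg(ohc, ohc_labels())
  stopifnot(inherits(dialect, "beam_dialect"))
  if (ohc == "systematic12" && dialect$name != "B")
    stop("systematic-stage-12 problems require dialect B", call. = FALSE)
  rng <- seq.int(dialect$value_range[1], dialect$value_range[2])
  n_slots <- if (ohc == "systematic12") 8L else 4L
  g <- as.matrix(do.call(expand.grid,
                         c(rep(list(rng), n_slots), KEEP.OUT.ATTRS = FALSE)))
  if (ohc == "systematic12") {
    keep <- rep(TRUE, nrow(g))           # full two-placement grid
    m <- g
  } else {
    m <- if (dialect$name == "B") cbind(g, matrix(0L, nrow(g), 4L)) else g
    keep <- .classify_rows(m) == ohc
  }
  m <- m[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  colnames(m) <- .col_names(dialect$vector_length)
  # canonical order: lexicographic over the encoded columns
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}

.one_hot <- function(outcome) {
  y <- matrix(0, length(outcome), 3,
              dimnames = list(NULL, .outcome_levels))
  y[cbind(seq_along(outcome), match(outcome, .outcome_levels))] <- 1
  y
}

#' Generate a labelled, encoded, split subset of one complexity class
#'
#' Draws configurations (exhaustively, or uniformly at random without
#' replacement when per-class quotas are given) from the enumerated space of
#' one OHC class, attaches one-hot torque-rule targets, and partitions the
#' samples into stratified training/validation/test splits (70/15/15).
#'
#' @inheritParams enumerate_configs
#' @param class_counts \code{"all"} to take the full enumeration, a single
#'   number for a balanced per-class quota, or a named vector/list with
#'   entries \code{fall_left}, \code{balance}, \code{fall_right}.
#' @param seed integer seed controlling sampling and the split.
#' @return An object of class \code{ohc_subset}: a list with the encoded
#'   input matrix \code{x}, one-hot target matrix \code{y}, outcome labels,
#'   split assignment, and generation metadata.
#' @export
#' @examples
#' s <- generate_subset("formal11", beam_dialect("B"), seed = 1)
#' table(s$outcome, s$split)
generate_subset <- function(ohc, dialect, class_counts = "all", seed = 1L) {
  ohc <- match.arg(ohc, ohc_labels())
  stopifnot(inherits(dialect, "beam_dialect"))
  pool <- enumerate_configs(ohc, dialect)
  outcome <- .sign_to_outcome(.torque_sign(pool))

  if (identical(class_counts, "all")) {
    take <- seq_len(nrow(pool))
    counts <- table(factor(outcome, levels = .outcome_levels))
  } else {
    if (length(class_counts) == 1L && is.numeric(class_counts)) {
      class_counts <- stats::setNames(rep(as.integer(class_counts), 3),
                                      .outcome_levels)
    }
    class_counts <- unlist(class_counts)
    if (!all(names(class_counts) %in% .outcome_levels))
      stop("class_counts names must be fall_left/balance/fall_right",
           call. = FALSE)
    set.seed(seed)
    take <- integer(0)
    for (cl in names(class_counts)) {
      idx <- which(outcome == cl)
      k <- class_counts[[cl]]
      if (k > length(idx))
        stop(sprintf(
          "requested %d '%s' samples but only %d %s configurations exist",
          k, cl, length(idx), ohc), call. = FALSE)
      take <- c(take, if (k == length(idx)) idx else sample(idx, k))
    }
    take <- sort(take)
    counts <- class_counts
  }

  x <- pool[take, , drop = FALSE]
  outcome <- outcome[take]
  split <- split_subset(outcome, seed = seed, x = x)
  structure(list(
    dialect = dialect, ohc = ohc,
    x = x, y = .one_hot(outcome),
    outcome = factor(outcome, levels = .outcome_levels),
    split = split,
    class_counts = as.integer(table(factor(outcome,
                                           levels = .outcome_levels))),
    seed = as.integer(seed)
  ), class = "ohc_subset")
}

#' @export
print.ohc_subset <- function(x, ...) {
  cat(sprintf("OHC subset: %s, dialect %s, %d samples (seed %d)\n",
              x$ohc, x$dialect$name, nrow(x$x), x$seed))
  print(table(outcome = x$outcome, split = x$split))
  invisible(x)
}

#' Stratified 70/15/15 split with largest-remainder rounding
#'
#' Assigns each sample to training, validation or test, stratified by class.
#' Within each class the per-split sizes are the largest-remainder rounding
#' of the 70/15/15 fractions; remainders are awarded in decreasing order of
#' fractional part with ties broken in split order (train, validation, test).
#' Membership is a function of the sample's content and the seed, not of its
#' position, so permuting the input rows leaves every sample's assignment
#' unchanged.
#'
#' @param outcome character/factor class label per sample.
#' @param seed integer seed.
#' @param x optional encoded input matrix used to order samples canonically;
#'   without it the input order is used as canonical.
#' @param fractions split fractions, default \code{c(0.70, 0.15, 0.15)}.
#' @return Factor with levels \code{train}, \code{validation}, \code{test}.
#' @export
split_subset <- function(outcome, seed = 1L, x = NULL,
                         fractions = c(train = 0.70, validation = 0.15,
                                       test = 0.15)) {
  n <- length(outcome)
  if (n < 3L) stop("need at least 3 samples to split", call. = FALSE)
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  split_names <- c("train", "validation", "test")
  out <- character(n)
  canon <- if (is.null(x)) seq_len(n) else do.call(order, as.data.frame(x))
  set.seed(seed)
  # classes visited in a fixed order so the RNG stream is independent of the
  # input row order
  for (cl in sort(unique(as.character(outcome)))) {
    idx <- canon[as.character(outcome)[canon] == cl]
    k <- length(idx)
    if (k < 3L) {
      warning(sprintf(
        "class '%s' has only %d sample(s); placing all in the training set",
        cl, k))
      out[idx] <- "train"
      next
    }
    quota <- k * fractions
    sizes <- floor(quota)
    rem <- k - sum(sizes)
    if (rem > 0) {
      frac <- quota - sizes
      award <- order(-frac, seq_along(frac))[seq_len(rem)]
      sizes[award] <- sizes[award] + 1
    }
    perm <- idx[sample.int(k)]
    out[perm] <- rep(split_names, times = sizes)
  }
  factor(out, levels = split_names)
}

#' Mirror a configuration left-right
#'
#' Swapping the two sides maps fall_left to fall_right (and back), preserves
#' balance, and preserves the OHC class.
#' @inheritParams torque_outcome
#' @return A \code{\link{beam_config}}.
#' @export
mirror_config <- function(config) {
  beam_config(right = config$left, left = config$right)
}

#' Write / read a subset as delimited text with a metadata sidecar
#'
#' One row per sample: input columns, the three one-hot target columns, the
#' outcome label and the split tag, as tab-separated text. Generation
#' metadata (dialect, ranges, seed, class counts) goes to \code{<path>.meta.yml}.
#'
#' @param subset an \code{ohc_subset}.
#' @param path file path for the TSV table.
#' @return \code{write_subset} returns \code{path} invisibly;
#'   \code{read_subset} returns the reconstructed \code{ohc_subset}.
#' @export
write_subset <- function(subset, path) {
  stopifnot(inherits(subset, "ohc_subset"))
  df <- data.frame(subset$x,
                   t_fall_left = subset$y[, 1], t_balance = subset$y[, 2],
                   t_fall_right = subset$y[, 3],
                   outcome = as.character(subset$outcome),
                   split = as.character(subset$split))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(ohc = subset$ohc, dialect = subset$dialect$name,
               vector_length = subset$dialect$vector_length,
               value_range = as.integer(subset$dialect$value_range),
               seed = subset$seed,
               class_counts = stats::setNames(as.list(subset$class_counts),
                                              .outcome_levels))
  yaml::write_yaml(meta, paste0(path, ".meta.yml"))
  invisible(path)
}

#' @rdname write_subset
#' @export
read_subset <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  meta <- yaml::read_yaml(paste0(path, ".meta.yml"))
  dialect <- beam_dialect(meta$dialect)
  xcols <- .col_names(dialect$vector_length)
  x <- as.matrix(df[, xcols])
  storage.mode(x) <- "integer"
  structure(list(
    dialect = dialect, ohc = meta$ohc, x = x,
    y = as.matrix(df[, c("t_fall_left", "t_balance", "t_fall_right")],
                  dimnames = list(NULL, .outcome_levels)),
    outcome = factor(df$outcome, levels = .outcome_levels),
    split = factor(df$split, levels = c("train", "validation", "test")),
    class_counts = as.integer(unlist(meta$class_counts)),
    seed = as.integer(meta$seed)
  ), class = "ohc_subset")
}
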