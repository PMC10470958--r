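#' Heuristic cap on hidden units
#'
#' \eqn{N_{hu} = N_s / (p (N_i + N_o))} rounded to the nearest integer: a
#' rule of thumb bounding layer width by the number of training samples per
#' weight, with scaling factor \code{p} (usually between 2 and 10; default 7).
#'
#' @param n_samples training-set size \eqn{N_s}.
#' @param n_inputs,n_outputs input and output unit counts.
#' @param p scaling factor.
#' @return Integer unit cap.
#' @export
#' @examples
#' heuristic_max_units(980, 4, 3) # 20
heuristic_max_units <- function(n_samples, n_inputs, n_outputs, p = 7) {
  stopifnot(n_samples > 0, n_inputs > 0, n_outputs > 0, p > 0)
  as.integer(round(n_samples / (p * (n_inputs + n_outputs))))
}

#' Inverse efficiency of a trained structure
#'
#' \eqn{EF = e_m^{1.5} / N_c}: the mean error count, overweighted by the
#' exponent 1.5 so that eliminating errors is rewarded more than saving
#' connections, per connection. Lower is better; 0 means a perfect network.
#' \code{reciprocal = TRUE} gives the alternative reading
#' \eqn{1 / (N_c\, e_m^{1.5})}.
#'
#' @param e_m mean number of wrong predictions over trials.
#' @param n_c connection count of the structure.
#' @param reciprocal use the reciprocal reading.
#' @return Numeric efficiency value.
#' @export
#' @examples
#' efficiency(4, 8) # 1
efficiency <- function(e_m, n_c, reciprocal = FALSE) {
  stopifnot(n_c > 0, all(e_m >= 0))
  if (reciprocal) ifelse(e_m == 0, Inf, 1 / (n_c * e_m^1.5))
  else e_m^1.5 / n_c
}

#' Efficiency differences along a growth series
#'
#' \eqn{Diff_{EF} = EF_u - EF_{u-1}} within one series of structures that
#' differ by one unit in the last internal layer. The first structure of a
#' series has no predecessor and gets \code{NA}. Most-negative values mark
#' the growth steps that buy the largest error reduction per connection.
#'
#' @param ef numeric vector of efficiency values in growth order.
#' @param series optional grouping vector; differences are taken within
#'   groups (e.g. per internal-layer width in a two-layer grid).
#' @return Numeric vector, \code{NA} at each series head.
#' @export
diff_efficiency <- function(ef, series = NULL) {
  if (is.null(series)) series <- rep(1L, length(ef))
  out <- rep(NA_real_, length(ef))
  for (g in unique(series)) {
    i <- which(series == g)
    if (length(i) > 1) out[i[-1]] <- diff(ef[i])
  }
  out
}

#' Train one architecture over repeated trials
#'
#' Runs the 20-trial protocol (trial seeds = base seed + trial index) and
#' summarizes: mean and sd of accuracy, maximum accuracy, mean error count,
#' connection count. Trials whose loss diverges are recorded and excluded
#' from the means.
#'
#' @param spec a \code{\link{network_spec}}.
#' @param subset an \code{ohc_subset}.
#' @param trials number of repeated trainings.
#' @param config a \code{\link{train_config}}.
#' @param seed base seed.
#' @param basis accuracy basis: \code{"full"} (default) or \code{"test"}.
#' @return A one-row data.frame of structure metrics (class
#'   \code{structure_metrics}) with the per-trial accuracies as an attribute.
#' @export
evaluate_structure <- function(spec, subset, trials = 20L,
                               config = train_config(), seed = 1L,
                               basis = c("full", "test")) {
  basis <- match.arg(basis)
  n_basis <- if (basis == "full") nrow(subset$x) else sum(subset$split == "test")
  acc <- rep(NA_real_, trials)
  failed <- 0L
  for (k in seq_len(trials)) {
    res <- train_network(spec, subset, config = config, seed = seed + k)
    if (res$stop_reason == "diverged") {
      failed <- failed + 1L
    } else {
      acc[k] <- res$accuracy[[basis]]
    }
  }
  ok <- acc[!is.na(acc)]
  e_m <- mean((1 - ok) * n_basis)
  n_c <- count_connections(spec)
  out <- data.frame(
    pattern = spec$pattern$id,
    units_internal = spec$units_internal,
    units_hidden = spec$units_hidden,
    n_c = n_c,
    a_m = mean(ok), a_sd = stats::sd(ok),
    max_ac = max(ok),
    e_m = e_m,
    ef = efficiency(e_m, n_c),
    n_trials = trials, n_failed = failed,
    stringsAsFactors = FALSE)
  attr(out, "trial_accuracy") <- acc
  class(out) <- c("structure_metrics", class(out))
  out
}

#' Systematic structure-growth search
#'
#' For each connectivity pattern: one-layer structures with 1 to
#' \code{max_units} internal units are trained over the trial protocol in
#' growth order; if any trial of a structure reaches 100\% accuracy the
#' search for that pattern stops there (no larger structure is tested).
#' Otherwise the two-layer grid follows (internal units outer, hidden units
#' inner loop), with the same early stop per inner series when
#' \code{early_stop = TRUE}. One-layer patterns (\code{net1}, \code{net2})
#' have no two-layer phase and vice versa.
#'
#' @param subset an \code{ohc_subset}.
#' @param patterns character vector of pattern ids to search.
#' @param trials trials per structure.
#' @param max_units unit cap per layer.
#' @param config a \code{\link{train_config}}.
#' @param seed base seed.
#' @param early_stop stop growing once a structure reaches 100\%.
#' @param basis accuracy basis passed to \code{\link{evaluate_structure}}.
#' @return Object of class \code{search_report}: a data.frame with one row
#'   per trained structure (columns as \code{\link{evaluate_structure}} plus
#'   \code{diff_ef}), with the stop condition (\code{"reached_100"} or
#'   \code{"grid_exhausted"}) per pattern as an attribute.
#' @export
grow_search <- function(subset, patterns = "net1", trials = 20L,
                        max_units = 20L, config = train_config(), seed = 1L,
                        early_stop = TRUE, basis = "full") {
  rows <- list()
  stop_condition <- character(0)
  for (pid in patterns) {
    pat <- connectivity_pattern(pid)
    one_layer <- !("L2" %in% pat$layers)
    reached <- FALSE
    if (one_layer) {
      for (u in seq_len(max_units)) {
        spec <- network_spec(ncol(subset$x), u, 0L, pat)
        m <- evaluate_structure(spec, subset, trials, config, seed, basis)
        m$series <- paste0(pid, "-1layer")
        rows[[length(rows) + 1L]] <- m
        if (early_stop && m$max_ac >= 1) { reached <- TRUE; break }
      }
    } else {
      for (ui in seq_len(max_units)) {
        for (uh in seq_len(max_units)) {
          spec <- network_spec(ncol(subset$x), ui, uh, pat)
          m <- evaluate_structure(spec, subset, trials, config, seed, basis)
          m$series <- sprintf("%s-2layer-i%02d", pid, ui)
          rows[[length(rows) + 1L]] <- m
          if (early_stop && m$max_ac >= 1) { reached <- TRUE; break }
        }
        if (reached) break
      }
    }
    stop_condition[pid] <- if (reached) "reached_100" else "grid_exhausted"
  }
  report <- do.call(rbind, lapply(rows, function(r) {
    attr(r, "trial_accuracy") <- NULL
    class(r) <- "data.frame"
    r
  }))
  report$diff_ef <- diff_efficiency(report$ef, report$series)
  attr(report, "stop_condition") <- stop_condition
  attr(report, "seed") <- seed
  class(report) <- c("search_report", class(report))
  report
}

#' Select candidate structures from a search report
#'
#' Accuracy prevails over efficiency: if any structure reached 100\%
#' maximum accuracy, the smallest such structure (fewest connections) per
#' layer-count family is selected. Otherwise candidates are the structures
#' with the most negative efficiency differences, keeping only those within
#' the same order of magnitude (same power of ten) as the most negative one,
#' per family.
#'
#' @param report a \code{search_report}.
#' @return Subset of the report rows, most promising first.
#' @export
select_best <- function(report) {
  stopifnot(nrow(report) > 0)
  fam <- ifelse(report$units_hidden == 0, "one_layer", "hidden_layer")
  perfect <- report$max_ac >= 1
  if (any(perfect)) {
    picked <- do.call(rbind, lapply(split(report[perfect, , drop = FALSE],
                                          fam[perfect]), function(d) {
      d[order(d$n_c), , drop = FALSE][1, , drop = FALSE]
    }))
    rownames(picked) <- NULL
    return(picked)
  }
  neg <- report[!is.na(report$diff_ef) & report$diff_ef < 0, , drop = FALSE]
  if (nrow(neg) == 0) return(report[order(report$ef), , drop = FALSE][1, ])
  fam_neg <- ifelse(neg$units_hidden == 0, "one_layer", "hidden_layer")
  picked <- do.call(rbind, lapply(split(neg, fam_neg), function(d) {
    d <- d[order(d$diff_ef), , drop = FALSE]
    mag <- floor(log10(-d$diff_ef))
    d[mag == mag[1], , drop = FALSE]
  }))
  rownames(picked) <- NULL
  picked[order(picked$diff_ef), , drop = FALSE]
}

#' Write a search report with metadata sidecar
#'
#' Delimited text mirroring the summary-table layout (efficiency
#' difference, unit counts, connections, mean accuracy with sd, maximum
#' accuracy) plus a structured-text sidecar with subset identity, seeds and
#' stop conditions.
#'
#' @param report a \code{search_report}.
#' @param subset the \code{ohc_subset} it was computed on.
#' @param path file path for the TSV table.
#' @export
write_search_report <- function(report, subset, path) {
  df <- data.frame(
    pattern = report$pattern,
    diff_ef = report$diff_ef,
    units_internal = report$units_internal,
    units_hidden = report$units_hidden,
    n_connections = report$n_c,
    mean_accuracy_pct = round(100 * report$a_m, 2),
    sd_accuracy_pct = round(100 * report$a_sd, 2),
    max_accuracy_pct = round(100 * report$max_ac, 2))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(ohc = subset$ohc, dialect = subset$dialect$name,
               n_samples = nrow(subset$x),
               subset_hash = rlang::hash(subset$x),
               seed = attr(report, "seed"),
               stop_condition = as.list(attr(report, "stop_condition")))
  yaml::write_yaml(meta, paste0(path, ".meta.yml"))
  invisible(path)
}
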