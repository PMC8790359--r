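# Rank-based prevalence classification of conditions between two corpora.
#
# Conditions are ranked by frequency separately in each corpus (rank 1 =
# most frequent; the higher the rank, the less prevalent).  An ordinary
# least-squares line of dream rank on waking rank is fitted to the
# conditions present in both corpora; conditions whose residual deviates
# from the mean residual by at least k_sigma standard deviations are
# peeled off (positive residual -> rarer in dreams than the trend
# predicts -> typical of waking discussions; negative -> typical of
# dreams) and the line is refitted on the remainder, until an iteration
# removes nothing.  Conditions absent from one corpus are assigned to the
# class typical of the other corpus.

CONDITION_CLASSES <- c("TYPICAL_WAKING", "EQUAL", "TYPICAL_DREAM")

#' Count condition frequencies
#'
#' For a mention table (data frame with a `condition` column) counts raw
#' mentions; for a list of reports counts the number of reports
#' containing each condition (per-report presence, not multiplicity).
#'
#' @param x A mention data frame or a list of character vectors
#'   (report condition sets).
#' @return Named integer vector of counts.
#' @export
count_frequencies <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) == 0) stop("empty mention table", call. = FALSE)
    tab <- table(x$condition)
  } else if (is.list(x)) {
    if (length(x) == 0) stop("empty report list", call. = FALSE)
    tab <- table(unlist(lapply(x, unique), use.names = FALSE))
  } else {
    stop("`x` must be a mention data frame or a list of reports",
         call. = FALSE)
  }
  if (length(tab) == 0) stop("no conditions found in input", call. = FALSE)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Fractional ranks by descending frequency
#'
#' Rank 1 is the most frequent condition; tied counts share the mean of
#' the positions they span (fractional / average ranking), which keeps
#' the downstream regression deterministic.
#'
#' @param counts Named vector (or table) of positive counts.
#' @return Named numeric vector of fractional ranks.
#' @export
rank_conditions <- function(counts) {
  counts <- as_named_counts(counts)
  if (length(counts) == 0) stop("empty count table", call. = FALSE)
  if (any(counts < 1)) {
    stop("ranks are defined only for conditions with count >= 1",
         call. = FALSE)
  }
  r <- rank(-as.numeric(counts), ties.method = "average")
  names(r) <- names(counts)
  r
}

#' Iterative residual-threshold classification on rank pairs
#'
#' Lower-level interface to the regression loop of
#' [classify_conditions()]: takes precomputed rank vectors instead of
#' counts.  Only conditions named in both vectors are classified (the
#' absent-condition rule lives in [classify_conditions()]).
#'
#' @param rank_waking,rank_dreams Named numeric rank vectors.
#' @param k_sigma Residual threshold in standard deviations.
#' @return List with `class` (named labels), `iterations` (trace) and
#'   `coefficients` (last fitted line).
#' @export
classify_ranks <- function(rank_waking, rank_dreams, k_sigma = 1.5) {
  k_sigma <- check_positive_real(k_sigma, "k_sigma")
  conds <- intersect(names(rank_waking), names(rank_dreams))
  rw <- as.numeric(rank_waking[conds])
  rd <- as.numeric(rank_dreams[conds])
  cls <- stats::setNames(rep(NA_character_, length(conds)), conds)
  iterations <- list()
  active <- seq_along(conds)
  coefs <- c(intercept = NA_real_, slope = NA_real_)

  repeat {
    if (length(active) < 3) {
      cls[conds[active]] <- "EQUAL"
      break
    }
    x <- rw[active]
    y <- rd[active]
    if (stats::var(x) == 0) {
      co <- c(mean(y), 0)
    } else {
      fit <- stats::lm.fit(cbind(1, x), y)
      co <- as.numeric(fit$coefficients)
    }
    coefs <- c(intercept = co[1], slope = co[2])
    res <- y - (co[1] + co[2] * x)
    mu <- mean(res)
    sigma <- stats::sd(res)
    if (!is.finite(sigma) || sigma < 1e-12) {
      iterations[[length(iterations) + 1L]] <- list(
        slope = co[2], intercept = co[1], mu = mu, sigma = max(sigma, 0),
        removed_waking = character(0), removed_dreams = character(0),
        n_remaining = length(active))
      cls[conds[active]] <- "EQUAL"
      break
    }
    hi <- res - mu >= k_sigma * sigma   # rarer in dreams than predicted
    lo <- res - mu <= -k_sigma * sigma  # rarer in waking than predicted
    cls[conds[active[hi]]] <- "TYPICAL_WAKING"
    cls[conds[active[lo]]] <- "TYPICAL_DREAM"
    removed <- hi | lo
    iterations[[length(iterations) + 1L]] <- list(
      slope = co[2], intercept = co[1], mu = mu, sigma = sigma,
      removed_waking = conds[active[hi]],
      removed_dreams = conds[active[lo]],
      n_remaining = sum(!removed))
    if (!any(removed)) {
      cls[conds[active]] <- "EQUAL"
      break
    }
    active <- active[!removed]
  }
  list(class = cls, iterations = iterations, coefficients = coefs)
}

#' Classify conditions by relative rank prevalence in two corpora
#'
#' The central fitting function.  Takes per-condition frequency counts
#' for the two corpora (see [count_frequencies()]), ranks each corpus
#' separately by descending frequency ([rank_conditions()]), and
#' partitions conditions into three classes:
#'
#' * conditions absent from one corpus are assigned to the class typical
#'   of the other corpus (`waking_only` -> `TYPICAL_WAKING`,
#'   `dream_only` -> `TYPICAL_DREAM`);
#' * conditions present in both corpora are classified by iteratively
#'   fitting dream rank against waking rank by ordinary least squares
#'   and peeling off conditions whose residual `res` satisfies
#'   `res - mu >= k_sigma * sigma` (`TYPICAL_WAKING`) or
#'   `res - mu <= -k_sigma * sigma` (`TYPICAL_DREAM`), where `mu` and
#'   `sigma` are the mean and standard deviation of the residuals of the
#'   surviving points, refitting until an iteration removes nothing;
#'   the remainder is `EQUAL`.
#'
#' @param waking Named count vector (or table) for the waking corpus.
#' @param dreams Named count vector (or table) for the dream corpus.
#' @param k_sigma Residual threshold in standard deviations (default 1.5).
#' @return An object of class `condition_classification` with components
#'   `table` (condition, counts, ranks, class, provenance), `iterations`
#'   (per-iteration regression trace) and `coefficients` (last fitted
#'   line).
#' @examples
#' waking <- c(fever = 50, cough = 40, flu = 30, rash = 5)
#' dreams <- c(fever = 20, cough = 18, maggots = 7)
#' cl <- classify_conditions(waking, dreams)
#' table(cl$table$class)
#' @export
classify_conditions <- function(waking, dreams, k_sigma = 1.5) {
  cw <- as_named_counts(waking, "waking")
  cd <- as_named_counts(dreams, "dreams")
  cw <- cw[cw > 0]
  cd <- cd[cd > 0]
  if (length(cw) == 0 || length(cd) == 0) {
    stop("each corpus must contain at least one condition", call. = FALSE)
  }
  conds <- sort(union(names(cw), names(cd)))
  in_w <- conds %in% names(cw)
  in_d <- conds %in% names(cd)
  provenance <- ifelse(in_w & in_d, "both_corpora",
                       ifelse(in_w, "waking_only", "dream_only"))
  rank_w <- rank_conditions(cw)
  rank_d <- rank_conditions(cd)

  cls <- stats::setNames(rep(NA_character_, length(conds)), conds)
  cls[provenance == "waking_only"] <- "TYPICAL_WAKING"
  cls[provenance == "dream_only"] <- "TYPICAL_DREAM"

  shared <- conds[provenance == "both_corpora"]
  if (length(shared) < 3) {
    if (length(shared) > 0) {
      warning("fewer than 3 conditions shared between corpora; ",
              "regression skipped, shared conditions labelled EQUAL")
      cls[shared] <- "EQUAL"
    }
    iterations <- list()
    coefs <- c(intercept = NA_real_, slope = NA_real_)
  } else {
    rc <- classify_ranks(rank_w[shared], rank_d[shared], k_sigma)
    cls[names(rc$class)] <- rc$class
    iterations <- rc$iterations
    coefs <- rc$coefficients
  }

  tab <- data.frame(
    condition = conds,
    count_waking = ifelse(in_w, as.integer(cw[conds]), 0L),
    count_dreams = ifelse(in_d, as.integer(cd[conds]), 0L),
    rank_waking = ifelse(in_w, as.numeric(rank_w[conds]), NA_real_),
    rank_dreams = ifelse(in_d, as.numeric(rank_d[conds]), NA_real_),
    class = unname(cls),
    provenance = provenance,
    stringsAsFactors = FALSE)

  structure(list(table = tab, iterations = iterations,
                 coefficients = coefs, k_sigma = k_sigma,
                 call = match.call()),
            class = "condition_classification")
}

#' @export
print.condition_classification <- function(x, ...) {
  counts <- table(factor(x$table$class, levels = CONDITION_CLASSES))
  cat("Condition classification by relative rank prevalence\n")
  cat(sprintf("  %d conditions (%d shared between corpora), k_sigma = %.3g\n",
              nrow(x$table), sum(x$table$provenance == "both_corpora"),
              x$k_sigma))
  cat(sprintf("  TYPICAL_WAKING: %d   EQUAL: %d   TYPICAL_DREAM: %d\n",
              counts[["TYPICAL_WAKING"]], counts[["EQUAL"]],
              counts[["TYPICAL_DREAM"]]))
  cat(sprintf("  regression iterations: %d\n", length(x$iterations)))
  invisible(x)
}

#' @export
summary.condition_classification <- function(object, ...) {
  tab <- object$table
  out <- list(
    n_conditions = nrow(tab),
    class_counts = table(factor(tab$class, levels = CONDITION_CLASSES)),
    provenance_counts = table(tab$provenance),
    class_by_provenance = table(tab$class, tab$provenance),
    n_iterations = length(object$iterations),
    coefficients = object$coefficients,
    k_sigma = object$k_sigma)
  class(out) <- "summary.condition_classification"
  out
}

#' @export
print.summary.condition_classification <- function(x, ...) {
  cat("Condition classification summary\n")
  cat(sprintf("  conditions: %d; k_sigma = %.3g; iterations: %d\n",
              x$n_conditions, x$k_sigma, x$n_iterations))
  cat("  class counts:\n")
  print(x$class_counts)
  cat("  provenance:\n")
  print(x$provenance_counts)
  if (all(is.finite(x$coefficients))) {
    cat(sprintf("  final line: dream_rank = %.4g + %.4g * waking_rank\n",
                x$coefficients[["intercept"]], x$coefficients[["slope"]]))
  }
  invisible(x)
}

#' @export
coef.condition_classification <- function(object, ...) {
  object$coefficients
}

#' @export
fitted.condition_classification <- function(object, ...) {
  tab <- object$table
  shared <- tab$provenance == "both_corpora"
  co <- object$coefficients
  stats::setNames(co[["intercept"]] + co[["slope"]] * tab$rank_waking[shared],
                  tab$condition[shared])
}

#' @export
residuals.condition_classification <- function(object, ...) {
  tab <- object$table
  shared <- tab$provenance == "both_corpora"
  stats::setNames(tab$rank_dreams[shared], tab$condition[shared]) -
    fitted(object)
}

#' Predict dream-corpus rank from waking-corpus rank
#'
#' Applies the final fitted regression line.
#'
#' @param object A `condition_classification`.
#' @param newdata Numeric vector of waking ranks; defaults to the shared
#'   conditions' waking ranks.
#' @param ... Unused.
#' @return Predicted dream ranks.
#' @export
predict.condition_classification <- function(object, newdata = NULL, ...) {
  co <- object$coefficients
  if (is.null(newdata)) return(fitted(object))
  co[["intercept"]] + co[["slope"]] * as.numeric(newdata)
}

#' Rank-rank scatter plot of a classification
#'
#' @param x A `condition_classification`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.condition_classification <- function(x, ...) {
  tab <- x$table[x$table$provenance == "both_corpora", ]
  cols <- c(TYPICAL_WAKING = "forestgreen", EQUAL = "darkorange",
            TYPICAL_DREAM = "steelblue")
  graphics::plot(tab$rank_waking, tab$rank_dreams,
                 col = cols[tab$class], pch = 16,
                 xlab = "rank in waking corpus",
                 ylab = "rank in dream corpus", ...)
  co <- x$coefficients
  if (all(is.finite(co))) {
    graphics::abline(co[["intercept"]], co[["slope"]], lty = 2,
                     col = "grey40")
  }
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 16,
                   bty = "n")
  invisible(x)
}

#' Write a classification table as TSV
#'
#' @param classification A `condition_classification`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(classification, path) {
  utils::write.table(classification$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the regression iteration trace as JSON
#'
#' @param classification A `condition_classification`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_iteration_trace <- function(classification, path) {
  jsonlite::write_json(classification$iterations, path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
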