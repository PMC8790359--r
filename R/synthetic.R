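# Synthetic two-corpus generator with planted prevalence classes and
# planted co-occurrence clusters.  The generator emulates the statistical
# shape of health-mention data: heavy-tailed (Zipfian) condition
# frequencies, conditions confined to a single corpus, rank-displaced
# ("enriched") conditions, and dream reports as small condition sets.

PLANTED_CLASSES <- c("EQUAL", "WAKING_ONLY", "DREAM_ONLY",
                     "TYPICAL_WAKING", "TYPICAL_DREAM")

#' Specification for a synthetic two-corpus experiment
#'
#' Bundles and validates every parameter of the synthetic generator.
#' The five class fractions must sum to one; conditions are apportioned
#' to classes by largest-remainder rounding so class counts sum exactly
#' to `n_conditions`.
#'
#' @param n_conditions Number of distinct conditions in the vocabulary.
#' @param zipf_exponent Decay exponent of the base Zipf frequency law;
#'   base sampling weight of the condition with popularity rank `i` is
#'   `i^-zipf_exponent`.
#' @param n_mentions_waking Number of condition mentions drawn for the
#'   waking corpus.  The default keeps roughly 5.5 mentions per
#'   vocabulary item, the mention-to-vocabulary ratio of a small
#'   health-mention corpus, so that most appearing conditions are rare.
#' @param n_reports Number of dream reports.  The default gives about
#'   2.2 dream mentions per vocabulary item, matching the shape of a
#'   survey-scale dream corpus.
#' @param report_size_mean Mean number of conditions per report; sizes are
#'   drawn as `1 + Poisson(report_size_mean - 1)` (so at least one).
#' @param frac_shared,frac_waking_only,frac_dream_only Fractions of the
#'   vocabulary planted as equally prevalent / present only in the waking
#'   corpus / present only in dream reports.
#' @param frac_waking_enriched,frac_dream_enriched Fractions planted as
#'   typical of waking discussions resp. of dream reports (present in both
#'   corpora, rank-displaced in the other one).
#' @param rank_shift Rank displacement strength for enriched classes: the
#'   sampling weight of an enriched condition in its non-enriched corpus is
#'   divided by `(1 + rank_shift)^zipf_exponent`, which multiplies its
#'   expected rank there by `1 + rank_shift`.
#' @param n_clusters Number of planted co-occurrence clusters.
#' @param within_cluster_prob Probability that a report is drawn from a
#'   single planted cluster rather than from the whole vocabulary.
#' @param seed Integer seed; generation is fully reproducible given the spec.
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_corpora()]
#' @export
synthetic_spec <- function(n_conditions = 500L,
                           zipf_exponent = 1.2,
                           n_mentions_waking = 2766L,
                           n_reports = 833L,
                           report_size_mean = 1.3,
                           frac_shared = 0.40,
                           frac_waking_only = 0.25,
                           frac_dream_only = 0.15,
                           frac_waking_enriched = 0.12,
                           frac_dream_enriched = 0.08,
                           rank_shift = 10,
                           n_clusters = 8L,
                           within_cluster_prob = 0.6,
                           seed = 42L) {
  spec <- list(
    n_conditions = check_count(n_conditions, "n_conditions"),
    zipf_exponent = check_positive_real(zipf_exponent, "zipf_exponent"),
    n_mentions_waking = check_count(n_mentions_waking, "n_mentions_waking"),
    n_reports = check_count(n_reports, "n_reports", min = 0L),
    report_size_mean = check_positive_real(report_size_mean, "report_size_mean"),
    frac_shared = check_unit_interval(frac_shared, "frac_shared"),
    frac_waking_only = check_unit_interval(frac_waking_only, "frac_waking_only"),
    frac_dream_only = check_unit_interval(frac_dream_only, "frac_dream_only"),
    frac_waking_enriched = check_unit_interval(frac_waking_enriched,
                                               "frac_waking_enriched"),
    frac_dream_enriched = check_unit_interval(frac_dream_enriched,
                                              "frac_dream_enriched"),
    rank_shift = check_positive_real(rank_shift, "rank_shift"),
    n_clusters = check_count(n_clusters, "n_clusters"),
    within_cluster_prob = check_unit_interval(within_cluster_prob,
                                              "within_cluster_prob"),
    seed = check_count(seed, "seed", min = -.Machine$integer.max)
  )
  total <- spec$frac_shared + spec$frac_waking_only + spec$frac_dream_only +
    spec$frac_waking_enriched + spec$frac_dream_enriched
  if (abs(total - 1) > 1e-9) {
    stop("class fractions must sum to 1 (got ", format(total), ")",
         call. = FALSE)
  }
  structure(spec, class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic two-corpus spec:\n")
  cat(sprintf("  %d conditions, Zipf exponent %.3g, seed %d\n",
              x$n_conditions, x$zipf_exponent, x$seed))
  cat(sprintf("  waking corpus: %d mentions; dream corpus: %d reports (mean size %.3g)\n",
              x$n_mentions_waking, x$n_reports, x$report_size_mean))
  cat(sprintf("  fractions shared/waking-only/dream-only/waking-enr/dream-enr: %.3g/%.3g/%.3g/%.3g/%.3g\n",
              x$frac_shared, x$frac_waking_only, x$frac_dream_only,
              x$frac_waking_enriched, x$frac_dream_enriched))
  cat(sprintf("  rank shift %.3g; %d clusters, within-cluster prob %.3g\n",
              x$rank_shift, x$n_clusters, x$within_cluster_prob))
  invisible(x)
}

# Largest-remainder apportionment of n items to fractions (exact sum).
largest_remainder <- function(fracs, n) {
  raw <- fracs * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

# Word-like pseudo-medical labels, built from current RNG state.
make_vocabulary <- function(n) {
  roots <- c("cardi", "derm", "gastr", "neur", "pulmon", "arthr", "hepat",
             "nephr", "psych", "oste", "haem", "myel", "angi", "bronch",
             "enter", "cephal", "phleb", "rhin", "ot", "odont", "cyst",
             "laryng", "mening", "thromb", "kerat")
  links <- c("o", "a", "io", "")
  suffixes <- c("algia", "itis", "osis", "pathy", "aemia", "plegia",
                "phobia", "spasm", "oma", "dynia", "rrhoea", "stenosis",
                "trophy", "penia", "megaly", "praxia", "sclerosis",
                "paresis", "ptosis", "lysis")
  pool <- as.vector(outer(as.vector(outer(roots, links, paste0)),
                          suffixes, paste0))
  pool <- unique(tolower(pool))
  if (n <= length(pool)) {
    sample(pool, n)
  } else {
    extra <- sprintf("%s %d",
                     sample(pool, n - length(pool), replace = TRUE),
                     seq_len(n - length(pool)))
    sample(c(pool, extra))
  }
}

#' Generate a deterministic vocabulary of condition labels
#'
#' @param n_conditions Number of unique, lowercase labels to generate.
#' @param seed Integer seed; output is identical across calls with the
#'   same arguments.
#' @return Character vector of `n_conditions` unique lowercase labels.
#' @export
generate_vocabulary <- function(n_conditions, seed) {
  n_conditions <- check_count(n_conditions, "n_conditions")
  with_preserved_seed(seed, make_vocabulary(n_conditions))
}

#' Generate synthetic waking mentions, dream reports and ground truth
#'
#' Draws a waking mention corpus and a list of dream reports over a shared
#' Zipfian vocabulary, with a planted five-class prevalence structure and
#' planted co-occurrence clusters:
#' * base sampling weight of condition `i` is `i^-zipf_exponent`;
#' * `WAKING_ONLY` / `DREAM_ONLY` conditions are excluded from the other
#'   corpus; `EQUAL` conditions have matched weights in both;
#' * `TYPICAL_WAKING` (`TYPICAL_DREAM`) conditions have their dream
#'   (waking) weight divided by `(1 + rank_shift)^zipf_exponent`, which
#'   displaces their expected rank there by a factor `1 + rank_shift`;
#' * each report is a set (no repeats); with probability
#'   `within_cluster_prob` its conditions are drawn from one planted
#'   cluster, otherwise from the whole dream-eligible vocabulary, so
#'   same-cluster pairs co-occur at an elevated rate.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `waking` (data.frame `record_id`, `corpus`,
#'   `condition`), `reports` (named list of character vectors, one set of
#'   conditions per report) and `truth` (data.frame `condition`, `class`,
#'   `cluster` with the planted labels).
#' @export
generate_corpora <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    spec <- do.call(synthetic_spec, as.list(spec))
  }
  with_preserved_seed(spec$seed, {
    n <- spec$n_conditions
    vocab <- make_vocabulary(n)
    class_counts <- largest_remainder(
      c(EQUAL = spec$frac_shared,
        WAKING_ONLY = spec$frac_waking_only,
        DREAM_ONLY = spec$frac_dream_only,
        TYPICAL_WAKING = spec$frac_waking_enriched,
        TYPICAL_DREAM = spec$frac_dream_enriched), n)
    planted <- rep(PLANTED_CLASSES, class_counts)[sample.int(n)]
    cluster <- sample.int(spec$n_clusters, n, replace = TRUE)

    w <- seq_len(n)^(-spec$zipf_exponent)
    suppression <- (1 + spec$rank_shift)^spec$zipf_exponent
    w_wake <- w
    w_dream <- w
    w_wake[planted == "DREAM_ONLY"] <- 0
    w_dream[planted == "WAKING_ONLY"] <- 0
    w_wake[planted == "TYPICAL_DREAM"] <-
      w_wake[planted == "TYPICAL_DREAM"] / suppression
    w_dream[planted == "TYPICAL_WAKING"] <-
      w_dream[planted == "TYPICAL_WAKING"] / suppression

    if (sum(w_wake) > 0) {
      idx <- sample.int(n, spec$n_mentions_waking, replace = TRUE,
                        prob = w_wake)
      waking <- data.frame(
        record_id = sprintf("w%07d", seq_len(spec$n_mentions_waking)),
        corpus = "waking",
        condition = vocab[idx],
        stringsAsFactors = FALSE)
    } else {
      waking <- data.frame(record_id = character(0), corpus = character(0),
                           condition = character(0), stringsAsFactors = FALSE)
    }

    eligible <- which(w_dream > 0)
    cl_weight <- vapply(seq_len(spec$n_clusters),
                        function(k) sum(w_dream[cluster == k & w_dream > 0]),
                        numeric(1))
    sizes <- 1L + stats::rpois(spec$n_reports,
                               max(spec$report_size_mean - 1, 0))
    reports <- vector("list", spec$n_reports)
    for (i in seq_len(spec$n_reports)) {
      pool <- eligible
      if (length(eligible) > 0 && any(cl_weight > 0) &&
          stats::runif(1) < spec$within_cluster_prob) {
        k <- sample.int(spec$n_clusters, 1L, prob = cl_weight)
        pool_k <- eligible[cluster[eligible] == k]
        if (length(pool_k) > 0) pool <- pool_k
      }
      sz <- min(sizes[i], length(pool))
      picked <- if (sz == 0) integer(0)
                else if (length(pool) == 1) pool
                else sample(pool, sz, prob = w_dream[pool])
      reports[[i]] <- sort(vocab[picked])
    }
    names(reports) <- sprintf("d%05d", seq_len(spec$n_reports))

    truth <- data.frame(condition = vocab, class = planted,
                        cluster = cluster, stringsAsFactors = FALSE)
    list(waking = waking, reports = reports, truth = truth)
  })
}

#' Generate null dream reports (no planted structure)
#'
#' Each report is a uniform random subset of fixed size of the vocabulary,
#' independent across reports.  Used as the null model when estimating the
#' type-I error rate of the edge filter.
#'
#' @param n_reports Number of reports (0 allowed).
#' @param n_conditions Vocabulary size.
#' @param report_size Conditions per report; must not exceed `n_conditions`.
#' @param seed Integer seed.
#' @return Named list of character vectors, one per report.
#' @export
generate_null_reports <- function(n_reports, n_conditions, report_size, seed) {
  n_reports <- check_count(n_reports, "n_reports", min = 0L)
  n_conditions <- check_count(n_conditions, "n_conditions")
  report_size <- check_count(report_size, "report_size")
  if (report_size > n_conditions) {
    stop("`report_size` must not exceed `n_conditions`", call. = FALSE)
  }
  with_preserved_seed(seed, {
    vocab <- make_vocabulary(n_conditions)
    reports <- lapply(seq_len(n_reports), function(i) {
      sort(vocab[sample.int(n_conditions, report_size)])
    })
    names(reports) <- sprintf("n%05d", seq_len(n_reports))
    reports
  })
}

#' Write a planted ground-truth table as TSV
#'
#' @param truth Data frame with columns `condition`, `class`, `cluster`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
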