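# Independent oracles used to cross-check the package implementation.
# These deliberately use brute-force / first-principles routes.

# phi as the Pearson correlation of the two presence indicator vectors
# built from the 2x2 contingency cells.
oracle_phi_2x2 <- function(n, p_i, p_j, p_ij) {
  x <- c(rep(1, p_ij), rep(1, p_i - p_ij), rep(0, p_j - p_ij),
         rep(0, n - p_i - p_j + p_ij))
  y <- c(rep(1, p_ij), rep(0, p_i - p_ij), rep(1, p_j - p_ij),
         rep(0, n - p_i - p_j + p_ij))
  suppressWarnings(stats::cor(x, y))
}

# relative risk as observed / expected co-occurrence under independence
oracle_rr_2x2 <- function(n, p_i, p_j, p_ij) {
  p_ij / (p_i * p_j / n)
}

# brute-force pair counting over reports
oracle_pair_counts <- function(reports) {
  reports <- lapply(reports, unique)
  conds <- sort(unique(unlist(reports)))
  P <- sapply(conds, function(cc) sum(vapply(reports, function(r) cc %in% r,
                                             logical(1))))
  pairs <- list()
  for (a in seq_along(conds)) {
    for (b in seq_along(conds)) {
      if (b <= a) next
      cnt <- sum(vapply(reports, function(r) {
        conds[a] %in% r && conds[b] %in% r
      }, logical(1)))
      if (cnt > 0) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          i = conds[a], j = conds[b], p_ij = cnt,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(N = length(reports), P = stats::setNames(as.integer(P), conds),
       pairs = if (length(pairs)) do.call(rbind, pairs)
               else data.frame(i = character(0), j = character(0),
                               p_ij = integer(0)))
}

# power-iteration PageRank with uniform teleport and dangling-mass
# redistribution, on an undirected (optionally weighted) igraph
oracle_pagerank <- function(g, damping = 0.85, weighted = TRUE) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(
    g, attr = if (weighted && "weight" %in% igraph::edge_attr_names(g))
      "weight" else NULL, sparse = FALSE))
  s <- rowSums(A)
  v <- rep(1 / n, n)
  for (iter in 1:10000) {
    inflow <- as.numeric(crossprod(A, ifelse(s > 0, v / s, 0)))
    dangling <- sum(v[s == 0])
    v_new <- (1 - damping) / n + damping * (inflow + dangling / n)
    if (max(abs(v_new - v)) < 1e-14) {
      v <- v_new
      break
    }
    v <- v_new
  }
  stats::setNames(v / sum(v), igraph::V(g)$name)
}

# Newman attribute assortativity from the hand-built class mixing matrix
oracle_assortativity <- function(g, classes) {
  ends <- igraph::ends(g, igraph::E(g), names = TRUE)
  c1 <- classes[ends[, 1]]
  c2 <- classes[ends[, 2]]
  lev <- sort(unique(c(c1, c2)))
  e <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  for (k in seq_along(c1)) {
    e[c1[k], c2[k]] <- e[c1[k], c2[k]] + 1
    e[c2[k], c1[k]] <- e[c2[k], c1[k]] + 1
  }
  e <- e / sum(e)
  ab <- sum(rowSums(e) * colSums(e))
  (sum(diag(e)) - ab) / (1 - ab)
}

# connected components by breadth-first search over an edge data frame
oracle_components <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (k in seq_len(nrow(edges))) {
    adj[[edges$i[k]]] <- c(adj[[edges$i[k]]], edges$j[k])
    adj[[edges$j[k]]] <- c(adj[[edges$j[k]]], edges$i[k])
  }
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  for (v in nodes) {
    if (!is.na(comp[v])) next
    cid <- cid + 1L
    queue <- v
    comp[v] <- cid
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      for (wnb in adj[[u]]) {
        if (is.na(comp[wnb])) {
          comp[wnb] <- cid
          queue <- c(queue, wnb)
        }
      }
    }
  }
  comp
}

# fractional descending ranks via a stable sort with tie-group averaging
oracle_fractional_rank <- function(counts) {
  ord <- order(-counts)
  pos <- seq_along(counts)
  r <- numeric(length(counts))
  sorted <- counts[ord]
  k <- 1
  while (k <= length(sorted)) {
    grp <- which(sorted == sorted[k])
    grp <- grp[grp >= k]
    r[ord[grp]] <- mean(pos[grp])
    k <- max(grp) + 1
  }
  stats::setNames(r, names(counts))
}

# brute-force longest-match lexicon scan with span masking
oracle_lexicon <- function(text, lexicon) {
  txt <- tolower(gsub("[[:space:]]+", " ", trimws(text)))
  chars <- strsplit(txt, "")[[1]]
  masked <- rep(FALSE, length(chars))
  is_word <- function(ch) grepl("[a-z0-9_]", ch)
  found <- character(0)
  for (ph in lexicon[order(-nchar(lexicon), lexicon)]) {
    L <- nchar(ph)
    hit_any <- FALSE
    for (s in seq_len(max(nchar(txt) - L + 1, 0))) {
      span <- s:(s + L - 1)
      if (substr(txt, s, s + L - 1) != ph) next
      if (any(masked[span])) next
      left_ok <- s == 1 || masked[s - 1] || !is_word(chars[s - 1])
      right_ok <- s + L - 1 == length(chars) || masked[s + L] ||
        !is_word(chars[s + L])
      if (left_ok && right_ok) {
        masked[span] <- TRUE
        hit_any <- TRUE
      }
    }
    if (hit_any) found <- c(found, ph)
  }
  sort(found)
}

# largest-remainder apportionment oracle
oracle_apportion <- function(fracs, n) {
  raw <- fracs * n
  base <- floor(raw)
  rem <- raw - base
  need <- n - sum(base)
  if (need > 0) {
    take <- order(rem, decreasing = TRUE)[seq_len(need)]
    base[take] <- base[take] + 1
  }
  base
}

# maps a planted five-way class to the label the classifier should give
planted_to_expected <- function(planted) {
  c(EQUAL = "EQUAL", WAKING_ONLY = "TYPICAL_WAKING",
    DREAM_ONLY = "TYPICAL_DREAM", TYPICAL_WAKING = "TYPICAL_WAKING",
    TYPICAL_DREAM = "TYPICAL_DREAM")[planted]
}

# the strong-separation study regime used for recovery checks: an
# equal/enriched mixture with a large planted rank displacement
strong_separation_spec <- function(seed, n_mentions = 200000L,
                                   n_reports = 20000L) {
  synthetic_spec(
    n_conditions = 300L, zipf_exponent = 1.2,
    n_mentions_waking = n_mentions, n_reports = n_reports,
    report_size_mean = 3, frac_shared = 0.5, frac_waking_only = 0.05,
    frac_dream_only = 0.05, frac_waking_enriched = 0.2,
    frac_dream_enriched = 0.2, rank_shift = 30, seed = seed)
}

# recovery of the three planted shared classes by the classifier
planted_recovery <- function(corpora, classification) {
  truth <- corpora$truth
  got <- stats::setNames(classification$table$class,
                         classification$table$condition)[truth$condition]
  expected <- planted_to_expected(truth$class)
  shared3 <- truth$class %in% c("EQUAL", "TYPICAL_WAKING", "TYPICAL_DREAM")
  list(overall = mean(got[shared3] == expected[shared3], na.rm = TRUE),
       equal = mean(got[truth$class == "EQUAL"] == "EQUAL", na.rm = TRUE),
       enriched = mean(
         got[shared3 & truth$class != "EQUAL"] ==
           expected[shared3 & truth$class != "EQUAL"], na.rm = TRUE))
}
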