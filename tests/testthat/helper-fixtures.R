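# Shared fixture builders; all randomness runs through explicit seeds.

tiny_annotation <- function(seed = 1, ...) {
  generate_genome_annotation(seed = seed, n_chromosomes = 1,
                             chromosome_length = 1e7, n_tads = 10,
                             n_genes = 100, n_cres = 500, ...)
}

# count_matrix from an explicit integer matrix, 2 conditions
cm_from <- function(counts, n_ctrl = ncol(counts) / 2) {
  colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("f", seq_len(nrow(counts)))
  }
  cond <- setNames(rep(c("control", "coculture"),
                       c(n_ctrl, ncol(counts) - n_ctrl)),
                   colnames(counts))
  count_matrix(counts, cond)
}

# simple two-armed survival data with a binary exposure of hazard ratio hr
binary_hazard_cohort <- function(seed, n = 600, hr = 2, p_exposed = 0.3,
                                 censor_frac = 0.3, baseline = 0.02) {
  withr::with_seed(seed, {
    exposed <- stats::rbinom(n, 1, p_exposed)
    t_event <- stats::rexp(n, rate = baseline * hr^exposed)
    if (censor_frac > 0) {
      t_cens <- stats::rexp(n, rate = baseline * censor_frac / (1 - censor_frac))
    } else {
      t_cens <- rep(Inf, n)
    }
    time <- pmax(pmin(t_event, t_cens), 1 / 30)
    event <- as.integer(t_event <= t_cens)
    expr <- matrix(stats::rnorm(2 * n), nrow = 2,
                   dimnames = list(c("gA", "gB"), sprintf("pt%04d", seq_len(n))))
    list(cohort = patient_cohort(expr, time, event),
         labels = factor(ifelse(exposed == 1, "ASI+", "ASI-"),
                         levels = c("ASI-", "ASI+")))
  })
}

# brute-force O(n*m) interval overlap oracle (half-open coordinates)
brute_overlaps <- function(query, database) {
  qid <- if ("id" %in% names(query)) query$id else as.character(seq_len(nrow(query)))
  did <- if ("id" %in% names(database)) database$id else as.character(seq_len(nrow(database)))
  rows <- list()
  for (i in seq_len(nrow(query))) {
    for (j in seq_len(nrow(database))) {
      if (query$chrom[i] != database$chrom[j]) next
      ov <- min(query$end[i], database$end[j]) - max(query$start[i], database$start[j])
      if (ov >= 1) {
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = qid[i], database_id = did[j], overlap_bp = ov,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(query_id = character(0), database_id = character(0),
                      overlap_bp = numeric(0)))
  }
  do.call(rbind, rows)
}

random_regions <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000,
                           max_len = 60, prefix = "r") {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             id = paste0(prefix, seq_len(n)),
             stringsAsFactors = FALSE)
}

# brute-force BH step-up: adj_i = min over j with p_(j) >= p_(i) of p_(j)*n/j
brute_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  stepped <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(stepped)))
  out <- numeric(n)
  out[ord] <- pmin(adj, 1)
  out
}

# brute-force two-sided Fisher p by enumerating tables with fixed margins
brute_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }, numeric(1))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force hypergeometric upper tail by pmf summation
brute_hyper_tail <- function(N, K, n, k) {
  xs <- k:min(K, n)
  sum(vapply(xs, function(x) {
    exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n))
  }, numeric(1)))
}
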