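# Independent brute-force reference implementations used as oracles.

ref_rank <- function(x) rank(x, ties.method = "average")

ref_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

ref_distance <- function(x, y, metric, transform = "log2", pc = 1) {
  if (transform == "log2") { x <- log2(x + pc); y <- log2(y + pc) }
  switch(metric,
    spearman_distance = 1 - ref_pearson(ref_rank(x), ref_rank(y)),
    pearson_distance = 1 - ref_pearson(x, y),
    euclidean = sqrt(sum((x - y)^2)),
    l1 = sum(abs(x - y)))
}

# Benjamini-Hochberg step-up, written out directly
ref_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# Exact two-sided Fisher P by full enumeration of the hypergeometric support
ref_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c_ + d; k <- a + c_
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

ref_tau <- function(x) {
  xhat <- x / max(x)
  sum(1 - xhat) / (length(x) - 1)
}

ref_filter <- function(x, y, min_counts, min_cpm) {
  cx <- x / sum(x) * 1e6
  cy <- y / sum(y) * 1e6
  keep <- logical(length(x))
  for (g in seq_along(x)) {
    drop_counts <- x[g] < min_counts && y[g] < min_counts
    drop_cpm <- cx[g] < min_cpm && cy[g] < min_cpm
    keep[g] <- !(drop_counts || drop_cpm)
  }
  keep
}

# Exhaustive restatement of the representative-iteration rule
ref_representative <- function(rho, p) {
  tol <- 1e-12
  mr <- median(rho); mp <- median(p)
  for (i in seq_along(rho)) {
    if (abs(rho[i] - mr) < tol && abs(p[i] - mp) < tol) return(i)
  }
  d <- abs(rho - mr)
  cand_vals <- unique(rho[abs(d - min(d)) < tol])
  cnt <- sapply(cand_vals, function(v) sum(abs(rho - v) < tol))
  winners <- cand_vals[cnt == max(cnt)]
  for (i in seq_along(rho)) {
    if (any(abs(rho[i] - winners) < tol)) return(i)
  }
  stop("unreachable")
}

# Cross-product reference for expression-matched pairing; mirrors the
# documented procedure (canonical pair order, seeded shuffle, greedy dedup,
# sign balancing) from scratch.
ref_match_pairs <- function(high_genes, other_genes, expression,
                            lfc_threshold, seed) {
  eh <- expression[intersect(high_genes, names(expression))]
  eo <- expression[intersect(other_genes, names(expression))]
  rows <- list()
  for (g1 in names(eh)) for (g2 in names(eo)) {
    lfc <- log2(eh[[g1]] / eo[[g2]])
    if (abs(lfc) < lfc_threshold) {
      rows[[length(rows) + 1]] <- data.frame(
        gene_high = g1, gene_other = g2, lfc = lfc,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  df <- do.call(rbind, rows)
  df <- df[order(df$gene_high, df$gene_other), , drop = FALSE]
  old_seed <- if (exists(".Random.seed", envir = globalenv(),
                         inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  df <- df[sample.int(nrow(df)), , drop = FALSE]
  used <- character(0)
  keep <- logical(nrow(df))
  for (r in seq_len(nrow(df))) {
    if (!(df$gene_high[r] %in% used) && !(df$gene_other[r] %in% used)) {
      keep[r] <- TRUE
      used <- c(used, df$gene_high[r], df$gene_other[r])
    }
  }
  df <- df[keep, , drop = FALSE]
  neg <- df[df$lfc < 0, , drop = FALSE]
  pos <- df[df$lfc > 0, , drop = FALSE]
  zer <- df[df$lfc == 0, , drop = FALSE]
  m <- min(nrow(neg), nrow(pos))
  if (nrow(neg) > m) neg <- neg[sample.int(nrow(neg), m), , drop = FALSE]
  if (nrow(pos) > m) pos <- pos[sample.int(nrow(pos), m), , drop = FALSE]
  out <- rbind(zer, neg, pos)
  rownames(out) <- NULL
  out
}
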